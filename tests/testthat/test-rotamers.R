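test_that("the shipped rotamer library satisfies its invariants", {
  lib <- default_rotamer_library()
  expect_length(lib, 20)
  for (res in names(lib)) {
    p <- lib[[res]]$probability
    expect_true(all(p > 0 & p <= 1))
    expect_lte(sum(p), 1 + 1e-6)
    expect_true(all(diff(p) <= 0))   # sorted by descending probability
    k <- spscore:::n_chi(res)
    if (k > 0) expect_true(all(!is.na(lib[[res]][[paste0("chi", k)]])))
  }
  expect_equal(nrow(lib$ALA), 1)
  expect_equal(nrow(lib$GLY), 1)
  expect_true(all(is.na(unlist(lib$GLY[, 1:4]))))
})

test_that("malformed rotamer libraries are rejected", {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(residue = "SER", chi1 = -65, chi2 = NA, chi3 = NA, chi4 = NA,
               probability = 1.2),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_rotamer_library(f), "probabilities")
  utils::write.table(
    data.frame(residue = c("SER", "SER"), chi1 = c(-65, 62), chi2 = NA,
               chi3 = NA, chi4 = NA, probability = c(0.7, 0.7)),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_rotamer_library(f), "sum")
})

test_that("rotamer placement is deterministic and respects the probability filter", {
  ctx <- fixture_ctx(20)
  lib <- default_rotamer_library()
  v <- parse_variant("A10M")
  r1 <- place_rotamers(ctx, v, lib)
  r2 <- place_rotamers(ctx, v, lib)
  expect_identical(r1, r2)
  expect_length(r1, nrow(lib$MET))                       # min_prob 0: all
  expect_length(place_rotamers(ctx, v, lib, min_prob = 0.1), 4)
  p <- vapply(r1, function(r) r$probability, numeric(1))
  expect_true(all(diff(p) <= 0))
  # glycine mutant: one trivial rotamer with an empty side chain
  g <- place_rotamers(ctx, parse_variant("A10G"), lib)
  expect_length(g, 1)
  expect_equal(nrow(g[[1]]$atoms), 0)
  expect_equal(g[[1]]$probability, 1)
})

test_that("constructed side chains obey ideal internal geometry", {
  ctx <- fixture_ctx(20)
  lib <- default_rotamer_library()
  for (mut in c("M", "W", "R", "V")) {
    rot <- place_rotamers(ctx, parse_variant(paste0("A10", mut)), lib)[[1]]
    res3 <- AA_CODES[[mut]]
    tp <- spscore:::sidechain_topology()[[res3]]
    coords <- c(rot$anchors,
                stats::setNames(
                  lapply(seq_len(nrow(rot$atoms)),
                         function(i) as.numeric(rot$atoms[i, c("x", "y", "z")])),
                  rot$atoms$name))
    for (i in seq_len(nrow(tp))) {
      row <- tp[i, ]
      d <- sqrt(sum((coords[[row$name]] - coords[[row$c]])^2))
      expect_lt(abs(d - row$bond), 0.05)
      ang <- spscore:::bond_angle(coords[[row$b]], coords[[row$c]],
                                  coords[[row$name]])
      expect_lt(abs(ang - row$angle), 3)
    }
    # chi angles measured back from coordinates match the library request
    ax <- spscore:::chi_axes(res3)
    tp1 <- tp[!is.na(tp$chi) & tp$off == 0, ]
    for (k in seq_along(rot$chi)) {
      abc <- c(list(coords[[tp1$a[tp1$chi == k]]], coords[[tp1$b[tp1$chi == k]]],
                    coords[[tp1$c[tp1$chi == k]]]),
               list(coords[[tp1$name[tp1$chi == k]]]))
      got <- do.call(spscore:::dihedral_angle, abc)
      expect_lt(abs(((got - rot$chi[k] + 180) %% 360) - 180), 1e-6)
    }
  }
})

test_that("a glycine wild-type gets a reconstructed CB with a warning", {
  ctx <- fixture_ctx(15, sequence = c(rep("A", 7), "G", rep("A", 7)), seed = 3)
  expect_warning(
    rots <- place_rotamers(ctx, parse_variant("G8S"), default_rotamer_library()),
    "reconstructed"
  )
  expect_gt(length(rots), 0)
  expect_equal(rots[[1]]$atoms$name, "OG")
})

test_that("clash arithmetic matches the overlap criterion literally", {
  # two carbons (r = 1.70 each) at 2.0 A: overlap 1.40 >= 0.60 -> clash
  ctx <- fake_ctx(atom_row("CB", "C", 2, 0, 0, 1.70))
  rot <- fake_rotamer(data.frame(name = "CG", elesy = "C", x = 0, y = 0, z = 0,
                                 radius = 1.70, stringsAsFactors = FALSE))
  cl <- detect_clashes(ctx, rot)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$overlap, 1.40)
  # same atoms at 3.40 A: overlap 0 -> no clash
  ctx2 <- fake_ctx(atom_row("CB", "C", 3.40, 0, 0, 1.70))
  expect_equal(nrow(detect_clashes(ctx2, rot)), 0)
  # polar pair: N vs O, raw overlap 0.80, allowance 0.40 -> 0.40 < 0.60
  ctxNO <- fake_ctx(atom_row("O", "O", 1.55 + 1.52 - 0.80, 0, 0, 1.52))
  rotN <- fake_rotamer(data.frame(name = "ND2", elesy = "N", x = 0, y = 0,
                                  z = 0, radius = 1.55, stringsAsFactors = FALSE))
  expect_equal(nrow(detect_clashes(ctxNO, rotN)), 0)
  # same geometry without the allowance (C vs C radii tuned): clash stands
  cfg0 <- sps_config(overrides = list(clash = list(hbond_allowance = 0)))
  expect_equal(nrow(detect_clashes(ctxNO, rotN, cfg0)), 1)
})

test_that("clash detection equals the brute-force all-pairs oracle on seeded fixtures", {
  lib <- default_rotamer_library()
  cfg <- sps_config()
  aa <- setdiff(names(AA_CODES), c("G", "P"))
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(6:12, 1)
    seqs <- sample(c("A", "A", "L", "F", "K"), n, replace = TRUE)
    ctx <- fixture_ctx(n, sequence = seqs, seed = seed)
    pos <- sample(2:(n - 1), 1)
    mut <- sample(setdiff(aa, seqs[pos]), 1)
    v <- parse_variant(paste0(seqs[pos], pos, mut))
    rots <- place_rotamers(ctx, v, lib)
    ri <- sample(length(rots), 1)
    got <- detect_clashes(ctx, rots[[ri]], cfg)
    expect_identical(clash_keys(got),
                     bf_overlaps(ctx, rots[[ri]], cfg$clash$overlap_cutoff,
                                 cfg$clash$hbond_allowance))
  }
})

test_that("a clash-free rotamer passes through relief unchanged", {
  ctx <- fixture_ctx(20)
  v <- parse_variant("A2S")   # terminal, exposed
  rot <- place_rotamers(ctx, v, default_rotamer_library())[[1]]
  expect_equal(nrow(detect_clashes(ctx, rot)), 0)
  rel <- relieve_clashes(ctx, rot)
  expect_true(rel$relieved)
  expect_identical(rel$atoms, rot$atoms)
})

test_that("relief succeeds exactly where an exhaustive chi-grid finds a clash-free state", {
  lib <- default_rotamer_library()
  cfg <- sps_config()
  # helix case: clashing tryptophan rotamer, grid search knows escape exists
  ctx <- fixture_ctx(20)
  v <- parse_variant("A9W")
  rots <- place_rotamers(ctx, v, lib)
  ncl <- vapply(rots, function(r) nrow(detect_clashes(ctx, r)), integer(1))
  ri <- which(ncl > 0)[1]
  expect_false(is.na(ri))
  expect_true(spscore:::chi_grid_has_clash_free(ctx, v, cfg))
  rel <- relieve_clashes(ctx, rots[[ri]], cfg)
  expect_true(rel$relieved)
  expect_equal(nrow(rel$clashes_after), 0)
  # cavity case: grid search proves no escape; relief must fail
  cctx <- fixture_ctx(11, geometry = "cavity", site = 6, mutation = "W", seed = 2)
  vw <- parse_variant("A6W")
  expect_false(spscore:::chi_grid_has_clash_free(cctx, vw, cfg, step = 60))
  crots <- place_rotamers(cctx, vw, lib)
  crel <- relieve_clashes(cctx, crots[[1]], cfg)
  expect_false(crel$relieved)
  expect_gt(nrow(crel$clashes_after), 0)
})

test_that("score D is 0 on exposed sites, 1 in the cavity, and within [0,1] elsewhere", {
  lib <- default_rotamer_library()
  ctx <- fixture_ctx(20)
  expect_equal(as.numeric(score_D(ctx, parse_variant("A2S"), lib)), 0)
  cctx <- fixture_ctx(11, geometry = "cavity", site = 6, mutation = "W", seed = 2)
  expect_equal(as.numeric(score_D(cctx, parse_variant("A6W"), lib)), 1)
  for (mut in c("M", "F", "K")) {
    d <- as.numeric(score_D(ctx, parse_variant(paste0("A10", mut)), lib))
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("disabling relief never decreases score D", {
  lib <- default_rotamer_library()
  cfg <- sps_config()
  cfg_off <- sps_config(overrides = list(relief = list(enabled = FALSE)))
  ctx <- fixture_ctx(20)
  for (id in c("A9W", "A10F", "A10M", "A2S")) {
    v <- parse_variant(id)
    expect_gte(as.numeric(score_D(ctx, v, lib, cfg_off)),
               as.numeric(score_D(ctx, v, lib, cfg)))
  }
})

test_that("score D is bit-identical across repeated runs", {
  ctx <- fixture_ctx(20)
  v <- parse_variant("A9W")
  d1 <- score_D(ctx, v)
  d2 <- score_D(ctx, v)
  expect_identical(d1, d2)
})
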