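test_that("registry loading validates positions and classes", {
  reg <- toy_registry()
  expect_s3_class(reg, "pathogenic_registry")
  expect_true(all(reg$positions >= 1))
  expect_true(562 %in% reg$positions)
  # position-level counting: H562 appears once despite two substitutions
  expect_equal(sum(reg$positions == 562), 1)
  expect_error(pathogenic_registry(data.frame(position = 10, acmg_class = 3)),
               "must be 4 or 5")
  expect_error(pathogenic_registry(data.frame(position = -1)), ">= 1")
  # position-only rows are fine
  expect_silent(pathogenic_registry(data.frame(position = c(5, 9))))
})

test_that("contact arithmetic follows the near-touching criterion", {
  # two carbons at 3.70 A: overlap -0.30 >= -0.40 -> contact
  ctx <- fake_ctx(atom_row("CB", "C", 3.70, 0, 0, 1.70))
  rot <- fake_rotamer(data.frame(name = "CG", elesy = "C", x = 0, y = 0, z = 0,
                                 radius = 1.70, stringsAsFactors = FALSE))
  cs <- contacts_of(ctx, rot)
  expect_equal(cs$n_total, 1)
  # at 4.20 A: overlap -0.80 < -0.40 -> no contact
  ctx2 <- fake_ctx(atom_row("CB", "C", 4.20, 0, 0, 1.70))
  expect_equal(contacts_of(ctx2, rot)$n_total, 0)
  # the H-bond allowance applies to clashes only, not contacts
  ctxNO <- fake_ctx(atom_row("O", "O", 1.55 + 1.52 + 0.35, 0, 0, 1.52))
  rotN <- fake_rotamer(data.frame(name = "ND2", elesy = "N", x = 0, y = 0,
                                  z = 0, radius = 1.55, stringsAsFactors = FALSE))
  expect_equal(contacts_of(ctxNO, rotN)$n_total, 1)
})

test_that("contact enumeration equals the brute-force oracle on seeded fixtures", {
  lib <- default_rotamer_library()
  cfg <- sps_config()
  aa <- setdiff(names(AA_CODES), c("G", "P"))
  for (seed in 101:200) {
    set.seed(seed)
    n <- sample(6:12, 1)
    seqs <- sample(c("A", "A", "L", "S", "E"), n, replace = TRUE)
    ctx <- fixture_ctx(n, sequence = seqs, seed = seed)
    pos <- sample(2:(n - 1), 1)
    mut <- sample(setdiff(aa, seqs[pos]), 1)
    rots <- place_rotamers(ctx, parse_variant(paste0(seqs[pos], pos, mut)), lib)
    ri <- sample(length(rots), 1)
    got <- contacts_of(ctx, rots[[ri]], cfg = cfg)
    bf <- bf_overlaps(ctx, rots[[ri]], cfg$contact$overlap_cutoff, 0)
    bf_res <- sort(unique(vapply(strsplit(bf, " "),
                                 function(x) paste(x[2], x[3]), character(1))))
    expect_identical(sort(paste(got$contacts$chain, got$contacts$resno)), bf_res)
  }
})

test_that("the hotspot score reproduces its published worked example", {
  # two rotamers: p = 0.2075 with 1 pathogenic of 4 contacts, p = 0.112 with
  # 2 of 5 -> 1/4 x 0.2075 + 2/5 x 0.112 = 0.0966875, printed as 0.097
  e <- score_E_contacts(c(0.2075, 0.112), c(1, 2), c(4, 5))
  expect_equal(e, 0.096675)
  expect_equal(round(e, 3), 0.097)
  # single rotamer, all contacts pathogenic
  expect_equal(score_E_contacts(0.5, 3, 3), 0.5)
  # no contacts contribute zero
  expect_equal(score_E_contacts(c(0.4, 0.3), c(0, 0), c(0, 2)), 0)
  expect_error(score_E_contacts(0.5, 4, 3), "exceed")
})

test_that("an empty registry yields score E of 0 for every variant", {
  ctx <- fixture_ctx(20)
  reg0 <- pathogenic_registry(data.frame(position = integer(0)))
  for (id in c("A9W", "A10F", "A10K")) {
    expect_equal(as.numeric(score_E(ctx, parse_variant(id), reg = reg0)), 0)
  }
})

test_that("score E grows monotonically as hotspot positions are added", {
  ctx <- fixture_ctx(20)
  v <- parse_variant("A9W")
  prev <- 0
  for (k in seq_len(10)) {
    reg <- pathogenic_registry(data.frame(position = seq(4, 3 + k)))
    e <- as.numeric(score_E(ctx, v, reg = reg))
    expect_gte(e, prev)
    expect_lte(e, 1)
    prev <- e
  }
  expect_gt(prev, 0)
})

test_that("score E equals a literal re-enumeration over filtered rotamers", {
  lib <- default_rotamer_library()
  cfg <- sps_config()
  ctx <- fixture_ctx(20)
  reg <- pathogenic_registry(data.frame(position = c(5, 6, 12, 13)))
  for (id in c("A9W", "A10M", "A10F")) {
    v <- parse_variant(id)
    got <- as.numeric(score_E(ctx, v, lib, reg = reg, cfg = cfg))
    rots <- place_rotamers(ctx, v, lib, cfg = cfg)
    manual <- 0
    for (r in rots) {
      if (!(r$probability > 0.10)) next
      keys <- bf_overlaps(ctx, r, cfg$contact$overlap_cutoff, 0)
      resn <- unique(vapply(strsplit(keys, " "),
                            function(x) as.integer(x[3]), integer(1)))
      if (length(resn) == 0) next
      manual <- manual + r$probability * sum(resn %in% reg$positions) / length(resn)
    }
    expect_equal(got, manual)
  }
})

test_that("the rotamer probability filter is strictly greater-than", {
  # custom library: SER rotamers at exactly 0.10 and at 0.48; only the
  # second may contribute
  f <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(residue = c("SER", "SER"), chi1 = c(62, -65), chi2 = NA,
               chi3 = NA, chi4 = NA, probability = c(0.48, 0.10)),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  lib <- read_rotamer_library(f)
  ctx <- fixture_ctx(20)
  v <- parse_variant("A10S")
  e <- score_E(ctx, v, lib = lib,
               reg = pathogenic_registry(data.frame(position = 1:20)))
  sets <- attr(e, "contacts")
  expect_length(sets, 1)
  expect_equal(sets[[1]]$probability, 0.48)
})
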