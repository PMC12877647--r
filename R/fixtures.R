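#' Deterministic synthetic fixtures
#'
#' Generators for small synthetic structures, variant tables, registries and
#' pre-scored calibration tables, so that every scoring operation can be
#' exercised without downloading real structures. Identical specs produce
#' byte-identical output files. Backbones are ideal helices (phi -57, psi
#' -47: rise about 1.5 angstrom and about 100 degrees per residue) or
#' extended strands; sequences default to poly-alanine so rotamer
#' enumeration stays exhaustive and cheap. The "cavity" geometry surrounds
#' a designated site with a cage of glycine residues so that a designated
#' mutation clashes in every rotamer (verified at generation time by
#' exhaustive chi-grid search - an infeasible planted feature is an error,
#' never a silently wrong fixture).
#'
#' @param seed Integer seed (controls sequence/variant randomness).
#' @param n_residues Number of residues in the main chain.
#' @param geometry `"helix"`, `"extended"` or `"cavity"`.
#' @param sequence Optional character vector of one-letter codes (length
#'   `n_residues`); default poly-alanine.
#' @param site Designated mutation site for planted features (default:
#'   middle residue).
#' @param mutation Mutant residue for cavity verification (default "W").
#' @param cage_radius Cage sphere radius in angstrom (cavity geometry).
#' @param cage_points Number of cage residues (cavity geometry).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_residues = 20,
                         geometry = c("helix", "extended", "cavity"),
                         sequence = NULL, site = NULL, mutation = "W",
                         cage_radius = 4.0, cage_points = 40) {
  geometry <- match.arg(geometry)
  if (is.null(site)) site <- ceiling(n_residues / 2)
  if (!is.null(sequence)) {
    sequence <- aa_normalize(sequence)
    stopifnot(length(sequence) == n_residues)
  }
  structure(list(seed = as.integer(seed), n_residues = as.integer(n_residues),
                 geometry = geometry, sequence = sequence,
                 site = as.integer(site), mutation = aa_normalize(mutation),
                 cage_radius = cage_radius,
                 cage_points = as.integer(cage_points)),
            class = "fixture_spec")
}

# ideal backbone torsions per geometry
geometry_torsions <- function(geometry) {
  switch(geometry,
         helix = c(phi = -57, psi = -47),
         extended = c(phi = -139, psi = 135),
         cavity = c(phi = -57, psi = -47))
}

# build an ideal backbone: data.frame of N, CA, C, O, CB rows per residue
build_backbone <- function(n, geometry, sequence) {
  tor <- geometry_torsions(geometry)
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7
  coords <- list()
  # seed the first three backbone atoms in the xy-plane
  N1 <- c(0, 0, 0)
  CA1 <- c(bNCA, 0, 0)
  C1 <- place_atom(c(-1, 1, 0), N1, CA1, bCAC, aNCAC, -140)
  bb <- vector("list", n)
  prevN <- N1; prevCA <- CA1; prevC <- C1
  for (i in seq_len(n)) {
    if (i > 1) {
      Ni <- place_atom(prevN, prevCA, prevC, bCN, aCACN, tor["psi"])
      CAi <- place_atom(prevCA, prevC, Ni, bNCA, aCNCA, 180)   # omega trans
      Ci <- place_atom(prevC, Ni, CAi, bCAC, aNCAC, tor["phi"])
      prevN <- Ni; prevCA <- CAi; prevC <- Ci
    }
    bb[[i]] <- list(N = prevN, CA = prevCA, C = prevC)
  }
  rows <- list()
  for (i in seq_len(n)) {
    res3 <- AA_CODES[[sequence[i]]]
    b <- bb[[i]]
    # carbonyl O points opposite the next residue's N
    Onext <- if (i < n) bb[[i + 1]]$N else NULL
    O <- if (is.null(Onext)) {
      place_atom(b$N, b$CA, b$C, 1.231, 120.5, tor["psi"] + 180)
    } else {
      place_atom(Onext, b$CA, b$C, 1.231, 120.5, 180)
    }
    at <- list(N = b$N, CA = b$CA, C = b$C, O = O)
    if (res3 != "GLY") at$CB <- ideal_cb(b$N, b$CA, b$C)
    rows[[i]] <- data.frame(
      chain = "A", resno = i, resid = res3, elety = names(at),
      elesy = substr(names(at), 1, 1),
      x = vapply(at, `[`, numeric(1), 1),
      y = vapply(at, `[`, numeric(1), 2),
      z = vapply(at, `[`, numeric(1), 3),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# add side chains (top library rotamer) for non-ALA/GLY residues
add_sidechains <- function(atoms, lib) {
  out <- list()
  for (rn in unique(atoms$resno[atoms$chain == "A"])) {
    res <- atoms[atoms$chain == "A" & atoms$resno == rn, , drop = FALSE]
    out[[length(out) + 1]] <- res
    res3 <- res$resid[1]
    if (res3 %in% c("ALA", "GLY") || n_chi(res3) == 0) next
    anchors <- list(
      N = as.numeric(res[res$elety == "N", c("x", "y", "z")]),
      CA = as.numeric(res[res$elety == "CA", c("x", "y", "z")]),
      C = as.numeric(res[res$elety == "C", c("x", "y", "z")]),
      CB = as.numeric(res[res$elety == "CB", c("x", "y", "z")])
    )
    chis <- lib_chis(lib[[res3]][1, ], res3)
    sc <- build_sidechain(res3, chis, anchors)
    out[[length(out) + 1]] <- data.frame(
      chain = "A", resno = rn, resid = res3, elety = sc$name,
      elesy = sc$elesy, x = sc$x, y = sc$y, z = sc$z,
      stringsAsFactors = FALSE
    )
  }
  rest <- atoms[atoms$chain != "A", , drop = FALSE]
  rbind(do.call(rbind, out), rest)
}

# deterministic points on a sphere (Fibonacci lattice)
sphere_points <- function(n, center, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + radius * sin(phi) * cos(theta),
        center[2] + radius * sin(phi) * sin(theta),
        center[3] + radius * cos(phi))
}

# glycine cage residues (chain B) around a center point
cage_atoms <- function(center, radius, npts, start_resno = 1) {
  pts <- sphere_points(npts, center, radius)
  rows <- vector("list", npts)
  for (i in seq_len(npts)) {
    p <- pts[i, ]
    u <- vnorm(p - center)
    # a compact 4-atom glycine laid out tangentially to the sphere
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- vnorm(vcross(u, ref)); t2 <- vcross(u, t1)
    at <- list(N = p + 1.33 * t1, CA = p, C = p + 1.33 * t2,
               O = p + 1.33 * t2 + 1.23 * u)
    rows[[i]] <- data.frame(
      chain = "B", resno = start_resno + i - 1, resid = "GLY",
      elety = names(at), elesy = substr(names(at), 1, 1),
      x = vapply(at, `[`, numeric(1), 1),
      y = vapply(at, `[`, numeric(1), 2),
      z = vapply(at, `[`, numeric(1), 3),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Generate a synthetic structure fixture
#'
#' @param spec A `fixture_spec`.
#' @param path Output PDB file path.
#' @param lib Rotamer library used for fixture side chains and cavity
#'   verification.
#' @param cfg Configuration (radii, clash criterion) used for cavity
#'   verification.
#' @return `path`, invisibly. The same spec always regenerates a
#'   byte-identical file.
#' @export
make_structure <- function(spec, path, lib = default_rotamer_library(),
                           cfg = sps_config()) {
  stopifnot(inherits(spec, "fixture_spec"))
  seq1 <- spec$sequence
  if (is.null(seq1)) seq1 <- rep("A", spec$n_residues)
  atoms <- build_backbone(spec$n_residues, spec$geometry, seq1)
  atoms <- add_sidechains(atoms, lib)
  if (spec$geometry == "cavity") {
    site_rows <- atoms[atoms$chain == "A" & atoms$resno == spec$site, , drop = FALSE]
    cb <- site_rows[site_rows$elety == "CB", c("x", "y", "z")]
    if (nrow(cb) == 0) stop("cavity site has no CB; use a non-glycine site")
    atoms <- rbind(atoms,
                   cage_atoms(as.numeric(cb), spec$cage_radius, spec$cage_points))
    verify_cavity(atoms, spec, lib, cfg)
  }
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
    write_cif_atoms(atoms, path)
  } else {
    write_pdb_atoms(atoms, path, cfg)
  }
  invisible(path)
}

# exhaustive chi-grid check that the designated mutation clashes everywhere
verify_cavity <- function(atoms, spec, lib, cfg) {
  radii <- unlist(cfg$vdw_radii)
  atoms$radius <- unname(radii[atoms$elesy])
  ctx <- new_struct_context(atoms)
  variant <- structure(list(position = spec$site, wt = "X", mut = spec$mutation,
                            id = paste0("cavity", spec$site)),
                       class = "sps_variant")
  free <- chi_grid_has_clash_free(ctx, variant, cfg, chain = "A", step = 60)
  if (free) {
    stop("infeasible cavity fixture: a clash-free ", spec$mutation,
         " rotamer exists at site ", spec$site)
  }
  invisible(TRUE)
}

# does any chi combination (grid search) of variant$mut at its site avoid
# all clashes? used by fixture verification and as a test oracle
chi_grid_has_clash_free <- function(ctx, variant, cfg, chain = "A", step = 30) {
  mut3 <- AA_CODES[[variant$mut]]
  k <- n_chi(mut3)
  wt_atoms <- residue_atoms(ctx, chain, variant$position)
  get_xyz <- function(nm) {
    i <- which(wt_atoms$elety == nm)
    if (length(i) == 0) NULL else as.numeric(wt_atoms[i[1], c("x", "y", "z")])
  }
  anchors <- list(N = get_xyz("N"), CA = get_xyz("CA"), C = get_xyz("C"),
                  CB = get_xyz("CB"))
  if (is.null(anchors$CB)) anchors$CB <- ideal_cb(anchors$N, anchors$CA, anchors$C)
  radii <- unlist(cfg$vdw_radii)
  env <- env_atoms(ctx, chain, variant$position)
  grid <- if (k == 0) list(numeric(0)) else {
    angles <- seq(-180 + step, 180, by = step)
    combos <- do.call(expand.grid, rep(list(angles), k))
    lapply(seq_len(nrow(combos)), function(i) as.numeric(combos[i, ]))
  }
  for (chis in grid) {
    sc <- build_sidechain(mut3, chis, anchors)
    if (nrow(sc) == 0) return(TRUE)
    sc$radius <- unname(radii[sc$elesy])
    ov <- overlap_matrix(sc, env, cfg$clash$hbond_allowance)
    if (all(ov < cfg$clash$overlap_cutoff)) return(TRUE)
  }
  FALSE
}

# minimal mmCIF atom_site loop
write_cif_atoms <- function(atoms, path) {
  head <- c("data_fixture", "#", "loop_",
            "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
            "_atom_site.label_atom_id", "_atom_site.label_alt_id",
            "_atom_site.label_comp_id", "_atom_site.label_asym_id",
            "_atom_site.label_entity_id", "_atom_site.label_seq_id",
            "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
            "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
            "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
            "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
            "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
            "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
                  seq_len(nrow(atoms)), atoms$elesy, atoms$elety, atoms$resid,
                  atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
                  atoms$resno, atoms$resid, atoms$chain, atoms$elety)
  writeLines(c(head, rows, "#"), path)
  invisible(path)
}

# fixed-width PDB ATOM records
write_pdb_atoms <- function(atoms, path, cfg = sps_config()) {
  lines <- character(nrow(atoms) + 1)
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    nm <- if (nchar(a$elety) < 4) sprintf(" %-3s", a$elety) else a$elety
    lines[i] <- sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                        i, nm, a$resid, a$chain, a$resno,
                        a$x, a$y, a$z, 1.0, 0.0, a$elesy)
  }
  lines[length(lines)] <- "END"
  writeLines(lines, path)
  invisible(path)
}

with_fixture_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a deterministic variant table
#'
#' Random missense substitutions (wild-type never equals mutant) in HGVS
#' protein notation, with an optional ACMG class mixture for calibration
#' tests.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param positions Candidate protein positions to sample from.
#' @param acmg_mixture Optional named numeric vector of class weights, e.g.
#'   `c("3" = 0.8, "4" = 0.1, "5" = 0.1)`; omitted = no ACMG column.
#' @param path Optional output TSV path.
#' @return Data.frame (written to `path` if given).
#' @export
make_variant_table <- function(n, seed = 1, positions = 1:100,
                               acmg_mixture = NULL, path = NULL) {
  df <- with_fixture_seed(seed, {
    aa <- names(AA_CODES)
    pos <- sample(positions, n, replace = TRUE)
    wt <- sample(aa, n, replace = TRUE)
    mut <- vapply(wt, function(w) sample(setdiff(aa, w), 1), character(1))
    d <- data.frame(
      variant = paste0("p.", unname(AA_CODES[wt]), pos, unname(AA_CODES[mut])),
      position = pos, wt = wt, mut = unname(mut), stringsAsFactors = FALSE
    )
    if (!is.null(acmg_mixture)) {
      d$acmg_class <- as.integer(sample(names(acmg_mixture), n, replace = TRUE,
                                        prob = acmg_mixture))
    }
    d
  })
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}

#' Generate a deterministic hotspot registry
#'
#' @param positions Integer vector of pathogenic positions to plant.
#' @param path Optional output TSV path.
#' @return Data.frame with columns position, acmg_class.
#' @export
make_registry <- function(positions, path = NULL) {
  df <- data.frame(position = sort(unique(as.integer(positions))),
                   acmg_class = 5L)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}

#' Generate a pre-scored table with a step-shaped pathogenic fraction
#'
#' Builds a scored variant table whose per-bin pathogenic fraction is
#' `frac_below` for SPS bins strictly below `step_at` and `frac_above` at
#' or above it - the constructed inverse of [saturation_fit()].
#'
#' @param step_at SPS bin at which the fraction steps up.
#' @param frac_below,frac_above Pathogenic fractions on either side.
#' @param per_bin Variants per bin.
#' @param bins SPS bins to populate.
#' @return Data.frame with columns variant, position, sps, acmg_class.
#' @export
make_scored_table <- function(step_at = 3.25, frac_below = 0,
                              frac_above = 0.34, per_bin = 50,
                              bins = seq(1, 5, by = 0.25)) {
  rows <- list()
  id <- 0
  for (b in bins) {
    frac <- if (b < step_at) frac_below else frac_above
    n_path <- round(frac * per_bin)
    cls <- c(rep(5L, n_path), rep(3L, per_bin - n_path))
    for (k in seq_len(per_bin)) {
      id <- id + 1
      rows[[id]] <- data.frame(variant = paste0("v", id), position = id,
                               sps = b, acmg_class = cls[k])
    }
  }
  do.call(rbind, rows)
}
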