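#' Rotamer library handling
#'
#' A rotamer library maps each residue type to a list of side-chain chi
#' angle combinations with occurrence probabilities. The shipped default is
#' a minimal backbone-independent library of the common chi modes with
#' typical frequencies; an external (e.g. backbone-dependent) library can be
#' loaded from TSV for full fidelity. Format: columns `residue` (three- or
#' one-letter), `chi1`..`chi4` (degrees, NA where absent) and `probability`.
#'
#' @param path Path to a rotamer library TSV.
#' @return Object of class `rotamer_library`: named list (three-letter
#'   codes) of data.frames with columns chi1..chi4, probability, sorted by
#'   descending probability.
#' @export
read_rotamer_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "chi1", "chi2", "chi3", "chi4", "probability")
  if (!all(need %in% names(df))) {
    stop("rotamer library must have columns: ", paste(need, collapse = ", "))
  }
  df$residue <- aa_three(df$residue)
  entries <- lapply(split(df, df$residue), function(d) {
    p <- d$probability
    if (any(p <= 0 | p > 1)) stop("rotamer probabilities must be in (0, 1]")
    if (sum(p) > 1 + 1e-6) {
      stop("rotamer probabilities for ", d$residue[1], " sum to ", sum(p), " > 1")
    }
    d <- d[order(-p), c("chi1", "chi2", "chi3", "chi4", "probability")]
    rownames(d) <- NULL
    d
  })
  for (res in c("ALA", "GLY")) {
    if (!is.null(entries[[res]]) &&
        (nrow(entries[[res]]) > 1 || any(!is.na(unlist(entries[[res]][, 1:4]))))) {
      stop(res, " must have at most one trivial (no-chi) rotamer entry")
    }
  }
  structure(entries, class = "rotamer_library")
}

#' @rdname read_rotamer_library
#' @export
default_rotamer_library <- function() {
  read_rotamer_library(prop_file("rotamers", "rotamer_library.tsv"))
}

#' @export
print.rotamer_library <- function(x, ...) {
  n <- vapply(x, nrow, integer(1))
  cat(sprintf("<rotamer_library: %d residue types, %d rotamers>\n",
              length(x), sum(n)))
  invisible(x)
}

# chi vector (only the first n_chi entries) for one library row
lib_chis <- function(row, res3) {
  k <- n_chi(res3)
  if (k == 0) return(numeric(0))
  as.numeric(row[paste0("chi", seq_len(k))])
}

# build side-chain heavy atoms beyond CB for residue type res3 at the given
# chi angles, anchored on backbone coordinates (named list N, CA, CB)
build_sidechain <- function(res3, chis, anchors) {
  tp <- sidechain_topology()[[res3]]
  if (is.null(tp)) {
    return(data.frame(name = character(0), elesy = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  }
  coords <- anchors
  for (i in seq_len(nrow(tp))) {
    row <- tp[i, ]
    dih <- if (is.na(row$chi)) row$off else chis[row$chi] + row$off
    coords[[row$name]] <- place_atom(coords[[row$a]], coords[[row$b]],
                                     coords[[row$c]], row$bond, row$angle, dih)
  }
  nm <- tp$name
  xyz <- do.call(rbind, coords[nm])
  data.frame(name = nm, elesy = element_from_name(nm),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Place candidate mutant side-chain rotamers
#'
#' The mutant side chain inherits the wild-type backbone (N, CA, C, O and
#' the CB position; CB is reconstructed from the backbone with a warning if
#' the wild-type is glycine) and is built from ideal internal geometry at
#' each library chi combination with probability >= `min_prob`, ordered by
#' descending probability. Deterministic.
#'
#' @param ctx A `struct_context`.
#' @param variant An `sps_variant` at a resolved position.
#' @param lib A `rotamer_library`.
#' @param min_prob Minimum library probability to retain a rotamer.
#' @param chain Chain carrying the mutation.
#' @param cfg Configuration (for VDW radii).
#' @return List of `placed_rotamer` objects: `chi`, `probability`, `atoms`
#'   (constructed side-chain heavy atoms with coordinates and radii).
#' @export
place_rotamers <- function(ctx, variant, lib, min_prob = 0, chain = "A",
                           cfg = sps_config()) {
  mut3 <- aa_three(variant$mut)
  entries <- lib[[mut3]]
  if (is.null(entries)) stop("residue type ", mut3, " not in rotamer library")
  wt_atoms <- residue_atoms(ctx, chain, variant$position)
  get_xyz <- function(name) {
    i <- which(wt_atoms$elety == name)
    if (length(i) == 0) return(NULL)
    as.numeric(wt_atoms[i[1], c("x", "y", "z")])
  }
  anchors <- list(N = get_xyz("N"), CA = get_xyz("CA"), C = get_xyz("C"),
                  CB = get_xyz("CB"))
  if (any(vapply(anchors[c("N", "CA", "C")], is.null, logical(1)))) {
    stop("incomplete backbone at position ", variant$position)
  }
  if (is.null(anchors$CB)) {
    if (mut3 != "GLY") {
      warning("no CB at position ", variant$position,
              "; reconstructed from backbone")
    }
    anchors$CB <- ideal_cb(anchors$N, anchors$CA, anchors$C)
  }
  keep <- entries$probability >= min_prob
  radii <- unlist(cfg$vdw_radii)
  out <- lapply(which(keep), function(i) {
    chis <- lib_chis(entries[i, ], mut3)
    atoms <- build_sidechain(mut3, chis, anchors)
    atoms$radius <- unname(radii[atoms$elesy])
    structure(list(residue = mut3, position = variant$position, chain = chain,
                   chi = chis, probability = entries$probability[i],
                   atoms = atoms, anchors = anchors),
              class = "placed_rotamer")
  })
  out
}

#' @export
print.placed_rotamer <- function(x, ...) {
  cat(sprintf("<placed_rotamer %s %s:%d p=%.4f chi=[%s] %d atoms>\n",
              x$residue, x$chain, x$position, x$probability,
              paste(round(x$chi), collapse = ", "), nrow(x$atoms)))
  invisible(x)
}

# effective VDW overlap matrix between probe atoms and environment atoms:
# overlap = r_i + r_j - d, minus the H-bond allowance for polar (N/O) pairs
overlap_matrix <- function(probe, env, allowance = 0) {
  if (nrow(probe) == 0 || nrow(env) == 0) {
    return(matrix(numeric(0), nrow(probe), nrow(env)))
  }
  d <- sqrt(pair_dist2(as.matrix(probe[, c("x", "y", "z")]),
                       as.matrix(env[, c("x", "y", "z")])))
  ov <- outer(probe$radius, env$radius, "+") - d
  if (allowance > 0) {
    polar_p <- probe$elesy %in% c("N", "O")
    polar_e <- env$elesy %in% c("N", "O")
    hb <- outer(polar_p, polar_e, "&")
    ov[hb] <- ov[hb] - allowance
  }
  ov
}

# environment atoms for a mutated residue: everything except that residue
env_atoms <- function(ctx, chain, position) {
  sel <- !(ctx$atoms$chain == chain & ctx$atoms$resno == position)
  ctx$atoms[sel, , drop = FALSE]
}

#' Detect steric clashes of a placed rotamer against the structure
#'
#' A clash is a van der Waals overlap `r_a + r_b - d` of at least
#' `overlap_cutoff` (default 0.6 angstrom) after subtracting an H-bond
#' allowance (default 0.4 angstrom) when both atoms are polar (N/O). Only
#' the constructed side-chain atoms of the rotamer are probed; atoms of the
#' mutated residue itself are excluded from the environment.
#'
#' @param ctx A `struct_context`.
#' @param rot A `placed_rotamer`.
#' @param cfg Configuration (its `clash` block is used).
#' @return Data.frame of clashes: rotamer atom, partner chain/resno/resid/
#'   atom, overlap (after allowance).
#' @export
detect_clashes <- function(ctx, rot, cfg = sps_config()) {
  env <- env_atoms(ctx, rot$chain, rot$position)
  ov <- overlap_matrix(rot$atoms, env, cfg$clash$hbond_allowance)
  hit <- which(ov >= cfg$clash$overlap_cutoff, arr.ind = TRUE)
  out <- data.frame(
    atom = rot$atoms$name[hit[, 1]],
    chain = env$chain[hit[, 2]], resno = env$resno[hit[, 2]],
    resid = env$resid[hit[, 2]], partner = env$elety[hit[, 2]],
    overlap = ov[hit], stringsAsFactors = FALSE
  )
  out[order(-out$overlap), , drop = FALSE]
}

# ---- torsion-space clash relief -------------------------------------------

# side-chain atom rows (beyond CB) of a residue present in the structure
structure_sidechain_rows <- function(ctx, chain, resno) {
  ra_idx <- which(ctx$atoms$chain == chain & ctx$atoms$resno == resno)
  res3 <- ctx$atoms$resid[ra_idx[1]]
  movable <- if (n_chi(res3) > 0) chi_movable(res3, 1) else character(0)
  ra_idx[ctx$atoms$elety[ra_idx] %in% movable]
}

#' Attempt to relieve clashes by torsion-space relaxation
#'
#' Deterministic coordinate descent over the chi angles of the mutant side
#' chain and of every clashing neighbour's side chain (backbone fixed),
#' minimizing the total squared effective overlap of all moved atoms against
#' their surroundings. The step schedule and sweep cap come from the
#' configuration. A clash counts as relieved only if, at the relaxed
#' geometry, no effective overlap of any moved atom reaches the clash
#' cutoff.
#'
#' @inheritParams detect_clashes
#' @return The rotamer with fields `clashes_before`, `clashes_after`,
#'   `relieved` and the relaxed `atoms`.
#' @export
relieve_clashes <- function(ctx, rot, cfg = sps_config()) {
  before <- detect_clashes(ctx, rot, cfg)
  rot$clashes_before <- before
  if (nrow(before) == 0) {
    rot$clashes_after <- before
    rot$relieved <- TRUE
    return(rot)
  }
  allow <- cfg$clash$hbond_allowance
  cutoff <- cfg$clash$overlap_cutoff

  # mobile neighbours: clashing residues with rotatable side chains
  nb <- unique(before[, c("chain", "resno")])
  nb_rows <- list()
  for (i in seq_len(nrow(nb))) {
    rows <- structure_sidechain_rows(ctx, nb$chain[i], nb$resno[i])
    if (length(rows) > 0) nb_rows[[paste(nb$chain[i], nb$resno[i])]] <- rows
  }

  work <- ctx$atoms          # working copy of environment coordinates
  mut_chis <- rot$chi

  rebuild_mut <- function(chis) {
    at <- build_sidechain(rot$residue, chis, rot$anchors)
    at$radius <- rot$atoms$radius[match(at$name, rot$atoms$name)]
    at
  }
  mut_atoms <- rot$atoms

  # objective: squared positive effective overlap of every mobile atom
  # against all atoms outside its own residue (mutant side chain included)
  objective <- function(mut_atoms, work) {
    total <- 0
    env <- work[!(work$chain == rot$chain & work$resno == rot$position), , drop = FALSE]
    ov <- overlap_matrix(mut_atoms, env, allow)
    total <- total + sum(pmax(ov, 0)^2)
    for (key in names(nb_rows)) {
      rows <- nb_rows[[key]]
      probe <- work[rows, , drop = FALSE]
      othr <- work[-rows, , drop = FALSE]
      othr <- othr[!(othr$chain == probe$chain[1] & othr$resno == probe$resno[1]), , drop = FALSE]
      ov1 <- overlap_matrix(probe, othr, allow)
      ov2 <- overlap_matrix(probe, mut_atoms, allow)
      total <- total + sum(pmax(ov1, 0)^2) + sum(pmax(ov2, 0)^2)
    }
    total
  }

  # torsion handles: mutant chis, then each mobile neighbour's chis
  handles <- list()
  for (k in seq_along(mut_chis)) handles[[length(handles) + 1]] <- list(kind = "mut", k = k)
  for (key in names(nb_rows)) {
    rows <- nb_rows[[key]]
    res3 <- ctx$atoms$resid[rows[1]]
    for (k in seq_len(n_chi(res3))) {
      handles[[length(handles) + 1]] <- list(kind = "nb", key = key, k = k)
    }
  }

  apply_delta <- function(h, delta, mut_atoms, work, mut_chis) {
    if (h$kind == "mut") {
      mut_chis[h$k] <- mut_chis[h$k] + delta
      mut_atoms <- rebuild_mut(mut_chis)
    } else {
      rows <- nb_rows[[h$key]]
      all_rows <- which(work$chain == work$chain[rows[1]] &
                        work$resno == work$resno[rows[1]])
      res3 <- work$resid[rows[1]]
      ax <- chi_axes(res3)[[h$k]]
      p1 <- as.numeric(work[all_rows[match(ax[1], work$elety[all_rows])],
                            c("x", "y", "z")])
      p2 <- as.numeric(work[all_rows[match(ax[2], work$elety[all_rows])],
                            c("x", "y", "z")])
      mv <- all_rows[work$elety[all_rows] %in% chi_movable(res3, h$k)]
      work[mv, c("x", "y", "z")] <-
        rotate_about_axis(as.matrix(work[mv, c("x", "y", "z")]), p1, p2, delta)
    }
    list(mut_atoms = mut_atoms, work = work, mut_chis = mut_chis)
  }

  best <- objective(mut_atoms, work)
  for (step in as.numeric(cfg$relief$steps)) {
    for (sweep in seq_len(cfg$relief$max_sweeps)) {
      improved <- FALSE
      for (h in handles) {
        for (delta in c(step, -step)) {
          cand <- apply_delta(h, delta, mut_atoms, work, mut_chis)
          val <- objective(cand$mut_atoms, cand$work)
          if (val < best - 1e-9) {
            best <- val
            mut_atoms <- cand$mut_atoms
            work <- cand$work
            mut_chis <- cand$mut_chis
            improved <- TRUE
            break
          }
        }
      }
      if (!improved || best == 0) break
    }
    if (best == 0) break
  }

  relaxed_ctx <- new_struct_context(work)
  rot$atoms <- mut_atoms
  rot$chi <- mut_chis
  after <- detect_clashes(relaxed_ctx, rot, cfg)
  rot$clashes_after <- after
  # neighbours must not have been pushed into new clashes
  nb_clash <- FALSE
  for (key in names(nb_rows)) {
    rows <- nb_rows[[key]]
    probe <- work[rows, , drop = FALSE]
    othr <- work[!(work$chain == probe$chain[1] & work$resno == probe$resno[1]), , drop = FALSE]
    if (any(overlap_matrix(probe, othr, allow) >= cutoff) ||
        any(overlap_matrix(probe, mut_atoms, allow) >= cutoff)) {
      nb_clash <- TRUE
      break
    }
  }
  rot$relieved <- nrow(after) == 0 && !nb_clash
  rot
}

#' Score D: rotamer-weighted steric-clash severity
#'
#' Every library rotamer of the mutant residue type is placed on the
#' wild-type backbone; each contributes 0 if it produces no clash, the
#' relieved weight (default 0.5) if its clashes disappear under torsion
#' relaxation, and 1 if they persist. Contributions are weighted by library
#' probabilities renormalized to sum to 1, so the score lies in [0, 1].
#'
#' @inheritParams place_rotamers
#' @param cfg Configuration (`clash`, `relief` and `score_d` blocks).
#' @return Number in [0, 1], with attribute `"rotamers"` carrying the
#'   per-rotamer detail (probability, clash counts, relieved flag).
#' @export
score_D <- function(ctx, variant, lib = default_rotamer_library(),
                    cfg = sps_config(), chain = "A") {
  rots <- place_rotamers(ctx, variant, lib, min_prob = cfg$score_d$min_prob,
                         chain = chain, cfg = cfg)
  if (length(rots) == 0) stop("no rotamers above min_prob for ", variant$id)
  p <- vapply(rots, function(r) r$probability, numeric(1))
  p_hat <- p / sum(p)
  s <- numeric(length(rots))
  detail <- vector("list", length(rots))
  for (i in seq_along(rots)) {
    cl <- detect_clashes(ctx, rots[[i]], cfg)
    if (nrow(cl) == 0) {
      s[i] <- 0
      rots[[i]]$clashes_before <- cl
      rots[[i]]$clashes_after <- cl
      rots[[i]]$relieved <- TRUE
    } else if (isTRUE(cfg$relief$enabled)) {
      rots[[i]] <- relieve_clashes(ctx, rots[[i]], cfg)
      s[i] <- if (rots[[i]]$relieved) cfg$score_d$w_relieved else 1
    } else {
      rots[[i]]$clashes_before <- cl
      rots[[i]]$clashes_after <- cl
      rots[[i]]$relieved <- FALSE
      s[i] <- 1
    }
    detail[[i]] <- list(chi = rots[[i]]$chi, probability = p[i],
                        weight = p_hat[i],
                        n_clash_before = nrow(rots[[i]]$clashes_before),
                        n_clash_after = nrow(rots[[i]]$clashes_after),
                        relieved = rots[[i]]$relieved, state = s[i])
  }
  structure(sum(p_hat * s), rotamers = detail)
}
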