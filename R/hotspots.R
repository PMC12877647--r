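#' Pathogenic-position registry
#'
#' Registry of protein positions at which at least one substitution is
#' classified ACMG class 4 or 5 (the "pathogenic hotspots"). Score E counts
#' contacts with these positions. Pathogenicity is decided at position
#' level: a position with any class 4/5 substitution counts once, however
#' many such substitutions are known.
#'
#' @param path Path to a registry TSV with columns `position`, optionally
#'   `wt`, `mut`, `acmg_class`. Position-only rows are tolerated.
#' @return Object of class `pathogenic_registry`: list with `entries`
#'   (data.frame) and `positions` (sorted unique integer vector).
#' @export
read_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"position" %in% names(df)) stop("registry must have a 'position' column")
  pathogenic_registry(df)
}

#' @rdname read_registry
#' @param entries Data.frame with at least a `position` column.
#' @export
pathogenic_registry <- function(entries) {
  entries$position <- as.integer(entries$position)
  if (any(is.na(entries$position) | entries$position < 1)) {
    stop("registry positions must be integers >= 1")
  }
  if ("acmg_class" %in% names(entries)) {
    cls <- entries$acmg_class[!is.na(entries$acmg_class)]
    if (!all(cls %in% c(4, 5))) {
      stop("registry ACMG classes must be 4 or 5 (pathogenic hotspots only)")
    }
  }
  structure(list(entries = entries,
                 positions = sort(unique(entries$position))),
            class = "pathogenic_registry")
}

#' A small demonstration registry of published hERG hotspot positions
#' @export
#' @rdname read_registry
toy_registry <- function() {
  read_registry(prop_file("registry", "toy_registry.tsv"))
}

#' @export
print.pathogenic_registry <- function(x, ...) {
  cat(sprintf("<pathogenic_registry: %d entries, %d positions>\n",
              nrow(x$entries), length(x$positions)))
  invisible(x)
}

#' Residues in direct contact with a placed rotamer
#'
#' A residue is a contact iff any of its atoms has a van der Waals overlap
#' of at least `contact$overlap_cutoff` (default -0.4 angstrom, i.e.
#' near-touching) with any constructed side-chain atom of the rotamer. The
#' rotamer's own residue is excluded; no H-bond allowance applies to the
#' contact criterion.
#'
#' @param ctx A `struct_context`.
#' @param rot A `placed_rotamer`.
#' @param reg Optional `pathogenic_registry` used to flag contacts at
#'   hotspot positions.
#' @param cfg Configuration (`contact` block).
#' @return Object of class `contact_set`: list with `contacts` (data.frame
#'   chain, resno, resid, max_overlap, pathogenic), `n_total`,
#'   `n_pathogenic` and the rotamer `probability`.
#' @export
contacts_of <- function(ctx, rot, reg = NULL, cfg = sps_config()) {
  env <- env_atoms(ctx, rot$chain, rot$position)
  ov <- overlap_matrix(rot$atoms, env, allowance = 0)
  hit <- which(ov >= cfg$contact$overlap_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    contacts <- data.frame(chain = character(0), resno = integer(0),
                           resid = character(0), max_overlap = numeric(0),
                           pathogenic = logical(0))
  } else {
    key <- paste(env$chain[hit[, 2]], env$resno[hit[, 2]], sep = ":")
    agg <- tapply(ov[hit], key, max)
    first <- !duplicated(key)
    contacts <- data.frame(
      chain = env$chain[hit[, 2]][first], resno = env$resno[hit[, 2]][first],
      resid = env$resid[hit[, 2]][first],
      max_overlap = as.numeric(agg[key[first]]), stringsAsFactors = FALSE
    )
    contacts$pathogenic <- if (is.null(reg)) FALSE else contacts$resno %in% reg$positions
    contacts <- contacts[order(contacts$chain, contacts$resno), , drop = FALSE]
    rownames(contacts) <- NULL
  }
  structure(list(contacts = contacts, n_total = nrow(contacts),
                 n_pathogenic = sum(contacts$pathogenic),
                 probability = rot$probability),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("<contact_set: %d contacts, %d pathogenic, p=%.4f>\n",
              x$n_total, x$n_pathogenic, x$probability))
  invisible(x)
}

#' Score E from explicit contact sets
#'
#' The arithmetic core of Score E: for rotamers with library probabilities
#' `p` and pathogenic/total contact counts, E = sum over rotamers of
#' (n_pathogenic / n_total) * p. Probabilities are raw (not renormalized);
#' rotamers with no contacts contribute 0. For the published Y427H worked
#' example - two rotamers, p = 0.2075 with 1 pathogenic of 4 contacts and
#' p = 0.112 with 2 pathogenic of 5 - this gives
#' 1/4 x 0.2075 + 2/5 x 0.112 = 0.097.
#'
#' @param probability Numeric vector of rotamer probabilities.
#' @param n_pathogenic,n_total Integer vectors of per-rotamer counts.
#' @return Number in [0, 1].
#' @examples
#' score_E_contacts(c(0.2075, 0.112), c(1, 2), c(4, 5))
#' @export
score_E_contacts <- function(probability, n_pathogenic, n_total) {
  stopifnot(length(probability) == length(n_pathogenic),
            length(probability) == length(n_total),
            all(probability >= 0), all(probability <= 1),
            all(n_pathogenic >= 0), all(n_pathogenic <= pmax(n_total, n_pathogenic)))
  if (any(n_pathogenic > n_total)) stop("n_pathogenic cannot exceed n_total")
  frac <- ifelse(n_total == 0, 0, n_pathogenic / n_total)
  sum(frac * probability)
}

#' Score E: pathogenic-hotspot contact score
#'
#' Over the mutant rotamers with library probability strictly greater than
#' `min_prob` (default 0.10), each contributes its fraction of contacts at
#' registry hotspot positions, weighted by its raw probability.
#'
#' @inheritParams place_rotamers
#' @param reg A `pathogenic_registry`.
#' @param min_prob Strict lower bound on rotamer probability (default from
#'   `cfg$score_e$min_prob`).
#' @return Number in [0, 1] with attribute `"contacts"` (per-rotamer
#'   `contact_set` list).
#' @export
score_E <- function(ctx, variant, lib = default_rotamer_library(),
                    reg = toy_registry(), cfg = sps_config(),
                    min_prob = cfg$score_e$min_prob, chain = "A") {
  rots <- place_rotamers(ctx, variant, lib, min_prob = 0, chain = chain, cfg = cfg)
  rots <- Filter(function(r) r$probability > min_prob, rots)
  if (length(rots) == 0) return(structure(0, contacts = list()))
  sets <- lapply(rots, function(r) contacts_of(ctx, r, reg = reg, cfg = cfg))
  e <- score_E_contacts(
    vapply(sets, function(s) s$probability, numeric(1)),
    vapply(sets, function(s) s$n_pathogenic, numeric(1)),
    vapply(sets, function(s) s$n_total, numeric(1))
  )
  structure(e, contacts = sets)
}
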