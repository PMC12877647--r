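#' Load a protein structure into a scoring context
#'
#' Parses a PDB or mmCIF file (via bio3d), keeps protein heavy atoms (and
#' hydrogens if present), drops waters and other non-protein HETATM records,
#' resolves alternate locations to the highest-occupancy conformer, and
#' attaches element-based van der Waals radii. The result carries an atom
#' table, a residue index and the neighbor-search machinery used by the
#' clash and contact scores.
#'
#' @param path Path to a structure file.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension).
#' @param cfg Configuration list from [sps_config()] (for the VDW radius set
#'   and numbering offset).
#' @return Object of class `struct_context` with elements `atoms`
#'   (data.frame: chain, resno, resid, elety, elesy, x, y, z, radius),
#'   `residues` (data.frame: chain, resno, resid, first, last) and `source`.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "cif"), cfg = sps_config()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  mdl <- withCallingHandlers(
    tryCatch(
      if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
      error = function(e) stop("could not parse ", format, " file '", path,
                               "': ", conditionMessage(e), call. = FALSE)
    ),
    warning = function(w) {
      if (grepl("beta version|helix/sheet", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  at <- mdl$atom
  # protein residues only; waters/ligands excluded
  keep <- at$resid %in% unname(AA_CODES)
  if (!any(keep)) warning("no protein residues found in ", path)
  at <- at[keep, , drop = FALSE]

  # highest-occupancy alternate conformer, deterministically
  if (nrow(at) > 0 && "alt" %in% names(at) && any(!is.na(at$alt) & at$alt != "")) {
    occ <- if ("o" %in% names(at)) ifelse(is.na(at$o), 1, at$o) else rep(1, nrow(at))
    key <- paste(at$chain, at$resno, at$elety)
    ord <- order(key, -occ, at$alt)
    keep_rows <- ord[!duplicated(key[ord])]
    at <- at[sort(keep_rows), , drop = FALSE]   # dedup, keep source order
  }

  elesy <- element_of(at)
  radii <- unlist(cfg$vdw_radii)
  unknown <- setdiff(unique(elesy), names(radii))
  if (length(unknown) > 0) {
    stop("unknown element(s) with no VDW radius: ", paste(unknown, collapse = ", "))
  }
  xyz <- cbind(at$x, at$y, at$z)
  if (nrow(at) > 0 && any(!is.finite(xyz))) stop("non-finite coordinates in ", path)

  atoms <- data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    resid = as.character(at$resid), elety = as.character(at$elety),
    elesy = elesy, x = at$x, y = at$y, z = at$z,
    radius = unname(radii[elesy]), stringsAsFactors = FALSE
  )
  new_struct_context(atoms, source = path)
}

# infer element symbol from the bio3d atom table
element_of <- function(at) {
  if (nrow(at) == 0) return(character(0))
  e <- if ("elesy" %in% names(at)) as.character(at$elesy) else rep(NA_character_, nrow(at))
  e[is.na(e) | e == ""] <- NA_character_
  miss <- is.na(e)
  if (any(miss)) {
    # first alphabetic character of the atom name, standard PDB convention
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", at$elety[miss]))
    e[miss] <- toupper(substr(nm, 1, 1))
  }
  toupper(e)
}

new_struct_context <- function(atoms, source = "memory") {
  stopifnot(is.data.frame(atoms))
  key <- paste(atoms$chain, atoms$resno, sep = ":")
  idx <- which(!duplicated(key))
  residues <- data.frame(
    chain = atoms$chain[idx], resno = atoms$resno[idx], resid = atoms$resid[idx],
    stringsAsFactors = FALSE
  )
  # atom span of each residue (atoms are stored grouped by source order)
  residues$first <- idx
  residues$last <- if (length(idx) > 0) c(idx[-1] - 1L, nrow(atoms)) else integer(0)
  if (nrow(atoms) > 0) {
    bad <- atoms$radius <= 0 | !is.finite(atoms$radius)
    if (any(bad)) stop("atoms with non-positive VDW radius")
  }
  structure(list(atoms = atoms, residues = residues, source = source),
            class = "struct_context")
}

#' @export
print.struct_context <- function(x, ...) {
  cat(sprintf("<struct_context: %d atoms, %d residues, %d chain(s); %s>\n",
              nrow(x$atoms), nrow(x$residues),
              length(unique(x$atoms$chain)), x$source))
  invisible(x)
}

# atom rows of one residue
residue_atoms <- function(ctx, chain, resno) {
  r <- ctx$residues
  i <- which(r$chain == chain & r$resno == resno)
  if (length(i) == 0) {
    stop("residue ", chain, ":", resno, " not in structure", call. = FALSE)
  }
  ctx$atoms[r$first[i[1]]:r$last[i[1]], , drop = FALSE]
}

#' Parse a missense variant
#'
#' Accepts `"G903R"`, `"p.G903R"` or `"p.Gly903Arg"`. Synonymous inputs
#' (wild-type equal to mutant) are rejected: they have no structural score.
#'
#' @param text Variant notation string.
#' @return Object of class `sps_variant`: list with `position`, `wt`, `mut`
#'   (one-letter) and `id` (the original string).
#' @examples
#' parse_variant("p.Gly903Arg")
#' @export
parse_variant <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- sub("^p\\.", "", trimws(text))
  m <- regmatches(s, regexec("^([A-Za-z]{1}|[A-Za-z]{3})([0-9]+)([A-Za-z]{1}|[A-Za-z]{3})$", s))[[1]]
  if (length(m) != 4) stop("malformed variant notation: '", text, "'", call. = FALSE)
  wt <- aa_normalize(m[2]); mut <- aa_normalize(m[4])
  pos <- as.integer(m[3])
  if (pos < 1) stop("variant position must be >= 1: '", text, "'", call. = FALSE)
  if (wt == mut) {
    stop("synonymous variant (wild-type equals mutant): '", text,
         "' - not scorable", call. = FALSE)
  }
  structure(list(position = pos, wt = wt, mut = mut, id = text),
            class = "sps_variant")
}

#' @export
print.sps_variant <- function(x, ...) {
  cat(sprintf("<variant %s%d%s>\n", x$wt, x$position, x$mut))
  invisible(x)
}

#' Region map: unresolved intervals and domain annotation
#'
#' The unresolved intervals are the protein positions absent from the
#' cryo-EM model of hERG (defaults: 132-398, 433-448, 511-519, 578-582,
#' 598-602, 864-1159, closed 1-based intervals); variants there are scored
#' in A-C mode. Domains are an ordered, configurable annotation used for
#' stratified calibration (the pore stratum in particular).
#'
#' @param cfg Configuration list (its `regions` block is used).
#' @return Object of class `region_map`: list with `unresolved` (two-column
#'   matrix of closed intervals) and `domains` (data.frame name/start/end).
#' @export
region_map <- function(cfg = sps_config()) {
  parse_iv <- function(s) {
    p <- as.integer(strsplit(s, "-", fixed = TRUE)[[1]])
    if (length(p) != 2 || any(is.na(p)) || p[1] > p[2]) stop("bad interval: ", s)
    p
  }
  un <- t(vapply(cfg$regions$unresolved, parse_iv, integer(2)))
  dimnames(un) <- list(NULL, c("start", "end"))
  un <- un[order(un[, 1]), , drop = FALSE]
  if (nrow(un) > 1 && any(un[-1, 1] <= un[-nrow(un), 2])) {
    stop("unresolved intervals overlap")
  }
  dom <- cfg$regions$domains
  domains <- data.frame(
    name = names(dom),
    start = vapply(dom, function(s) parse_iv(s)[1], integer(1)),
    end = vapply(dom, function(s) parse_iv(s)[2], integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(unresolved = un, domains = domains), class = "region_map")
}

#' Is a protein position resolved in the structural model?
#'
#' @param position 1-based protein position(s).
#' @param regions A `region_map`.
#' @return Logical: FALSE iff the position falls inside an unresolved
#'   interval (closed bounds).
#' @export
is_resolved <- function(position, regions = region_map()) {
  stopifnot(all(position >= 1))
  vapply(position, function(p) {
    !any(p >= regions$unresolved[, "start"] & p <= regions$unresolved[, "end"])
  }, logical(1))
}

#' Domain of a protein position
#'
#' @inheritParams is_resolved
#' @return Character domain name (or NA if not covered).
#' @export
domain_of <- function(position, regions = region_map()) {
  d <- regions$domains
  vapply(position, function(p) {
    i <- which(p >= d$start & p <= d$end)
    if (length(i) == 0) NA_character_ else d$name[i[1]]
  }, character(1))
}

# ---- neighbor search ------------------------------------------------------

# grid cell-list over atom coordinates; queries return candidate atom rows
build_grid <- function(xyz, cell) {
  org <- apply(xyz, 2, min)
  key <- floor(sweep(xyz, 2, org) / cell)
  id <- paste(key[, 1], key[, 2], key[, 3], sep = ",")
  list(org = org, cell = cell, bins = split(seq_len(nrow(xyz)), id))
}

grid_candidates <- function(grid, xyz_query) {
  key <- floor(sweep(xyz_query, 2, grid$org) / grid$cell)
  want <- unique(do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    expand.grid(key[i, 1] + (-1:1), key[i, 2] + (-1:1), key[i, 3] + (-1:1))
  })))
  ids <- paste(want[, 1], want[, 2], want[, 3], sep = ",")
  sort(unique(unlist(grid$bins[ids], use.names = FALSE)))
}

#' Residues with any atom within a radius of a query residue
#'
#' Neighbor search over all chains using a cell-list grid; a residue is a
#' neighbor if at least one of its atoms lies within `radius` angstrom of
#' any atom of the query residue. The query residue itself is excluded.
#'
#' @param ctx A `struct_context`.
#' @param position Residue number of the query residue.
#' @param radius Search radius in angstrom.
#' @param chain Chain of the query residue.
#' @return Data.frame of neighbor residues (chain, resno, resid, min_dist).
#' @export
neighbors_of <- function(ctx, position, radius, chain = "A") {
  q <- residue_atoms(ctx, chain, position)
  qxyz <- as.matrix(q[, c("x", "y", "z")])
  axyz <- as.matrix(ctx$atoms[, c("x", "y", "z")])
  grid <- build_grid(axyz, cell = max(radius, 1))
  cand <- grid_candidates(grid, qxyz)
  self <- ctx$atoms$chain == chain & ctx$atoms$resno == position
  cand <- cand[!self[cand]]
  if (length(cand) == 0) {
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), min_dist = numeric(0)))
  }
  d2 <- pair_dist2(axyz[cand, , drop = FALSE], qxyz)
  mind <- sqrt(apply(d2, 1, min))
  hit <- cand[mind <= radius]
  if (length(hit) == 0) {
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), min_dist = numeric(0)))
  }
  key <- paste(ctx$atoms$chain[hit], ctx$atoms$resno[hit], sep = ":")
  agg <- tapply(sqrt(apply(d2, 1, min))[mind <= radius], key, min)
  first <- !duplicated(key)
  out <- data.frame(
    chain = ctx$atoms$chain[hit][first], resno = ctx$atoms$resno[hit][first],
    resid = ctx$atoms$resid[hit][first],
    min_dist = as.numeric(agg[key[first]]), stringsAsFactors = FALSE
  )
  out[order(out$chain, out$resno), , drop = FALSE]
}

# squared distances between every row of A (n x 3) and every row of B (m x 3)
pair_dist2 <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  pmax(d2, 0)
}

#' Check that the structure agrees with the variant's wild-type residue
#'
#' @param ctx A `struct_context`.
#' @param variant An `sps_variant`.
#' @param chain Chain to check.
#' @return Invisibly TRUE; errors on mismatch (mismatches are never silently
#'   rescored).
#' @export
check_wildtype <- function(ctx, variant, chain = "A") {
  ra <- residue_atoms(ctx, chain, variant$position)
  found <- aa_normalize(ra$resid[1])
  if (found != variant$wt) {
    stop("structure/sequence mismatch at position ", variant$position,
         ": structure has ", found, ", variant expects ", variant$wt,
         call. = FALSE)
  }
  invisible(TRUE)
}
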