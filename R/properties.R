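#' Amino-acid property tables and the structure-independent scores
#'
#' Scores A (size), B (hydrophobicity) and C (charge) quantify how much a
#' missense substitution perturbs local physicochemistry, each on a 0-1
#' scale, without reference to any 3D structure. Score A is the median over
#' one or more size tables (residue volume, solvent-accessible surface area)
#' of the normalized absolute property difference between mutant and
#' wild-type; Score B is the same construction over hydrophobicity scales
#' (four by default); Score C is half the absolute formal-charge difference,
#' so it takes only the values 0, 0.5 and 1 (a full charge inversion such as
#' Glu to Lys scores 1).
#'
#' Normalization divides each raw difference by the maximum absolute
#' difference over all ordered residue pairs within that table, computed at
#' load time, so every normalized difference lies in [0, 1] and at least one
#' pair attains 1.
#'
#' @name properties
NULL

#' Construct a property table
#'
#' @param values Named numeric vector with one value per canonical residue
#'   (names are one- or three-letter codes).
#' @param name Label for the table (used in reports).
#' @param kind Either `"size"` or `"hydrophobicity"`.
#' @return An object of class `property_table` with fields `name`, `kind`,
#'   `values` (named by one-letter code) and `max_pair_diff`.
#' @export
property_table <- function(values, name = "table", kind = c("size", "hydrophobicity")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(values), !is.null(names(values)))
  codes <- aa_normalize(names(values))
  if (anyDuplicated(codes)) stop("duplicate residue in property table '", name, "'")
  missing <- setdiff(names(AA_CODES), codes)
  if (length(missing) > 0) {
    stop("property table '", name, "' missing residues: ",
         paste(missing, collapse = ", "))
  }
  if (any(!is.finite(values))) stop("non-finite value in property table '", name, "'")
  v <- stats::setNames(as.numeric(values), codes)[names(AA_CODES)]
  mpd <- max(abs(outer(v, v, "-")))
  if (mpd <= 0) stop("property table '", name, "' is constant; cannot normalize")
  structure(list(name = name, kind = kind, values = v, max_pair_diff = mpd),
            class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table '%s' (%s), max pair diff %.4g>\n",
              x$name, x$kind, x$max_pair_diff))
  invisible(x)
}

#' Read a property table from TSV
#'
#' Expects columns `residue` and `value`.
#'
#' @param path Path to a TSV file.
#' @inheritParams property_table
#' @return A `property_table`.
#' @export
read_property_table <- function(path, name = basename(path),
                                kind = c("size", "hydrophobicity")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(df))) {
    stop("property table file must have columns 'residue' and 'value': ", path)
  }
  property_table(stats::setNames(df$value, df$residue), name = name, kind = kind)
}

prop_file <- function(...) {
  system.file("extdata", ..., package = "spscore", mustWork = TRUE)
}

#' Default property tables
#'
#' The shipped defaults are standard published scales: Zamyatnin residue
#' volumes and Tien et al. theoretical maximum solvent-accessible surface
#' areas for size; Kyte-Doolittle, Hopp-Woods, Eisenberg consensus and
#' Fauchere-Pliska for hydrophobicity. All are overridable: any list of
#' `property_table` objects of the right kind can be passed to the scoring
#' functions instead.
#'
#' @return A list of `property_table` objects.
#' @export
default_size_tables <- function() {
  list(
    read_property_table(prop_file("properties", "volume_zamyatnin.tsv"),
                        name = "volume (Zamyatnin)", kind = "size"),
    read_property_table(prop_file("properties", "surface_tien.tsv"),
                        name = "surface area (Tien max ASA)", kind = "size")
  )
}

#' @rdname default_size_tables
#' @export
default_hydrophobicity_scales <- function() {
  list(
    read_property_table(prop_file("properties", "hydro_kyte_doolittle.tsv"),
                        name = "Kyte-Doolittle", kind = "hydrophobicity"),
    read_property_table(prop_file("properties", "hydro_hopp_woods.tsv"),
                        name = "Hopp-Woods", kind = "hydrophobicity"),
    read_property_table(prop_file("properties", "hydro_eisenberg.tsv"),
                        name = "Eisenberg consensus", kind = "hydrophobicity"),
    read_property_table(prop_file("properties", "hydro_fauchere_pliska.tsv"),
                        name = "Fauchere-Pliska", kind = "hydrophobicity")
  )
}

#' Formal-charge assignment
#'
#' Asp and Glu carry -1, Lys and Arg +1, all other residues 0. Histidine is
#' neutral by default (pH 7.4); set `histidine_positive = TRUE` to treat it
#' as +1.
#'
#' @param histidine_positive Treat His as +1 instead of 0.
#' @return Named integer vector over the 20 one-letter codes, values in
#'   {-1, 0, 1}.
#' @export
default_charges <- function(histidine_positive = FALSE) {
  ch <- stats::setNames(rep(0L, 20L), names(AA_CODES))
  ch[c("D", "E")] <- -1L
  ch[c("K", "R")] <- 1L
  if (isTRUE(histidine_positive)) ch["H"] <- 1L
  ch
}

# normalized |v(mut) - v(wt)| / max_pair_diff for one table
norm_diff <- function(tab, wt, mut) {
  abs(tab$values[[mut]] - tab$values[[wt]]) / tab$max_pair_diff
}

check_tables <- function(tables, kind) {
  if (!is.list(tables) || length(tables) == 0) {
    stop("need at least one property table of kind '", kind, "'")
  }
  ok <- vapply(tables, function(t) inherits(t, "property_table") && t$kind == kind,
               logical(1))
  if (!all(ok)) stop("all tables must be property_table objects of kind '", kind, "'")
  invisible(tables)
}

#' Score A: size alteration
#'
#' Median over the size tables of the normalized absolute property
#' difference between mutant and wild-type residue. Symmetric in its two
#' residues; 0 for a synonymous pair. With an even number of tables the
#' median is the mean of the two central values.
#'
#' @param wt,mut Wild-type and mutant residue codes (one- or three-letter).
#' @param tables List of `property_table` objects of kind `"size"`.
#' @return Number in [0, 1].
#' @examples
#' score_A("C", "F")
#' @export
score_A <- function(wt, mut, tables = default_size_tables()) {
  check_tables(tables, "size")
  wt <- aa_normalize(wt); mut <- aa_normalize(mut)
  stats::median(vapply(tables, norm_diff, numeric(1), wt = wt, mut = mut))
}

#' Score B: hydrophobicity alteration
#'
#' Median over the hydrophobicity scales (four by default) of the normalized
#' absolute difference between mutant and wild-type.
#'
#' @inheritParams score_A
#' @param scales List of `property_table` objects of kind `"hydrophobicity"`.
#' @return Number in [0, 1].
#' @examples
#' score_B("L", "R")
#' @export
score_B <- function(wt, mut, scales = default_hydrophobicity_scales()) {
  check_tables(scales, "hydrophobicity")
  wt <- aa_normalize(wt); mut <- aa_normalize(mut)
  stats::median(vapply(scales, norm_diff, numeric(1), wt = wt, mut = mut))
}

#' Score C: formal-charge alteration
#'
#' Half the absolute difference in formal charge: each gained or lost unit
#' of charge is penalized by half a point, so a full inversion (e.g. Glu to
#' Lys) scores 1 and loss of a single charge (e.g. Asp to Ala) scores 0.5.
#'
#' @inheritParams score_A
#' @param charges Named charge vector as from [default_charges()].
#' @return 0, 0.5 or 1.
#' @examples
#' score_C("E", "K")
#' @export
score_C <- function(wt, mut, charges = default_charges()) {
  stopifnot(is.numeric(charges), all(names(AA_CODES) %in% names(charges)))
  if (!all(charges %in% c(-1, 0, 1))) stop("charges must be in {-1, 0, +1}")
  wt <- aa_normalize(wt); mut <- aa_normalize(mut)
  abs(charges[[mut]] - charges[[wt]]) / 2
}
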