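#' Canonical amino-acid codes
#'
#' The 20 canonical residues, as a named character vector mapping one-letter
#' to three-letter codes.
#'
#' @format Named character vector of length 20.
#' @export
AA_CODES <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

#' Validate and normalize an amino-acid code
#'
#' Accepts one-letter or three-letter codes, case-insensitively, and returns
#' the canonical upper-case one-letter code. Anything outside the 20 canonical
#' residues is rejected with the offending code named.
#'
#' @param x Character vector of residue codes.
#' @return Character vector of one-letter codes.
#' @examples
#' aa_normalize(c("gly", "R", "Trp"))
#' @export
aa_normalize <- function(x) {
  stopifnot(is.character(x), length(x) >= 1)
  x_up <- toupper(trimws(x))
  out <- character(length(x_up))
  three_to_one <- stats::setNames(names(AA_CODES), unname(AA_CODES))
  for (i in seq_along(x_up)) {
    xi <- x_up[i]
    if (nchar(xi) == 1 && xi %in% names(AA_CODES)) {
      out[i] <- xi
    } else if (nchar(xi) == 3 && xi %in% names(three_to_one)) {
      out[i] <- three_to_one[[xi]]
    } else {
      stop("unknown amino-acid code: '", x[i], "'", call. = FALSE)
    }
  }
  out
}

#' @rdname aa_normalize
#' @export
aa_three <- function(x) unname(AA_CODES[aa_normalize(x)])
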