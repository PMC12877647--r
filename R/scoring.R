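#' Scale a raw score sum onto the 1-5 SPS grid
#'
#' The cumulative sum of Scores A-E is rescaled so that 0 maps to SPS 1 and
#' the observed maximum (`scale_max_sum`, 3.30 for the hERG study set) maps
#' to SPS 5, rounded to the nearest 0.25 increment:
#' `x = (sum / scale_max_sum) * 16; SPS = 1 + floor(x + 1/2) / 4`.
#' Half-way values round up. The image is the 17-value grid
#' 1.00, 1.25, ..., 5.00. Sums above `scale_max_sum` (possible only with
#' non-default property tables) clamp to the maximum with a warning.
#'
#' @param raw_sum Non-negative cumulative score sum (vectorized).
#' @param cfg Configuration (`scoring$scale_max_sum`).
#' @return SPS grid value(s) in `seq(1, 5, by = 0.25)`.
#' @examples
#' scale_sps(c(0, 1.65, 3.30))
#' @export
scale_sps <- function(raw_sum, cfg = sps_config()) {
  if (any(!is.finite(raw_sum)) || any(raw_sum < 0)) {
    stop("raw score sum must be finite and >= 0")
  }
  mx <- cfg$scoring$scale_max_sum
  if (any(raw_sum > mx + 1e-9)) {
    warning("raw score sum above ", mx, " clamped to the scale maximum")
    raw_sum <- pmin(raw_sum, mx)
  }
  x <- raw_sum / mx * 16
  1 + floor(x + 0.5) / 4
}

#' Classify an SPS value
#'
#' High pathogenic risk iff SPS >= threshold (default 3.25). Scores below
#' the threshold mean "uncertain pathogenic risk" - never "benign".
#'
#' @param sps SPS grid value(s).
#' @param cfg Configuration (`scoring$threshold`).
#' @return Character vector: `"high"` or `"uncertain"`.
#' @examples
#' classify_sps(c(3.0, 3.25, 5.0))
#' @export
classify_sps <- function(sps, cfg = sps_config()) {
  ifelse(sps >= cfg$scoring$threshold, "high", "uncertain")
}

#' Score one missense variant
#'
#' Computes the structure-independent Scores A-C always; Scores D (steric
#' clash) and E (pathogenic-hotspot contacts) only when the position is
#' resolved in the structural model and a structure is supplied (otherwise
#' D = E = 0 and the variant is scored in A-C mode through the same scaling
#' equation). A structure/sequence mismatch at the position is an error: no
#' score is emitted.
#'
#' @param variant An `sps_variant` (or a string parsed by
#'   [parse_variant()]).
#' @param ctx A `struct_context`, or NULL for A-C-only scoring.
#' @param size_tables,hydro_scales,charges Property inputs (defaults as
#'   shipped).
#' @param lib A `rotamer_library`.
#' @param reg A `pathogenic_registry`.
#' @param regions A `region_map`.
#' @param cfg Configuration.
#' @param chain Chain carrying the mutation.
#' @param mode `"auto"` (A-E where resolved), `"ac"` (force A-C), or
#'   `"ae"` (require structure; error at unresolved positions).
#' @return Object of class `score_breakdown`: variant, A, B, C, D, E,
#'   raw_sum, sps_ac, sps, mode, risk, domain and detail provenance.
#' @export
score_variant <- function(variant, ctx = NULL,
                          size_tables = default_size_tables(),
                          hydro_scales = default_hydrophobicity_scales(),
                          charges = default_charges(),
                          lib = default_rotamer_library(),
                          reg = toy_registry(),
                          regions = region_map(cfg),
                          cfg = sps_config(), chain = "A",
                          mode = c("auto", "ac", "ae")) {
  mode <- match.arg(mode)
  if (is.character(variant)) variant <- parse_variant(variant)
  A <- score_A(variant$wt, variant$mut, size_tables)
  B <- score_B(variant$wt, variant$mut, hydro_scales)
  C <- score_C(variant$wt, variant$mut, charges)
  resolved <- is_resolved(variant$position, regions)
  use_struct <- switch(mode,
    ac = FALSE,
    ae = if (!resolved) stop("position ", variant$position,
                             " is unresolved; use A-C mode") else TRUE,
    auto = resolved && !is.null(ctx)
  )
  if (use_struct && is.null(ctx)) {
    stop("a structure is required to score D and E at resolved positions")
  }
  D <- 0; E <- 0; detail <- NULL
  if (use_struct) {
    check_wildtype(ctx, variant, chain = chain)
    D <- score_D(ctx, variant, lib = lib, cfg = cfg, chain = chain)
    E <- score_E(ctx, variant, lib = lib, reg = reg, cfg = cfg, chain = chain)
    detail <- list(rotamers = attr(D, "rotamers"),
                   contacts = lapply(attr(E, "contacts"), function(s) {
                     list(probability = s$probability, n_total = s$n_total,
                          n_pathogenic = s$n_pathogenic,
                          contacts = s$contacts)
                   }))
    D <- as.numeric(D); E <- as.numeric(E)
  }
  raw_ac <- A + B + C
  raw <- raw_ac + D + E
  dom <- domain_of(variant$position, regions)
  sps_ac <- scale_sps(raw_ac, cfg)
  sps <- scale_sps(raw, cfg)
  structure(list(
    variant = variant, A = A, B = B, C = C, D = D, E = E,
    raw_sum = raw, mode = if (use_struct) "A-E" else "A-C",
    sps_ac = sps_ac, sps = sps,
    risk = classify_sps(sps, cfg),
    domain = dom,
    in_pore = identical(dom, "pore"),
    pore_call = identical(dom, "pore") && sps >= cfg$scoring$pore_threshold,
    details = detail
  ), class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  v <- x$variant
  cat(sprintf("<%s%d%s [%s] A=%.3f B=%.3f C=%.2f D=%.3f E=%.3f sum=%.3f SPS=%.2f (%s risk)>\n",
              v$wt, v$position, v$mut, x$mode, x$A, x$B, x$C, x$D, x$E,
              x$raw_sum, x$sps, x$risk))
  invisible(x)
}

#' Batch-score a variant table
#'
#' Scores every row of a variant table, preserving input order. Rows that
#' fail validation (malformed notation, synonymous variants,
#' structure/sequence mismatches) are carried through with an `error`
#' message, never silently dropped. Per-variant structured detail reports
#' (rotamers, probabilities, contacts, clash lists) are written as JSON
#' when `details_dir` is given.
#'
#' @param variants Data.frame with a `variant` column (HGVS-style notation)
#'   or columns `position`, `wt`, `mut`; or a path to such a TSV/CSV file.
#'   An optional `acmg_class` column is carried through for calibration.
#' @inheritParams score_variant
#' @param details_dir Optional directory for per-variant JSON detail
#'   reports.
#' @return Data.frame with one row per input row: variant, position, wt,
#'   mut, mode, A-E, raw_sum, sps_ac, sps_ae, sps, risk, domain, in_pore,
#'   pore_call, error (NA when scored), plus any carried-through columns.
#' @export
batch_score <- function(variants, ctx = NULL,
                        size_tables = default_size_tables(),
                        hydro_scales = default_hydrophobicity_scales(),
                        charges = default_charges(),
                        lib = default_rotamer_library(),
                        reg = toy_registry(),
                        regions = region_map(cfg),
                        cfg = sps_config(), chain = "A",
                        mode = c("auto", "ac", "ae"),
                        details_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(variants) && length(variants) == 1 && file.exists(variants)) {
    sep <- if (grepl("\\.csv$", variants, ignore.case = TRUE)) "," else "\t"
    variants <- utils::read.delim(variants, sep = sep, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(variants), nrow(variants) >= 1)
  notation <- if ("variant" %in% names(variants)) {
    as.character(variants$variant)
  } else if (all(c("position", "wt", "mut") %in% names(variants))) {
    paste0(variants$wt, variants$position, variants$mut)
  } else {
    stop("variant table needs a 'variant' column or position/wt/mut columns")
  }
  if (!is.null(details_dir) && !dir.exists(details_dir)) {
    dir.create(details_dir, recursive = TRUE)
  }
  rows <- vector("list", length(notation))
  for (i in seq_along(notation)) {
    res <- tryCatch(
      score_variant(notation[i], ctx = ctx, size_tables = size_tables,
                    hydro_scales = hydro_scales, charges = charges,
                    lib = lib, reg = reg, regions = regions, cfg = cfg,
                    chain = chain, mode = mode),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(
        variant = notation[i], position = NA_integer_, wt = NA_character_,
        mut = NA_character_, mode = NA_character_, A = NA_real_, B = NA_real_,
        C = NA_real_, D = NA_real_, E = NA_real_, raw_sum = NA_real_,
        sps_ac = NA_real_, sps_ae = NA_real_, sps = NA_real_,
        risk = NA_character_, domain = NA_character_, in_pore = NA,
        pore_call = NA, error = conditionMessage(res),
        stringsAsFactors = FALSE
      )
    } else {
      v <- res$variant
      rows[[i]] <- data.frame(
        variant = notation[i], position = v$position, wt = v$wt, mut = v$mut,
        mode = res$mode, A = res$A, B = res$B, C = res$C, D = res$D,
        E = res$E, raw_sum = res$raw_sum, sps_ac = res$sps_ac,
        sps_ae = if (res$mode == "A-E") res$sps else NA_real_,
        sps = res$sps, risk = res$risk, domain = res$domain,
        in_pore = res$in_pore, pore_call = res$pore_call,
        error = NA_character_, stringsAsFactors = FALSE
      )
      if (!is.null(details_dir)) {
        jsonlite::write_json(
          list(variant = notation[i],
               scores = rows[[i]][, c("A", "B", "C", "D", "E", "raw_sum",
                                      "sps", "mode", "risk")],
               details = res$details),
          file.path(details_dir, paste0(gsub("[^A-Za-z0-9]", "_", notation[i]),
                                        ".json")),
          auto_unbox = TRUE, digits = NA, force = TRUE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if ("acmg_class" %in% names(variants)) out$acmg_class <- variants$acmg_class
  rownames(out) <- NULL
  out
}

#' Write a scored table as TSV with a provenance header
#'
#' @param scored Data.frame from [batch_score()].
#' @param path Output file.
#' @param cfg Configuration to serialize into `#` header lines.
#' @export
write_scores <- function(scored, path, cfg = sps_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(cfg), con)
  utils::write.table(scored, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a scored table written by [write_scores()]
#' @param path Path to the TSV.
#' @export
read_scores <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
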