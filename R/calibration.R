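#' Calibrate SPS against ACMG classification
#'
#' Tallies, per SPS grid bin, the number of variants in each ACMG class
#' (1-5) and the pathogenic fraction (class 4 + class 5) / total - the bar
#' chart used to read off the high-risk threshold. Rows with missing or
#' invalid ACMG labels are counted and excluded from the fractions.
#' Conflicting-interpretation labels should be mapped to class 3 upstream.
#'
#' @param scored Data.frame with columns `sps` and `acmg_class`, e.g. from
#'   [batch_score()] on a table carrying ACMG labels.
#' @param stratum `"all"`, `"structured"`, `"non-structured"` or `"pore"`;
#'   strata are defined by the region map.
#' @param regions A `region_map` (needed for strata other than `"all"`).
#' @return Object of class `calibration_table`: data.frame with one row per
#'   occupied SPS bin (bin, class1..class5, total, pathogenic_fraction),
#'   plus attributes `n_invalid` and `stratum`.
#' @export
calibrate <- function(scored,
                      stratum = c("all", "structured", "non-structured", "pore"),
                      regions = region_map()) {
  stratum <- match.arg(stratum)
  stopifnot(is.data.frame(scored), "sps" %in% names(scored),
            "acmg_class" %in% names(scored))
  df <- scored
  if (stratum != "all") {
    if (!"position" %in% names(df)) stop("stratified calibration needs a 'position' column")
    keep <- switch(stratum,
      "structured" = is_resolved(df$position, regions),
      "non-structured" = !is_resolved(df$position, regions),
      "pore" = domain_of(df$position, regions) == "pore"
    )
    keep[is.na(keep)] <- FALSE
    df <- df[keep, , drop = FALSE]
  }
  cls <- suppressWarnings(as.integer(df$acmg_class))
  invalid <- is.na(cls) | !(cls %in% 1:5) | is.na(df$sps)
  df <- df[!invalid, , drop = FALSE]
  cls <- cls[!invalid]
  if (nrow(df) == 0) {
    out <- data.frame(bin = numeric(0), class1 = integer(0), class2 = integer(0),
                      class3 = integer(0), class4 = integer(0), class5 = integer(0),
                      total = integer(0), pathogenic_fraction = numeric(0))
    return(structure(out, class = c("calibration_table", "data.frame"),
                     n_invalid = sum(invalid), stratum = stratum))
  }
  bins <- sort(unique(df$sps))
  tab <- t(vapply(bins, function(b) {
    in_bin <- df$sps == b
    counts <- vapply(1:5, function(k) sum(cls[in_bin] == k), integer(1))
    counts
  }, integer(5)))
  total <- rowSums(tab)
  out <- data.frame(bin = bins, class1 = tab[, 1], class2 = tab[, 2],
                    class3 = tab[, 3], class4 = tab[, 4], class5 = tab[, 5],
                    total = total,
                    pathogenic_fraction = (tab[, 4] + tab[, 5]) / total)
  structure(out, class = c("calibration_table", "data.frame"),
            n_invalid = sum(invalid), stratum = stratum)
}

#' Fit the saturation / rupture structure of a calibration curve
#'
#' Fits a monotone saturating model - piecewise linear with a single
#' breakpoint: a non-decreasing line over the bins below the breakpoint and
#' a constant plateau from the breakpoint up - to (bin, pathogenic
#' fraction) pairs by weighted least squares (weights = bin counts), the
#' breakpoint chosen by grid search over the occupied bins. Returns the
#' fitted saturation onset (the breakpoint, i.e. the first bin on the
#' plateau) and the rupture bin, the bin at which the fraction jumps most
#' between consecutive occupied bins. Strictly increasing fractions force
#' the breakpoint to the top bin and raise the poor-fit flag; constant
#' fractions are degenerate and no fit is attempted.
#'
#' @param table A `calibration_table` with at least 4 occupied bins.
#' @return List: `saturation` (SPS value), `rupture` (SPS value),
#'   `plateau` (fitted plateau fraction), `sse`, `fit_family`,
#'   `poor_fit` (TRUE when the plateau holds fewer than 2 bins),
#'   `degenerate` (TRUE for constant fractions).
#' @export
saturation_fit <- function(table) {
  stopifnot(inherits(table, "calibration_table"))
  tb <- table[table$total > 0, , drop = FALSE]
  if (nrow(tb) < 4) stop("need at least 4 occupied SPS bins to fit")
  x <- tb$bin; y <- tb$pathogenic_fraction; w <- tb$total
  if (max(y) - min(y) < 1e-12) {
    return(list(saturation = NA_real_, rupture = NA_real_,
                plateau = y[1], sse = 0, fit_family = "breakpoint-plateau",
                poor_fit = FALSE, degenerate = TRUE))
  }
  n <- length(x)
  best <- NULL
  # candidate breakpoints: first plateau bin, leaving >= 2 bins on the left
  for (j in 3:n) {
    L <- seq_len(j - 1); R <- j:n
    fit <- stats::lm.wfit(cbind(1, x[L]), y[L], w[L])
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    if (!is.finite(b) || b < 0) {        # enforce a non-decreasing rise
      a <- stats::weighted.mean(y[L], w[L]); b <- 0
    }
    plateau <- stats::weighted.mean(y[R], w[R])
    if (a + b * x[j - 1] > plateau + 1e-9) next   # monotone join
    sse <- sum(w[L] * (y[L] - (a + b * x[L]))^2) +
      sum(w[R] * (y[R] - plateau)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(bp = x[j], sse = sse, plateau = plateau,
                   n_plateau = length(R))
    }
  }
  if (is.null(best)) {
    return(list(saturation = NA_real_, rupture = NA_real_, plateau = NA_real_,
                sse = NA_real_, fit_family = "breakpoint-plateau",
                poor_fit = TRUE, degenerate = FALSE))
  }
  rupture <- x[-1][which.max(diff(y))]
  list(saturation = best$bp, rupture = rupture,
       plateau = as.numeric(best$plateau), sse = best$sse,
       fit_family = "breakpoint-plateau",
       poor_fit = best$n_plateau < 2, degenerate = FALSE)
}

#' Concordance with an external predictor
#'
#' Cross-tabulates the high-risk calls of this scorer against an external
#' predictor's categorical calls (e.g. AlphaMissense likely-pathogenic /
#' ambiguous / likely-benign), joined on variant identity. Reports counts,
#' percentages of high-risk variants sharing the external pathogenic call,
#' and unmatched variants.
#'
#' @param scored Data.frame with columns `variant` and `risk` (from
#'   [batch_score()]).
#' @param external Data.frame with columns `variant` and `call`; `call`
#'   values equal to `pathogenic_label` count as concordant-pathogenic.
#' @param pathogenic_label External call value meaning pathogenic.
#' @return List: `table` (cross-tabulation), `n_high`, `n_concordant`,
#'   `percent_concordant`, `unmatched` (variant ids present in `scored`
#'   high-risk rows but absent from `external`).
#' @export
concordance <- function(scored, external, pathogenic_label = "pathogenic") {
  stopifnot(all(c("variant", "risk") %in% names(scored)),
            all(c("variant", "call") %in% names(external)))
  if (anyDuplicated(scored$variant)) {
    stop("duplicate variants in scored table: ",
         paste(unique(scored$variant[duplicated(scored$variant)]), collapse = ", "))
  }
  if (anyDuplicated(external$variant)) {
    stop("duplicate variants in external table: ",
         paste(unique(external$variant[duplicated(external$variant)]), collapse = ", "))
  }
  m <- merge(scored[, c("variant", "risk")], external[, c("variant", "call")],
             by = "variant", all.x = TRUE)
  unmatched <- m$variant[m$risk == "high" & is.na(m$call)]
  mm <- m[!is.na(m$call), , drop = FALSE]
  tab <- table(risk = mm$risk, call = mm$call)
  high <- mm[mm$risk == "high", , drop = FALSE]
  n_high <- nrow(high)
  n_conc <- sum(high$call == pathogenic_label)
  list(table = tab, n_high = n_high, n_concordant = n_conc,
       percent_concordant = if (n_high > 0) 100 * n_conc / n_high else NA_real_,
       unmatched = unmatched)
}

#' Bar-chart of a calibration table (requires ggplot2)
#'
#' @param table A `calibration_table`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  long <- do.call(rbind, lapply(1:5, function(k) {
    data.frame(bin = table$bin, class = factor(k, levels = 5:1),
               count = table[[paste0("class", k)]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$bin), y = .data$count,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(
      data = data.frame(bin = table$bin, total = table$total,
                        lab = sprintf("%.0f%%", 100 * table$pathogenic_fraction)),
      ggplot2::aes(x = factor(.data$bin), y = .data$total, label = .data$lab),
      vjust = -0.4, inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = "SPS", y = "variants", fill = "ACMG class")
}
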