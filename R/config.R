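#' Scoring configuration
#'
#' All tunable cutoffs live in one nested list: the scaling constant
#' (`scoring$scale_max_sum`, 3.3 = the maximum cumulative A-E sum observed
#' across the hERG variant set), the high-risk threshold (3.25), the
#' advisory pore threshold (2.5), the van der Waals clash criterion
#' (overlap >= 0.6 A, H-bond allowance 0.4 A), the contact criterion
#' (overlap >= -0.4 A, i.e. near-touching), relief-search controls, the
#' Score D weight for relieved clashes (0.5), the Score E rotamer
#' probability filter (strictly greater than 0.10), element VDW radii and
#' the unresolved-region / domain intervals of the target channel.
#'
#' `sps_config()` returns the package defaults, optionally overridden by a
#' YAML config file and/or a nested list of overrides (later sources win,
#' merged key-by-key).
#'
#' @param file Optional path to a YAML configuration file.
#' @param overrides Optional nested list of overrides.
#' @return Nested configuration list of class `sps_config`.
#' @export
sps_config <- function(file = NULL, overrides = NULL) {
  cfg <- yaml::read_yaml(prop_file("config", "default_config.yaml"))
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    cfg <- merge_config(cfg, yaml::read_yaml(file))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  stopifnot(cfg$scoring$scale_max_sum > 0,
            cfg$scoring$threshold > 0, cfg$scoring$threshold <= 5)
  class(cfg) <- "sps_config"
  cfg
}

# recursive right-biased merge of nested lists
merge_config <- function(base, over) {
  if (!is.list(over)) return(over)
  for (k in names(over)) {
    if (is.list(over[[k]]) && is.list(base[[k]]) &&
        !is.null(names(over[[k]]))) {
      base[[k]] <- merge_config(base[[k]], over[[k]])
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' @export
print.sps_config <- function(x, ...) {
  cat("<sps_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

# serialize resolved config into "# key: value" header lines for outputs
config_header <- function(cfg) {
  flat <- unlist(unclass(cfg))
  c(sprintf("# spscore %s", as.character(utils::packageVersion("spscore"))),
    sprintf("# config %s: %s", names(flat), as.character(flat)))
}
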