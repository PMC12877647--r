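test_that("the scaling equation hits its anchor points and stays on the grid", {
  expect_equal(scale_sps(0), 1)
  expect_equal(scale_sps(3.30), 5)
  expect_equal(scale_sps(1.65), 3)          # x = 8 -> 1 + 8/4
  grid <- seq(1, 5, by = 0.25)
  sweep <- scale_sps(seq(0, 3.3, by = 0.001))
  expect_true(all(sweep %in% grid))
  expect_true(all(diff(sweep) >= 0))        # monotone non-decreasing
  expect_error(scale_sps(-0.1), ">= 0")
  expect_warning(out <- scale_sps(3.5), "clamped")
  expect_equal(out, 5)
})

test_that("half-grid raw sums round up", {
  # x + 0.5 integral: raw = 3.3 * (k + 0.5) / 16 -> floor rounds the tie up
  raw <- 3.3 * 8.5 / 16
  expect_equal(scale_sps(raw), 1 + 9 / 4)
})

test_that("classification is a threshold rule that never says benign", {
  expect_equal(classify_sps(3.25), "high")
  expect_equal(classify_sps(3.00), "uncertain")
  expect_equal(classify_sps(5.00), "high")
  expect_true(all(classify_sps(seq(1, 5, 0.25)) %in% c("high", "uncertain")))
})

test_that("the high-risk call is equivalent to a raw-sum threshold of 8.5/16 of the scale max", {
  cfg <- sps_config()
  cut <- 8.5 * cfg$scoring$scale_max_sum / 16   # 1.753125 at defaults
  for (s in c(seq(0, 3.3, by = 0.0013), cut, cut - 1e-9, cut + 1e-9)) {
    expect_equal(classify_sps(scale_sps(s, cfg), cfg) == "high", s >= cut,
                 info = paste("raw sum", s))
  }
})

test_that("variants in unresolved regions are scored in A-C mode with D = E = 0", {
  sb <- score_variant("G903R")
  expect_equal(sb$mode, "A-C")
  expect_identical(c(sb$D, sb$E), c(0, 0))
  expect_equal(sb$sps, 3.25)
  expect_equal(sb$risk, "high")
  # same equation, structure present but position unresolved
  ctx <- fixture_ctx(20)
  sb2 <- score_variant("G903R", ctx = ctx)
  expect_equal(sb2$mode, "A-C")
  expect_equal(sb2$sps, sb$sps)
})

test_that("glycine/arginine swaps in non-structured regions land exactly on the 3.25 threshold", {
  # the structure-independent screen singles out G<->R substitutions: both
  # directions score identically and exactly at the high-risk threshold
  for (id in c("G873R", "G879R", "R885G", "G903R")) {
    sb <- score_variant(id)
    expect_equal(sb$sps, 3.25)
    expect_equal(sb$risk, "high")
  }
  # a conservative substitution in the same region stays below threshold
  expect_equal(score_variant("S906T")$risk, "uncertain")
})

test_that("a variant with all components forced to zero scores SPS 1, uncertain", {
  # engineered tables in which Leu and Ile are indistinguishable
  same <- function(kind) {
    v <- stats::setNames(seq(10, 200, by = 10), names(AA_CODES))
    v["I"] <- v["L"]
    property_table(v, "engineered", kind)
  }
  sb <- score_variant("L500I", size_tables = list(same("size")),
                      hydro_scales = list(same("hydrophobicity")))
  expect_equal(sb$raw_sum, 0)
  expect_equal(sb$sps, 1)
  expect_equal(sb$risk, "uncertain")
})

test_that("A-E scoring never falls below A-C scoring for the same variant", {
  ctx <- fixture_ctx(20)
  reg <- pathogenic_registry(data.frame(position = c(6, 13)))
  for (id in c("A9W", "A10M", "A10F", "A2S", "A10K")) {
    sb <- score_variant(id, ctx = ctx, reg = reg)
    expect_equal(sb$mode, "A-E")
    expect_gte(sb$sps, sb$sps_ac)
  }
})

test_that("batch scoring conserves rows, order and flags bad rows", {
  ctx <- fixture_ctx(20)
  vt <- data.frame(variant = c("A10M", "not-a-variant", "p.Gly903Arg",
                               "p.A5A", "R10W"))
  out <- batch_score(vt, ctx = ctx)
  expect_equal(nrow(out), 5)
  expect_identical(out$variant, vt$variant)
  expect_true(all(c("A", "B", "C", "D", "E", "raw_sum", "sps_ac", "sps_ae",
                    "mode", "risk", "error") %in% names(out)))
  expect_match(out$error[2], "malformed")
  expect_match(out$error[4], "synonymous")
  expect_match(out$error[5], "mismatch")
  expect_equal(sum(is.na(out$error)), 2)
  # row-count conservation on random tables of varying size
  for (n in c(1, 7, 23)) {
    tab <- make_variant_table(n, seed = n, positions = 865:1000)
    expect_equal(nrow(batch_score(tab, mode = "ac")), n)
  }
})

test_that("batch detail reports are written as JSON per scored variant", {
  ctx <- fixture_ctx(20)
  dir <- tempfile()
  out <- batch_score(data.frame(variant = c("A10M", "junk")), ctx = ctx,
                     details_dir = dir)
  files <- list.files(dir)
  expect_length(files, 1)
  det <- jsonlite::read_json(file.path(dir, files[1]))
  expect_equal(det$variant, "A10M")
  expect_true(!is.null(det$details$rotamers))
})

test_that("scored tables round-trip through TSV with a provenance header", {
  out <- batch_score(data.frame(variant = c("G903R", "A879S")), mode = "ac")
  f <- tempfile(fileext = ".tsv")
  write_scores(out, f)
  head <- readLines(f, n = 2)
  expect_match(head[1], "spscore")
  expect_match(head[2], "config")
  back <- read_scores(f)
  expect_equal(nrow(back), 2)
  expect_equal(back$sps, out$sps)
})

test_that("pore variants carry the advisory pore flag without changing the primary call", {
  cfg <- sps_config()
  sb <- score_variant("G628R")    # conduction-pore position
  expect_true(sb$in_pore)
  expect_equal(sb$pore_call, sb$sps >= cfg$scoring$pore_threshold)
  # the primary binary call still uses the 3.25 threshold, not 2.5
  expect_equal(sb$risk == "high", sb$sps >= cfg$scoring$threshold)
  sb2 <- score_variant("G903R")   # C-tail: not pore
  expect_false(sb2$in_pore)
  expect_false(sb2$pore_call)
})
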