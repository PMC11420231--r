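test_that("RY matches the binomial-proportion oracle on hand-built tables", {
  cases <- expand.grid(nx = c(1, 9, 20, 100, 900, 980, 5000, 20000),
                       ny = c(0, 1, 20, 100, 500))
  cases <- cases[cases$nx + cases$ny >= 1, ]
  expect_gte(nrow(cases), 20)
  for (i in seq_len(nrow(cases))) {
    cc <- make_counts(cases$nx[i], cases$ny[i])
    got <- compute_ry(cc)
    want <- oracle_ry(cases$nx[i], cases$ny[i])
    expect_equal(got$ry, want$ry)
    expect_equal(got$se, want$se)
    expect_equal(got$ci_low, want$ci_low)
    expect_equal(got$ci_high, want$ci_high)
    expect_equal(got$n_xy, want$n_xy)
    expect_true(got$ci_low <= got$ry && got$ry <= got$ci_high)
  }
  # spec-level anchors
  r <- compute_ry(make_counts(900, 100))
  expect_equal(r$ry, 0.1)
  expect_equal(r$se, 0.009486833, tolerance = 1e-6)
  expect_equal(c(r$ci_low, r$ci_high), c(0.0814058, 0.1185942), tolerance = 1e-6)
  # degenerate all-X table gives a zero-width interval at 0
  d <- compute_ry(make_counts(20000, 0))
  expect_equal(c(d$ry, d$ci_low, d$ci_high), c(0, 0, 0))
  # no sex-chromosome reads at all is an error
  expect_error(compute_ry(make_counts(0, 0)), "undefined")
})

test_that("RX matches the coverage-ratio oracle, including exclusions", {
  # identity: every chromosome at the same per-base rate
  eq <- make_counts(1000, 10)
  r <- compute_rx(eq)
  expect_equal(r$rx, 1.0)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  expect_equal(r$n_autosomes_used, 22)

  # male copy-number limit: X at half the autosomal rate
  half <- make_counts(500, 50)
  expect_equal(compute_rx(half)$rx, 0.5)

  # noisy tables against the brute-force oracle
  set.seed(101)
  for (i in 1:12) {
    cc <- make_counts(nx = sample(200:2000, 1), ny = sample(0:50, 1),
                      autosome_counts = sample(500:1500, 22, replace = TRUE))
    got <- compute_rx(cc)
    want <- oracle_rx(cc)
    expect_equal(got$rx, want$rx)
    expect_equal(got$ci_low, want$ci_low)
    expect_equal(got$ci_high, want$ci_high)
  }

  # zero-count autosomes are excluded with a warning
  cc0 <- make_counts(1000, 10, autosome_counts = c(rep(1000, 21), 0))
  expect_warning(r0 <- compute_rx(cc0), "excluded")
  expect_equal(r0$n_autosomes_used, 21)
  # fewer than two usable autosomes is an error
  cc1 <- make_counts(1000, 10, autosome_counts = c(1000, rep(0, 21)))
  expect_error(suppressWarnings(compute_rx(cc1)), "at least two")
})

test_that("RY classification covers every interval position exactly once", {
  grid <- seq(0, 0.15, by = 0.004)
  for (lo in grid) for (hi in grid[grid >= lo]) {
    point <- (lo + hi) / 2
    res <- classify_ry(list(ry = point, ci_low = lo, ci_high = hi))
    expect_true(res$class %in% c("XX", "consistent-XX", "XY", "consistent-XY",
                                 "indeterminate"))
    if (hi < 0.016) expect_equal(res$class, "XX")
    if (lo > 0.077) expect_equal(res$class, "XY")
    if (lo <= 0.016 && hi >= 0.077) expect_equal(res$class, "indeterminate")
  }
  # spec anchors
  expect_equal(classify_ry(list(ry = 0, ci_low = 0, ci_high = 0))$class, "XX")
  expect_equal(classify_ry(list(ry = 0.1, ci_low = 0.0814, ci_high = 0.1186))$class, "XY")
  expect_equal(classify_ry(list(ry = 0.02, ci_low = 0.0113, ci_high = 0.0287))$class,
               "consistent-XX")
})

test_that("RX classification covers every interval position exactly once", {
  grid <- seq(0.3, 1.2, by = 0.02)
  for (lo in grid) for (hi in grid[grid >= lo]) {
    point <- (lo + hi) / 2
    res <- classify_rx(list(rx = point, ci_low = lo, ci_high = hi))
    expect_true(res$class %in% c("XX", "consistent-XX", "XY", "consistent-XY",
                                 "indeterminate"))
    if (hi < 0.6) expect_equal(res$class, "XY")
    if (lo > 0.8) expect_equal(res$class, "XX")
    if (lo <= 0.6 && hi >= 0.8) expect_equal(res$class, "indeterminate")
  }
  expect_equal(classify_rx(list(rx = 1, ci_low = 1, ci_high = 1))$class, "XX")
  expect_equal(classify_rx(list(rx = 0.5, ci_low = 0.48, ci_high = 0.55))$class, "XY")
  # interval inside the open (0.6, 0.8) band: proximity rule plus QC flag
  mid <- classify_rx(list(rx = 0.7, ci_low = 0.65, ci_high = 0.75))
  expect_equal(mid$class, "consistent-XY")
  expect_true(mid$qc_flag)
  hi <- classify_rx(list(rx = 0.78, ci_low = 0.755, ci_high = 0.795))
  expect_equal(hi$class, "consistent-XX")
})

test_that("final call follows RY grade with RX as confirmation", {
  expect_equal(combine_calls("XX", "XX", "confident")$final, "F")
  expect_equal(combine_calls("XX", "consistent-XX", "confident")$final, "F")
  expect_equal(combine_calls("consistent-XX", "consistent-XX", "relaxed")$final, "PF")
  expect_equal(combine_calls("consistent-XX", "XX", "relaxed")$final, "PF")
  expect_equal(combine_calls("XY", "XY", "confident")$final, "M")
  expect_equal(combine_calls("consistent-XY", "XY", "relaxed")$final, "PM")
  # contradiction between estimators
  disc <- combine_calls("XX", "XY", "confident")
  expect_equal(disc$final, "indeterminate")
  expect_false(disc$concordant)
  # unconfirmed (RX indeterminate) calls are downgraded, not dropped
  down <- combine_calls("XX", "indeterminate", "confident")
  expect_equal(down$final, "PF")
  expect_match(down$qc_note, "downgraded")
  # RY indeterminate or insufficient depth means no call
  expect_equal(combine_calls("indeterminate", "XX", "confident")$final, "indeterminate")
  expect_equal(combine_calls("XX", "XX", "insufficient")$final, "indeterminate")
})

test_that("depth tiers gate the final call at 100,000 and 10,000 reads", {
  expect_equal(depth_tier(100000), "confident")
  expect_equal(depth_tier(99999), "relaxed")
  expect_equal(depth_tier(10000), "relaxed")
  expect_equal(depth_tier(9999), "insufficient")
  cc <- make_counts(400, 40, autosome_counts = rep(300, 22))  # ~7k reads
  expect_equal(molecular_sex(cc)$final, "indeterminate")
  expect_equal(molecular_sex(cc)$tier, "insufficient")
})

test_that("interval width shrinks and grades strengthen as depth grows", {
  # fixed ry, growing n_xy: Wald width is monotone decreasing
  widths <- vapply(c(100, 1000, 10000, 100000), function(n) {
    r <- compute_ry(make_counts(nx = round(0.91 * n), ny = round(0.09 * n)))
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  # on a simulated depth ladder the ordering indeterminate -> probable ->
  # confident follows depth
  acc <- depth_accuracy_experiment(c(1e3, 1e4, 1e5), n_per_depth = 40, seed = 5)
  xy <- acc[acc$karyotype == "XY", ]
  xy <- xy[order(xy$depth), ]
  expect_true(all(diff(xy$frac_indeterminate) <= 0))
  expect_gte(xy$frac_confident[3], xy$frac_confident[1])
  expect_true(all(acc$frac_wrong == 0))
})

test_that("RY and RX are computed on the same filtered chromosome set", {
  lens <- stats::setNames(rep(1e8, 24), c(paste0("chr", 1:22), "chrX", "chrY"))
  cnts <- stats::setNames(rep(100, 24), names(lens))
  p <- write_idxstats_file(cnts, lens, extra_lines = "chrM\t16571\t5000\t0")
  cc <- read_idxstats(p)
  # chrM's 5000 reads enter neither estimator nor the depth total
  expect_equal(attr(cc, "total_reads"), 2400)
  expect_equal(compute_ry(cc)$n_xy, 200)
  expect_equal(compute_rx(cc)$n_autosomes_used, 22)
})
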