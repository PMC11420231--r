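#' Y-fraction sex estimator (RY) from sex-chromosome read counts
#'
#' RY is the fraction of sex-chromosome reads aligning to Y,
#' `nY / (nX + nY)`. In females it is near 0 (only Y-mismapped reads
#' contribute); in males it sits around 0.09 for typical short-read
#' mappability of the Y chromosome. The 95% confidence interval is the
#' normal (Wald) binomial approximation `ry +/- 1.96 * se` with
#' `se = sqrt(ry (1 - ry) / (nX + nY))`, clamped to `[0, 1]`; degenerate
#' counts (all-X or all-Y) give a zero-width interval.
#'
#' @param counts A `chrom_counts` table (see [read_idxstats()],
#'   [chrom_counts()]).
#' @return A list of class `ry_result`: `ry`, `se`, `ci_low`, `ci_high`,
#'   `n_xy`.
#' @export
compute_ry <- function(counts) {
  nx <- counts$mapped[counts$role == "X"]
  ny <- counts$mapped[counts$role == "Y"]
  n <- nx + ny
  if (n < 1) abort("RY undefined: no reads mapped to X or Y")
  ry <- ny / n
  se <- sqrt(ry * (1 - ry) / n)
  structure(list(ry = ry, se = se,
                 ci_low = max(0, ry - 1.96 * se),
                 ci_high = min(1, ry + 1.96 * se),
                 n_xy = n),
            class = "ry_result")
}

#' @export
print.ry_result <- function(x, ...) {
  cat(sprintf("RY = %.4f (95%% CI %.4f-%.4f), nX+nY = %d\n",
              x$ry, x$ci_low, x$ci_high, as.integer(x$n_xy)))
  invisible(x)
}

#' Classify an RY estimate against the female/male interval bounds
#'
#' A sample is `XX` when the whole confidence interval lies below the
#' female bound, `XY` when it lies entirely above the male bound;
#' `consistent-XX` / `consistent-XY` when the interval excludes the
#' opposite sex but does not clear its own bound; `indeterminate` when it
#' spans both bounds. An interval falling strictly inside the open band
#' between the two bounds satisfies both consistency conditions; it is
#' resolved by whichever karyotype expectation (0 for XX, 0.09 for XY
#' mappability) the point estimate is nearer, and flagged for review.
#'
#' @param r An `ry_result` from [compute_ry()].
#' @param bounds Numeric length-2: upper bound for confident female
#'   assignment and lower bound for confident male assignment; defaults
#'   `c(0.016, 0.077)`.
#' @return A list: `class` (one of `XX`, `consistent-XX`, `XY`,
#'   `consistent-XY`, `indeterminate`) and `qc_flag` (logical, TRUE for the
#'   in-band ambiguity).
#' @export
classify_ry <- function(r, bounds = c(0.016, 0.077)) {
  classify_interval(r$ci_low, r$ci_high, point = r$ry,
                    female_bound = bounds[1], male_bound = bounds[2],
                    female_is_low = TRUE, female_ref = 0, male_ref = 0.09)
}

#' X/autosome coverage sex estimator (RX)
#'
#' For each chromosome, the per-base alignment rate is
#' `rho_c = mapped_c / length_c`. RX is the mean over autosomes of
#' `q_c = rho_X / rho_c`: about 1.0 for XX individuals (two X copies, like
#' the autosomes) and about 0.5 for XY (one X copy). The 95% confidence
#' interval is `mean(q) +/- 1.96 * sd(q) / sqrt(n)` over the autosomes
#' used. Autosomes with zero mapped reads are excluded with a warning; at
#' least two usable autosomes are required.
#'
#' @inheritParams compute_ry
#' @return A list of class `rx_result`: `rx`, `ci_low`, `ci_high`,
#'   `n_autosomes_used`.
#' @export
compute_rx <- function(counts) {
  x_row <- counts[counts$role == "X", ]
  if (x_row$mapped <= 0) abort("RX undefined: no reads mapped to X")
  aut <- counts[counts$role == "autosome", ]
  usable <- aut$mapped > 0
  if (any(!usable)) {
    warn(paste0(sum(!usable), " autosome(s) with zero mapped reads excluded from RX"))
    aut <- aut[usable, ]
  }
  if (nrow(aut) < 2) abort("RX requires at least two autosomes with mapped reads")
  rho_x <- x_row$mapped / x_row$length
  q <- rho_x / (aut$mapped / aut$length)
  rx <- mean(q)
  half <- 1.96 * sd(q) / sqrt(length(q))
  structure(list(rx = rx, ci_low = rx - half, ci_high = rx + half,
                 n_autosomes_used = length(q)),
            class = "rx_result")
}

#' @export
print.rx_result <- function(x, ...) {
  cat(sprintf("RX = %.4f (95%% CI %.4f-%.4f), %d autosomes\n",
              x$rx, x$ci_low, x$ci_high, x$n_autosomes_used))
  invisible(x)
}

#' Classify an RX estimate against the male/female interval bounds
#'
#' Mirror image of [classify_ry()]: here males are low (one X copy,
#' expectation 0.5) and females high (expectation 1.0). Confident `XY`
#' requires the interval entirely below the male bound, confident `XX`
#' entirely above the female bound; intervals inside the open band between
#' the bounds are resolved by proximity of the point estimate to 0.5 vs
#' 1.0 and flagged.
#'
#' @param r An `rx_result` from [compute_rx()].
#' @param bounds Numeric length-2: upper bound for confident male
#'   assignment and lower bound for confident female assignment; defaults
#'   `c(0.6, 0.8)`.
#' @return As [classify_ry()].
#' @export
classify_rx <- function(r, bounds = c(0.6, 0.8)) {
  classify_interval(r$ci_low, r$ci_high, point = r$rx,
                    female_bound = bounds[2], male_bound = bounds[1],
                    female_is_low = FALSE, female_ref = 1.0, male_ref = 0.5)
}

## Shared interval rule table. `female_is_low` orients the axis: RY has
## females at small values, RX at large values. Exactly one class is
## returned for every interval; the in-band double-consistency case is
## broken by distance of `point` to the karyotype references.
classify_interval <- function(ci_low, ci_high, point, female_bound, male_bound,
                              female_is_low, female_ref, male_ref) {
  if (!female_is_low) {
    # reflect so that female side is always "low"; bounds swap and negate
    res <- classify_interval(-ci_high, -ci_low, -point,
                             female_bound = -female_bound, male_bound = -male_bound,
                             female_is_low = TRUE,
                             female_ref = -female_ref, male_ref = -male_ref)
    return(res)
  }
  confident_f <- ci_high < female_bound
  confident_m <- ci_low > male_bound
  consist_f <- ci_high < male_bound
  consist_m <- ci_low > female_bound
  qc <- FALSE
  if (confident_f) {
    cls <- "XX"
  } else if (confident_m) {
    cls <- "XY"
  } else if (consist_f && consist_m) {
    qc <- TRUE
    cls <- if (abs(point - female_ref) <= abs(point - male_ref)) "consistent-XX" else "consistent-XY"
  } else if (consist_f) {
    cls <- "consistent-XX"
  } else if (consist_m) {
    cls <- "consistent-XY"
  } else {
    cls <- "indeterminate"
  }
  list(class = cls, qc_flag = qc)
}

#' Depth tier of a sample from its total mapped reads
#'
#' Molecular sex can be assigned confidently from about 100,000
#' genome-wide reads; down to about 10,000 reads an estimate is still
#' accurate but less confident; below that no call is made.
#'
#' @param total_reads Total mapped reads over retained chromosomes.
#' @param tiers Numeric length-2 thresholds, default `c(1e5, 1e4)`.
#' @return `"confident"`, `"relaxed"` or `"insufficient"`.
#' @export
depth_tier <- function(total_reads, tiers = c(1e5, 1e4)) {
  if (total_reads >= tiers[1]) "confident"
  else if (total_reads >= tiers[2]) "relaxed"
  else "insufficient"
}

#' Combine RY and RX classifications into a final molecular sex call
#'
#' RY is the primary estimator and fixes the confidence grade; RX is
#' confirmatory. A confident RY class (`XX`/`XY`) confirmed by any
#' same-sex RX class gives a definite call (`F`/`M`); a consistent RY
#' class confirmed by RX gives a probable call (`PF`/`PM`). When RX is
#' indeterminate the call is downgraded to probable with a QC note rather
#' than dropped. Discordant sexes between the two estimators yield
#' `indeterminate` with `concordant = FALSE`; insufficient depth always
#' yields `indeterminate`.
#'
#' @param ry_class,rx_class Classes from [classify_ry()]/[classify_rx()]
#'   (character).
#' @param tier Depth tier from [depth_tier()].
#' @return A list: `final` (`F`, `PF`, `M`, `PM`, `indeterminate`),
#'   `concordant` (logical), `qc_note`.
#' @export
combine_calls <- function(ry_class, rx_class, tier) {
  side <- function(cls) {
    switch(cls, "XX" = , "consistent-XX" = "female",
           "XY" = , "consistent-XY" = "male", "none")
  }
  if (tier == "insufficient") {
    return(list(final = "indeterminate", concordant = NA,
                qc_note = "below minimum read depth for molecular sexing"))
  }
  ry_side <- side(ry_class)
  rx_side <- side(rx_class)
  if (ry_side == "none") {
    return(list(final = "indeterminate", concordant = NA,
                qc_note = "RY interval spans both classification bounds"))
  }
  if (rx_side != "none" && rx_side != ry_side) {
    return(list(final = "indeterminate", concordant = FALSE,
                qc_note = "RY and RX assign opposite sexes"))
  }
  confident_ry <- ry_class %in% c("XX", "XY")
  confirmed <- rx_side == ry_side
  grade <- if (confident_ry && confirmed) "definite" else "probable"
  final <- switch(paste(ry_side, grade),
                  "female definite" = "F", "female probable" = "PF",
                  "male definite" = "M", "male probable" = "PM")
  note <- if (!confirmed) "RX indeterminate: call downgraded to probable" else NA_character_
  list(final = final, concordant = if (confirmed) TRUE else NA, qc_note = note)
}

#' Full molecular sex determination for one count table
#'
#' Runs [compute_ry()], [compute_rx()], classification and
#' [combine_calls()] on one per-chromosome count table.
#'
#' @inheritParams compute_ry
#' @param ry_bounds,rx_bounds Classification bounds, see [classify_ry()]
#'   and [classify_rx()].
#' @param tiers Depth-tier thresholds, see [depth_tier()].
#' @return A one-row tibble: `sample_id`, `total_reads`, `n_x`, `n_y`,
#'   `ry`, `ry_low`, `ry_high`, `rx`, `rx_low`, `rx_high`, `ry_class`,
#'   `rx_class`, `tier`, `final`, `concordant`, `qc_note`.
#' @export
molecular_sex <- function(counts, ry_bounds = c(0.016, 0.077),
                          rx_bounds = c(0.6, 0.8), tiers = c(1e5, 1e4)) {
  total <- attr(counts, "total_reads") %||% sum(counts$mapped)
  tier <- depth_tier(total, tiers)
  ry_est <- compute_ry(counts)
  rx_est <- compute_rx(counts)
  ryc <- classify_ry(ry_est, ry_bounds)
  rxc <- classify_rx(rx_est, rx_bounds)
  comb <- combine_calls(ryc$class, rxc$class, tier)
  notes <- c(if (ryc$qc_flag) "RY interval inside ambiguity band",
             if (rxc$qc_flag) "RX interval inside ambiguity band",
             if (!is.na(comb$qc_note)) comb$qc_note)
  tibble::tibble(
    sample_id = attr(counts, "sample_id") %||% NA_character_,
    total_reads = total,
    n_x = counts$mapped[counts$role == "X"],
    n_y = counts$mapped[counts$role == "Y"],
    ry = ry_est$ry, ry_low = ry_est$ci_low, ry_high = ry_est$ci_high,
    rx = rx_est$rx, rx_low = rx_est$ci_low, rx_high = rx_est$ci_high,
    ry_class = ryc$class, rx_class = rxc$class,
    tier = tier, final = comb$final,
    concordant = comb$concordant,
    qc_note = if (length(notes)) paste(notes, collapse = "; ") else NA_character_
  )
}
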