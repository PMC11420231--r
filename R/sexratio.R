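#' Count males and females under an inclusion policy
#'
#' Probable calls (`PM`/`PF`) count as males/females under
#' `include_probable` and are dropped under `definite_only`;
#' `indeterminate` records never count.
#'
#' @param records Individuals tibble (see [read_individuals()]).
#' @param policy `"include_probable"` (default) or `"definite_only"`.
#' @return A list of class `sex_count`: `pm` (males), `pf` (females),
#'   `policy`.
#' @export
sex_count <- function(records, policy = c("include_probable", "definite_only")) {
  policy <- match.arg(policy)
  male_set <- if (policy == "include_probable") c("M", "PM") else "M"
  female_set <- if (policy == "include_probable") c("F", "PF") else "F"
  structure(list(pm = sum(records$sex %in% male_set),
                 pf = sum(records$sex %in% female_set),
                 policy = policy),
            class = "sex_count")
}

#' Sex ratio (males per female)
#'
#' `SR = Pm / Pf`, the number of males per female, optionally scaled by
#' 100 (`scale = "hundreds"`). The numeric value is exact; `sr_display`
#' carries the fixed-precision rendering (see [sr_display()]), used only
#' for presentation.
#'
#' @param counts A `sex_count` (or list with `pm`, `pf`).
#' @param scale `"units"` (default) or `"hundreds"`.
#' @param display Display mode passed to [sr_display()].
#' @param stratum Label carried through to the result.
#' @return A list of class `sex_ratio_result`: `pm`, `pf`, `sr`,
#'   `sr_display`, `range_class`, `stratum`, `undefined`.
#' @examples
#' compute_sr(list(pm = 12, pf = 15))   # 0.8 males per female
#' @export
compute_sr <- function(counts, scale = c("units", "hundreds"),
                       display = c("trunc2", "round1"), stratum = "all") {
  scale <- match.arg(scale)
  display <- match.arg(display)
  if (counts$pf == 0) {
    abort(sprintf("sex ratio undefined: no females counted (pm = %d, pf = 0)",
                  counts$pm), class = "paleosex_undefined_ratio")
  }
  sr <- counts$pm / counts$pf
  if (scale == "hundreds") sr <- sr * 100
  structure(list(pm = counts$pm, pf = counts$pf, sr = sr,
                 sr_display = sr_display(sr, display),
                 range_class = classify_sr_range(counts$pm / counts$pf),
                 stratum = stratum, undefined = FALSE),
            class = "sex_ratio_result")
}

#' Render a sex ratio at fixed precision
#'
#' `"trunc2"` truncates toward zero at two decimals (1/6 renders as 0.16,
#' not 0.17); `"round1"` rounds half away from zero at one decimal
#' (17/27 renders as 0.6). Truncation guards against binary
#' representation error with a 1e-9 tolerance so exact hundredths are not
#' pulled down a cent.
#'
#' @param sr Numeric ratio.
#' @param mode `"trunc2"` or `"round1"`.
#' @return Character rendering.
#' @export
sr_display <- function(sr, mode = c("trunc2", "round1")) {
  mode <- match.arg(mode)
  if (mode == "trunc2") {
    sprintf("%.2f", trunc(sr * 100 + 1e-9) / 100)
  } else {
    sprintf("%.1f", floor(sr * 10 + 0.5 + 1e-9) / 10)
  }
}

#' Classify a sex ratio against natural-population ranges
#'
#' Modern human populations show sex ratios between about 0.95 and 1.02
#' males per female; values outside 0.9--1.05 are considered extreme, and
#' anything in between intermediate.
#'
#' @param sr Numeric sex ratio in units (males per female).
#' @return `"natural"`, `"intermediate"` or `"extreme"`.
#' @export
classify_sr_range <- function(sr) {
  if (sr >= 0.95 && sr <= 1.02) "natural"
  else if (sr < 0.9 || sr > 1.05) "extreme"
  else "intermediate"
}

#' Stratified sex ratios for a set of individuals
#'
#' Splits the records by the requested criterion and computes one sex
#' ratio per stratum. Indeterminate individuals are always excluded;
#' records whose stratum value is `unknown` drop out of that
#' stratification only (an individual without an assignable phase still
#' counts in the tomb and method strata). Strata with no counted females
#' are reported with `undefined = TRUE` rather than raising an error.
#'
#' @param records Individuals tibble (see [read_individuals()]).
#' @param by One of `"tomb"`, `"phase"`, `"method"`, `"age_class"`,
#'   `"none"` (single overall stratum).
#' @param policy Probable-inclusion policy, see [sex_count()].
#' @param display Display mode, see [sr_display()].
#' @return A tibble: `stratum`, `pm`, `pf`, `sr`, `sr_display`,
#'   `range_class`, `undefined`.
#' @examples
#' ind <- read_individuals(system.file("extdata", "panoria_individuals.tsv",
#'                                     package = "paleosex"))
#' stratify_sex_ratio(ind, by = "method")
#' @export
stratify_sex_ratio <- function(records,
                               by = c("none", "tomb", "phase", "method", "age_class"),
                               policy = c("include_probable", "definite_only"),
                               display = c("trunc2", "round1")) {
  by <- match.arg(by)
  policy <- match.arg(policy)
  display <- match.arg(display)
  recs <- records[records$sex != "indeterminate", , drop = FALSE]
  if (by == "none") {
    groups <- list(all = recs)
  } else {
    vals <- recs[[by]]
    keep <- vals != "unknown"
    recs <- recs[keep, , drop = FALSE]
    vals <- vals[keep]
    groups <- split(recs, vals)
    groups <- groups[order(names(groups))]
  }
  purrr::map_dfr(names(groups), function(g) {
    cnt <- sex_count(groups[[g]], policy)
    if (cnt$pf == 0) {
      tibble::tibble(stratum = g, pm = cnt$pm, pf = cnt$pf,
                     sr = NA_real_, sr_display = NA_character_,
                     range_class = NA_character_, undefined = TRUE)
    } else {
      r <- compute_sr(cnt, display = display, stratum = g)
      tibble::tibble(stratum = g, pm = r$pm, pf = r$pf, sr = r$sr,
                     sr_display = r$sr_display, range_class = r$range_class,
                     undefined = FALSE)
    }
  })
}

#' Exact binomial test for departure from an even sex ratio
#'
#' Two-sided exact binomial test of the observed male count against a
#' null male probability `p0`. Offered as an optional check on whether an
#' observed imbalance could plausibly arise from even-sex-ratio sampling.
#'
#' @param counts A `sex_count` (or list with `pm`, `pf`).
#' @param p0 Null male probability, strictly inside (0, 1); default 0.5.
#' @return The two-sided p-value.
#' @export
binomial_departure_test <- function(counts, p0 = 0.5) {
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie strictly inside (0, 1)")
  n <- counts$pm + counts$pf
  if (n < 1) abort("binomial test requires at least one sexed individual")
  binom.test(counts$pm, n, p = p0)$p.value
}
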