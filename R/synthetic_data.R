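#' Configuration for the per-chromosome read-count simulator
#'
#' Reads are distributed over chromosomes multinomially with weight
#' `effective_length(c) * copy_number(c | karyotype)` (autosomes 2 copies;
#' X 2 in XX, 1 in XY; Y 0 in XX, 1 in XY). Effective lengths default to
#' the hg19 physical lengths for autosomes and X. The Y effective length
#' is a *calibration* parameter, not the physical length: short-read
#' mappability of the repeat-rich Y is poor, and empirically a male's
#' expected RY is near 0.09, not the ~0.28 the physical Y length would
#' imply. The default sets the Y weight to `0.09/0.91 * L_X` so a male's
#' expected RY is exactly 0.09, comfortably above the 0.077 male bound,
#' while the default female Y-mismapping rate of 0.005 keeps the expected
#' female RY well below the 0.016 female bound.
#'
#' @param karyotype `"XX"` or `"XY"`.
#' @param total_reads Positive integer number of mapped reads to place.
#' @param effective_lengths Named numeric vector over `chr1`..`chr22`,
#'   `chrX`, `chrY`.
#' @param female_y_noise Fraction of X/Y-region reads mismapped to Y in XX
#'   individuals, in `[0, 1)`; default 0.005.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(karyotype = c("XX", "XY"), total_reads = 1e6,
                            effective_lengths = default_effective_lengths(),
                            female_y_noise = 0.005, seed = NULL) {
  karyotype <- match.arg(karyotype)
  if (total_reads < 1) abort("total_reads must be positive")
  if (any(effective_lengths <= 0)) abort("effective lengths must be positive")
  if (female_y_noise < 0 || female_y_noise >= 1) {
    abort("female_y_noise must lie in [0, 1)")
  }
  stopifnot(all(c(AUTOSOME_NAMES, "chrX", "chrY") %in% names(effective_lengths)))
  structure(list(karyotype = karyotype, total_reads = as.integer(total_reads),
                 effective_lengths = effective_lengths,
                 female_y_noise = female_y_noise, seed = seed),
            class = "read_sim_config")
}

#' Default effective chromosome lengths for the read simulator
#'
#' hg19 physical lengths for the autosomes and X; Y set to
#' `0.09/0.91 * L_X` so the expected male RY is 0.09 (see
#' [read_sim_config()]).
#'
#' @param male_ry_target Expected male RY the Y weight is calibrated to.
#' @return Named numeric vector of lengths (bp).
#' @export
default_effective_lengths <- function(male_ry_target = 0.09) {
  len <- HG19_LENGTHS
  len["chrY"] <- male_ry_target / (1 - male_ry_target) * len[["chrX"]]
  len
}

#' Simulate a per-chromosome read-count table
#'
#' Draws `total_reads` reads over the 24 chromosomes from the
#' copy-number-weighted multinomial of [read_sim_config()], then, for XX
#' individuals, reassigns each X/Y-region read to Y independently with
#' probability `female_y_noise` (mimicking mismapping of X-derived or
#' microbial reads to the Y reference). Counts always sum exactly to
#' `total_reads`; the draw is reproducible under a fixed seed.
#'
#' @param cfg A [read_sim_config()].
#' @return A `chrom_counts` table (lengths are the hg19 physical lengths;
#'   the calibrated Y weight affects only the draw).
#' @examples
#' cc <- simulate_read_counts(read_sim_config("XY", total_reads = 1e5, seed = 1))
#' compute_ry(cc)
#' @export
simulate_read_counts <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  chroms <- c(AUTOSOME_NAMES, "chrX", "chrY")
  copy <- c(rep(2, 22),
            if (cfg$karyotype == "XX") c(2, 0) else c(1, 1))
  w <- cfg$effective_lengths[chroms] * copy
  counts <- as.vector(rmultinom(1, size = cfg$total_reads, prob = w))
  names(counts) <- chroms
  if (cfg$karyotype == "XX" && cfg$female_y_noise > 0) {
    n_sex <- counts[["chrX"]] + counts[["chrY"]]
    moved <- rbinom(1, n_sex, cfg$female_y_noise)
    counts[["chrX"]] <- counts[["chrX"]] + counts[["chrY"]] - moved
    counts[["chrY"]] <- moved
  }
  chrom_counts(chrom = chroms, length = HG19_LENGTHS[chroms], mapped = counts,
               sample_id = paste0("sim_", cfg$karyotype))
}

#' Configuration for the peptide peak-area simulator
#'
#' @param sex `"F"` or `"M"` (ground truth).
#' @param signal_scale Median area of a detected peak (arbitrary units);
#'   default 5e7, the magnitude observed in enamel digests.
#' @param sdlog Log-scale standard deviation of peak areas; default 0.5.
#' @param dropout_prob Per-peptide probability that a truly present
#'   peptide yields no recorded peak.
#' @param carryover_scale Median area of a spurious carryover Y2 peak
#'   injected into female samples (0 disables); when active the spurious
#'   area is drawn log-normally around this scale.
#' @param carryover_prob Probability a female sample receives a carryover
#'   Y2 peak, given `carryover_scale > 0`.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `peptide_sim_config`.
#' @export
peptide_sim_config <- function(sex = c("F", "M"), signal_scale = 5e7,
                               sdlog = 0.5, dropout_prob = 0,
                               carryover_scale = 0, carryover_prob = 1,
                               seed = NULL) {
  sex <- match.arg(sex)
  if (signal_scale <= 0) abort("signal_scale must be positive")
  if (dropout_prob < 0 || dropout_prob > 1) abort("dropout_prob must lie in [0, 1]")
  if (carryover_prob < 0 || carryover_prob > 1) abort("carryover_prob must lie in [0, 1]")
  if (carryover_scale < 0) abort("carryover_scale must be non-negative")
  structure(list(sex = sex, signal_scale = signal_scale, sdlog = sdlog,
                 dropout_prob = dropout_prob, carryover_scale = carryover_scale,
                 carryover_prob = carryover_prob, seed = seed),
            class = "peptide_sim_config")
}

#' Simulate amelogenin peak-area rows
#'
#' Peak areas for sex-appropriate peptides are drawn log-normally around
#' `signal_scale` (areas in real enamel digests are positive and
#' right-skewed over roughly 1e5--1e8). Sex-inappropriate peptides are 0,
#' except for an optional spurious carryover Y2 peak in female samples.
#' Dropout zeroes individual peptides independently.
#'
#' @param cfg A [peptide_sim_config()].
#' @param n Number of samples to simulate.
#' @return A peak-area tibble as from [read_peak_areas()].
#' @export
simulate_peptide_areas <- function(cfg, n) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cols <- c("area_y1", "area_y2", "area_y3", "area_x1", "area_x2")
  present <- if (cfg$sex == "M") rep(TRUE, 5) else c(FALSE, FALSE, FALSE, TRUE, TRUE)
  out <- tibble::tibble(sample_id = sprintf("sim_%s_%03d", cfg$sex, seq_len(n)))
  mat <- matrix(0, nrow = n, ncol = 5, dimnames = list(NULL, cols))
  if (n > 0) {
    for (j in which(present)) {
      areas <- rlnorm(n, meanlog = log(cfg$signal_scale), sdlog = cfg$sdlog)
      drop <- runif(n) < cfg$dropout_prob
      areas[drop] <- 0
      mat[, j] <- areas
    }
    if (cfg$sex == "F" && cfg$carryover_scale > 0) {
      hit <- runif(n) < cfg$carryover_prob
      mat[hit, "area_y2"] <- rlnorm(sum(hit), meanlog = log(cfg$carryover_scale),
                                    sdlog = cfg$sdlog)
    }
  }
  for (j in seq_along(cols)) out[[cols[j]]] <- mat[, j]
  out
}

#' Configuration for the whole-cemetery individuals simulator
#'
#' @param n_individuals Number of sexed individuals to generate.
#' @param true_male_prob Probability an individual is male.
#' @param method_mix Named probabilities over
#'   `osteology`/`proteomics`/`aDNA`; defaults reflect a commingled
#'   assemblage where osteology dominates.
#' @param probable_prob Probability an observed M/F call is degraded to
#'   the probable grade PM/PF.
#' @param indeterminate_prob Probability a record is observed as
#'   indeterminate.
#' @param tombs Character vector of tomb labels individuals are assigned
#'   to uniformly.
#' @param phase_probs Named probabilities over `A`/`B`/`unknown`.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `cemetery_sim_config`.
#' @export
cemetery_sim_config <- function(n_individuals, true_male_prob = 1 / 3,
                                method_mix = c(osteology = 0.6, proteomics = 0.15,
                                               aDNA = 0.25),
                                probable_prob = 0.4, indeterminate_prob = 0,
                                tombs = c("3", "10", "11", "15"),
                                phase_probs = c(A = 0.45, B = 0.5, unknown = 0.05),
                                seed = NULL) {
  if (true_male_prob <= 0 || true_male_prob >= 1) abort("true_male_prob must lie in (0, 1)")
  if (abs(sum(method_mix) - 1) > 1e-8) abort("method_mix must sum to 1")
  if (abs(sum(phase_probs) - 1) > 1e-8) abort("phase_probs must sum to 1")
  if (probable_prob < 0 || probable_prob > 1) abort("probable_prob must lie in [0, 1]")
  if (indeterminate_prob < 0 || indeterminate_prob > 1) {
    abort("indeterminate_prob must lie in [0, 1]")
  }
  if (probable_prob + indeterminate_prob > 1) {
    abort("probable_prob + indeterminate_prob must not exceed 1")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 true_male_prob = true_male_prob, method_mix = method_mix,
                 probable_prob = probable_prob,
                 indeterminate_prob = indeterminate_prob,
                 tombs = tombs, phase_probs = phase_probs, seed = seed),
            class = "cemetery_sim_config")
}

#' Simulate a cemetery of sexed individuals with known ground truth
#'
#' True sex is Bernoulli(`true_male_prob`); the observed call is the true
#' sex, degraded to a probable grade with probability `probable_prob` or
#' to indeterminate with probability `indeterminate_prob`. Tomb, phase,
#' method and age class are assigned independently of sex, so every
#' stratification shares the same expected sex ratio.
#'
#' @param cfg A [cemetery_sim_config()].
#' @return A list: `records` (individuals tibble as from
#'   [read_individuals()]) and `truth` (tibble `individual_id`,
#'   `true_sex`).
#' @export
simulate_cemetery <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_individuals
  true_sex <- ifelse(runif(n) < cfg$true_male_prob, "M", "F")
  u <- runif(n)
  observed <- ifelse(u < cfg$indeterminate_prob, "indeterminate",
                     ifelse(u < cfg$indeterminate_prob + cfg$probable_prob,
                            paste0("P", true_sex), true_sex))
  method <- sample(names(cfg$method_mix), n, replace = TRUE, prob = cfg$method_mix)
  records <- tibble::tibble(
    individual_id = sprintf("SIM-%05d", seq_len(n)),
    tomb = sample(cfg$tombs, n, replace = TRUE),
    phase = sample(names(cfg$phase_probs), n, replace = TRUE,
                   prob = cfg$phase_probs),
    method = method,
    sex = observed,
    # enamel peptide sexing targets non-adults; molecular and osteological
    # samples here are adults, mirroring the usual sampling pattern
    age_class = ifelse(method == "proteomics", "non-adult", "adult")
  )
  list(records = records,
       truth = tibble::tibble(individual_id = records$individual_id,
                              true_sex = true_sex))
}

#' Depth ladder: classification accuracy of molecular sexing vs read depth
#'
#' For each depth and karyotype, simulates `n_per_depth` individuals,
#' runs the full molecular-sex pipeline and tallies the outcome fractions.
#' `frac_confident` / `frac_probable` are based on the final call grade
#' (`M`/`F` vs `PM`/`PF`), `frac_indeterminate` on final indeterminate
#' calls (including insufficient depth), and `frac_wrong` on final calls
#' assigning the opposite sex to the simulated karyotype.
#'
#' @param depths Integer vector of total read depths.
#' @param n_per_depth Replicates per depth and karyotype.
#' @param karyotypes Karyotypes to simulate.
#' @param female_y_noise,effective_lengths Passed to [read_sim_config()].
#' @param seed Integer seed for the whole experiment.
#' @return A tibble: `depth`, `karyotype`, `n`, `frac_confident`,
#'   `frac_probable`, `frac_indeterminate`, `frac_wrong`.
#' @export
depth_accuracy_experiment <- function(depths, n_per_depth,
                                      karyotypes = c("XX", "XY"),
                                      female_y_noise = 0.005,
                                      effective_lengths = default_effective_lengths(),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(depth = depths, karyotype = karyotypes,
                      stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    depth <- grid$depth[i]
    kar <- grid$karyotype[i]
    cfg <- read_sim_config(kar, total_reads = depth,
                           effective_lengths = effective_lengths,
                           female_y_noise = female_y_noise)
    finals <- vapply(seq_len(n_per_depth), function(r) {
      molecular_sex(simulate_read_counts(cfg))$final
    }, character(1))
    truth <- if (kar == "XX") c("F", "PF") else c("M", "PM")
    wrong <- setdiff(c("F", "PF", "M", "PM"), truth)
    tibble::tibble(
      depth = depth, karyotype = kar, n = n_per_depth,
      frac_confident = mean(finals %in% c("M", "F")),
      frac_probable = mean(finals %in% c("PM", "PF")),
      frac_indeterminate = mean(finals == "indeterminate"),
      frac_wrong = mean(finals %in% wrong)
    )
  })
}
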