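# Builders for small in-code fixtures and independent arithmetic oracles.

fixture_path <- function(name) {
  system.file("extdata", name, package = "paleosex")
}

# chrom_counts table with explicit per-chromosome mapped counts
make_counts <- function(nx, ny, autosome_counts = rep(1000, 22),
                        lengths = NULL, sample_id = "test") {
  chroms <- c(paste0("chr", 1:22), "chrX", "chrY")
  if (is.null(lengths)) {
    lengths <- stats::setNames(rep(1e8, 24), chroms)
  }
  chrom_counts(chrom = chroms, length = lengths[chroms],
               mapped = c(autosome_counts, nx, ny), sample_id = sample_id)
}

# peak-area row builder
make_row <- function(y1 = 0, y2 = 0, y3 = 0, x1 = 0, x2 = 0, id = "s1") {
  tibble::tibble(sample_id = id, area_y1 = y1, area_y2 = y2, area_y3 = y3,
                 area_x1 = x1, area_x2 = x2)
}

# Brute-force binomial-proportion oracle for RY, spelled out step by step.
oracle_ry <- function(nx, ny) {
  n <- nx + ny
  p <- ny / n
  se <- sqrt(p * (1 - p) / n)
  lo <- p - 1.96 * se
  hi <- p + 1.96 * se
  list(ry = p, se = se, ci_low = if (lo < 0) 0 else lo,
       ci_high = if (hi > 1) 1 else hi, n_xy = n)
}

# Brute-force RX oracle: explicit loops and a hand-written sd.
oracle_rx <- function(counts) {
  x <- counts[counts$role == "X", ]
  aut <- counts[counts$role == "autosome" & counts$mapped > 0, ]
  q <- numeric(nrow(aut))
  for (i in seq_len(nrow(aut))) {
    rate_x <- x$mapped / x$length
    rate_a <- aut$mapped[i] / aut$length[i]
    q[i] <- rate_x / rate_a
  }
  m <- sum(q) / length(q)
  ss <- 0
  for (i in seq_along(q)) ss <- ss + (q[i] - m)^2
  s <- sqrt(ss / (length(q) - 1))
  half <- 1.96 * s / sqrt(length(q))
  list(rx = m, ci_low = m - half, ci_high = m + half, n = length(q))
}

# Exact two-sided binomial tail oracle: sum of all outcome probabilities
# not exceeding that of the observed count.
oracle_binom_two_sided <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# write a temporary idxstats file; returns its path
write_idxstats_file <- function(counts_named, lengths_named,
                                extra_lines = character()) {
  path <- withr::local_tempfile(fileext = ".idxstats",
                                .local_envir = parent.frame())
  lines <- c(vapply(names(counts_named), function(ch) {
    paste(ch, lengths_named[[ch]], counts_named[[ch]], 0, sep = "\t")
  }, character(1)), extra_lines)
  writeLines(lines, path)
  path
}
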