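---
title: "Methods: multi-proxy biological sex determination and sex-ratio analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-proxy biological sex determination and sex-ratio analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleosex)
```

`paleosex` implements three complementary ways of assigning biological sex to
skeletal individuals from a commingled burial context, and the demographic
summaries built on top of them. This vignette documents the statistical model
behind each proxy, the default parameters and why they take the values they
do, and the design of the synthetic-data generators used for validation.

## 1. Amelogenin peptide sexing

Enamel proteome digests are searched for five sex-diagnostic amelogenin
peptides: three from the Y-copy of the gene (Y1–Y3) and two from the X-copy
(X1–X2). The observable per sample is a vector of five chromatographic peak
areas; a peptide counts as *detected* when its area meets its cut-off
(inclusive, `>=`):

```{r}
cutoff_set()
```

The Y cut-offs are set high enough that trace contamination does not register;
the X peptides are abundant in every enamel sample, so their cut-offs mainly
guard against failed digests. Classification applies ordered rules:

1. no X peptide detected → **indeterminate** (the digest failed; absence of Y
   is then uninformative);
2. X detected, no Y detected → **female**;
3. X and Y detected → compute the validation ratio X1/Y2 (the two
   best-behaved peptides). If the ratio is ≤ 10 the Y signal is at genuine
   male abundance → **male**; if it exceeds 10, the Y2 peak is attributed to
   instrument carryover from a preceding male sample → **female** with
   `carryover_flag = TRUE`.
4. Y detected without Y2 → **male**, with a QC note (the ratio cannot be
   validated).

The 10:1 limit encodes the expectation that in a true male the X and Y
amelogenin peptides are found at comparable abundance (the genes are
expressed from both chromosomes), whereas carryover leaves a Y peak one to
two orders of magnitude below the X signal.

```{r}
areas <- read_peak_areas(system.file("extdata", "panoria_peak_areas.tsv",
                                     package = "paleosex"))
classify_peptide_batch(areas)$calls
```

## 2. Molecular (shotgun-sequencing) sexing

The input is a per-chromosome table of mapped read counts (`samtools
idxstats` layout). Two estimators are computed.

**RY** is the fraction of sex-chromosome reads mapping to Y,
$R_Y = n_Y / (n_X + n_Y)$, with a normal-approximation (Wald) 95% interval
$R_Y \pm 1.96\sqrt{R_Y(1-R_Y)/(n_X+n_Y)}$ clamped to $[0,1]$. An XX
individual has $R_Y$ near zero (non-zero only through mismapping); an XY
individual sits near 0.09 rather than near the physical length fraction of Y,
because most of the Y chromosome is repetitive and effectively unmappable.
The classification bounds are 0.016 (upper bound below it → XX) and 0.077
(lower bound above it → XY); intervals crossing one bound only are graded
*consistent-XX*/*consistent-XY*, and intervals spanning both are
indeterminate.

**RX** compares X coverage to autosomal coverage: with per-chromosome rate
$\rho_c = \text{mapped}_c / \text{length}_c$, each autosome yields
$q_c = \rho_X / \rho_c$, and $R_X$ is the mean of the 22 ratios with interval
$\bar q \pm 1.96\, s_q/\sqrt{n}$. Expectation: 1.0 for XX, 0.5 for XY.
Bounds: upper < 0.6 → XY, lower > 0.8 → XX.

Three numerical choices deserve a note:

- *Wald intervals.* Counts here are in the thousands whenever a call is
  attempted at all, where the Wald interval is accurate; below that, the
  depth gate (next paragraph) refuses a call before interval shape matters.
  The degenerate case $R_Y \in \{0, 1\}$ yields a zero-width interval, which
  is the correct statement at this resolution ("no Y read observed").
- *Proximity rule for fully in-band intervals.* A narrow interval lying
  wholly between the two bounds matches neither side's rule. Both
  classifiers resolve it to the *consistent* grade of whichever reference
  point (XX vs XY expectation: 0 vs 0.09 for RY, 1.0 vs 0.5 for RX) is
  nearer the point estimate, and attach a QC flag. A first-match-wins
  ordering would instead call a clearly male-leaning interval
  consistent-XX, which is indefensible.
- *Ordered combination.* RY is the primary classifier; RX confirms. The
  final grade follows the RY class when RX agrees in direction (RY `XX` →
  **F**, RY `consistent-XX` → **PF**, likewise for males); an indeterminate
  RX downgrades a firm RY call to probable; an indeterminate RY, or a
  direction conflict, yields **indeterminate** (conflicts are additionally
  flagged non-concordant).

Calls are gated on total mapped reads: ≥ 100,000 reads permits the full
grade ladder; 10,000–99,999 reads caps confidence (tier "relaxed"); below
10,000 reads no call is attempted. The tiers reflect where the interval
width stops being dominated by counting noise.

```{r}
molecular_sex(simulate_read_counts(read_sim_config("XY", total_reads = 2e5,
                                                   seed = 1)))
```

## 3. Sex-ratio analysis

Per-individual calls use a five-level scale: `M`, `PM` (probable male),
`PF`, `F`, `indeterminate`. The sex ratio is $SR = P_m / P_f$ (males per
female), computed under two policies — `include_probable` (PM counts with M,
PF with F) and `definite_only` — and reported at two display precisions:
`trunc2` (truncate to two decimals, matching the convention of reporting
0.85 for 6/7) and `round1`. Truncation is guarded with a $10^{-9}$ epsilon
so exact decimal fractions stored in binary do not fall to the lower cent.
A ratio is *natural* inside [0.95, 1.02] (the band observed in large birth
cohorts), *extreme* outside [0.9, 1.05], *intermediate* between. Strata with
no females give an undefined ratio (flagged, never `Inf`), and departure from
parity is tested with an exact two-sided binomial test (`stats::binom.test`).

```{r}
ind <- read_individuals(system.file("extdata", "panoria_individuals.tsv",
                                    package = "paleosex"))
stratify_sex_ratio(ind, by = "method")
```

## 4. Synthetic-data generators

The generators are first-class: all accuracy claims in the test suite are
made against data with known ground truth.

**Read counts.** `simulate_read_counts()` draws one multinomial sample over
the 24 chromosomes with weights $\text{effective length} \times \text{copy
number}$ (copy numbers 2 for autosomes; X/Y = 2/0 for XX, 1/1 for XY). The
autosomal and X effective lengths are the hg19 physical lengths, but the Y
effective length is a *calibration parameter*: the default solves
$E[R_Y \mid XY] = 0.09$ exactly, i.e. $L_Y^{\text{eff}} = \frac{0.09}{0.91}
L_X$. Using the physical Y length would put male $R_Y$ near 0.28 —
unobservable in practice because of Y's repeat content — and would make the
0.077 bound meaningless. XX samples receive mismapping noise: each X read
is independently reassigned to Y with probability `female_y_noise = 0.005`,
which places female $R_Y$ near 0.005, comfortably below 0.016 but non-zero,
as real data look. Limits: reads are exchangeable (no GC, length, or damage
structure), so the generator validates the estimators, not the aligner.

**Peptide areas.** `simulate_peptide_areas()` draws areas log-normally
around a per-peptide signal scale (default `5e7`, the magnitude of real
enamel digests; `sdlog = 0.5` mimics run-to-run spread), with optional
per-peptide dropout and, for females, optional injected Y2 carryover at a
smaller scale. This closes the loop through the classifier: clean males come
back male, clean females female, and carryover females female-with-flag.

**Cemetery.** `simulate_cemetery()` draws true sexes Bernoulli
(`true_male_prob = 1/3` by default, i.e. true SR = 0.5), assigns tombs,
phases, age classes and a method mix, then degrades calls — some firm calls
become probable (`probable_prob`), some indeterminate — *without flipping
sex*, so the generator is unbiased by construction and recovery error is
pure sampling noise.

**Depth ladder.** `depth_accuracy_experiment()` simulates both karyotypes
across a grid of sequencing depths and reports the fraction of confident,
probable, indeterminate and wrong-sex final calls. At the package's default
thresholds the wrong-sex rate is zero at every depth: an under-powered
sample degrades to probable and then to indeterminate before it can cross
to the wrong side.

```{r}
depth_accuracy_experiment(c(1e4, 1e5), n_per_depth = 100, seed = 42)
```

Problem sizes in the examples (hundreds of simulated samples, cemeteries of
a few thousand individuals) are the package's own choice: large enough that
binomial noise cannot mask a calibration error of the size the bounds care
about, small enough to run in seconds on one core.

## 5. The end-to-end run

`run_all()` chains the stages: peptide classification, molecular sexing (if
count tables are supplied), merging of per-method calls into unique
individuals, and the full stratified ratio report. Merging is by explicit
id mapping only — sample names never auto-match individual ids — and
discordant duplicate calls are conflict-flagged and excluded from every
ratio rather than silently resolved.

```{r}
fixture <- function(f) system.file("extdata", f, package = "paleosex")
rep <- run_all(run_config(
  peak_areas = fixture("panoria_peak_areas.tsv"),
  individuals = read_individuals(fixture("panoria_individuals.tsv")),
  id_mapping = fixture("panoria_id_mapping_synthetic.tsv"),
  display = "round1", seed = 1))
rep
```
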