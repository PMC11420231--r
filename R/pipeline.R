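#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable constant of the three stages with the documented
#' defaults: Table-style peak-area cut-offs and the 10/1 carryover limit;
#' RY bounds 0.016/0.077 and RX bounds 0.6/0.8; depth tiers 100,000 and
#' 10,000 reads; two-decimal truncation display; probable calls included.
#'
#' @param peak_areas Path to a peak-area table, or a tibble, or `NULL` to
#'   skip the peptide stage.
#' @param idxstats Character vector of idxstats paths, or a list of
#'   `chrom_counts` tables, or `NULL` to skip the molecular stage.
#' @param individuals Path or tibble of already-sexed individuals
#'   (e.g. osteological calls), or `NULL`.
#' @param cutoffs A [cutoff_set()].
#' @param ry_bounds,rx_bounds,tiers See [molecular_sex()].
#' @param display,policy See [stratify_sex_ratio()].
#' @param id_mapping Named character vector mapping stage-level sample ids
#'   to canonical individual ids (see [merge_individuals()]), or the path
#'   to a two-column TSV (`sample_id`, `individual_id`). Required whenever
#'   the same individual enters through more than one stage; without it
#'   every sample id is taken as a distinct individual.
#' @param seed Integer seed recorded in run metadata and used by any
#'   simulation-backed input.
#' @param output_dir Directory for result tables, or `NULL` to skip
#'   writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(peak_areas = NULL, idxstats = NULL, individuals = NULL,
                       cutoffs = cutoff_set(),
                       ry_bounds = c(0.016, 0.077), rx_bounds = c(0.6, 0.8),
                       tiers = c(1e5, 1e4),
                       display = "trunc2", policy = "include_probable",
                       id_mapping = NULL, seed = NULL, output_dir = NULL) {
  if (is.character(id_mapping) && length(id_mapping) == 1 &&
      is.null(names(id_mapping)) && file.exists(id_mapping)) {
    map_tbl <- readr::read_tsv(id_mapping, show_col_types = FALSE,
                               progress = FALSE)
    id_mapping <- stats::setNames(as.character(map_tbl[[2]]),
                                  as.character(map_tbl[[1]]))
  }
  if (is.null(peak_areas) && is.null(idxstats) && is.null(individuals)) {
    abort("at least one stage input (peak_areas, idxstats, individuals) is required")
  }
  structure(list(peak_areas = peak_areas, idxstats = idxstats,
                 individuals = individuals, cutoffs = cutoffs,
                 ry_bounds = ry_bounds, rx_bounds = rx_bounds, tiers = tiers,
                 display = display, policy = policy, id_mapping = id_mapping,
                 seed = seed, output_dir = output_dir),
            class = "run_config")
}

#' Merge per-method sex calls into one individuals table
#'
#' Concatenates individuals tables coming from different estimation
#' methods. When the same `individual_id` appears more than once with a
#' concordant sex (probable grades count as their definite sex), one
#' record is kept and the contributing methods are joined with `+`; the
#' call keeps the most confident grade. Discordant duplicate calls are
#' kept as a single flagged record with sex `indeterminate` (so they drop
#' out of all ratios) and raise a warning -- cross-method identity
#' conflicts are surfaced, never silently resolved.
#'
#' @param tables A list of individuals tibbles (see [read_individuals()]).
#' @param id_mapping Optional named character vector mapping source ids to
#'   canonical individual ids (applied before merging); identity when
#'   `NULL`.
#' @return One individuals tibble with an added logical `conflict` column.
#' @export
merge_individuals <- function(tables, id_mapping = NULL) {
  all <- dplyr::bind_rows(tables)
  if (!is.null(id_mapping)) {
    hit <- all$individual_id %in% names(id_mapping)
    all$individual_id[hit] <- unname(id_mapping[all$individual_id[hit]])
  }
  all$conflict <- FALSE
  base_sex <- function(s) sub("^P", "", s)
  merged <- lapply(split(all, all$individual_id), function(g) {
    if (nrow(g) == 1) return(g)
    sexes <- unique(base_sex(g$sex[g$sex != "indeterminate"]))
    rec <- g[1, ]
    rec$method <- paste(unique(g$method), collapse = "+")
    if (length(sexes) > 1) {
      warn(paste0("discordant sex calls for individual '", g$individual_id[1],
                  "': ", paste(unique(g$sex), collapse = " vs "),
                  "; record flagged and excluded from ratios"))
      rec$sex <- "indeterminate"
      rec$conflict <- TRUE
    } else if (length(sexes) == 1) {
      calls <- g$sex[g$sex != "indeterminate"]
      rec$sex <- if (any(calls %in% c("M", "F"))) sexes else paste0("P", sexes)
    }
    rec
  })
  out <- dplyr::bind_rows(merged)
  out[order(out$individual_id), ]
}

#' Run the full multi-proxy sexing and sex-ratio pipeline
#'
#' Executes the configured stages (peptide classification, molecular
#' sexing, consumption of given calls), merges all calls into one
#' individuals table, and produces stratified sex-ratio reports by tomb,
#' phase, method and age class under both probable-inclusion policies.
#' With `output_dir` set, every table plus a key-value run summary is
#' written as TSV; output ordering is fixed so regeneration under the
#' same config is byte-identical.
#'
#' @param cfg A [run_config()].
#' @return A list of class `run_report`: `peptide` (calls + summary or
#'   `NULL`), `molecular` (per-sample call table or `NULL`), `individuals`
#'   (merged table), `sex_ratios` (tibble over stratification x policy),
#'   `metadata`.
#' @export
run_all <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  peptide <- NULL
  pep_records <- NULL
  if (!is.null(cfg$peak_areas)) {
    areas <- if (is.character(cfg$peak_areas)) read_peak_areas(cfg$peak_areas) else cfg$peak_areas
    peptide <- classify_peptide_batch(areas, cfg$cutoffs)
    pep_records <- tibble::tibble(
      individual_id = peptide$calls$sample_id,
      tomb = "unknown", phase = "unknown", method = "proteomics",
      sex = dplyr::recode(peptide$calls$call, female = "F", male = "M",
                          indeterminate = "indeterminate"),
      age_class = "unknown"
    )
  }

  molecular <- NULL
  mol_records <- NULL
  if (!is.null(cfg$idxstats)) {
    tables <- if (is.character(cfg$idxstats)) {
      lapply(cfg$idxstats, read_idxstats)
    } else cfg$idxstats
    molecular <- purrr::map_dfr(tables, molecular_sex, ry_bounds = cfg$ry_bounds,
                                rx_bounds = cfg$rx_bounds, tiers = cfg$tiers)
    mol_records <- tibble::tibble(
      individual_id = molecular$sample_id,
      tomb = "unknown", phase = "unknown", method = "aDNA",
      sex = molecular$final, age_class = "unknown"
    )
  }

  given <- NULL
  if (!is.null(cfg$individuals)) {
    given <- if (is.character(cfg$individuals)) read_individuals(cfg$individuals) else cfg$individuals
  }

  pieces <- Filter(Negate(is.null), list(given, pep_records, mol_records))
  individuals <- merge_individuals(pieces, id_mapping = cfg$id_mapping)

  strat_axes <- c("none", "tomb", "phase", "method", "age_class")
  policies <- c("include_probable", "definite_only")
  sex_ratios <- purrr::map_dfr(strat_axes, function(ax) {
    purrr::map_dfr(policies, function(pol) {
      res <- stratify_sex_ratio(individuals, by = ax, policy = pol,
                                display = cfg$display)
      res$stratification <- ax
      res$policy <- pol
      res[, c("stratification", "policy", setdiff(names(res), c("stratification", "policy")))]
    })
  })
  sex_ratios <- sex_ratios[order(sex_ratios$stratification, sex_ratios$stratum,
                                 sex_ratios$policy), ]

  report <- structure(list(
    peptide = peptide, molecular = molecular, individuals = individuals,
    sex_ratios = tibble::as_tibble(sex_ratios),
    metadata = list(package_version = as.character(utils::packageVersion("paleosex")),
                    seed = cfg$seed, policy = cfg$policy, display = cfg$display,
                    ry_bounds = cfg$ry_bounds, rx_bounds = cfg$rx_bounds,
                    tiers = cfg$tiers,
                    upstream_filters = "assumes MAPQ>=25 and duplicate removal already applied")
  ), class = "run_report")

  if (!is.null(cfg$output_dir)) write_run_report(report, cfg$output_dir)
  report
}

#' Write a run report to a directory
#'
#' Writes each stage table as TSV plus `run_summary.txt`, a one-document
#' key-value summary of the run.
#'
#' @param report A `run_report` from [run_all()].
#' @param dir Output directory (created if needed).
#' @return `report`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$peptide)) {
    write_result_table(report$peptide$calls, file.path(dir, "peptide_calls.tsv"))
  }
  if (!is.null(report$molecular)) {
    write_result_table(report$molecular, file.path(dir, "molecular_calls.tsv"))
  }
  write_result_table(report$individuals, file.path(dir, "individuals.tsv"))
  write_result_table(report$sex_ratios, file.path(dir, "sex_ratios.tsv"))
  md <- report$metadata
  lines <- vapply(names(md), function(k) {
    paste0(k, ": ", paste(format(md[[k]], trim = TRUE), collapse = " "))
  }, character(1))
  writeLines(lines, file.path(dir, "run_summary.txt"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Multi-proxy sexing run\n")
  if (!is.null(x$peptide)) {
    cat(sprintf("  peptide calls: %s\n",
                paste(names(x$peptide$summary), x$peptide$summary,
                      sep = "=", collapse = ", ")))
  }
  if (!is.null(x$molecular)) {
    cat(sprintf("  molecular calls: %d samples\n", nrow(x$molecular)))
  }
  cat(sprintf("  individuals: %d (%d conflict-flagged)\n",
              nrow(x$individuals), sum(x$individuals$conflict)))
  overall <- x$sex_ratios[x$sex_ratios$stratification == "none", ]
  for (i in seq_len(nrow(overall))) {
    cat(sprintf("  overall SR [%s]: %s (%s)\n", overall$policy[i],
                overall$sr_display[i], overall$range_class[i]))
  }
  invisible(x)
}
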