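#' Read a table of amelogenin peptide peak areas
#'
#' Parses a delimited table of integrated peak areas for the five
#' sex-diagnostic amelogenin peptides (AMELOGENIN-Y1/Y2/Y3 from AMELY,
#' AMELOGENIN-X1/X2 from AMELX), one row per tooth sample. Areas are
#' arbitrary-unit integrated intensities as exported from targeted LC-MS/MS
#' peak integration; a value of 0 means no peak above the instrument cut-off
#' was recorded. Blank or missing cells are coerced to 0 with a warning.
#'
#' Column matching is by header name, case-insensitively and ignoring
#' punctuation, so `AMELOGENIN-Y1`, `area_y1` and `Y1` all address the same
#' peptide. Column order is not significant.
#'
#' @param path Path to a TSV/CSV file. The header must name a sample
#'   identifier column and the five peptides.
#' @param dialect Field delimiter. `NULL` (default) auto-detects tab vs
#'   comma from the header line; otherwise a single character.
#' @return A tibble with columns `sample_id`, `area_y1`, `area_y2`,
#'   `area_y3`, `area_x1`, `area_x2`.
#' @examples
#' path <- system.file("extdata", "panoria_peak_areas.tsv", package = "paleosex")
#' read_peak_areas(path)
#' @export
read_peak_areas <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- dialect %||% detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  key <- normalize_header(names(raw))
  wanted <- c(sample_id = "sample", area_y1 = "y1", area_y2 = "y2",
              area_y3 = "y3", area_x1 = "x1", area_x2 = "x2")
  idx <- match(wanted, key)
  if (anyNA(idx)) {
    abort(paste0("peak-area header must name a sample column and the five ",
                 "amelogenin peptides; missing: ",
                 paste(names(wanted)[is.na(idx)], collapse = ", ")))
  }
  out <- tibble::tibble(sample_id = as.character(raw[[idx[1]]]))
  for (j in 2:6) {
    col <- raw[[idx[j]]]
    blank <- is.na(col) | trimws(col) == ""
    if (any(blank)) {
      warn(paste0(sum(blank), " blank area cell(s) in column '",
                  names(wanted)[j], "' coerced to 0"))
      col[blank] <- "0"
    }
    val <- suppressWarnings(as.numeric(col))
    if (anyNA(val)) abort(paste0("non-numeric area in column '", names(wanted)[j], "'"))
    if (any(val < 0)) abort(paste0("negative peak area in column '", names(wanted)[j],
                                   "': areas must be >= 0"))
    out[[names(wanted)[j]]] <- val
  }
  if (anyDuplicated(out$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", ")))
  }
  out
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

normalize_header <- function(x) {
  x <- tolower(x)
  x <- gsub("amelogenin|amel|area|precursor", "", x)
  x <- gsub("[^a-z0-9]", "", x)
  x[x %in% c("sampleid", "sample", "id", "anchemid")] <- "sample"
  x
}

#' Read per-chromosome mapped-read counts (idxstats format)
#'
#' Reads the four-column tab-separated per-chromosome summary emitted by
#' `samtools idxstats` (reference name, sequence length, mapped reads,
#' unmapped reads) and assigns each retained chromosome a role: one of the
#' 22 autosomes, X, or Y. Mitochondrial, unplaced and decoy contigs are
#' excluded from all role sets. Counts are assumed to come from an already
#' quality- and duplicate-filtered alignment.
#'
#' @param path Path to an idxstats-format TSV (no header).
#' @param config Name mapping produced by [chrom_config()]; handles
#'   `"chrX"`/`"X"` style dialects.
#' @param sample_id Sample label; defaults to the file name without
#'   extension.
#' @return An object of class `chrom_counts`: a tibble with columns
#'   `chrom`, `length`, `mapped`, `role`, carrying attributes `sample_id`
#'   and `total_reads` (sum of mapped reads over retained chromosomes).
#' @export
read_idxstats <- function(path, config = chrom_config(),
                          sample_id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_names = c("chrom", "length", "mapped", "unmapped"),
                         col_types = "cccc", progress = FALSE, show_col_types = FALSE)
  for (col in c("length", "mapped")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v) || any(v != floor(v))) {
      abort(paste0("non-integer value in idxstats column '", col, "'"))
    }
    raw[[col]] <- v
  }
  chrom_counts(chrom = raw$chrom, length = raw$length, mapped = raw$mapped,
               config = config,
               sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Chromosome-name role mapping
#'
#' Maps reference-dialect chromosome names onto the roles used by the sex
#' estimators. The default strips an optional `chr` prefix and recognises
#' `1`..`22` as autosomes and `X`/`Y` (case-insensitive); everything else
#' (mitochondrion, unplaced contigs, `*`) is excluded.
#'
#' @param autosomes,x,y Character vectors of accepted names (without regard
#'   to a `chr` prefix).
#' @return A list used by [read_idxstats()] and [chrom_counts()].
#' @export
chrom_config <- function(autosomes = as.character(1:22), x = "X", y = "Y") {
  list(autosomes = toupper(autosomes), x = toupper(x), y = toupper(y))
}

#' Construct a per-chromosome count table
#'
#' Lower-level constructor behind [read_idxstats()], useful for building
#' tables in code (e.g. from the read simulator).
#'
#' @param chrom Character vector of chromosome names.
#' @param length Positive integer chromosome lengths (bp).
#' @param mapped Non-negative integer mapped-read counts.
#' @param config Role mapping, see [chrom_config()].
#' @param sample_id Sample label.
#' @return A `chrom_counts` tibble (see [read_idxstats()]).
#' @export
chrom_counts <- function(chrom, length, mapped, config = chrom_config(),
                         sample_id = "sample") {
  if (anyDuplicated(chrom)) abort("duplicate chromosome names")
  stripped <- toupper(sub("^chr", "", chrom, ignore.case = TRUE))
  role <- dplyr::case_when(
    stripped %in% config$autosomes ~ "autosome",
    stripped %in% config$x ~ "X",
    stripped %in% config$y ~ "Y",
    TRUE ~ "excluded"
  )
  if (sum(role == "X") != 1L) abort("X chromosome must be present exactly once")
  if (sum(role == "Y") != 1L) abort("Y chromosome must be present exactly once")
  if (sum(role == "autosome") < 1L) abort("at least one autosome required")
  tbl <- tibble::tibble(chrom = chrom, length = as.numeric(length),
                        mapped = as.numeric(mapped), role = role)
  tbl <- tbl[tbl$role != "excluded", ]
  if (any(tbl$length <= 0)) abort("chromosome lengths must be positive")
  if (any(tbl$mapped < 0)) abort("mapped-read counts must be non-negative")
  structure(tbl, class = c("chrom_counts", class(tbl)),
            sample_id = sample_id, total_reads = sum(tbl$mapped))
}

#' Read a table of buried individuals
#'
#' Reads one row per sexed individual: tomb, ritual phase, estimation
#' method, sex call and age class, with any radiocarbon columns carried
#' through as opaque text. Values are normalised to closed enumerations
#' (e.g. `"Phase A"` to `A`, `"Probably male"` to `PM`, `"Adult (26-40)"`
#' to `adult`); the placeholder `"x"` or a blank phase becomes `unknown`
#' with a warning. Any value outside the enumerations is a hard error
#' naming the offending row.
#'
#' @param path Path to a TSV/CSV with header columns (case-insensitive)
#'   `tomb`, `phase`, `method`, `sex`, an age column, and optionally
#'   `individual_id`.
#' @param dialect Field delimiter; `NULL` auto-detects.
#' @return A tibble with columns `individual_id`, `tomb`, `phase`
#'   (`A`/`B`/`unknown`), `method` (`osteology`/`proteomics`/`aDNA`),
#'   `sex` (`M`/`PM`/`F`/`PF`/`indeterminate`), `age_class`
#'   (`adult`/`non-adult`/`unknown`), plus passthrough columns.
#' @examples
#' path <- system.file("extdata", "panoria_individuals.tsv", package = "paleosex")
#' ind <- read_individuals(path)
#' table(ind$method)
#' @export
read_individuals <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- dialect %||% detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  key <- tolower(gsub("[^a-z0-9]", "", tolower(names(raw))))
  pick <- function(candidates) {
    i <- which(key %in% candidates)
    if (length(i) == 0) abort(paste0("individuals table missing column: ",
                                     candidates[1]))
    i[1]
  }
  i_tomb <- pick("tomb"); i_phase <- pick("phase"); i_method <- pick("method")
  i_sex <- pick("sex")
  i_age <- pick(c("ageclass", "age", "ageatdeath"))
  i_id <- which(key %in% c("individualid", "id"))

  n <- nrow(raw)
  out <- tibble::tibble(
    individual_id = if (length(i_id)) as.character(raw[[i_id[1]]]) else sprintf("IND-%03d", seq_len(n)),
    tomb = as.character(raw[[i_tomb]]),
    phase = normalize_phase(raw[[i_phase]]),
    method = normalize_enum(raw[[i_method]], c(
      osteology = "osteology", proteomics = "proteomics", adna = "aDNA"), "method"),
    sex = normalize_sex(raw[[i_sex]]),
    age_class = normalize_age(raw[[i_age]])
  )
  extra <- setdiff(seq_along(raw), c(i_tomb, i_phase, i_method, i_sex, i_age, i_id))
  for (j in extra) out[[names(raw)[j]]] <- as.character(raw[[j]])
  out
}

normalize_phase <- function(x) {
  s <- tolower(trimws(as.character(x)))
  s <- sub("^phase\\s*", "", s)
  unknown <- is.na(s) | s %in% c("", "x", "unknown", "na")
  if (any(unknown)) {
    warn(paste0(sum(unknown), " phase value(s) coerced to 'unknown'"))
    s[unknown] <- "unknown"
  }
  bad <- !s %in% c("a", "b", "unknown")
  if (any(bad)) abort(paste0("unknown phase value '", x[bad][1], "' at row ", which(bad)[1]))
  unname(c(a = "A", b = "B", unknown = "unknown")[s])
}

normalize_sex <- function(x) {
  s <- gsub("[^a-z]", "", tolower(as.character(x)))
  map <- c(m = "M", male = "M", pm = "PM", probablymale = "PM", probablemale = "PM",
           f = "F", female = "F", pf = "PF", probablyfemale = "PF",
           probablefemale = "PF", indeterminate = "indeterminate",
           ind = "indeterminate", unknown = "indeterminate")
  out <- unname(map[s])
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    abort(paste0("unknown sex value '", x[bad], "' at row ", bad))
  }
  out
}

normalize_age <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(s))
  out[grepl("^non[- ]?adult", s)] <- "non-adult"
  out[is.na(out) & grepl("^adult", s)] <- "adult"
  out[is.na(out) & (s %in% c("", "x", "unknown", "na") | is.na(s))] <- "unknown"
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    abort(paste0("unknown age class '", x[bad], "' at row ", bad))
  }
  out
}

normalize_enum <- function(x, map, what) {
  s <- gsub("[^a-z]", "", tolower(as.character(x)))
  out <- unname(map[s])
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    abort(paste0("unknown ", what, " value '", x[bad], "' at row ", bad))
  }
  out
}

#' Write a result table as TSV
#'
#' Numeric columns are written with full precision (15 significant digits)
#' so a write/read round trip preserves integers exactly and reals to at
#' least 12 significant digits.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_result_table <- function(x, path) {
  out <- as.data.frame(x)
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}
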