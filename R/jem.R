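#' Construct a job-exposure matrix
#'
#' A job-exposure matrix (JEM) assigns an arithmetic-mean airborne fibre
#' concentration (f/mL) and its standard deviation to each
#' factory x job x calendar-period combination. Combinations that were never
#' measured are simply absent — they are never zero-filled, so downstream
#' grids produce no prediction for them.
#'
#' @param cells a data frame with columns `factory`, `job`, `period_start`,
#'   `period_end`, `mean_f_ml`, `sd_f_ml`, and optionally `n_samples` and
#'   `flag` (TRUE for care-and-maintenance periods).
#' @param provenance free-text source tag stored as an attribute.
#' @return a `jem` object (a tibble of cells).
#' @export
jem <- function(cells, provenance = "unspecified") {
  cells <- tibble::as_tibble(cells)
  required <- c("factory", "job", "period_start", "period_end",
                "mean_f_ml", "sd_f_ml")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    stop("JEM is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"n_samples" %in% names(cells)) cells$n_samples <- NA_integer_
  if (!"flag" %in% names(cells)) cells$flag <- FALSE
  cells$flag[is.na(cells$flag)] <- FALSE

  key <- paste(cells$factory, cells$job, cells$period_start,
               cells$period_end, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (factory, job, period) keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  if (any(cells$mean_f_ml < 0, na.rm = TRUE)) {
    stop("negative mean concentration in JEM", call. = FALSE)
  }
  if (any(cells$sd_f_ml < 0, na.rm = TRUE)) {
    stop("negative standard deviation in JEM", call. = FALSE)
  }
  if (any(cells$period_start > cells$period_end, na.rm = TRUE)) {
    stop("period_start exceeds period_end in JEM", call. = FALSE)
  }
  structure(cells, class = c("jem", class(cells)),
            provenance = provenance)
}

#' Read a job-exposure matrix from CSV
#'
#' Expects the header `factory,job,period_start,period_end,mean_f_ml,sd_f_ml,
#' n_samples,flag` (UTF-8, "." decimal separator). Rows whose mean field is
#' empty or `-` are skipped: a missing JEM cell is absent, not zero.
#'
#' @param path CSV file path. Defaults to the bundled two-factory chrysotile
#'   JEM.
#' @return a [jem] object.
#' @export
load_jem <- function(path = ardrisk_fixture("jem")) {
  if (!file.exists(path)) {
    stop("JEM file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("factory", "job", "period_start", "period_end",
                "mean_f_ml", "sd_f_ml")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("JEM header is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(raw$mean_f_ml) & trimws(raw$mean_f_ml) != "" &
    trimws(raw$mean_f_ml) != "-"
  raw <- raw[keep, , drop = FALSE]

  parse_col <- function(col, line_tag) {
    tryCatch(parse_printed_number(col),
             error = function(e) stop("malformed ", line_tag, " in ", path,
                                      ": ", conditionMessage(e), call. = FALSE))
  }
  cells <- tibble::tibble(
    factory = raw$factory,
    job = raw$job,
    period_start = as.integer(raw$period_start),
    period_end = as.integer(raw$period_end),
    mean_f_ml = parse_col(raw$mean_f_ml, "mean_f_ml"),
    sd_f_ml = parse_col(raw$sd_f_ml, "sd_f_ml"),
    n_samples = if ("n_samples" %in% names(raw)) {
      suppressWarnings(as.integer(raw$n_samples))
    } else NA_integer_,
    flag = if ("flag" %in% names(raw)) {
      toupper(trimws(ifelse(is.na(raw$flag), "FALSE", raw$flag))) == "TRUE"
    } else FALSE
  )
  jem(cells, provenance = path)
}

#' Write a job-exposure matrix to CSV
#'
#' Inverse of [load_jem()]: `load_jem(write_jem(x, path))` reproduces `x`
#' field for field.
#'
#' @param x a [jem] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_jem <- function(x, path) {
  stopifnot(inherits(x, "jem"))
  out <- tibble::as_tibble(x)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @export
print.jem <- function(x, ...) {
  cat("Job-exposure matrix: ", nrow(x), " cells, ",
      length(unique(x$factory)), " factories (source: ",
      attr(x, "provenance"), ")\n", sep = "")
  NextMethod()
}

#' Read the OSHA cancer-mortality calibration table
#'
#' Parses the table of estimated asbestos-related cancer mortality per
#' 100,000 exposed workers by fibre concentration (f/mL) and exposure
#' duration (1, 20, 45 years), covering lung cancer, mesothelioma, and
#' gastrointestinal cancer plus the printed total. Printed comma dialects
#' ("14,4" as a decimal, "13,996.7" as thousands) are normalized by
#' [parse_printed_number()].
#'
#' @param path CSV file path with header `duration_years,conc_f_ml,
#'   lung_per_100k,meso_per_100k,gi_per_100k,total_per_100k`. Defaults to the
#'   bundled table.
#' @return a tibble, one row per (duration, concentration) entry.
#' @export
load_osha_table <- function(path = ardrisk_fixture("osha")) {
  if (!file.exists(path)) {
    stop("OSHA table file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("duration_years", "conc_f_ml", "lung_per_100k",
                "meso_per_100k", "gi_per_100k", "total_per_100k")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("OSHA table header is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows <- tibble::tibble(
    duration_years = parse_printed_number(raw$duration_years),
    conc_f_ml = parse_printed_number(raw$conc_f_ml),
    lung_per_100k = parse_printed_number(raw$lung_per_100k),
    meso_per_100k = parse_printed_number(raw$meso_per_100k),
    gi_per_100k = parse_printed_number(raw$gi_per_100k),
    total_per_100k = parse_printed_number(raw$total_per_100k)
  )
  if (any(rows$conc_f_ml <= 0) || any(rows$duration_years <= 0)) {
    stop("OSHA table requires positive concentration and duration",
         call. = FALSE)
  }
  key <- paste(rows$duration_years, rows$conc_f_ml)
  if (anyDuplicated(key)) {
    stop("duplicate (duration, concentration) rows in OSHA table: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  rows
}

#' Internal-consistency check of the calibration table
#'
#' Flags rows whose printed per-cancer components do not add up to the
#' printed total within `tol` cases per 100,000 (severity `"warning"`), and
#' any negative mortality entry (severity `"error"`). The input is never
#' modified. In the bundled table exactly one row fails the sum check: the
#' 20-year, 10.0 f/mL row, whose components sum to 19,418.7 against a
#' printed total of 13,996.7.
#'
#' @param rows a tibble from [load_osha_table()].
#' @param tol absolute tolerance on `|lung + meso + gi - total|`, in cases
#'   per 100,000.
#' @return a `validation_report`: list with `issues` (tibble of severity,
#'   location, message) and `passed` (TRUE iff no `"error"` issue).
#' @export
validate_osha_table <- function(rows, tol = 1.0) {
  issues <- tibble::tibble(severity = character(), location = character(),
                           message = character())
  loc <- sprintf("duration %g yr, conc %g f/mL",
                 rows$duration_years, rows$conc_f_ml)
  neg <- rows$lung_per_100k < 0 | rows$meso_per_100k < 0 |
    rows$gi_per_100k < 0 | rows$total_per_100k < 0
  if (any(neg)) {
    issues <- dplyr::bind_rows(issues, tibble::tibble(
      severity = "error", location = loc[neg],
      message = "negative mortality value"
    ))
  }
  comp_sum <- rows$lung_per_100k + rows$meso_per_100k + rows$gi_per_100k
  off <- abs(comp_sum - rows$total_per_100k) > tol & !neg
  if (any(off)) {
    issues <- dplyr::bind_rows(issues, tibble::tibble(
      severity = "warning", location = loc[off],
      message = sprintf("components sum to %.1f but printed total is %.1f",
                        comp_sum[off], rows$total_per_100k[off])
    ))
  }
  report <- list(issues = issues,
                 passed = !any(issues$severity == "error"))
  class(report) <- "validation_report"
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report:", if (x$passed) "passed" else "FAILED",
      sprintf("(%d issue%s)\n", nrow(x$issues),
              if (nrow(x$issues) == 1) "" else "s"))
  if (nrow(x$issues) > 0) {
    for (i in seq_len(nrow(x$issues))) {
      cat(sprintf("  [%s] %s: %s\n", x$issues$severity[i],
                  x$issues$location[i], x$issues$message[i]))
    }
  }
  invisible(x)
}

#' Read the transcribed published cancer grid
#'
#' Long-format transcription of the published summary of total cancer
#' mortality cases per 100,000 exposed (and % incidence) by factory, job,
#' time period, and exposure duration. Used as a regression reference for
#' [build_cancer_grid()].
#'
#' @param path CSV path; defaults to the bundled transcription.
#' @return tibble with columns factory, job, period_start, period_end,
#'   mean_f_ml, duration_years, total_per_100k, incidence_pct.
#' @export
load_reference_cancer_grid <- function(path = ardrisk_fixture("cancer_reference")) {
  wide <- readr::read_csv(path, col_types = readr::cols(
    factory = readr::col_character(), job = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  long <- tidyr::pivot_longer(
    wide,
    cols = dplyr::matches("^(total|inc)_"),
    names_to = c(".value", "duration"),
    names_pattern = "(total|inc)_([0-9]+)y"
  )
  dplyr::transmute(
    long,
    factory = .data$factory, job = .data$job,
    period_start = as.integer(.data$period_start),
    period_end = as.integer(.data$period_end),
    mean_f_ml = .data$mean_f_ml,
    duration_years = as.numeric(.data$duration),
    total_per_100k = .data$total,
    incidence_pct = .data$inc
  )
}

#' Read the transcribed published asbestosis grid
#'
#' Transcription of the published cumulative-exposure and asbestosis
#' incidence table at 25 years of exposure, with a `suspected_typo` flag on
#' the three cells whose printed values contradict the table's own rounding
#' convention (see the package vignette).
#'
#' @param path CSV path; defaults to the bundled transcription.
#' @return tibble, one row per JEM cell.
#' @export
load_reference_asbestosis_grid <- function(path = ardrisk_fixture("asbestosis_reference")) {
  readr::read_csv(path, col_types = readr::cols(
    factory = readr::col_character(), job = readr::col_character(),
    suspected_typo = readr::col_logical(),
    .default = readr::col_double()
  ), progress = FALSE)
}
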