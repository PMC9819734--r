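#' Configure the projection pipeline
#'
#' Collects every tunable of the end-to-end run: input paths (bundled
#' fixtures by default), calibration mode, intercept handling, exposure
#' durations, asbestosis slope, per-1000 policy thresholds, output
#' directory, seed, and verbosity. Invalid settings fail here, naming the
#' offending field, so [run_pipeline()] can assume a sound configuration.
#'
#' @param jem_path path to the JEM CSV.
#' @param osha_path path to the calibration-table CSV.
#' @param mode calibration mode (see [calibrate_models()]).
#' @param with_intercept intercept flag for the OLS calibration modes.
#' @param durations cancer-grid exposure durations, years.
#' @param m asbestosis incidence slope, % per f/mL-year.
#' @param thresholds_per_1000 policy thresholds for risk classification.
#' @param asbestosis_duration duration for the asbestosis grid, years.
#' @param out_dir directory for the output CSVs.
#' @param seed integer seed (only synthetic-data steps draw random numbers,
#'   but the seed is fixed up front for reproducibility).
#' @param verbose print progress to standard error?
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(jem_path = ardrisk_fixture("jem"),
                            osha_path = ardrisk_fixture("osha"),
                            mode = "implied",
                            with_intercept = TRUE,
                            durations = c(1, 10, 20, 25),
                            m = 0.055,
                            thresholds_per_1000 = c(1, 4),
                            asbestosis_duration = 25,
                            out_dir = tempfile("ardrisk-run-"),
                            seed = 1,
                            verbose = FALSE) {
  if (length(durations) == 0 || any(durations <= 0)) {
    stop("config field 'durations' must be non-empty and positive",
         call. = FALSE)
  }
  if (any(thresholds_per_1000 <= 0)) {
    stop("config field 'thresholds_per_1000' must be positive", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1 || m <= 0) {
    stop("config field 'm' must be a positive number", call. = FALSE)
  }
  if (length(asbestosis_duration) != 1 || asbestosis_duration <= 0) {
    stop("config field 'asbestosis_duration' must be a positive number",
         call. = FALSE)
  }
  structure(
    list(jem_path = jem_path, osha_path = osha_path, mode = mode,
         with_intercept = with_intercept, durations = durations, m = m,
         thresholds_per_1000 = thresholds_per_1000,
         asbestosis_duration = asbestosis_duration, out_dir = out_dir,
         seed = as.integer(seed), verbose = verbose),
    class = "pipeline_config"
  )
}

#' Run the full projection pipeline
#'
#' Loads and validates the inputs, calibrates the per-cancer models, builds
#' the cancer and asbestosis grids and the per-1000 risk report, and writes
#' each as CSV under `config$out_dir`. Reruns with the same configuration
#' and seed produce byte-identical files. Validation findings are returned
#' (and surfaced on standard error when `verbose`); an `"error"`-severity
#' finding marks the run as failed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `calibration`, `cancer_grid`,
#'   `asbestosis_grid`, `risk`, `validation`, and `files` (named vector of
#'   written paths).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(...)
  set.seed(config$seed)

  if (!file.exists(config$jem_path)) {
    stop("cannot read JEM input: ", config$jem_path, call. = FALSE)
  }
  if (!file.exists(config$osha_path)) {
    stop("cannot read calibration input: ", config$osha_path, call. = FALSE)
  }
  jem <- load_jem(config$jem_path)
  say("loaded JEM with ", nrow(jem), " cells from ", config$jem_path)
  osha <- load_osha_table(config$osha_path)
  validation <- validate_osha_table(osha)
  for (i in seq_len(nrow(validation$issues))) {
    say(sprintf("calibration table [%s] %s: %s",
                validation$issues$severity[i], validation$issues$location[i],
                validation$issues$message[i]))
  }

  models <- calibrate_models(osha, mode = config$mode,
                             with_intercept = config$with_intercept)
  say("calibration mode: ", config$mode)
  calib <- calibration_report(models)
  cancer <- build_cancer_grid(jem, models, durations = config$durations)
  asb <- build_asbestosis_grid(jem, asbestosis_model(config$m),
                               d = config$asbestosis_duration)
  risk <- risk_report(cancer, thresholds_per_1000 = config$thresholds_per_1000)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    calibration = file.path(config$out_dir, "calibration.csv"),
    cancer_grid = file.path(config$out_dir, "cancer_grid.csv"),
    asbestosis_grid = file.path(config$out_dir, "asbestosis_grid.csv"),
    risk = file.path(config$out_dir, "risk_report.csv")
  )
  readr::write_csv(calib, files[["calibration"]], progress = FALSE)
  readr::write_csv(cancer, files[["cancer_grid"]], progress = FALSE)
  readr::write_csv(asb, files[["asbestosis_grid"]], progress = FALSE)
  readr::write_csv(risk, files[["risk"]], progress = FALSE)
  say("wrote ", length(files), " files under ", config$out_dir)

  invisible(list(calibration = calib, cancer_grid = cancer,
                 asbestosis_grid = asb, risk = risk,
                 validation = validation, files = files))
}

#' Compare a produced grid against a reference grid
#'
#' Joins on key columns and reports per-cell relative differences for each
#' value column, with a summary of the maximum and mean absolute relative
#' deviation and the list of cells exceeding `rel_tol`. Used to regression-
#' test the package's grids against transcriptions of the published tables.
#' Relative difference is `|produced - reference| / |reference|` (absolute
#' difference where the reference is 0).
#'
#' @param produced,reference data frames sharing `by` and `values` columns.
#' @param values named character vector mapping produced value columns to
#'   reference value columns (or a plain vector when names coincide).
#' @param by key columns to join on.
#' @param rel_tol tolerance on the relative difference; 0 demands exact
#'   agreement.
#' @return list with `cells` (per-cell long tibble including `rel_diff` and
#'   `exceeds`), `summary` (per value column), and `n_exceeding`.
#' @export
compare_to_reference <- function(produced, reference, values,
                                 by = c("factory", "job", "period_start",
                                        "period_end"),
                                 rel_tol = 0) {
  if (is.null(names(values)) || any(names(values) == "")) {
    names(values) <- values
  }
  missing_by <- setdiff(by, intersect(names(produced), names(reference)))
  if (length(missing_by) > 0) {
    stop("key columns absent from one grid: ",
         paste(missing_by, collapse = ", "), call. = FALSE)
  }
  key_of <- function(df) do.call(paste, c(df[by], sep = "|"))
  miss_in_ref <- setdiff(key_of(produced), key_of(reference))
  miss_in_prod <- setdiff(key_of(reference), key_of(produced))
  if (length(miss_in_ref) > 0 || length(miss_in_prod) > 0) {
    stop("grids do not cover the same cells; missing keys: ",
         paste(utils::head(c(miss_in_ref, miss_in_prod), 10), collapse = "; "),
         call. = FALSE)
  }
  ref <- reference[, c(by, unname(values))]
  names(ref)[match(unname(values), names(ref))] <-
    paste0("ref_", names(values))
  joined <- dplyr::inner_join(produced, ref, by = by)

  cells <- dplyr::bind_rows(lapply(names(values), function(v) {
    prod_v <- joined[[v]]
    ref_v <- joined[[paste0("ref_", v)]]
    denom <- ifelse(ref_v == 0, 1, abs(ref_v))
    rel <- abs(prod_v - ref_v) / denom
    tibble::tibble(joined[by], quantity = v, produced = prod_v,
                   reference = ref_v, rel_diff = rel,
                   exceeds = rel > rel_tol)
  }))
  summary <- dplyr::summarise(
    dplyr::group_by(cells, .data$quantity),
    n = dplyr::n(),
    max_rel_diff = max(.data$rel_diff),
    mean_rel_diff = mean(.data$rel_diff),
    n_exceeding = sum(.data$exceeds),
    .groups = "drop"
  )
  list(cells = cells, summary = summary, n_exceeding = sum(cells$exceeds))
}
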