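CANCER_TYPES <- c("lung", "mesothelioma", "gastrointestinal")

cancer_column <- function(cancer_type) {
  switch(cancer_type,
         lung = "lung_per_100k",
         mesothelioma = "meso_per_100k",
         gastrointestinal = "gi_per_100k",
         total = "total_per_100k",
         stop("unknown cancer type: '", cancer_type, "'", call. = FALSE))
}

new_dose_response_model <- function(cancer_type, slope, intercept, mode,
                                    r_squared = NA_real_, n_points = NA_integer_) {
  structure(
    list(cancer_type = cancer_type, slope = slope, intercept = intercept,
         mode = mode, r_squared = r_squared, n_points = n_points),
    class = "dose_response_model"
  )
}

#' @export
print.dose_response_model <- function(x, ...) {
  cat(sprintf(
    "Linear excess-risk model [%s, mode %s]: cases/100k = %.4f + %.4f * CE (R2 %s, n %s)\n",
    x$cancer_type, x$mode, x$intercept, x$slope,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
    ifelse(is.na(x$n_points), "NA", x$n_points)), sep = "")
  invisible(x)
}

#' Turn calibration-table rows into cumulative-exposure points
#'
#' Each (concentration, duration) entry of the calibration table becomes one
#' point with cumulative exposure `ce = conc * duration` (f/mL-years, exact
#' product) and the tabulated mortality per 100,000 for the requested cancer
#' type. Points are returned in ascending CE order.
#'
#' @param rows tibble from [load_osha_table()].
#' @param cancer_type `"lung"`, `"mesothelioma"`, `"gastrointestinal"`, or
#'   `"total"`.
#' @param ce_max optional cap: keep only points with `ce <= ce_max`.
#' @param durations optional subset of source durations (years) to keep.
#' @return tibble with columns `ce`, `mortality`, `cancer_type`,
#'   `source_duration`.
#' @export
extract_points <- function(rows, cancer_type, ce_max = NULL, durations = NULL) {
  col <- cancer_column(cancer_type)
  pts <- tibble::tibble(
    ce = rows$conc_f_ml * rows$duration_years,
    mortality = rows[[col]],
    cancer_type = cancer_type,
    source_duration = rows$duration_years
  )
  if (!is.null(durations)) {
    pts <- pts[pts$source_duration %in% durations, , drop = FALSE]
  }
  if (!is.null(ce_max)) {
    pts <- pts[pts$ce <= ce_max, , drop = FALSE]
  }
  if (nrow(pts) == 0) {
    stop("no calibration points after filtering", call. = FALSE)
  }
  pts[order(pts$ce), , drop = FALSE]
}

#' Ordinary least-squares dose-response fit
#'
#' Fits mortality per 100,000 as a linear function of cumulative exposure by
#' ordinary least squares (via [stats::lm()]), optionally through the
#' origin. The fit is closed-form and deterministic; on exactly collinear
#' input the coefficient of determination is 1.
#'
#' @param points tibble from [extract_points()] (columns `ce`, `mortality`).
#' @param with_intercept fit an intercept? With `FALSE` the line is forced
#'   through the origin (a single point then suffices).
#' @param mode label stored on the returned model.
#' @return a `dose_response_model` with fields `slope` (cases per 100,000
#'   per f/mL-year), `intercept` (cases per 100,000), `r_squared`,
#'   `n_points`.
#' @export
fit_linear <- function(points, with_intercept = TRUE, mode = "custom") {
  n <- nrow(points)
  min_n <- if (with_intercept) 2L else 1L
  if (n < min_n) {
    stop("need at least ", min_n, " calibration point(s)", call. = FALSE)
  }
  if (with_intercept && length(unique(points$ce)) < 2) {
    stop("singular fit: all points share one cumulative exposure",
         call. = FALSE)
  }
  fml <- if (with_intercept) mortality ~ ce else mortality ~ ce + 0
  fit <- stats::lm(fml, data = points)
  coefs <- stats::coef(fit)
  slope <- unname(coefs[["ce"]])
  intercept <- if (with_intercept) unname(coefs[["(Intercept)"]]) else 0
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- 1  # zero-variance response fitted exactly
  ct <- if ("cancer_type" %in% names(points) && nrow(points) > 0) {
    points$cancer_type[1]
  } else "unspecified"
  new_dose_response_model(ct, slope, intercept, mode, r2, n)
}

#' Zero-intercept models implied by the published worked example
#'
#' The published per-cancer regression equations are not legible, but the
#' worked example anchors them at one cumulative exposure: at
#' CE = 0.19 f/mL-years (1 year at 0.19 f/mL) the per-cancer grids show 13.7
#' lung, 8 mesothelioma, and 1.3 gastrointestinal cases per 100,000, summing
#' to 23. Dividing each by 0.19 yields zero-intercept unit-risk slopes that
#' reproduce that example exactly; they are the package's default
#' calibration.
#'
#' @return named list of `dose_response_model` objects for `lung`,
#'   `mesothelioma`, and `gastrointestinal`, mode `"implied"`.
#' @export
implied_models <- function() {
  anchors <- c(lung = 13.7, mesothelioma = 8, gastrointestinal = 1.3)
  models <- lapply(names(anchors), function(ct) {
    new_dose_response_model(ct, slope = anchors[[ct]] / 0.19, intercept = 0,
                            mode = "implied", r_squared = NA_real_,
                            n_points = 1L)
  })
  names(models) <- names(anchors)
  models
}

#' Calibrate per-cancer dose-response models
#'
#' Builds one linear excess-risk model per cancer type under a named
#' calibration mode:
#' \describe{
#'   \item{`"implied"`}{zero-intercept slopes reverse-derived from the
#'     published worked example ([implied_models()]); the default, because
#'     it is the only calibration the publication pins down exactly.}
#'   \item{`"pooled"`}{OLS over all rows of the calibration table.}
#'   \item{`"per-duration:D"`}{OLS restricted to the duration-D block
#'     (D in 1, 20, 45).}
#'   \item{`"low-ce:X"`}{OLS over points with CE <= X f/mL-years
#'     (default X = 10), the region closest to the factory exposures.}
#' }
#'
#' @param rows calibration table (ignored for mode `"implied"`); defaults to
#'   the bundled table.
#' @param mode calibration mode string.
#' @param with_intercept passed to [fit_linear()] for the OLS modes.
#' @return named list of `dose_response_model` for lung, mesothelioma,
#'   gastrointestinal.
#' @export
calibrate_models <- function(rows = NULL, mode = "implied",
                             with_intercept = TRUE) {
  if (identical(mode, "implied")) {
    return(implied_models())
  }
  if (is.null(rows)) rows <- load_osha_table()
  ce_max <- NULL
  durations <- NULL
  if (identical(mode, "pooled")) {
    # no filtering
  } else if (grepl("^per-duration:[0-9]+$", mode)) {
    durations <- as.numeric(sub("^per-duration:", "", mode))
    if (!durations %in% unique(rows$duration_years)) {
      stop("duration ", durations, " not present in calibration table",
           call. = FALSE)
    }
  } else if (grepl("^low-ce(:[0-9.]+)?$", mode)) {
    ce_max <- if (grepl(":", mode)) as.numeric(sub("^low-ce:", "", mode)) else 10
  } else {
    stop("unknown calibration mode: '", mode, "'", call. = FALSE)
  }
  models <- lapply(CANCER_TYPES, function(ct) {
    pts <- extract_points(rows, ct, ce_max = ce_max, durations = durations)
    fit_linear(pts, with_intercept = with_intercept, mode = mode)
  })
  names(models) <- CANCER_TYPES
  models
}

#' Tabulate calibrated models
#'
#' @param models named list of `dose_response_model` objects.
#' @return tibble with one row per model (cancer_type, mode, slope,
#'   intercept, r_squared, n_points), the calibration-report CSV schema.
#' @export
calibration_report <- function(models) {
  dplyr::bind_rows(lapply(models, function(m) {
    tibble::tibble(cancer_type = m$cancer_type, mode = m$mode,
                   slope = m$slope, intercept = m$intercept,
                   r_squared = m$r_squared, n_points = m$n_points)
  }))
}

#' Linear cumulative-dose asbestosis model
#'
#' Predicted asbestosis incidence follows `Ra = m * f * d` (percent), where
#' `f` is the fibre concentration (f/mL), `d` the exposure duration (years),
#' and `m` the slope of the underlying linear regression, 0.055 % incidence
#' per f/mL-year by default.
#'
#' @param m slope override (% incidence per f/mL-year); must be positive.
#' @return an `asbestosis_model` object.
#' @export
asbestosis_model <- function(m = 0.055) {
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m <= 0) {
    stop("asbestosis slope m must be a positive number", call. = FALSE)
  }
  structure(list(m = m), class = "asbestosis_model")
}

#' @export
print.asbestosis_model <- function(x, ...) {
  cat(sprintf("Asbestosis cumulative-dose model: Ra = %.3f * f * d (%% incidence)\n",
              x$m))
  invisible(x)
}
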