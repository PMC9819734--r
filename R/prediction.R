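#' Cumulative exposure in fibre/mL-years
#'
#' Cumulative exposure is the airborne fibre concentration a worker breathes
#' (f/mL) multiplied by the years worked at that level. Both the exact
#' product and its value rounded half-up to 1 decimal place are returned:
#' the published asbestosis grid rounds CE before applying the incidence
#' slope, while the cancer grid works from the exact product.
#'
#' @param f fibre concentration, f/mL (vectorized, `>= 0`).
#' @param d exposure duration, years (`> 0`).
#' @return tibble with columns `f`, `d`, `ce_exact`, `ce_rounded`.
#' @examples
#' cumulative_exposure(0.19, 25) # ce_exact 4.75, ce_rounded 4.8
#' @export
cumulative_exposure <- function(f, d) {
  if (any(f < 0)) stop("concentration f must be >= 0", call. = FALSE)
  if (any(d <= 0)) stop("duration d must be > 0", call. = FALSE)
  ce <- f * d
  tibble::tibble(f = f, d = d, ce_exact = ce,
                 ce_rounded = round_half_up(ce, 1))
}

#' Predict excess cancer mortality per 100,000 exposed
#'
#' Applies per-cancer linear excess-risk models to the exact cumulative
#' exposure `f * d`. Each per-cancer prediction `a + b * ce` is clamped at
#' zero; the total is their exact sum, also reported rounded to whole cases
#' with the derived percent incidence (`total / 1000`, 2 dp), matching the
#' published "cases (% incidence)" style. Durations beyond the 45-year span
#' of the calibration table trigger an extrapolation warning but still
#' return a value.
#'
#' @param models named list with `dose_response_model` entries `lung`,
#'   `mesothelioma`, `gastrointestinal` (e.g. from [calibrate_models()]).
#' @param f fibre concentration, f/mL (vectorized).
#' @param d exposure duration, years.
#' @return tibble with `f`, `d`, `ce_exact`, unrounded `lung`, `meso`, `gi`
#'   and `total` cases per 100,000, `total_per_100k` (half-up to whole
#'   cases), and `incidence_pct`.
#' @export
predict_cancer <- function(models, f, d) {
  missing_models <- setdiff(CANCER_TYPES, names(models))
  if (length(missing_models) > 0) {
    stop("missing dose-response model for: ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  }
  ce <- cumulative_exposure(f, d)
  if (any(ce$d > 45)) {
    warning("duration exceeds the 45-year calibration range; ",
            "predictions are extrapolations", call. = FALSE)
  }
  pred_one <- function(m) pmax(0, m$intercept + m$slope * ce$ce_exact)
  lung <- pred_one(models$lung)
  meso <- pred_one(models$mesothelioma)
  gi <- pred_one(models$gastrointestinal)
  total <- lung + meso + gi
  tibble::tibble(
    f = ce$f, d = ce$d, ce_exact = ce$ce_exact,
    lung = lung, meso = meso, gi = gi, total = total,
    total_per_100k = round_half_up(total, 0),
    incidence_pct = round_half_up(total / 1000, 2)
  )
}

#' Predict asbestosis incidence
#'
#' Evaluates the linear cumulative-dose model `Ra = m * f * d` with the
#' rounding conventions of the published grid: the incidence slope is
#' applied to the CE value already rounded to 1 decimal place, the resulting
#' percent incidence is rounded half-up to 2 decimal places, and cases per
#' 100,000 are incidence x 1000.
#'
#' @param model an [asbestosis_model()].
#' @param f fibre concentration, f/mL (vectorized).
#' @param d exposure duration, years (25 in the published grid).
#' @return tibble with `f`, `d`, `ce_exact`, `ce_rounded`, `ra_raw`
#'   (unrounded % incidence), `incidence_pct`, `cases_per_100k`.
#' @examples
#' predict_asbestosis(asbestosis_model(), 0.16, 25) # CE 4.0, 0.22 %, 220
#' @export
predict_asbestosis <- function(model, f, d) {
  stopifnot(inherits(model, "asbestosis_model"))
  ce <- cumulative_exposure(f, d)
  ra_raw <- model$m * ce$ce_rounded
  incidence_pct <- round_half_up(ra_raw, 2)
  tibble::tibble(
    f = ce$f, d = ce$d, ce_exact = ce$ce_exact, ce_rounded = ce$ce_rounded,
    ra_raw = ra_raw, incidence_pct = incidence_pct,
    cases_per_100k = round_half_up(incidence_pct * 1000, 0)
  )
}

#' Cancer-case grid over a job-exposure matrix
#'
#' One prediction per JEM cell and exposure duration. Factory-wide rows are
#' driven by the "Overall factory" cells of the JEM, which carry the
#' published factory-wide mean concentrations rather than a re-average of
#' job cells (the published averaging weights are unstated).
#'
#' @param jem a [jem] object.
#' @param models per-cancer models, e.g. [calibrate_models()].
#' @param durations exposure durations in years; the default
#'   `c(1, 10, 20, 25)` matches the published horizon, capped at 25 years by
#'   the span of the underlying exposure records.
#' @return tibble keyed by factory, job, period and duration, with the
#'   prediction columns of [predict_cancer()].
#' @export
build_cancer_grid <- function(jem, models, durations = c(1, 10, 20, 25)) {
  stopifnot(inherits(jem, "jem"))
  if (length(durations) == 0 || any(durations <= 0)) {
    stop("durations must be a non-empty set of positive years", call. = FALSE)
  }
  if (nrow(jem) == 0) {
    warning("empty JEM: returning an empty grid", call. = FALSE)
    return(tibble::tibble())
  }
  cells <- tibble::as_tibble(jem)
  grid <- tidyr::expand_grid(cells, duration_years = as.numeric(durations))
  pred <- predict_cancer(models, grid$mean_f_ml, grid$duration_years)
  dplyr::bind_cols(
    grid[, c("factory", "job", "period_start", "period_end", "mean_f_ml",
             "duration_years")],
    pred[, c("ce_exact", "lung", "meso", "gi", "total", "total_per_100k",
             "incidence_pct")]
  )
}

#' Asbestosis grid over a job-exposure matrix
#'
#' One [predict_asbestosis()] result per JEM cell at a single exposure
#' duration (default 25 years, the span of the exposure records).
#'
#' @param jem a [jem] object.
#' @param model an [asbestosis_model()].
#' @param d exposure duration, years.
#' @return tibble keyed by factory, job and period.
#' @export
build_asbestosis_grid <- function(jem, model = asbestosis_model(), d = 25) {
  stopifnot(inherits(jem, "jem"))
  if (length(d) != 1 || d <= 0) {
    stop("duration d must be a single positive number", call. = FALSE)
  }
  if (nrow(jem) == 0) {
    warning("empty JEM: returning an empty grid", call. = FALSE)
    return(tibble::tibble())
  }
  cells <- tibble::as_tibble(jem)
  pred <- predict_asbestosis(model, cells$mean_f_ml, d)
  dplyr::bind_cols(
    cells[, c("factory", "job", "period_start", "period_end", "mean_f_ml")],
    pred[, c("d", "ce_exact", "ce_rounded", "ra_raw", "incidence_pct",
             "cases_per_100k")]
  )
}

#' Convert cases per 100,000 to a per-1000 rate
#'
#' @param cases_per_100k nonnegative cases per 100,000 workers.
#' @return rate per 1,000 workers, rounded half-up to 2 decimal places.
#' @examples
#' per_1000(347) # 3.47
#' @export
per_1000 <- function(cases_per_100k) {
  if (any(cases_per_100k < 0)) {
    stop("cases per 100,000 must be >= 0", call. = FALSE)
  }
  round_half_up(cases_per_100k / 100, 2)
}

#' Classify excess risk against a policy threshold
#'
#' Regulatory practice treats an excess cancer mortality of more than 1 case
#' per 1,000 workers over a working lifetime as a significant risk (OSHA);
#' the Netherlands and Germany use 4 per 1,000. The comparison is a strict
#' inequality: a rate exactly at the threshold is not significant.
#'
#' @param rate_per_1000 nonnegative rate per 1,000 workers (vectorized).
#' @param threshold_per_1000 positive policy threshold per 1,000.
#' @return tibble with `rate_per_1000`, `threshold_per_1000`, `significant`.
#' @export
classify_risk <- function(rate_per_1000, threshold_per_1000 = 1) {
  if (any(rate_per_1000 < 0)) stop("rate must be >= 0", call. = FALSE)
  if (any(threshold_per_1000 <= 0)) stop("threshold must be > 0", call. = FALSE)
  tibble::tibble(
    rate_per_1000 = rate_per_1000,
    threshold_per_1000 = threshold_per_1000,
    significant = rate_per_1000 > threshold_per_1000
  )
}

#' Per-1000 risk report for a cancer grid
#'
#' Converts every grid cell's total cases per 100,000 to a per-1000 rate and
#' classifies it against each policy threshold.
#'
#' @param grid output of [build_cancer_grid()].
#' @param thresholds_per_1000 policy thresholds (default OSHA 1/1000 and
#'   Netherlands/Germany 4/1000).
#' @return tibble with one row per grid cell x threshold.
#' @export
risk_report <- function(grid, thresholds_per_1000 = c(1, 4)) {
  out <- tidyr::expand_grid(grid, threshold_per_1000 = thresholds_per_1000)
  rate <- per_1000(out$total_per_100k)
  cls <- classify_risk(rate, out$threshold_per_1000)
  dplyr::bind_cols(
    out[, c("factory", "job", "period_start", "period_end",
            "duration_years")],
    cls
  )
}
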