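#' Moment-matched lognormal parameters
#'
#' Solves for the `meanlog`/`sdlog` of a lognormal distribution whose
#' arithmetic mean and standard deviation equal the targets:
#' `sdlog^2 = log(1 + sd^2/mean^2)`, `meanlog = log(mean) - sdlog^2 / 2`.
#' Occupational exposure concentrations are conventionally modelled as
#' lognormal, which also guarantees positive draws.
#'
#' @param mean target arithmetic mean (> 0 unless `sd` is 0).
#' @param sd target standard deviation (>= 0).
#' @return list with `meanlog` and `sdlog`.
#' @export
lognormal_moment_params <- function(mean, sd) {
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  if (any(mean <= 0 & sd > 0)) {
    stop("mean must be > 0 when sd > 0", call. = FALSE)
  }
  sdlog2 <- ifelse(sd == 0, 0, log(1 + (sd / mean)^2))
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Define a synthetic personal-sampling campaign
#'
#' A campaign fixes, for every JEM cell to be emulated, the target
#' arithmetic mean and standard deviation of individual personal
#' measurements (f/mL), plus the sampling schedule (measurements per month,
#' number of months) and a random seed. The bundled defaults echo the scale
#' of the source data set — about 25 years of records condensed into ~1,700
#' monthly means from ~3,400 measurements over 48 job x period cells — but
#' every knob is explicit.
#'
#' @param cell_params data frame with columns `factory`, `job`,
#'   `period_start`, `period_end`, `target_mean`, `target_sd`.
#' @param samples_per_month measurements drawn per cell per month (>= 1).
#' @param months months sampled per cell (>= 1).
#' @param seed integer random seed.
#' @return a `sampling_campaign` object.
#' @export
sampling_campaign <- function(cell_params, samples_per_month = 2,
                              months = 36, seed = 1) {
  cell_params <- tibble::as_tibble(cell_params)
  required <- c("factory", "job", "period_start", "period_end",
                "target_mean", "target_sd")
  missing_cols <- setdiff(required, names(cell_params))
  if (length(missing_cols) > 0) {
    stop("cell_params missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (samples_per_month < 1 || months < 1) {
    stop("samples_per_month and months must be >= 1", call. = FALSE)
  }
  if (any(cell_params$target_sd < 0)) {
    stop("target_sd must be >= 0", call. = FALSE)
  }
  if (any(cell_params$target_mean <= 0 & cell_params$target_sd > 0)) {
    stop("target_mean must be > 0 when target_sd > 0", call. = FALSE)
  }
  structure(
    list(cell_params = cell_params,
         samples_per_month = as.integer(samples_per_month),
         months = as.integer(months), seed = as.integer(seed)),
    class = "sampling_campaign"
  )
}

#' Campaign emulating a job-exposure matrix
#'
#' Takes each JEM cell's mean and sd as the measurement-level targets.
#' Cells without a standard deviation (the factory-wide summary rows) are
#' excluded: they are derived quantities, not sampled strata.
#'
#' @param jem a [jem] object.
#' @inheritParams sampling_campaign
#' @return a `sampling_campaign`.
#' @export
campaign_from_jem <- function(jem, samples_per_month = 2, months = 36,
                              seed = 1) {
  stopifnot(inherits(jem, "jem"))
  cells <- tibble::as_tibble(jem)
  cells <- cells[!is.na(cells$sd_f_ml), , drop = FALSE]
  sampling_campaign(
    tibble::tibble(
      factory = cells$factory, job = cells$job,
      period_start = cells$period_start, period_end = cells$period_end,
      target_mean = cells$mean_f_ml, target_sd = cells$sd_f_ml
    ),
    samples_per_month = samples_per_month, months = months, seed = seed
  )
}

#' Draw synthetic personal measurements
#'
#' For every campaign cell and month, draws `samples_per_month` lognormal
#' concentrations whose arithmetic mean and sd are moment-matched to the
#' cell targets ([lognormal_moment_params()]). A zero target sd yields the
#' mean exactly on every draw. Fully reproducible: the campaign seed is set
#' once and cells are generated in their stored order, so identical
#' campaigns give bit-identical measurement sets.
#'
#' @param campaign a [sampling_campaign()].
#' @return tibble with columns `factory`, `job`, `period_start`,
#'   `period_end`, `month_index`, `conc_f_ml`.
#' @export
generate_measurements <- function(campaign) {
  stopifnot(inherits(campaign, "sampling_campaign"))
  set.seed(campaign$seed)
  cp <- campaign$cell_params
  n_per_cell <- campaign$samples_per_month * campaign$months
  draws <- lapply(seq_len(nrow(cp)), function(i) {
    if (cp$target_sd[i] == 0) {
      conc <- rep(cp$target_mean[i], n_per_cell)
    } else {
      p <- lognormal_moment_params(cp$target_mean[i], cp$target_sd[i])
      conc <- stats::rlnorm(n_per_cell, p$meanlog, p$sdlog)
    }
    tibble::tibble(
      factory = cp$factory[i], job = cp$job[i],
      period_start = cp$period_start[i], period_end = cp$period_end[i],
      month_index = rep(seq_len(campaign$months),
                        each = campaign$samples_per_month),
      conc_f_ml = conc
    )
  })
  dplyr::bind_rows(draws)
}

#' Aggregate measurements to monthly means
#'
#' Arithmetic mean per (factory, job, period, month) — the summary metric
#' used throughout, as is standard for chronic-disease exposure assessment
#' under a linear exposure-response model.
#'
#' @param measurements tibble from [generate_measurements()].
#' @return tibble with one row per distinct key and columns `monthly_mean`
#'   and `n_measurements`.
#' @export
aggregate_monthly <- function(measurements) {
  dplyr::summarise(
    dplyr::group_by(measurements, .data$factory, .data$job,
                    .data$period_start, .data$period_end, .data$month_index),
    monthly_mean = mean(.data$conc_f_ml),
    n_measurements = dplyr::n(),
    .groups = "drop"
  )
}

#' Rebuild a job-exposure matrix from monthly means
#'
#' Each JEM cell's concentration is the arithmetic mean of its monthly
#' means; the cell sd is the standard deviation of those monthly means and
#' `n_samples` counts them. Composing
#' `recover_jem(aggregate_monthly(generate_measurements(...)))` closes the
#' loop measurement -> monthly mean -> JEM and converges to the campaign
#' targets as the schedule grows.
#'
#' @param monthly tibble from [aggregate_monthly()].
#' @return a [jem] object.
#' @export
recover_jem <- function(monthly) {
  cells <- dplyr::summarise(
    dplyr::group_by(monthly, .data$factory, .data$job,
                    .data$period_start, .data$period_end),
    mean_f_ml = mean(.data$monthly_mean),
    sd_f_ml = stats::sd(.data$monthly_mean),
    n_samples = dplyr::n(),
    .groups = "drop"
  )
  cells$sd_f_ml[is.na(cells$sd_f_ml)] <- 0  # single-month cells
  jem(cells, provenance = "recovered from synthetic monthly means")
}
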