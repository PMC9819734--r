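test_that("cumulative exposure returns exact and 1-dp rounded values", {
  ce <- cumulative_exposure(0.19, 25)
  expect_equal(ce$ce_exact, 4.75)
  expect_equal(ce$ce_rounded, 4.8)  # half rounds up
  expect_equal(cumulative_exposure(0, 25)$ce_exact, 0)
  expect_equal(cumulative_exposure(0.1, 45)$ce_exact, 4.5)
  expect_error(cumulative_exposure(-0.1, 25), ">= 0")
  expect_error(cumulative_exposure(0.1, 0), "> 0")
})

test_that("half-up rounding follows the grid convention", {
  expect_equal(round_half_up(4.75, 1), 4.8)
  expect_equal(round_half_up(0.165, 2), 0.17)
  expect_equal(round_half_up(0.055 * 1.0, 2), 0.06)
  expect_equal(round_half_up(4.25, 1), 4.3)
  expect_equal(round_half_up(c(0.5, 1.5, 2.44), 0), c(1, 2, 2))
})

test_that("cancer prediction reproduces the published worked example", {
  p <- predict_cancer(implied_models(), 0.19, 1)
  expect_equal(p$lung, 13.7)
  expect_equal(p$meso, 8)
  expect_equal(p$gi, 1.3)
  expect_equal(p$total, 23)
  expect_equal(p$total_per_100k, 23)
  expect_equal(p$incidence_pct, 0.02)
})

test_that("cancer predictions depend on (f, d) only through cumulative exposure", {
  models <- implied_models()
  a <- predict_cancer(models, 0.19, 2)
  b <- predict_cancer(models, 0.38, 1)
  expect_equal(a[c("lung", "meso", "gi", "total")],
               b[c("lung", "meso", "gi", "total")])
})

test_that("cancer prediction handles edges: zero exposure, missing model, extrapolation", {
  models <- implied_models()
  z <- predict_cancer(models, 0, 10)
  expect_equal(z$total, 0)
  expect_error(predict_cancer(models[c("lung", "mesothelioma")], 0.1, 1),
               "gastrointestinal")
  expect_warning(predict_cancer(models, 0.1, 50), "45-year")
  # negative intercepts are clamped to zero cases, never negative
  neg <- list(
    lung = ardrisk:::new_dose_response_model("lung", 10, -5, "custom"),
    mesothelioma = ardrisk:::new_dose_response_model("mesothelioma", 5, -5, "custom"),
    gastrointestinal = ardrisk:::new_dose_response_model("gastrointestinal", 1, -5, "custom")
  )
  p <- predict_cancer(neg, 0.01, 1)
  expect_equal(p$total, 0)
})

test_that("predictions are monotone in concentration and duration", {
  models <- calibrate_models(load_osha_table(), mode = "low-ce:10")
  f_grid <- seq(0.02, 0.5, by = 0.04)
  d_grid <- c(1, 5, 10, 20, 25)
  for (d in d_grid) {
    tot <- predict_cancer(models, f_grid, d)$total
    expect_true(all(diff(tot) >= 0))
  }
  for (f in f_grid) {
    tot <- vapply(d_grid, function(d) predict_cancer(models, f, d)$total,
                  numeric(1))
    expect_true(all(diff(tot) >= 0))
    asb <- vapply(d_grid, function(d)
      predict_asbestosis(asbestosis_model(), f, d)$ra_raw, numeric(1))
    expect_true(all(diff(asb) >= 0))
  }
})

test_that("asbestosis prediction applies the slope to rounded CE", {
  m <- asbestosis_model()
  a <- predict_asbestosis(m, 0.16, 25)
  expect_equal(a$ce_rounded, 4.0)
  expect_equal(a$incidence_pct, 0.22)
  expect_equal(a$cases_per_100k, 220)
  b <- predict_asbestosis(m, 0.12, 25)
  expect_equal(b$incidence_pct, 0.17)
  expect_equal(b$cases_per_100k, 170)
  # the rounded-CE convention is what the published cells force:
  # 0.17 f/mL x 25 yr -> CE 4.3 -> 0.24 %, not round(0.055 * 4.25) = 0.23
  c_ <- predict_asbestosis(m, 0.17, 25)
  expect_equal(c_$ce_rounded, 4.3)
  expect_equal(c_$incidence_pct, 0.24)
  expect_equal(predict_asbestosis(m, 0, 25)$cases_per_100k, 0)
})

test_that("unrounded asbestosis incidence is exactly linear in rounded CE", {
  m <- asbestosis_model()
  one <- predict_asbestosis(m, 0.06, 25)   # ce_rounded 1.5
  two <- predict_asbestosis(m, 0.12, 25)   # ce_rounded 3.0
  expect_equal(two$ra_raw, 2 * one$ra_raw)
})

test_that("grids cover every JEM cell at every duration with exact additivity", {
  j <- load_jem()
  models <- implied_models()
  grid <- build_cancer_grid(j, models)
  expect_equal(nrow(grid), 4 * nrow(j))
  expect_equal(grid$total, grid$lung + grid$meso + grid$gi)
  expect_true(all(grid[c("lung", "meso", "gi", "total")] >= 0))

  asb <- build_asbestosis_grid(j)
  expect_equal(nrow(asb), nrow(j))
  expect_equal(max(asb$cases_per_100k), 260)
  harare_overall <- asb[asb$factory == "Harare" & asb$job == "Overall factory", ]
  expect_equal(harare_overall$ce_rounded, 2.8)
  expect_equal(harare_overall$cases_per_100k, 150)

  expect_error(build_cancer_grid(j, models, durations = numeric()), "durations")
  empty <- jem(tibble::as_tibble(j)[0, ])
  expect_warning(g0 <- build_cancer_grid(empty, models), "empty JEM")
  expect_equal(nrow(g0), 0)
})

test_that("per-1000 conversion and strict threshold classification", {
  expect_equal(per_1000(347), 3.47)
  expect_equal(per_1000(0), 0)
  expect_equal(per_1000(100), 1)
  expect_error(per_1000(-1), ">= 0")

  expect_true(classify_risk(3.47, 1)$significant)
  expect_false(classify_risk(3.47, 4)$significant)
  expect_false(classify_risk(1, 1)$significant)  # strictly greater than
  expect_error(classify_risk(-1, 1), ">= 0")
  expect_error(classify_risk(1, 0), "> 0")
})

test_that("risk report classifies each grid cell against each threshold", {
  j <- load_jem()
  grid <- build_cancer_grid(j, implied_models(), durations = 25)
  rep <- risk_report(grid, thresholds_per_1000 = c(1, 4))
  expect_equal(nrow(rep), 2 * nrow(grid))
  h25 <- rep[rep$job == "Overall factory" & rep$factory == "Harare", ]
  expect_true(h25$significant[h25$threshold_per_1000 == 1])
  expect_false(h25$significant[h25$threshold_per_1000 == 4])
})
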