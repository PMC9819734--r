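test_that("printed numeric tokens are normalized across both comma dialects", {
  expect_equal(parse_printed_number(c("14,4", "13.8", "10,476.9", "12,177")),
               c(14.4, 13.8, 10476.9, 12177))
  expect_equal(parse_printed_number(c("-", "", NA)), rep(NA_real_, 3))
  expect_error(parse_printed_number("12,34x"), "numeric")
})

test_that("bundled JEM has the non-missing cells of the published matrix", {
  j <- load_jem()
  jobs <- j[j$job != "Overall factory", ]
  expect_equal(sum(jobs$factory == "Harare"), 23)
  expect_equal(sum(jobs$factory == "Bulawayo"), 25)
  # factory-wide summary rows carried as cells with the published means
  overall <- j[j$job == "Overall factory", ]
  expect_equal(overall$mean_f_ml[overall$factory == "Harare"], 0.11)
  expect_equal(overall$mean_f_ml[overall$factory == "Bulawayo"], 0.12)
  # care-and-maintenance periods flagged, never encoded in the period label
  expect_true(all(j$flag[j$factory == "Harare" & j$period_start == 2018 &
                           j$job != "Overall factory"]))
  expect_false(any(j$flag[j$job == "Pipe joints operator"]))
})

test_that("single-row and header-only JEM files load correctly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("factory,job,period_start,period_end,mean_f_ml,sd_f_ml,n_samples,flag",
               "Harare,Saw cutting operator,1996,2000,0.19,0.01,,FALSE"), path)
  j <- load_jem(path)
  expect_equal(nrow(j), 1)
  expect_equal(j$mean_f_ml, 0.19)
  expect_equal(j$sd_f_ml, 0.01)

  writeLines("factory,job,period_start,period_end,mean_f_ml,sd_f_ml,n_samples,flag",
             path)
  expect_equal(nrow(load_jem(path)), 0)
})

test_that("missing means are skipped, never zero-filled", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("factory,job,period_start,period_end,mean_f_ml,sd_f_ml,n_samples,flag",
               "Harare,Saw cutting operator,1996,2000,0.19,0.01,,FALSE",
               "Harare,Saw cutting operator,2009,2016,-,,,FALSE",
               "Harare,Saw cutting operator,2018,2020,,,,FALSE"), path)
  j <- load_jem(path)
  expect_equal(nrow(j), 1)
  expect_false(any(j$mean_f_ml == 0))
})

test_that("JEM validation rejects duplicates, negatives, inverted periods", {
  cells <- tibble::as_tibble(toy_jem())
  expect_error(jem(dplyr::bind_rows(cells, cells[1, ])), "duplicate")
  bad <- cells; bad$mean_f_ml[1] <- -0.1
  expect_error(jem(bad), "negative mean")
  bad <- cells; bad$sd_f_ml[1] <- -1
  expect_error(jem(bad), "negative standard deviation")
  bad <- cells; bad$period_start[1] <- 2010L
  expect_error(jem(bad), "period_start")
})

test_that("JEM round-trips through CSV field for field", {
  j <- load_jem()
  path <- withr::local_tempfile(fileext = ".csv")
  write_jem(j, path)
  j2 <- load_jem(path)
  strip <- function(x) { x <- tibble::as_tibble(x); attr(x, "provenance") <- NULL; x }
  expect_equal(strip(j), strip(j2))
})

test_that("calibration table loads 21 normalized rows", {
  osha <- load_osha_table()
  expect_equal(nrow(osha), 21)
  expect_equal(sort(unique(osha$duration_years)), c(1, 20, 45))
  r <- osha[osha$duration_years == 1 & osha$conc_f_ml == 0.1, ]
  expect_equal(unlist(r[c("lung_per_100k", "meso_per_100k", "gi_per_100k",
                          "total_per_100k")], use.names = FALSE),
               c(7.2, 6.9, 0.7, 14.8))
  # comma-decimal and thousands-separator cells normalized on load
  expect_equal(osha$lung_per_100k[osha$duration_years == 1 &
                                    osha$conc_f_ml == 0.2], 14.4)
  expect_equal(osha$total_per_100k[osha$duration_years == 20 &
                                     osha$conc_f_ml == 5], 10476.9)
})

test_that("duplicate calibration rows are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("duration_years,conc_f_ml,lung_per_100k,meso_per_100k,gi_per_100k,total_per_100k",
               "1,0.1,7.2,6.9,0.7,14.8",
               "1,0.1,7.2,6.9,0.7,14.8"), path)
  expect_error(load_osha_table(path), "duplicate")
})

test_that("row-sum validation flags only the inconsistent 20-year row", {
  osha <- load_osha_table()
  report <- validate_osha_table(osha, tol = 1.0)
  expect_true(report$passed)
  expect_equal(nrow(report$issues), 1)
  expect_equal(report$issues$severity, "warning")
  expect_match(report$issues$location, "duration 20 yr, conc 10 f/mL")
  # all 1-year rows are internally consistent
  one_year <- validate_osha_table(osha[osha$duration_years == 1, ], tol = 1.0)
  expect_equal(nrow(one_year$issues), 0)
})

test_that("validation is pure and reports negatives as errors", {
  osha <- load_osha_table()
  before <- osha
  invisible(validate_osha_table(osha))
  expect_identical(osha, before)

  bad <- osha
  bad$lung_per_100k[1] <- -1
  report <- validate_osha_table(bad)
  expect_false(report$passed)
  expect_true("error" %in% report$issues$severity)
})
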