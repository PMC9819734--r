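# Independent normal-equations OLS oracle: explicit sum arithmetic only,
# no lm(), kept deliberately separate from the fitting code it checks.
ols_oracle <- function(x, y, intercept = TRUE) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x * x)
  if (intercept) {
    slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
    a <- (sy - slope * sx) / n
    ss_res <- sum((y - a - slope * x)^2)
    ss_tot <- sum((y - sy / n)^2)
  } else {
    slope <- sxy / sxx
    a <- 0
    ss_res <- sum((y - slope * x)^2)
    ss_tot <- sum(y^2)
  }
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = a, r_squared = r2)
}

# Small hand-written JEM used where the bundled fixture would be overkill.
toy_jem <- function() {
  jem(tibble::tibble(
    factory = c("A", "A", "B"),
    job = c("saw", "saw", "mill"),
    period_start = c(2000L, 2005L, 2000L),
    period_end = c(2004L, 2009L, 2004L),
    mean_f_ml = c(0.2, 0.1, 0.05),
    sd_f_ml = c(0.05, 0.02, 0.01)
  ), provenance = "toy")
}
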