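#' Round half away from zero
#'
#' Decimal rounding with the "round half up" convention used throughout the
#' reported grids (4.75 -> 4.8, 0.165 -> 0.17), as opposed to the IEEE
#' round-half-to-even rule of [base::round()]. Values are pre-rounded at 1e-8
#' so that binary floating-point representations of decimal inputs (e.g.
#' `0.19 * 25`) sit exactly on the intended half-way point before the rule is
#' applied.
#'
#' @param x numeric vector (nonnegative in all package uses; negative values
#'   round half away from zero).
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded to `digits` decimal places.
#' @examples
#' round_half_up(4.75, 1)  # 4.8
#' round_half_up(0.165, 2) # 0.17
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(round(abs(x) * p, 8) + 0.5) / p
}

#' Normalize a printed numeric token
#'
#' Source tables mix two comma dialects: a comma as a decimal separator
#' ("14,4") and commas as thousands separators ("13,996.7", "12,177"). A
#' comma is treated as a thousands separator when a period is also present or
#' when exactly three digits follow it; otherwise (one or two trailing
#' digits, no period) it is read as a decimal point.
#'
#' @param x character vector of printed tokens.
#' @return numeric vector; an unparseable token raises an error naming it.
#' @examples
#' parse_printed_number(c("14,4", "12,177", "13,996.7")) # 14.4 12177 13996.7
#' @export
parse_printed_number <- function(x) {
  x <- trimws(as.character(x))
  out <- vapply(x, function(tok) {
    if (is.na(tok) || tok == "" || tok == "-") {
      return(NA_real_)
    }
    t <- gsub(" ", "", tok)
    if (grepl(",", t, fixed = TRUE)) {
      if (grepl(".", t, fixed = TRUE) || grepl(",[0-9]{3}(,|\\.|$)", t)) {
        t <- gsub(",", "", t, fixed = TRUE)
      } else if (grepl("^[0-9]+,[0-9]{1,2}$", t)) {
        t <- sub(",", ".", t, fixed = TRUE)
      } else {
        stop("cannot normalize numeric token: '", tok, "'", call. = FALSE)
      }
    }
    val <- suppressWarnings(as.numeric(t))
    if (is.na(val)) {
      stop("non-numeric cell after normalization: '", tok, "'", call. = FALSE)
    }
    val
  }, numeric(1), USE.NAMES = FALSE)
  out
}

#' Path to a bundled data file
#'
#' Accessor for the plain-text tables shipped with the package: the OSHA
#' cancer-mortality calibration table, the chrysotile job-exposure matrix for
#' the two asbestos-cement factories, and transcriptions of the published
#' cancer and asbestosis prediction grids used as regression references.
#'
#' @param name one of `"osha"`, `"jem"`, `"cancer_reference"`,
#'   `"asbestosis_reference"`, or a raw file name under `extdata/`.
#' @return absolute path to the file.
#' @export
ardrisk_fixture <- function(name = c("osha", "jem", "cancer_reference",
                                     "asbestosis_reference")) {
  files <- c(
    osha = "osha_cancer_mortality.csv",
    jem = "jem_chrysotile.csv",
    cancer_reference = "reference_cancer_grid.csv",
    asbestosis_reference = "reference_asbestosis_grid.csv"
  )
  name <- name[1]
  file <- if (name %in% names(files)) files[[name]] else name
  path <- system.file("extdata", file, package = "ardrisk")
  if (!nzchar(path)) {
    stop("no bundled file '", file, "'", call. = FALSE)
  }
  path
}
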