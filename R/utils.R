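# Small shared helpers.

#' Fiscal quarter of a calendar date
#'
#' Canadian fiscal-year convention: the fiscal year starts April 1, so Q1 is
#' April-June, Q2 July-September, Q3 October-December, and Q4 January-March
#' (labelled with the fiscal year that began the previous April).
#'
#' @param date a `Date` vector.
#' @return Character vector of quarter labels, e.g. `"FY2004-Q1"`, and the
#'   quarter start date as an attribute-free companion via
#'   [fiscal_quarter_start()].
#' @export
#' @examples
#' fiscal_quarter(as.Date(c("2004-04-01", "2004-03-31")))
fiscal_quarter <- function(date) {
  stopifnot(inherits(date, "Date"))
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  fy <- ifelse(m >= 4L, y, y - 1L)
  q <- ((m - 4L) %% 12L) %/% 3L + 1L
  sprintf("FY%d-Q%d", fy, q)
}

#' Start date of the fiscal quarter containing a date
#'
#' @param date a `Date` vector.
#' @return `Date` vector of quarter start dates.
#' @export
fiscal_quarter_start <- function(date) {
  stopifnot(inherits(date, "Date"))
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  qm <- c(1L, 1L, 1L, 4L, 4L, 4L, 7L, 7L, 7L, 10L, 10L, 10L)[m]
  as.Date(sprintf("%d-%02d-01", y, qm))
}

# Round half away from zero (the tabulation convention for percentages);
# base round() rounds half to even.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# log(sum(exp(x))) without overflow; x a matrix -> row-wise.
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Demand category vocabulary
#'
#' `demand_levels()` returns the four clearance-time categories in
#' increasing order of demand; `demand_score(category)` maps them to the
#' ordinal score 0..3 used by the random demand slope.
#'
#' @param category character or factor of category labels.
#' @return A character vector of levels, or a numeric score vector.
#' @export
demand_levels <- function() c("benchmark", "medium", "high", "excessive")

#' @rdname demand_levels
#' @export
demand_score <- function(category) {
  as.numeric(factor(as.character(category), levels = demand_levels())) - 1
}
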