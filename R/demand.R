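#' Classify a clearance time into the four demand categories
#'
#' Benchmark demand clears within 2 days, medium within 4, high within 6, and
#' excessive demand needs 7 or more days. Boundaries are closed on the right:
#' `C <= 2` is benchmark, `2 < C <= 4` medium, `4 < C <= 6` high, `C > 6`
#' excessive (with integer censuses and weekly rates, a clearance time beyond
#' 6 days requires at least 7 days at the daily rate). Setting
#' `ceiling_days = TRUE` classifies `ceiling(C)` instead, i.e. the whole
#' number of days actually needed.
#'
#' @param C numeric clearance time(s) in days.
#' @param ceiling_days classify the rounded-up day count instead of raw `C`.
#' @return Character vector of categories.
#' @export
classify_clearance <- function(C, ceiling_days = FALSE) {
  x <- if (ceiling_days) ceiling(C) else C
  lv <- demand_levels()
  ifelse(x <= 2, lv[1], ifelse(x <= 4, lv[2], ifelse(x <= 6, lv[3], lv[4])))
}

#' Clearance time from census and maximum weekly rate
#'
#' The clearance time is the expected number of days needed for all `Q`
#' preoperative hip-fracture patients present in hospital to undergo surgery
#' at the hospital's maximum weekly service rate `S`, with no new arrivals:
#' `C = Q / (S / 7)`.
#'
#' @param Q nonnegative integer census (preoperative patients present).
#' @param S positive integer maximum weekly service rate (surgeries/week).
#' @param ceiling_days passed to [classify_clearance()].
#' @return Tibble with `Q`, `S`, `C` and `category`.
#' @export
#' @examples
#' clearance_time(2, 7)   # exactly the 2-day benchmark
clearance_time <- function(Q, S, ceiling_days = FALSE) {
  if (any(S < 1)) abort("`S` must be >= 1: the weekly service rate is undefined otherwise.")
  if (any(Q < 0)) abort("`Q` must be nonnegative.")
  C <- Q / (S / 7)
  tibble(Q = Q, S = S, C = C,
         category = factor(classify_clearance(C, ceiling_days),
                           levels = demand_levels()))
}

#' Maximum weekly service rate per hospital and fiscal quarter
#'
#' For each hospital-quarter, counts surgeries within consecutive 7-day
#' blocks anchored at the fiscal quarter's first day (a final partial block
#' is still counted) and takes the maximum over blocks.
#'
#' @param cohort tibble of episodes with `index_hospital_id` and
#'   `surgery_date`.
#' @return Tibble with `hospital_id`, `fiscal_quarter`, `max_weekly_rate`.
#' @export
max_weekly_rates <- function(cohort) {
  cohort %>%
    filter(!is.na(.data$surgery_date)) %>%
    mutate(
      fiscal_quarter = fiscal_quarter(.data$surgery_date),
      week = as.integer(.data$surgery_date -
                          fiscal_quarter_start(.data$surgery_date)) %/% 7L
    ) %>%
    count(.data$index_hospital_id, .data$fiscal_quarter, .data$week) %>%
    group_by(hospital_id = .data$index_hospital_id, .data$fiscal_quarter) %>%
    summarise(max_weekly_rate = max(.data$n), .groups = "drop")
}

#' Preoperative census at a hospital on a day
#'
#' Number of cohort episodes at the hospital that are present and still
#' preoperative on the day: admitted on or before it, with surgery on or
#' after it (or, if no surgery, discharged on or after it). The index
#' patient admitted that day counts themself.
#'
#' @param cohort tibble of episodes with `index_hospital_id`, `admit_date`,
#'   `surgery_date`, `discharge_date`.
#' @param hospital_id hospital to count at.
#' @param day a `Date`.
#' @return Integer census.
#' @export
preop_census <- function(cohort, hospital_id, day) {
  x <- cohort[cohort$index_hospital_id == hospital_id, ]
  end <- dplyr::coalesce(x$surgery_date, x$discharge_date)
  sum(x$admit_date <= day & end >= day)
}

#' Assess demand for every episode in a cohort
#'
#' Joins each episode to the maximum weekly service rate of its hospital in
#' the fiscal quarter containing its admission date, computes the
#' preoperative census on the admission day at the index hospital, and
#' derives the clearance time and demand category. Episodes admitted in a
#' hospital-quarter with no surgeries (no defined rate) are dropped from the
#' assessment with a message reporting the count.
#'
#' @param cohort tibble of episodes (post-exclusion).
#' @param rates optional precomputed [max_weekly_rates()] table.
#' @param include_index count the index patient in the census (default TRUE).
#' @param ceiling_days passed to [classify_clearance()].
#' @return The cohort with `Q`, `S`, `C` and `demand` columns added; rows
#'   without a defined rate are excluded.
#' @export
assess_demand <- function(cohort, rates = NULL, include_index = TRUE,
                          ceiling_days = FALSE) {
  if (is.null(rates)) rates <- max_weekly_rates(cohort)
  x <- cohort %>%
    mutate(.row = row_number(),
           fiscal_quarter = fiscal_quarter(.data$admit_date)) %>%
    left_join(rates, by = c(index_hospital_id = "hospital_id", "fiscal_quarter"))
  undef <- is.na(x$max_weekly_rate)
  if (any(undef)) {
    inform(sprintf("%d episode(s) admitted in a hospital-quarter with no surgeries; excluded from demand assessment.",
                   sum(undef)))
    x <- x[!undef, ]
  }

  # census per episode at its own admission day, by hospital event sweep
  end_all <- dplyr::coalesce(cohort$surgery_date, cohort$discharge_date)
  Q <- integer(nrow(x))
  for (h in unique(x$index_hospital_id)) {
    in_h <- cohort$index_hospital_id == h
    starts <- cohort$admit_date[in_h]
    ends <- end_all[in_h]
    rows <- which(x$index_hospital_id == h)
    days <- x$admit_date[rows]
    # count intervals [start, end] covering each admission day
    Q[rows] <- vapply(seq_along(days), function(i) {
      sum(starts <= days[i] & ends >= days[i])
    }, integer(1))
  }
  if (!include_index) Q <- Q - 1L

  ct <- clearance_time(Q, x$max_weekly_rate, ceiling_days = ceiling_days)
  x$Q <- ct$Q
  x$S <- x$max_weekly_rate
  x$C <- ct$C
  x$demand <- ct$category
  x %>% select(-".row", -"max_weekly_rate")
}
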