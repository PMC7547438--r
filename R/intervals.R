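#' Build censoring intervals for time to surgery
#'
#' Surgery on inpatient day `N` locates the time to surgery in the interval
#' `(N - 1, N]` days. Day 1 gives a left-censored observation at 1 day (the
#' log of the zero lower bound is unbounded below); surgery after the
#' censoring horizon (default 7 inpatient days) is right-censored at the
#' horizon, delays beyond a week being attributed to medical instability
#' rather than demand. Episodes with no surgery day whose stay is within the
#' horizon carry no information and are dropped with a message.
#'
#' @param cohort tibble of episodes with an `N` column (inpatient day of
#'   surgery, `NA` if none) and `discharge_date`/`admit_date` for the
#'   no-surgery rule.
#' @param horizon right-censoring horizon in inpatient days (default 7).
#' @return The cohort with `lower`, `upper` (day scale; `upper = Inf` when
#'   right-censored) and `censor_kind` in `{"left", "interval", "right"}`.
#' @export
build_intervals <- function(cohort, horizon = 7) {
  x <- as_tibble(cohort)
  if (!"N" %in% names(x)) abort("`cohort` must carry the inpatient day of surgery `N`.")
  no_n <- is.na(x$N)
  if (any(no_n)) {
    los <- as.numeric(x$discharge_date - x$admit_date)[no_n] + 1
    drop <- no_n
    drop[no_n] <- los <= horizon
    keepable <- no_n & !drop
    if (any(drop)) {
      inform(sprintf("%d episode(s) without a surgery day and discharged within %d days; excluded from the interval data.",
                     sum(drop), horizon))
    }
    x <- x[!drop, ]
    no_n <- is.na(x$N)
  }
  n <- x$N
  x$lower <- dplyr::case_when(
    is.na(n) ~ as.numeric(horizon),   # alive in hospital past the horizon
    n > horizon ~ as.numeric(horizon),
    TRUE ~ pmax(as.numeric(n) - 1, 0)
  )
  x$upper <- dplyr::case_when(
    is.na(n) | n > horizon ~ Inf,
    TRUE ~ as.numeric(n)
  )
  x$censor_kind <- dplyr::case_when(
    is.infinite(x$upper) ~ "right",
    x$lower == 0 ~ "left",
    TRUE ~ "interval"
  )
  x
}
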