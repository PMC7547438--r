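#' Merge discharge abstracts into care episodes
#'
#' Two abstracts of the same patient are combined when the later admission
#' date falls on, or within one day of, the earlier discharge date (the
#' same-day/next-day transfer rule); merging is transitive, so a chain of
#' contiguous abstracts forms one episode. Same-patient stays that overlap
#' without being contiguous (a later admission strictly before the earlier
#' discharge) are kept separate with a warning.
#'
#' Episode-level fields: the admission date is the earliest admission and the
#' discharge date the latest discharge across the chain; the hospital and all
#' covariates are taken from the abstract containing the surgery (or the
#' first abstract when no surgery occurred); `preop_transfer` is `TRUE` iff
#' the episode comprises more than one abstract (or an input row already
#' carried the flag); `medical_reason_for_delay` is the union of the
#' SCU-admission and NICE-124 flags; `N` is the inpatient day of surgery,
#' `surgery_date - admit_date + 1`. The function is idempotent: merging
#' already-merged episodes changes nothing.
#'
#' @param abstracts data frame of discharge abstracts (one row per abstract)
#'   with at least `patient_id`, `hospital_id` (or `index_hospital_id`),
#'   `admit_date`, `discharge_date`, `surgery_date`.
#' @return Tibble of care episodes, one row per episode.
#' @export
merge_episodes <- function(abstracts) {
  ab <- as_tibble(abstracts)
  if (nrow(ab) == 0L) return(ab)
  if (!"hospital_id" %in% names(ab) && "index_hospital_id" %in% names(ab)) {
    ab$hospital_id <- ab$index_hospital_id
  }
  had_transfer_flag <- "preop_transfer" %in% names(ab)
  if (!had_transfer_flag) ab$preop_transfer <- FALSE

  ab <- ab %>%
    arrange(.data$patient_id, .data$admit_date, .data$discharge_date) %>%
    group_by(.data$patient_id) %>%
    mutate(
      gap = as.numeric(.data$admit_date - lag(.data$discharge_date)),
      overlap = !is.na(.data$gap) & .data$gap < 0,
      episode_seq = cumsum(is.na(.data$gap) | .data$gap > 1 | .data$gap < 0)
    ) %>%
    ungroup() %>%
    mutate(episode_key = paste(.data$patient_id, .data$episode_seq, sep = "#"))
  n_overlap <- sum(ab$overlap)
  if (n_overlap > 0L) {
    warn(sprintf("%d same-patient abstract(s) overlap without being contiguous; kept as separate episodes.",
                 n_overlap))
  }

  if (!"n_abstracts" %in% names(ab)) ab$n_abstracts <- 1L
  spans <- ab %>%
    group_by(.data$episode_key) %>%
    summarise(
      episode_admit = min(.data$admit_date),
      episode_discharge = max(.data$discharge_date),
      n_abstracts = sum(.data$n_abstracts),
      any_transfer_flag = any(.data$preop_transfer),
      .groups = "drop"
    )

  # covariate source: the abstract containing the surgery, else the first
  src <- ab %>%
    arrange(.data$episode_key, is.na(.data$surgery_date), .data$admit_date) %>%
    distinct(.data$episode_key, .keep_all = TRUE)

  drop_cols <- c("gap", "overlap", "episode_seq", "episode_key",
                 "admit_date", "discharge_date", "preop_transfer",
                 "hospital_id", "index_hospital_id", "N", "n_abstracts",
                 "medical_reason_for_delay")
  out <- src %>%
    mutate(index_hospital_id = .data$hospital_id) %>%
    select(-dplyr::any_of(setdiff(drop_cols, c("episode_key", "index_hospital_id")))) %>%
    left_join(spans, by = "episode_key") %>%
    rename(admit_date = "episode_admit", discharge_date = "episode_discharge") %>%
    mutate(
      preop_transfer = .data$n_abstracts > 1L | .data$any_transfer_flag,
      N = as.integer(as.numeric(.data$surgery_date - .data$admit_date)) + 1L
    ) %>%
    select(-"episode_key", -"any_transfer_flag")
  if (all(c("scu_admission", "nice124_condition") %in% names(out))) {
    out$medical_reason_for_delay <- out$scu_admission | out$nice124_condition
  }
  arrange(out, .data$patient_id, .data$admit_date)
}

#' Apply the cohort exclusions
#'
#' Removes episodes without a surgery date, and episodes whose surgery took
#' place in a hospital that performed 24 or fewer hip fracture surgeries in
#' that calendar year (annual volume counted on the pre-exclusion episodes at
#' the hospital of surgery).
#'
#' @param episodes tibble of care episodes from [merge_episodes()].
#' @param min_annual_volume hospitals at or below this annual surgery count
#'   are excluded (default 24).
#' @return List with `cohort` (retained episodes) and `exclusions`, a tibble
#'   of reason/count pairs satisfying
#'   `nrow(cohort) + sum(exclusions$n) == nrow(episodes)`.
#' @export
apply_exclusions <- function(episodes, min_annual_volume = 24L) {
  ep <- as_tibble(episodes)
  if (nrow(ep) == 0L) {
    return(list(cohort = ep,
                exclusions = tibble(reason = c("no surgery date",
                                               "low-volume hospital-year"),
                                    n = c(0L, 0L))))
  }
  no_surgery <- is.na(ep$surgery_date)
  with_surg <- ep[!no_surgery, ]

  surgery_year <- as.integer(format(with_surg$surgery_date, "%Y"))
  vol_key <- paste(with_surg$index_hospital_id, surgery_year)
  vol <- table(vol_key)
  low <- as.integer(vol[vol_key]) <= min_annual_volume

  cohort <- with_surg[!low, ]
  exclusions <- tibble(
    reason = c("no surgery date", "low-volume hospital-year"),
    n = c(sum(no_surgery), sum(low))
  )
  list(cohort = cohort, exclusions = exclusions)
}

#' Write a plain-text exclusion ledger
#'
#' @param exclusions the `exclusions` tibble from [apply_exclusions()].
#' @param path output file.
#' @param n_input,n_cohort optional input/retained episode counts for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(exclusions, path, n_input = NA, n_cohort = NA) {
  lines <- c(
    sprintf("episodes in: %s", n_input),
    sprintf("excluded - %s: %d", exclusions$reason, exclusions$n),
    sprintf("cohort retained: %s", n_cohort)
  )
  writeLines(lines, path)
  invisible(path)
}
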