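# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

# a small, fast simulation configuration
tiny_config <- function(...) {
  sim_config(
    n_hospitals = 5, start_date = "2004-01-01", end_date = "2004-12-31",
    arrival_rate_per_hospital_day = 0.5, base_capacity_per_week = 8,
    hospital_size_sd = 0.2, seed = 101L, ...
  )
}

# hand-built abstracts for the merge rules
make_abstract <- function(patient_id, hospital_id, admit, discharge,
                          surgery = NA) {
  tibble::tibble(
    patient_id = patient_id, hospital_id = hospital_id,
    admit_date = as.Date(admit), discharge_date = as.Date(discharge),
    surgery_date = as.Date(surgery),
    age_group = "75-84", sex = "women",
    scu_admission = FALSE, nice124_condition = FALSE
  )
}

# day-grid interval data (N-1, N] with right censoring at `horizon`
grid_intervals <- function(N, horizon = 7) {
  tibble::tibble(
    N = N,
    lower = ifelse(N > horizon, horizon, N - 1),
    upper = ifelse(N > horizon, Inf, N)
  )
}
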