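test_that("capacity calendars honour base rate, multipliers and size factors", {
  cfg <- sim_config(n_hospitals = 3, start_date = "2004-04-01",
                    end_date = "2005-03-31", base_capacity_per_week = 7,
                    capacity_quarter_multipliers = c(1, 1, 1, 1),
                    hospital_size_sd = 0, seed = 1)
  hosp <- generate_hospitals(cfg)
  expect_true(all(hosp$capacity$weekly_slots == 7L))
  # daily slots within any anchored 7-day block sum to the weekly total
  wk <- hosp$capacity %>%
    dplyr::mutate(block = as.integer(date - fiscal_quarter_start(date)) %/% 7L) %>%
    dplyr::count(hospital_id, fiscal_quarter, block, wt = slots, name = "tot") %>%
    dplyr::filter(tot > 0)
  full_weeks <- wk %>% dplyr::group_by(hospital_id, fiscal_quarter) %>%
    dplyr::filter(block < max(block))     # final block may be partial
  expect_true(all(full_weeks$tot == 7L))

  cfg2 <- sim_config(n_hospitals = 2, start_date = "2004-04-01",
                     end_date = "2005-03-31", base_capacity_per_week = 14,
                     capacity_quarter_multipliers = c(1, 0.5, 1, 1),
                     hospital_size_sd = 0, seed = 1)
  cap2 <- generate_hospitals(cfg2)$capacity
  q2 <- grepl("Q2$", cap2$fiscal_quarter)
  expect_true(all(cap2$weekly_slots[q2] == 7L))
  expect_true(all(cap2$weekly_slots[!q2] == 14L))
})

test_that("zero hospitals yield empty but well-formed outputs", {
  cfg <- sim_config(n_hospitals = 0, seed = 1)
  hosp <- generate_hospitals(cfg)
  expect_equal(nrow(hosp$hospitals), 0)
  expect_equal(nrow(hosp$capacity), 0)
  expect_equal(nrow(simulate_patients(cfg, hosp)), 0)
})

test_that("capacity must be positive", {
  expect_error(sim_config(base_capacity_per_week = 0), "positive")
  expect_error(sim_config(capacity_quarter_multipliers = c(1, -1, 1, 1)),
               "positive")
})

test_that("with slack capacity and null effects the queue never binds", {
  cfg <- sim_config(n_hospitals = 6, start_date = "2004-01-01",
                    end_date = "2004-12-31",
                    arrival_rate_per_hospital_day = 0.2,
                    base_capacity_per_week = 40, hospital_size_sd = 0,
                    true_log_effects = c(medium = 0, high = 0, excessive = 0),
                    random_intercept_sd = 0, random_slope_sd = 0,
                    medical_delay_prevalence = 0, seed = 5)
  traj <- simulate_patients(cfg)
  done <- traj[!traj$truncated, ]
  # surgery on the first eligible day for essentially everyone
  expect_gt(mean(done$N == done$eligible_day), 0.99)
})

test_that("a capacity outage delays every admission in the window", {
  cfg <- sim_config(n_hospitals = 1, start_date = "2004-01-01",
                    end_date = "2004-12-31",
                    arrival_rate_per_hospital_day = 0.6,
                    base_capacity_per_week = 10, hospital_size_sd = 0,
                    seed = 8)
  hosp <- generate_hospitals(cfg)
  out_start <- as.Date("2004-03-01")
  out_end <- out_start + 9
  hosp$capacity$slots[hosp$capacity$date >= out_start &
                        hosp$capacity$date <= out_end] <- 0L
  traj <- simulate_patients(cfg, hosp)
  hit <- traj[traj$admit_date >= out_start & traj$admit_date <= out_end &
                !traj$truncated, ]
  expect_gt(nrow(hit), 0)
  expect_true(all(hit$surgery_date > out_end))
})

test_that("the generator is deterministic given the seed", {
  cfg <- tiny_config()
  a <- suppressWarnings(sim_cohort(cfg))
  b <- suppressWarnings(sim_cohort(cfg))
  expect_identical(a$abstracts, b$abstracts)
  expect_identical(a$episodes, b$episodes)
  expect_identical(a$capacity, b$capacity)
})

test_that("split abstracts are contiguous and partition the episodes", {
  cfg <- tiny_config(transfer_split_fraction = 0.2)
  coh <- suppressWarnings(sim_cohort(cfg))
  ab <- coh$abstracts
  expect_equal(dplyr::n_distinct(ab$patient_id), nrow(coh$episodes))
  two <- ab %>% dplyr::count(patient_id) %>% dplyr::filter(n == 2)
  expect_gt(nrow(two), 0)
  pair <- ab %>% dplyr::filter(patient_id %in% two$patient_id) %>%
    dplyr::arrange(patient_id, admit_date) %>%
    dplyr::group_by(patient_id) %>%
    dplyr::summarise(contig = dplyr::last(admit_date) == dplyr::first(discharge_date),
                     flagged = all(preop_transfer))
  expect_true(all(pair$contig))
  expect_true(all(pair$flagged))
  # zero split fraction: exactly one abstract per episode
  cfg0 <- tiny_config(transfer_split_fraction = 0)
  coh0 <- suppressWarnings(sim_cohort(cfg0))
  expect_equal(nrow(coh0$abstracts), nrow(coh0$episodes))
})

test_that("uncongested null simulation reproduces the log-normal day grid", {
  cfg <- sim_config(n_hospitals = 10, start_date = "2004-01-01",
                    end_date = "2004-12-31",
                    arrival_rate_per_hospital_day = 2.8,
                    base_capacity_per_week = 120, hospital_size_sd = 0,
                    true_log_effects = c(medium = 0, high = 0, excessive = 0),
                    random_intercept_sd = 0, random_slope_sd = 0,
                    medical_delay_prevalence = 0, seed = 12)
  traj <- simulate_patients(cfg)
  done <- traj[!traj$truncated, ]
  expect_gt(nrow(done), 1e4)
  mu <- cfg$baseline_log_median; sg <- cfg$true_sigma
  for (k in 1:4) {
    expect_lt(abs(mean(done$N <= k) - pnorm((log(k) - mu) / sg)), 0.02)
  }
})

test_that("simulation configs round-trip through YAML", {
  cfg <- tiny_config(true_covariate_effects = list(sex = c(men = -0.05)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$true_log_effects, cfg$true_log_effects)
  expect_equal(cfg2$covariate_frequency_table, cfg$covariate_frequency_table)
  expect_equal(cfg2$start_date, cfg$start_date)
  expect_equal(cfg2$true_covariate_effects, cfg$true_covariate_effects)
})
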