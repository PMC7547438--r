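#' Simulation settings for the synthetic discharge-abstract generator
#'
#' Builds the configuration object consumed by [generate_hospitals()],
#' [simulate_patients()], [emit_abstracts()] and [sim_cohort()]. Defaults
#' describe a nine-year, 89-hospital system calibrated to published Canadian
#' hip-fracture summaries: a mean of roughly 190 surgeries per hospital-year,
#' a baseline median time to surgery of 1.5 days with log-scale standard
#' deviation 0.6 (which puts about 68/94/98% of benchmark-demand surgeries
#' within 2/4/7 days), true demand effects of +5.1/+12.2/+22.0% on the median
#' for medium/high/excessive demand, a 6.7% prevalence of medical reasons for
#' delay adding a median 0.7-day preoperative hold, and an 8.6% transfer-split
#' fraction.
#'
#' @param n_hospitals number of hospitals.
#' @param start_date,end_date horizon of admissions (Date or string).
#' @param arrival_rate_per_hospital_day Poisson arrival rate at a hospital of
#'   size factor 1.
#' @param base_capacity_per_week surgical slots per week at a hospital of size
#'   factor 1 before quarter multipliers.
#' @param capacity_quarter_multipliers length-4 positive multipliers applied to
#'   weekly capacity in fiscal quarters Q1 (Apr-Jun) through Q4 (Jan-Mar).
#' @param hospital_size_sd log-scale SD of the per-hospital size factor that
#'   scales both arrivals and capacity (0 = identical hospitals).
#' @param true_log_effects named vector of log time-ratios for the
#'   `medium`, `high` and `excessive` demand categories (reference =
#'   benchmark).
#' @param baseline_log_median log median time-to-surgery (days) at benchmark
#'   demand for an average hospital.
#' @param true_sigma residual SD of log time-to-surgery.
#' @param random_intercept_sd,random_slope_sd SDs of the per-hospital random
#'   intercept and of the random slope on the ordinal demand score (0..3).
#' @param medical_delay_prevalence probability that an episode carries a
#'   medical reason for delay (SCU admission or a NICE-124 condition).
#' @param medical_delay_log_shift,medical_delay_sdlog meanlog and sdlog of the
#'   log-normal preoperative stabilization hold (days) added for episodes with
#'   a medical reason for delay. The default meanlog `log(0.7)` gives a median
#'   hold of 0.7 days.
#' @param transfer_split_fraction fraction of episodes emitted as two
#'   contiguous abstracts (a preoperative transfer).
#' @param covariate_frequency_table named list of probability tables for the
#'   episode covariates; see [default_covariate_table()].
#' @param true_covariate_effects optional named list mapping a covariate column
#'   to a named numeric vector of log time shifts per level, e.g.
#'   `list(sex = c(men = -0.05))`. Defaults to no covariate effects so the
#'   demand estimand is unconfounded by construction.
#' @param postop_los_mean mean postoperative length of stay in days.
#' @param seed integer seed fixing every random draw of the generator.
#' @return A list of class `hw_sim_config`.
#' @export
sim_config <- function(n_hospitals = 89,
                       start_date = "2004-01-01",
                       end_date = "2012-12-31",
                       arrival_rate_per_hospital_day = 0.52,
                       base_capacity_per_week = 8,
                       capacity_quarter_multipliers = c(1, 0.85, 1, 1.1),
                       hospital_size_sd = 0.3,
                       true_log_effects = c(medium = log(1.051),
                                            high = log(1.122),
                                            excessive = log(1.220)),
                       baseline_log_median = log(1.5),
                       true_sigma = 0.6,
                       random_intercept_sd = 0.10,
                       random_slope_sd = 0.05,
                       medical_delay_prevalence = 0.067,
                       medical_delay_log_shift = log(0.7),
                       medical_delay_sdlog = 0.5,
                       transfer_split_fraction = 0.086,
                       covariate_frequency_table = default_covariate_table(),
                       true_covariate_effects = list(),
                       postop_los_mean = 9,
                       seed = 2004L) {
  cfg <- list(
    n_hospitals = as.integer(n_hospitals),
    start_date = as.Date(start_date),
    end_date = as.Date(end_date),
    arrival_rate_per_hospital_day = arrival_rate_per_hospital_day,
    base_capacity_per_week = base_capacity_per_week,
    capacity_quarter_multipliers = capacity_quarter_multipliers,
    hospital_size_sd = hospital_size_sd,
    true_log_effects = true_log_effects,
    baseline_log_median = baseline_log_median,
    true_sigma = true_sigma,
    random_intercept_sd = random_intercept_sd,
    random_slope_sd = random_slope_sd,
    medical_delay_prevalence = medical_delay_prevalence,
    medical_delay_log_shift = medical_delay_log_shift,
    medical_delay_sdlog = medical_delay_sdlog,
    transfer_split_fraction = transfer_split_fraction,
    covariate_frequency_table = covariate_frequency_table,
    true_covariate_effects = true_covariate_effects,
    postop_los_mean = postop_los_mean,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "hw_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_hospitals < 0) abort("`n_hospitals` must be >= 0.")
  if (cfg$start_date > cfg$end_date) abort("`start_date` must precede `end_date`.")
  if (cfg$arrival_rate_per_hospital_day <= 0) abort("arrival rate must be positive.")
  if (cfg$base_capacity_per_week <= 0) abort("`base_capacity_per_week` must be positive.")
  if (length(cfg$capacity_quarter_multipliers) != 4 ||
      any(cfg$capacity_quarter_multipliers <= 0)) {
    abort("`capacity_quarter_multipliers` must be 4 positive numbers.")
  }
  probs <- c(cfg$medical_delay_prevalence, cfg$transfer_split_fraction)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1].")
  if (cfg$true_sigma <= 0) abort("`true_sigma` must be positive.")
  if (cfg$random_intercept_sd < 0 || cfg$random_slope_sd < 0) {
    abort("random-effect SDs must be nonnegative.")
  }
  eff <- cfg$true_log_effects
  if (!setequal(names(eff), c("medium", "high", "excessive"))) {
    abort("`true_log_effects` must name exactly medium, high and excessive.")
  }
  invisible(cfg)
}

#' Default covariate frequency tables
#'
#' Marginal distributions for the episode covariates, set to the published
#' overall distribution of the Canadian hip-fracture cohort (age, sex,
#' prefracture status, admission timing and status, preoperative procedures,
#' hospital type, fracture and procedure type, province).
#'
#' @return Named list of named probability vectors.
#' @export
default_covariate_table <- function() {
  list(
    age_group = c(`65-74` = 0.150, `75-84` = 0.393, `85-94` = 0.404, `>=95` = 0.053),
    sex = c(women = 0.734, men = 0.266),
    prefracture_status = c(home_without_comorbidity = 0.425,
                           home_with_comorbidity_or_care = 0.181,
                           facility = 0.208, elsewhere = 0.186),
    weekday_timing = c(weekday_am = 0.472, weekday_pm = 0.528),
    admission_status = c(urgent = 0.982, other = 0.018),
    preop_procedure = c(`TRUE` = 0.111, `FALSE` = 0.889),
    hospital_type = c(teaching = 0.390, community_large = 0.458,
                      community_medium_small = 0.152),
    fracture_type = c(transcervical = 0.521, inter_subtrochanteric = 0.479),
    procedure_type = c(fixation = 0.598, arthroplasty = 0.402),
    province = c(AB = 0.110, BC = 0.190, MB = 0.056, NB = 0.035, NL = 0.023,
                 NS = 0.043, ON = 0.485, PE = 0.007, SK = 0.051),
    # split of (scu, nice124) among episodes with a medical reason for delay
    delay_flags = c(scu_only = 0.25, nice_only = 0.55, both = 0.20)
  )
}

sample_levels <- function(tab, n) {
  sample(names(tab), n, replace = TRUE, prob = tab)
}

#' Generate hospital capacity calendars
#'
#' Draws per-hospital size factors, types and provinces, and lays out daily
#' surgical slot counts over the horizon. Weekly capacity is
#' `round(base * quarter multiplier * size factor)` (at least 1), assigned to
#' consecutive 7-day blocks anchored at each fiscal quarter's first day and
#' spread as evenly as possible across the days of a block.
#'
#' @param config a [sim_config()] object.
#' @return List with `hospitals` (one row per hospital: id, size factor, type,
#'   province) and `capacity` (one row per hospital-day: date, fiscal quarter,
#'   slots, and the week's planned total `weekly_slots`).
#' @export
generate_hospitals <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_hospitals
  if (n == 0L) {
    return(list(
      hospitals = tibble(hospital_id = character(), size_factor = numeric(),
                         hospital_type = character(), province = character()),
      capacity = tibble(hospital_id = character(), date = as.Date(character()),
                        fiscal_quarter = character(), slots = integer(),
                        weekly_slots = integer())
    ))
  }
  tab <- config$covariate_frequency_table
  hospitals <- tibble(
    hospital_id = sprintf("H%03d", seq_len(n)),
    size_factor = exp(rnorm(n, -config$hospital_size_sd^2 / 2,
                            config$hospital_size_sd)),
    hospital_type = sample_levels(tab$hospital_type, n),
    province = sample_levels(tab$province, n)
  )

  days <- seq(config$start_date, config$end_date, by = "day")
  q_start <- fiscal_quarter_start(days)
  fq <- fiscal_quarter(days)
  day_in_q <- as.integer(days - q_start)
  week_in_q <- day_in_q %/% 7L
  day_in_week <- day_in_q %% 7L
  q_num <- as.integer(substring(fq, nchar(fq)))  # 1..4

  capacity <- purrr::map_dfr(seq_len(n), function(h) {
    wk_total <- pmax(1L, as.integer(round(
      config$base_capacity_per_week *
        config$capacity_quarter_multipliers[q_num] *
        hospitals$size_factor[h]
    )))
    slots <- wk_total %/% 7L + as.integer(day_in_week < wk_total %% 7L)
    tibble(hospital_id = hospitals$hospital_id[h], date = days,
           fiscal_quarter = fq, slots = slots, weekly_slots = wk_total)
  })
  list(hospitals = hospitals, capacity = capacity)
}

#' Simulate admissions, queueing and surgery scheduling
#'
#' Runs a per-hospital discrete-event simulation over the horizon. Admissions
#' are homogeneous Poisson per hospital-day. Each patient receives a latent
#' log time-to-surgery equal to the baseline log median, plus the true effect
#' of the demand category realized at admission, plus any configured covariate
#' effects and hospital random effects, plus Normal(0, sigma) noise; episodes
#' with a medical reason for delay are additionally held for a log-normal
#' stabilization time. The patient becomes eligible for surgery on inpatient
#' day `ceiling(latent days)` and is then scheduled first-in-first-out among
#' eligible patients, subject to the day's slot count, which discretizes the
#' outcome to whole inpatient days and produces realistic preoperative queues.
#'
#' @param config a [sim_config()] object.
#' @param hospitals output of [generate_hospitals()] (list with `hospitals`
#'   and `capacity`); regenerated from `config` when omitted.
#' @return Tibble of patient trajectories (the ground-truth episode table):
#'   ids, dates, inpatient day of surgery `N`, the census `Q_true`, planned
#'   weekly rate `S_true`, clearance time and demand category realized at
#'   admission, covariates and flags. Patients still waiting when the horizon
#'   ends are flagged `truncated` (with a warning) and carry no surgery date.
#' @export
simulate_patients <- function(config, hospitals = NULL) {
  validate_sim_config(config)
  if (is.null(hospitals)) hospitals <- generate_hospitals(config)
  set.seed(config$seed + 1L)
  hosp <- hospitals$hospitals
  cap <- hospitals$capacity
  tab <- config$covariate_frequency_table
  days <- seq(config$start_date, config$end_date, by = "day")
  n_days <- length(days)
  wd <- as.POSIXlt(days)$wday  # 0 = Sunday
  is_weekend <- wd == 0L | wd == 6L

  out <- vector("list", nrow(hosp))
  for (h in seq_len(nrow(hosp))) {
    hid <- hosp$hospital_id[h]
    hcap <- cap[cap$hospital_id == hid, ]
    slots <- hcap$slots
    weekly <- hcap$weekly_slots
    fq <- hcap$fiscal_quarter
    rate <- config$arrival_rate_per_hospital_day * hosp$size_factor[h]
    n_arr_day <- rpois(n_days, rate)
    n_pat <- sum(n_arr_day)
    if (n_pat == 0L) next
    admit_abs <- rep.int(seq_len(n_days), n_arr_day)

    b0 <- rnorm(1, 0, config$random_intercept_sd)
    b1 <- rnorm(1, 0, config$random_slope_sd)

    # queue-independent draws, one per patient
    eps <- rnorm(n_pat, 0, config$true_sigma)
    delayed <- runif(n_pat) < config$medical_delay_prevalence
    hold <- ifelse(delayed,
                   rlnorm(n_pat, config$medical_delay_log_shift,
                          config$medical_delay_sdlog), 0)
    covs <- tibble(
      age_group = sample_levels(tab$age_group, n_pat),
      sex = sample_levels(tab$sex, n_pat),
      prefracture_status = sample_levels(tab$prefracture_status, n_pat),
      admission_timing = ifelse(is_weekend[admit_abs], "weekend",
                                sample_levels(tab$weekday_timing, n_pat)),
      admission_status = sample_levels(tab$admission_status, n_pat),
      preop_procedure = sample_levels(tab$preop_procedure, n_pat) == "TRUE",
      fracture_type = sample_levels(tab$fracture_type, n_pat),
      procedure_type = sample_levels(tab$procedure_type, n_pat)
    )
    cov_shift <- rep(0, n_pat)
    for (nm in names(config$true_covariate_effects)) {
      sh <- config$true_covariate_effects[[nm]]
      idx <- match(as.character(covs[[nm]]), names(sh))
      cov_shift <- cov_shift + ifelse(is.na(idx), 0, sh[idx])
    }
    eta_base <- config$baseline_log_median + b0 + cov_shift + eps

    eff <- c(benchmark = 0, config$true_log_effects[demand_levels()[-1]])
    names(eff) <- demand_levels()

    Q_rec <- integer(n_pat); S_rec <- integer(n_pat)
    C_rec <- numeric(n_pat); cat_rec <- character(n_pat)
    elig_abs <- integer(n_pat); surg_abs <- rep(NA_integer_, n_pat)
    in_queue <- rep(FALSE, n_pat)
    p_next <- 1L
    for (d in seq_len(n_days)) {
      # admissions first: same-day surgery is possible if slots remain
      k <- n_arr_day[d]
      if (k > 0L) {
        # day-level census: patients still awaiting surgery at the start of
        # the day (including any operated later today) plus all of today's
        # admissions, the index patient among them
        Q_day <- sum(in_queue) + k
        for (j in seq_len(k)) {
          i <- p_next; p_next <- p_next + 1L
          Q <- Q_day
          S <- weekly[d]
          C <- 7 * Q / S
          cat_i <- classify_clearance(C)
          sc <- demand_score(cat_i)
          t_lat <- exp(eta_base[i] + eff[[cat_i]] + b1 * sc) + hold[i]
          Q_rec[i] <- Q; S_rec[i] <- S; C_rec[i] <- C; cat_rec[i] <- cat_i
          elig_abs[i] <- admit_abs[i] + max(1, ceiling(t_lat)) - 1L
          in_queue[i] <- TRUE
        }
      }
      # serve FIFO among eligible, up to today's slots
      if (slots[d] > 0L && any(in_queue)) {
        q_idx <- which(in_queue)              # arrival order
        ready <- q_idx[elig_abs[q_idx] <= d]
        if (length(ready) > 0L) {
          take <- ready[seq_len(min(slots[d], length(ready)))]
          surg_abs[take] <- d
          in_queue[take] <- FALSE
        }
      }
    }
    truncated <- is.na(surg_abs)
    postop <- 1L + rpois(n_pat, max(config$postop_los_mean - 1, 0))
    disc_abs <- ifelse(truncated, n_days, pmin(surg_abs + postop, n_days))

    out[[h]] <- dplyr::bind_cols(
      tibble(
        hospital_id = hid,
        admit_date = days[admit_abs],
        surgery_date = as.Date(ifelse(truncated, NA, days[pmin(surg_abs, n_days)]),
                               origin = "1970-01-01"),
        discharge_date = days[disc_abs],
        N = ifelse(truncated, NA_integer_, surg_abs - admit_abs + 1L),
        eligible_day = elig_abs - admit_abs + 1L,
        Q_true = Q_rec, S_true = S_rec, clearance_true = C_rec,
        demand_true = cat_rec,
        medical_reason_for_delay = delayed,
        truncated = truncated,
        hospital_type = hosp$hospital_type[h],
        province = hosp$province[h]
      ),
      covs
    )
  }
  traj <- dplyr::bind_rows(out)
  if (nrow(traj) == 0L) {
    return(tibble(patient_id = character()))
  }
  traj <- traj %>%
    arrange(.data$admit_date, .data$hospital_id) %>%
    mutate(patient_id = sprintf("P%06d", row_number()),
           era = era_of(.data$admit_date, config$start_date)) %>%
    select("patient_id", dplyr::everything())
  if (any(traj$truncated)) {
    warn(sprintf("%d patient(s) still awaiting surgery at the end of the horizon; flagged `truncated`.",
                 sum(traj$truncated)))
  }
  traj
}

# three-year treatment-era blocks counted from the horizon start
era_of <- function(date, start) {
  y0 <- as.integer(format(start, "%Y"))
  y <- as.integer(format(date, "%Y"))
  b <- (y - y0) %/% 3L
  sprintf("%d-%d", y0 + 3L * b, y0 + 3L * b + 2L)
}

#' Emit discharge abstracts from simulated trajectories
#'
#' Writes each trajectory as one discharge abstract, except that a configured
#' fraction of episodes with at least one full preoperative day are split into
#' two abstracts with contiguous discharge/admission dates (a preoperative
#' transfer from a randomly chosen referring hospital), exercising the episode
#' merge rule downstream. SCU/NICE-124 flags are assigned so their union
#' equals the episode's medical-reason-for-delay flag.
#'
#' @param trajectories output of [simulate_patients()].
#' @param config the [sim_config()] used to generate them.
#' @return List with `abstracts` (one row per abstract) and `episodes` (the
#'   ground-truth episode table, one row per trajectory, including the
#'   `preop_transfer` flag).
#' @export
emit_abstracts <- function(trajectories, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  traj <- trajectories
  if (nrow(traj) == 0L) {
    return(list(abstracts = traj, episodes = traj))
  }
  tab <- config$covariate_frequency_table
  n <- nrow(traj)

  flg <- rep("none", n)
  del <- which(traj$medical_reason_for_delay)
  if (length(del) > 0) flg[del] <- sample_levels(tab$delay_flags, length(del))
  traj$scu_admission <- flg %in% c("scu_only", "both")
  traj$nice124_condition <- flg %in% c("nice_only", "both")

  can_split <- !is.na(traj$N) & traj$N >= 2L & config$n_hospitals >= 1L
  do_split <- can_split & runif(n) < config$transfer_split_fraction
  traj$preop_transfer <- do_split

  hosp_ids <- unique(traj$hospital_id)
  cov_cols <- c("age_group", "sex", "prefracture_status", "admission_timing",
                "admission_status", "preop_procedure", "scu_admission",
                "nice124_condition", "hospital_type", "fracture_type",
                "procedure_type", "era", "province", "preop_transfer")

  single <- traj[!do_split, ]
  ab_single <- tibble(
    patient_id = single$patient_id,
    hospital_id = single$hospital_id,
    admit_date = single$admit_date,
    discharge_date = single$discharge_date,
    surgery_date = single$surgery_date
  ) %>% dplyr::bind_cols(single[cov_cols])

  sp <- traj[do_split, ]
  if (nrow(sp) > 0L) {
    # transfer on a random preoperative day; same-day contiguity
    split_off <- vapply(sp$N, function(N) sample.int(N - 1L, 1L), integer(1))
    xfer_date <- sp$admit_date + split_off
    ref_hosp <- unname(vapply(sp$hospital_id, function(h) {
      others <- setdiff(hosp_ids, h)
      if (length(others) == 0L) h else sample(others, 1L)
    }, character(1)))
    ab_a <- tibble(patient_id = sp$patient_id, hospital_id = ref_hosp,
                   admit_date = sp$admit_date, discharge_date = xfer_date,
                   surgery_date = as.Date(NA)) %>%
      dplyr::bind_cols(sp[cov_cols])
    ab_b <- tibble(patient_id = sp$patient_id, hospital_id = sp$hospital_id,
                   admit_date = xfer_date, discharge_date = sp$discharge_date,
                   surgery_date = sp$surgery_date) %>%
      dplyr::bind_cols(sp[cov_cols])
    abstracts <- bind_rows(ab_single, ab_a, ab_b)
  } else {
    abstracts <- ab_single
  }
  abstracts <- arrange(abstracts, .data$patient_id, .data$admit_date)
  list(abstracts = abstracts, episodes = traj)
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper running [generate_hospitals()], [simulate_patients()]
#' and [emit_abstracts()] in sequence. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return List with `abstracts`, `episodes` (ground truth), `hospitals`,
#'   `capacity` and the `config`.
#' @export
sim_cohort <- function(config = sim_config()) {
  hosp <- generate_hospitals(config)
  traj <- simulate_patients(config, hosp)
  em <- emit_abstracts(traj, config)
  list(abstracts = em$abstracts, episodes = em$episodes,
       hospitals = hosp$hospitals, capacity = hosp$capacity, config = config)
}

#' Simulate interval-censored AFT data directly
#'
#' Draws day-grid interval-censored log-normal times with known demand effects
#' and hospital random effects, bypassing the queueing simulation. Intended
#' for parameter-recovery experiments where the estimand must match the fitted
#' model exactly.
#'
#' @param n_hospitals,n_per_hospital design size.
#' @param effects named log time-ratios for medium/high/excessive demand.
#' @param baseline_log_median,sigma log-normal location (benchmark) and scale.
#' @param tau0,tau1 SDs of the hospital random intercept and of the random
#'   slope on the ordinal demand score.
#' @param cat_probs probabilities of the four demand categories.
#' @param horizon right-censoring horizon in days.
#' @param seed integer seed.
#' @return Tibble with `hospital_id`, `demand` (factor), `demand_score`,
#'   latent `time`, inpatient day `N`, and day-scale interval bounds
#'   `lower`/`upper` (`upper = Inf` when right-censored at the horizon).
#' @export
sim_interval_data <- function(n_hospitals, n_per_hospital,
                              effects = c(medium = log(1.051),
                                          high = log(1.122),
                                          excessive = log(1.220)),
                              baseline_log_median = log(1.5), sigma = 0.6,
                              tau0 = 0.1, tau1 = 0,
                              cat_probs = c(0.402, 0.469, 0.113, 0.016),
                              horizon = 7, seed = 1L) {
  set.seed(seed)
  n <- n_hospitals * n_per_hospital
  hid <- rep(sprintf("H%03d", seq_len(n_hospitals)), each = n_per_hospital)
  b0 <- rep(rnorm(n_hospitals, 0, tau0), each = n_per_hospital)
  b1 <- rep(rnorm(n_hospitals, 0, tau1), each = n_per_hospital)
  lv <- demand_levels()
  demand <- factor(sample(lv, n, replace = TRUE, prob = cat_probs), levels = lv)
  sc <- demand_score(demand)
  beta <- c(benchmark = 0, effects[lv[-1]])
  names(beta) <- lv
  eta <- baseline_log_median + beta[as.character(demand)] + b0 + b1 * sc
  tt <- exp(eta + rnorm(n, 0, sigma))
  N <- pmax(1L, as.integer(ceiling(tt)))
  tibble(
    hospital_id = hid, demand = demand, demand_score = sc, time = tt, N = N,
    lower = ifelse(N > horizon, horizon, N - 1),
    upper = ifelse(N > horizon, Inf, N)
  )
}

#' Write and read simulation configs as YAML
#'
#' @param config a [sim_config()] object.
#' @param path file path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns a validated [sim_config()] object.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$start_date <- format(x$start_date)
  x$end_date <- format(x$end_date)
  x$true_log_effects <- as.list(x$true_log_effects)
  x$covariate_frequency_table <- purrr::map(x$covariate_frequency_table, as.list)
  x$true_covariate_effects <- purrr::map(x$true_covariate_effects, as.list)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$true_log_effects <- unlist(x$true_log_effects)
  x$covariate_frequency_table <- purrr::map(x$covariate_frequency_table, unlist)
  x$true_covariate_effects <- purrr::map(x$true_covariate_effects, unlist)
  do.call(sim_config, x)
}

#' Write a simulated cohort to CSV
#'
#' Writes `abstracts.csv`, `episodes.csv` (ground truth) and `metadata.yaml`
#' (config incl. seed) into a directory.
#'
#' @param cohort output of [sim_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$abstracts, file.path(dir, "abstracts.csv"), row.names = FALSE)
  write.csv(cohort$episodes, file.path(dir, "episodes.csv"), row.names = FALSE)
  write_sim_config(cohort$config, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read discharge abstracts from CSV
#'
#' @param path a CSV written by [write_cohort_csv()] (the `abstracts.csv`
#'   file) or any file with the same header.
#' @return Tibble of abstracts with `Date` columns restored.
#' @export
read_abstracts_csv <- function(path) {
  x <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  for (col in intersect(c("admit_date", "discharge_date", "surgery_date"),
                        names(x))) {
    x[[col]] <- as.Date(x[[col]])
  }
  x
}
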