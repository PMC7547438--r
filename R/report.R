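# Descriptive and inferential tables, and the end-to-end pipeline.

#' Demographic table by demand category
#'
#' Counts and percentages of every characteristic, overall and within each
#' demand category. Percentages are column percentages within a
#' characteristic (they sum to 100 up to rounding) rounded half-up to one
#' decimal, the usual convention of administrative-data tables.
#'
#' @param cohort tibble of episodes with a `demand` column (from
#'   [assess_demand()]).
#' @param vars characteristic columns to tabulate; defaults to the standard
#'   covariate set present in the data.
#' @return Long tibble with `characteristic`, `level`, `group` (`"all"` or a
#'   demand category), `n` and `pct`.
#' @export
table_demographics <- function(cohort, vars = NULL) {
  if (is.null(vars)) {
    vars <- intersect(
      c("age_group", "sex", "prefracture_status", "admission_timing",
        "admission_status", "preop_transfer", "preop_procedure",
        "medical_reason_for_delay", "hospital_type", "fracture_type",
        "procedure_type", "era", "province"),
      names(cohort)
    )
  }
  groups <- c("all", levels(factor(cohort$demand)))
  purrr::map_dfr(vars, function(v) {
    purrr::map_dfr(groups, function(g) {
      d <- if (g == "all") cohort else cohort[as.character(cohort$demand) == g, ]
      tb <- table(as.character(d[[v]]))
      tibble(characteristic = v, level = names(tb), group = g,
             n = as.integer(tb),
             pct = round_half_up(100 * as.integer(tb) / nrow(d), 1))
    })
  })
}

#' Audit that printed percentages match printed counts
#'
#' Recomputes every percentage of a [table_demographics()] table from its
#' counts and checks agreement to the printed precision.
#'
#' @param tab a [table_demographics()] table.
#' @return `TRUE` invisibly; aborts when a percentage cannot be recomputed
#'   from the counts.
#' @export
audit_percentages <- function(tab) {
  chk <- tab %>%
    group_by(.data$characteristic, .data$group) %>%
    mutate(recomputed = round_half_up(100 * .data$n / sum(.data$n), 1)) %>%
    ungroup()
  bad <- chk[abs(chk$recomputed - chk$pct) > 1e-9, ]
  if (nrow(bad) > 0) {
    abort(sprintf("%d table cell(s) have percentages inconsistent with counts.",
                  nrow(bad)))
  }
  invisible(TRUE)
}

#' Median time to surgery and percent changes by demand level
#'
#' Assembles the per-demand-level results from a pair of fits: the group
#' medians (with CIs) from the unadjusted demand-only model, the unadjusted
#' percent changes from the same model, and the adjusted percent changes
#' from the full model. The reference (benchmark) row carries a zero percent
#' change.
#'
#' @param data the interval data the fits were computed on (for the group
#'   sizes).
#' @param fit_unadjusted a demand-only [aft_intreg()] fit.
#' @param fit_adjusted the fully adjusted fit, or `NULL` to omit the
#'   adjusted column.
#' @param label subgroup label stored in the `subgroup` column.
#' @return Tibble with one row per demand level.
#' @export
demand_results <- function(data, fit_unadjusted, fit_adjusted = NULL,
                           label = "overall") {
  lv <- intersect(demand_levels(), as.character(unique(data$demand)))
  med <- predicted_median(fit_unadjusted,
                          tibble(demand = factor(lv, levels = levels(data$demand)),
                                 demand_score = demand_score(lv)))
  pc_u <- percent_change(fit_unadjusted)
  pc_a <- if (!is.null(fit_adjusted)) percent_change(fit_adjusted) else NULL
  pick <- function(pc, level, col) {
    if (is.null(pc)) return(NA_real_)
    i <- match(paste0("demand", level), pc$term)
    if (is.na(i)) NA_real_ else pc[[col]][i]
  }
  purrr::map_dfr(seq_along(lv), function(i) {
    l <- lv[i]
    ref <- l == "benchmark"
    tibble(
      subgroup = label, demand = l,
      n = sum(as.character(data$demand) == l),
      median_days = med$median_days[i],
      median_low = med$conf.low[i], median_high = med$conf.high[i],
      unadj_pct = if (ref) 0 else pick(pc_u, l, "pct_change"),
      unadj_low = if (ref) NA_real_ else pick(pc_u, l, "conf.low"),
      unadj_high = if (ref) NA_real_ else pick(pc_u, l, "conf.high"),
      adj_pct = if (ref) 0 else pick(pc_a, l, "pct_change"),
      adj_low = if (ref) NA_real_ else pick(pc_a, l, "conf.low"),
      adj_high = if (ref) NA_real_ else pick(pc_a, l, "conf.high")
    )
  })
}

#' Results table overall and by medical reason for delay
#'
#' Binds [demand_results()] for the overall cohort and the two
#' presence/absence-of-medical-reason subgroups (whose adjusted fits drop
#' the medical-reason covariate). A subgroup covering fewer than two
#' hospitals is omitted with a warning.
#'
#' @param fits a list as produced by [run_pipeline()]: elements `overall`,
#'   `without_delay`, `with_delay`, each a list with `data`, `unadjusted`
#'   and (optionally) `adjusted`.
#' @return Tibble with one row per subgroup x demand level.
#' @export
table_results <- function(fits) {
  purrr::map_dfr(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is.null(f)) return(NULL)
    demand_results(f$data, f$unadjusted, f$adjusted, label = nm)
  })
}

default_adjusters <- function() {
  c("age_group", "sex", "prefracture_status", "admission_timing",
    "admission_status", "preop_transfer", "preop_procedure",
    "medical_reason_for_delay", "hospital_type", "fracture_type",
    "procedure_type", "era", "province")
}

fit_pair <- function(iv, adjusters, random, nodes, adjusted = TRUE) {
  iv$demand <- droplevels(iv$demand)
  iv$demand_score <- demand_score(iv$demand)
  keep <- adjusters[vapply(adjusters, function(v) {
    v %in% names(iv) && dplyr::n_distinct(iv[[v]]) > 1
  }, logical(1))]
  un <- aft_intreg(iv, cbind(lower, upper) ~ demand, cluster = "index_hospital_id",
                   random = random, score = "demand_score", nodes = nodes)
  ad <- NULL
  if (adjusted) {
    fml <- stats::reformulate(c("demand", keep),
                              response = quote(cbind(lower, upper)))
    # warm start: shared parameters from the demand-only fit
    Xad <- model.matrix(fml[-2], iv)
    start <- setNames(numeric(ncol(Xad)), colnames(Xad))
    shared <- intersect(names(start), names(un$coefficients))
    start[shared] <- un$coefficients[shared]
    start <- c(start, un$theta[-seq_along(un$coefficients)])
    ad <- aft_intreg(iv, fml, cluster = "index_hospital_id",
                     random = random, score = "demand_score", nodes = nodes,
                     start = unname(start))
  }
  list(data = iv, unadjusted = un, adjusted = ad, adjusters = keep)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) discharge abstracts, merges them into care episodes,
#' applies the cohort exclusions, assesses demand, builds censoring
#' intervals, fits the unadjusted and adjusted interval-censored AFT models
#' overall (and per medical-reason subgroup), fits the per-category Turnbull
#' curves, and assembles the demographic and results tables. Deterministic
#' given the seed.
#'
#' @param config a [sim_config()] (simulate mode), or `NULL` when
#'   `abstracts_csv` is given.
#' @param abstracts_csv path to an abstracts CSV (csv mode). Exactly one of
#'   `config`/`abstracts_csv` must be supplied.
#' @param seed overrides `config$seed` when given.
#' @param out_dir optional directory; when given, tables, curves, the
#'   exclusion ledger and run metadata are written as CSV/YAML.
#' @param horizon right-censoring horizon in days (default 7).
#' @param include_index count the index patient in the census (default TRUE).
#' @param random,nodes random-effects structure and quadrature nodes for the
#'   model fits.
#' @param adjusted fit the fully adjusted models (default TRUE).
#' @param subgroups fit the medical-reason subgroups (default TRUE).
#' @param subgroup_adjusted also fit the adjusted models within subgroups
#'   (default `adjusted`; set `FALSE` to keep subgroup reporting unadjusted).
#' @return List: `cohort`, `exclusions`, `fits`, `curves`,
#'   `table_demographics`, `table_results`, `rates` and `meta`.
#' @export
run_pipeline <- function(config = NULL, abstracts_csv = NULL, seed = NULL,
                         out_dir = NULL, horizon = 7, include_index = TRUE,
                         random = "intercept_slope", nodes = 9,
                         adjusted = TRUE, subgroups = TRUE,
                         subgroup_adjusted = adjusted) {
  if (is.null(config) == is.null(abstracts_csv)) {
    abort("supply exactly one of `config` (simulate mode) or `abstracts_csv` (csv mode).")
  }
  if (!is.null(config)) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    cohort_sim <- sim_cohort(config)
    abstracts <- cohort_sim$abstracts
  } else {
    abstracts <- read_abstracts_csv(abstracts_csv)
  }

  episodes <- merge_episodes(abstracts)
  excl <- apply_exclusions(episodes)
  cohort <- excl$cohort
  rates <- max_weekly_rates(cohort)
  dem <- assess_demand(cohort, rates, include_index = include_index)
  iv <- build_intervals(dem, horizon = horizon)
  iv$demand_score <- demand_score(iv$demand)

  adjusters <- default_adjusters()
  fits <- list(overall = fit_pair(iv, adjusters, random, nodes, adjusted))
  if (subgroups) {
    for (nm in c("without_delay", "with_delay")) {
      sub <- iv[iv$medical_reason_for_delay == (nm == "with_delay"), ]
      if (dplyr::n_distinct(sub$index_hospital_id) < 2) {
        warn(sprintf("subgroup '%s' covers fewer than 2 hospitals; omitted.", nm))
        next
      }
      fits[[nm]] <- fit_pair(sub, setdiff(adjusters, "medical_reason_for_delay"),
                             random, nodes, adjusted && subgroup_adjusted)
    }
  }

  curves <- surgery_curves(iv, group = "demand", times = seq_len(horizon))
  tab_dem <- table_demographics(iv)
  audit_percentages(tab_dem)
  tab_res <- table_results(fits)

  meta <- list(
    mode = if (is.null(config)) "csv" else "simulate",
    seed = if (is.null(config)) NA_integer_ else config$seed,
    horizon = horizon, include_index = include_index,
    random = random, nodes = nodes,
    n_abstracts = nrow(abstracts), n_episodes = nrow(episodes),
    n_cohort = nrow(cohort), n_analyzed = nrow(iv),
    package_version = as.character(utils::packageVersion("hipwait"))
  )

  out <- list(cohort = iv, exclusions = excl$exclusions, fits = fits,
              curves = curves, table_demographics = tab_dem,
              table_results = tab_res, rates = rates, meta = meta)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(out$table_demographics, file.path(dir, "table_demographics.csv"),
            row.names = FALSE)
  write.csv(out$table_results, file.path(dir, "table_results.csv"),
            row.names = FALSE)
  write.csv(out$curves, file.path(dir, "curves.csv"), row.names = FALSE)
  write.csv(out$rates, file.path(dir, "hospital_quarter_rates.csv"),
            row.names = FALSE)
  write.csv(
    out$cohort[, intersect(c("patient_id", "index_hospital_id", "admit_date",
                             "surgery_date", "N", "Q", "S", "C", "demand",
                             "lower", "upper", "censor_kind"),
                           names(out$cohort))],
    file.path(dir, "demand_assessment.csv"), row.names = FALSE
  )
  write_exclusion_log(out$exclusions, file.path(dir, "exclusions.txt"),
                      n_input = out$meta$n_episodes,
                      n_cohort = out$meta$n_cohort)
  for (nm in names(out$fits)) {
    f <- out$fits[[nm]]
    for (kind in c("unadjusted", "adjusted")) {
      if (is.null(f[[kind]])) next
      write.csv(tidy(f[[kind]], conf.int = TRUE),
                file.path(dir, sprintf("fit_%s_%s.csv", nm, kind)),
                row.names = FALSE)
    }
  }
  yaml::write_yaml(out$meta, file.path(dir, "run_metadata.yaml"))
  invisible(dir)
}
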