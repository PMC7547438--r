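test_that("the likelihood reduces to the two-Phi interval formula", {
  d <- tibble::tibble(lower = 1, upper = 2, hospital_id = "H1")
  for (mu in c(-0.5, 0.3, 1)) {
    for (sg in c(0.4, 0.8)) {
      ll <- aft_loglik(c(mu, log(sg)), d, cbind(lower, upper) ~ 1,
                       cluster = "hospital_id", random = "none")
      direct <- log(pnorm((log(2) - mu) / sg) - pnorm((log(1) - mu) / sg))
      expect_equal(ll, direct, tolerance = 1e-10)
    }
  }
  # left- and right-censored terms
  dl <- tibble::tibble(lower = 0, upper = 1, hospital_id = "H1")
  expect_equal(aft_loglik(c(0.3, log(0.5)), dl, cbind(lower, upper) ~ 1,
                          cluster = "hospital_id"),
               pnorm((0 - 0.3) / 0.5, log.p = TRUE), tolerance = 1e-10)
  dr <- tibble::tibble(lower = 7, upper = Inf, hospital_id = "H1")
  expect_equal(aft_loglik(c(0.3, log(0.5)), dr, cbind(lower, upper) ~ 1,
                          cluster = "hospital_id"),
               pnorm((log(7) - 0.3) / 0.5, lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-10)
})

test_that("an uninformative interval carries zero log-likelihood", {
  d <- tibble::tibble(lower = rep(0, 5), upper = rep(Inf, 5),
                      hospital_id = paste0("H", 1:5))
  expect_equal(aft_loglik(c(1.7, log(0.3)), d, cbind(lower, upper) ~ 1,
                          cluster = "hospital_id", random = "none"), 0)
})

test_that("adaptive quadrature is stable in the node count", {
  d <- sim_interval_data(5, 30, tau0 = 0.15, seed = 9)
  th <- c(0.4, 0.05, 0.12, 0.2, log(0.6), log(0.15))
  ll9 <- aft_loglik(th, d, cbind(lower, upper) ~ demand,
                    cluster = "hospital_id", random = "intercept", nodes = 9)
  ll15 <- aft_loglik(th, d, cbind(lower, upper) ~ demand,
                     cluster = "hospital_id", random = "intercept", nodes = 15)
  expect_lt(abs(ll9 - ll15), 1e-6)
})

test_that("fixed-effects estimates agree with survreg on interval data", {
  skip_if_not_installed("survival")
  d <- sim_interval_data(25, 60, tau0 = 0, seed = 3)
  f <- aft_intreg(d, cbind(lower, upper) ~ demand, cluster = "hospital_id",
                  random = "none")
  L <- ifelse(d$lower <= 0, NA, d$lower)
  U <- ifelse(is.infinite(d$upper), NA, d$upper)
  sr <- survival::survreg(survival::Surv(L, U, type = "interval2") ~ demand,
                          data = d, dist = "lognormal")
  expect_equal(coef(f), coef(sr), tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(f$sigma, sr$scale, tolerance = 1e-5)
})

test_that("the likelihood is equivariant under a time-scale shift", {
  d <- sim_interval_data(10, 40, tau0 = 0, seed = 21)
  f1 <- aft_intreg(d, cbind(lower, upper) ~ demand, cluster = "hospital_id",
                   random = "none")
  cc <- 0.7
  d2 <- d %>% dplyr::mutate(lower = lower * exp(cc), upper = upper * exp(cc))
  f2 <- aft_intreg(d2, cbind(lower, upper) ~ demand, cluster = "hospital_id",
                   random = "none")
  expect_equal(coef(f2)[["(Intercept)"]], coef(f1)[["(Intercept)"]] + cc,
               tolerance = 1e-5)
  expect_equal(coef(f2)[-1], coef(f1)[-1], tolerance = 1e-5)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-5)
})

test_that("an intercept-only fit on symmetric log intervals recovers the centre", {
  width <- rep(c(0.2, 0.5, 0.9), each = 20)
  d <- tibble::tibble(lower = 2 * exp(-width), upper = 2 * exp(width),
                      hospital_id = rep(c("H1", "H2"), 30))
  f <- suppressWarnings(aft_intreg(d, cbind(lower, upper) ~ 1,
                                   cluster = "hospital_id", random = "none"))
  expect_equal(predicted_median(f, tibble::tibble(.rows = 1))$median_days, 2,
               tolerance = 1e-4)
})

test_that("the fitted scale converges to the SD of the logs on exact data", {
  set.seed(77)
  n <- 1e5
  y <- exp(rnorm(n, 0.5, 0.6))
  d <- tibble::tibble(lower = y, upper = y,
                      hospital_id = rep(c("H1", "H2"), n / 2))
  f <- aft_intreg(d, cbind(lower, upper) ~ 1, cluster = "hospital_id",
                  random = "none")
  expect_equal(f$sigma, sd(log(y)), tolerance = 0.02)
  expect_equal(coef(f)[["(Intercept)"]], mean(log(y)), tolerance = 1e-4)
})

test_that("percent changes follow the exp(beta)-1 transform with Wald limits", {
  d <- sim_interval_data(15, 50, tau0 = 0, seed = 14)
  f <- aft_intreg(d, cbind(lower, upper) ~ demand, cluster = "hospital_id",
                  random = "none")
  pc <- percent_change(f)
  td <- tidy(f)
  for (i in seq_len(nrow(pc))) {
    b <- td$estimate[td$term == pc$term[i]]
    se <- td$std.error[td$term == pc$term[i]]
    expect_equal(pc$pct_change[i], (exp(b) - 1) * 100)
    expect_equal(pc$conf.low[i], (exp(b - qnorm(0.975) * se) - 1) * 100)
    expect_equal(pc$conf.high[i], (exp(b + qnorm(0.975) * se) - 1) * 100)
    expect_lt(pc$conf.low[i], pc$conf.high[i])
  }
  # beta = 0 maps to a 0% change
  expect_equal((exp(0) - 1) * 100, 0)
})

test_that("median ratios and percent changes are algebraically consistent", {
  d <- sim_interval_data(12, 40, tau0 = 0.1, seed = 15)
  f <- aft_intreg(d, cbind(lower, upper) ~ demand, cluster = "hospital_id",
                  random = "intercept", nodes = 5)
  med <- predicted_median(
    f, tibble::tibble(demand = factor(demand_levels(), levels = demand_levels()))
  )
  pc <- percent_change(f)
  for (i in 2:4) {
    expect_equal((med$median_days[i] / med$median_days[1] - 1) * 100,
                 pc$pct_change[i - 1], tolerance = 1e-10)
  }
})

test_that("duplicating every cluster halves the sandwich covariance", {
  d <- sim_interval_data(30, 30, tau0 = 0, seed = 18)
  f1 <- aft_intreg(d, cbind(lower, upper) ~ demand, cluster = "hospital_id",
                   random = "none")
  d2 <- dplyr::bind_rows(d, d %>% dplyr::mutate(hospital_id = paste0(hospital_id, "bis")))
  f2 <- aft_intreg(d2, cbind(lower, upper) ~ demand, cluster = "hospital_id",
                   random = "none", start = f1$theta)
  G <- f1$n_clusters
  corr <- (2 * G / (2 * G - 1)) / (G / (G - 1))   # small-sample factors
  expect_equal(f2$vcov_sandwich, f1$vcov_sandwich / 2 * corr, tolerance = 1e-3)
})

test_that("glance and tidy expose the fit summaries", {
  d <- sim_interval_data(10, 30, tau0 = 0.1, seed = 19)
  f <- aft_intreg(d, cbind(lower, upper) ~ demand, cluster = "hospital_id",
                  random = "intercept", nodes = 5)
  g <- glance(f)
  expect_true(g$converged)
  expect_equal(g$nobs, 300L)
  expect_equal(g$n_clusters, 10L)
  expect_gt(g$sigma, 0)
  td <- tidy(f, conf.int = TRUE)
  expect_true(all(c("term", "estimate", "std.error", "conf.low") %in% names(td)))
  expect_equal(nrow(td), 4)
  expect_output(print(f), "log-normal AFT")
})

test_that("degenerate designs and inputs are rejected with clear errors", {
  d <- sim_interval_data(6, 20, tau0 = 0, seed = 20)
  d$dup <- demand_score(d$demand)
  expect_error(aft_intreg(d, cbind(lower, upper) ~ demand + demand_score + dup,
                          cluster = "hospital_id", random = "none"),
               "rank deficient")
  d1 <- d %>% dplyr::mutate(hospital_id = "H1")
  expect_error(aft_intreg(d1, cbind(lower, upper) ~ demand,
                          cluster = "hospital_id", random = "intercept"),
               "at least 2 hospitals")
  dbad <- d %>% dplyr::mutate(lower = upper + 1)
  expect_error(aft_intreg(dbad, cbind(lower, upper) ~ demand,
                          cluster = "hospital_id", random = "none"),
               "lower")
})
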