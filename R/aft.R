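# Log-normal accelerated failure time model for interval-censored day-grid
# times, with optional hospital random effects (random intercept, plus a
# random slope on the ordinal demand score) integrated out by adaptive
# Gauss-Hermite quadrature, and a clustered sandwich covariance.

# ---- data preparation --------------------------------------------------

# Encode kinds as integers: 0 exact, 1 interval, 2 left, 3 right.
build_aft_parts <- function(data, formula, cluster, random, score, nodes) {
  mf <- model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.null(dim(y)) || ncol(y) != 2) {
    abort("the model response must be `cbind(lower, upper)` on the day scale.")
  }
  X <- model.matrix(attr(mf, "terms"), mf)
  lower <- as.numeric(y[, 1]); upper <- as.numeric(y[, 2])
  if (any(lower > upper)) abort("found `lower` > `upper`.")
  kind <- ifelse(lower == upper, 0L,
                 ifelse(lower <= 0, 2L, ifelse(is.infinite(upper), 3L, 1L)))
  if (any(kind == 0L & lower <= 0)) abort("exact observations must be positive.")
  logL <- ifelse(lower > 0, log(lower), -Inf)
  logU <- ifelse(is.infinite(upper), Inf, log(upper))

  cl <- factor(data[[cluster]])
  if (anyNA(cl)) abort("missing cluster ids.")
  sc <- if (is.null(score)) rep(0, nrow(X)) else as.numeric(data[[score]])
  if (random == "intercept_slope" && is.null(score)) {
    abort("a `score` column is required for the random demand slope.")
  }

  # collapse duplicated (cluster, covariate pattern, interval) rows
  key <- paste(as.integer(cl), apply(X, 1L, paste, collapse = "\r"),
               logL, logU, kind, sc, sep = "\r")
  first <- !duplicated(key)
  agg_map <- match(key, key[first])
  w <- as.numeric(tabulate(agg_map, nbins = sum(first)))
  parts <- list(
    X = X[first, , drop = FALSE],
    logL = logL[first], logU = logU[first], kind = kind[first],
    w = w, cl = as.integer(cl)[first], score = sc[first], agg_map = agg_map,
    G = nlevels(cl), cluster_levels = levels(cl),
    n_obs = nrow(X), random = random, nodes = nodes,
    terms = delete.response(attr(mf, "terms")),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf)
  )
  parts$idx <- lapply(0:3, function(k) which(parts$kind == k))
  parts$idx_cens <- which(parts$kind != 0L)
  parts$gh <- pracma::gaussHermite(nodes)
  parts
}

# Per-observation log-likelihood contributions at linear predictor eta.
# With deriv = TRUE also returns first and second derivatives with respect
# to eta (the censored log-normal log-likelihood is concave in eta, so the
# second derivative is nonpositive).
aft_obs_ll <- function(eta, parts, sigma, deriv = FALSE) {
  n <- length(eta)
  ll <- numeric(n)
  d1 <- if (deriv) numeric(n) else NULL
  d2 <- if (deriv) numeric(n) else NULL
  i0 <- parts$idx[[1]]   # exact
  ic <- parts$idx_cens   # interval / left / right, handled uniformly
  if (length(i0)) {
    z <- (parts$logL[i0] - eta[i0]) / sigma
    ll[i0] <- -0.5 * z^2 - log(sigma) - 0.918938533204673  # log(sqrt(2*pi))
    if (deriv) {
      d1[i0] <- z / sigma
      d2[i0] <- -1 / sigma^2
    }
  }
  if (length(ic)) {
    zl <- (parts$logL[ic] - eta[ic]) / sigma   # -Inf when left-censored
    zu <- (parts$logU[ic] - eta[ic]) / sigma   # +Inf when right-censored
    pos <- zl > 0
    p <- numeric(length(ic))
    p[pos] <- pnorm(zl[pos], lower.tail = FALSE) - pnorm(zu[pos], lower.tail = FALSE)
    p[!pos] <- pnorm(zu[!pos]) - pnorm(zl[!pos])
    p <- pmax(p, 1e-320)
    ll[ic] <- log(p)
    if (deriv) {
      pd <- pmax(p, 1e-15)   # keep derivatives finite in extreme tails
      phl <- dnorm(zl); phu <- dnorm(zu)
      g <- (phl - phu) / (sigma * pd)
      zphl <- zl * phl; zphl[!is.finite(zphl)] <- 0
      zphu <- zu * phu; zphu[!is.finite(zphu)] <- 0
      d1[ic] <- g
      d2[ic] <- (zphl - zphu) / (sigma^2 * pd) - g^2
    }
  }
  if (deriv) list(ll = ll, d1 = d1, d2 = d2) else list(ll = ll)
}

# ---- marginal log-likelihood -------------------------------------------

n_var_par <- function(random) switch(random, none = 0L, intercept = 1L, intercept_slope = 2L)

split_theta <- function(theta, parts) {
  p <- ncol(parts$X)
  out <- list(beta = theta[seq_len(p)], sigma = unname(exp(theta[p + 1L])))
  if (parts$random != "none") out$tau0 <- unname(exp(theta[p + 2L]))
  if (parts$random == "intercept_slope") out$tau1 <- unname(exp(theta[p + 3L]))
  out
}

# cluster-summed data log-likelihood at random-effect values b (G-vectors);
# with deriv = TRUE also the cluster-summed gradient/Hessian blocks with
# respect to (b0, b1)
cluster_data_ll <- function(b0, b1, eta0, parts, sigma, deriv = FALSE) {
  eta <- eta0 + b0[parts$cl]
  if (!is.null(b1)) eta <- eta + b1[parts$cl] * parts$score
  o <- aft_obs_ll(eta, parts, sigma, deriv = deriv)
  if (!deriv) return(drop(rowsum(parts$w * o$ll, parts$cl)))
  if (is.null(b1)) {
    m <- rowsum(cbind(o$ll, o$d1, o$d2) * parts$w, parts$cl)
    list(f = m[, 1], g1 = m[, 2], H11 = m[, 3])
  } else {
    s <- parts$score
    m <- rowsum(cbind(o$ll, o$d1, s * o$d1, o$d2, s * o$d2, s * s * o$d2) *
                  parts$w, parts$cl)
    list(f = m[, 1], g1 = m[, 2], g2 = m[, 3],
         H11 = m[, 4], H12 = m[, 5], H22 = m[, 6])
  }
}

#' @keywords internal
#' @noRd
aft_marginal_ll <- function(theta, parts, by_cluster = FALSE,
                            on_nonfinite = "abort") {
  pr <- split_theta(theta, parts)
  in_range <- function(x, lo, hi) is.null(x) || (is.finite(x) && x > lo && x < hi)
  ok <- all(is.finite(pr$beta)) && in_range(pr$sigma, 1e-6, 1e3) &&
    in_range(pr$tau0, 1e-8, 1e3) && in_range(pr$tau1, 1e-8, 1e3)
  if (!ok) {
    return(finish_ll(rep(-Inf, parts$G), parts, by_cluster, on_nonfinite))
  }
  eta0 <- drop(parts$X %*% pr$beta)
  G <- parts$G

  if (parts$random == "none") {
    llc <- drop(rowsum(parts$w * aft_obs_ll(eta0, parts, pr$sigma)$ll, parts$cl))
    return(finish_ll(llc, parts, by_cluster, on_nonfinite))
  }

  gh <- parts$gh
  xk <- gh$x; lwk <- log(gh$w) + gh$x^2

  newton_steps <- 6L

  if (parts$random == "intercept") {
    tau0 <- pr$tau0
    # posterior mode of the random intercept: damped Newton with analytic
    # derivatives (the objective is strictly concave in b)
    b <- numeric(G)
    H <- NULL
    for (it in seq_len(newton_steps)) {
      cd <- cluster_data_ll(b, NULL, eta0, parts, pr$sigma, deriv = TRUE)
      g <- cd$g1 - b / tau0^2
      H <- pmin(cd$H11 - 1 / tau0^2, -1e-8)
      H[!is.finite(H)] <- -1e-8
      step <- -g / H
      step[!is.finite(step)] <- 0
      b <- b + sign(step) * pmin(abs(step), 4 * tau0 + 0.1)
      if (max(abs(step)) < 1e-9) break
    }
    s_hat <- 1 / sqrt(-H)
    h <- function(bb) cluster_data_ll(bb, NULL, eta0, parts, pr$sigma) +
      dnorm(bb, 0, tau0, log = TRUE)
    m <- matrix(0, G, length(xk))
    for (k in seq_along(xk)) m[, k] <- lwk[k] + h(b + sqrt(2) * s_hat * xk[k])
    llc <- log(sqrt(2) * s_hat) + logsumexp_rows(m)
    return(finish_ll(llc, parts, by_cluster, on_nonfinite))
  }

  # random intercept + random slope on the demand score (d = 2)
  tau0 <- pr$tau0; tau1 <- pr$tau1
  b0 <- numeric(G); b1 <- numeric(G)
  H11 <- H12 <- H22 <- NULL
  for (it in seq_len(newton_steps)) {
    cd <- cluster_data_ll(b0, b1, eta0, parts, pr$sigma, deriv = TRUE)
    g1 <- cd$g1 - b0 / tau0^2
    g2 <- cd$g2 - b1 / tau1^2
    H11 <- pmin(cd$H11 - 1 / tau0^2, -1e-8)
    H22 <- pmin(cd$H22 - 1 / tau1^2, -1e-8)
    H12 <- cd$H12
    H11[!is.finite(H11)] <- -1e-8
    H22[!is.finite(H22)] <- -1e-8
    H12[!is.finite(H12)] <- 0
    det <- H11 * H22 - H12^2
    bad <- !is.finite(det) | det <= 1e-12
    H12[bad] <- 0
    det[bad] <- H11[bad] * H22[bad]
    s1 <- -(H22 * g1 - H12 * g2) / det
    s2 <- -(H11 * g2 - H12 * g1) / det
    s1[!is.finite(s1)] <- 0
    s2[!is.finite(s2)] <- 0
    b0 <- b0 + sign(s1) * pmin(abs(s1), 4 * tau0 + 0.1)
    b1 <- b1 + sign(s2) * pmin(abs(s2), 4 * tau1 + 0.1)
    if (max(abs(s1), abs(s2)) < 1e-9) break
  }
  # Sigma-hat = (-H)^{-1}; lower Cholesky factor, closed form per cluster
  M11 <- -H11; M22 <- -H22; M12 <- -H12
  detM <- pmax(M11 * M22 - M12^2, 1e-12)
  a11 <- sqrt(M22 / detM); a21 <- -M12 / detM / a11
  a22 <- sqrt(pmax(M11 / detM - a21^2, 1e-12))
  h2 <- function(bb0, bb1) cluster_data_ll(bb0, bb1, eta0, parts, pr$sigma) +
    dnorm(bb0, 0, tau0, log = TRUE) + dnorm(bb1, 0, tau1, log = TRUE)
  K <- length(xk)
  m <- matrix(0, G, K * K)
  idx <- 1L
  for (j in seq_len(K)) {
    off0j <- sqrt(2) * a11 * xk[j]
    off1j <- sqrt(2) * a21 * xk[j]
    for (k in seq_len(K)) {
      m[, idx] <- lwk[j] + lwk[k] +
        h2(b0 + off0j, b1 + off1j + sqrt(2) * a22 * xk[k])
      idx <- idx + 1L
    }
  }
  llc <- log(2 * a11 * a22) + logsumexp_rows(m)
  finish_ll(llc, parts, by_cluster, on_nonfinite)
}

finish_ll <- function(llc, parts, by_cluster, on_nonfinite) {
  if (any(!is.finite(llc))) {
    if (on_nonfinite == "abort") {
      bad <- parts$cluster_levels[which(!is.finite(llc))[1]]
      abort(sprintf("non-finite likelihood contribution for hospital block '%s'.", bad))
    }
    return(if (by_cluster) llc else -1e10)
  }
  if (by_cluster) llc else sum(llc)
}

#' Interval-censored log-normal AFT log-likelihood
#'
#' Evaluates the marginal log-likelihood of the interval-censored log-normal
#' accelerated failure time model at given parameter values. With random
#' effects, each hospital's contribution is the integral over the random
#' intercept (and, optionally, the random slope on the demand score) of the
#' product of interval probabilities
#' `Phi((log U - eta)/sigma) - Phi((log L - eta)/sigma)`, computed by
#' adaptive Gauss-Hermite quadrature.
#'
#' @param theta parameter vector `c(beta, log sigma, log tau0, log tau1)`
#'   (variance entries present according to `random`).
#' @param data data frame with day-scale `lower`/`upper` bounds, covariates
#'   and the cluster column.
#' @param formula model formula `cbind(lower, upper) ~ ...`.
#' @param cluster name of the hospital id column.
#' @param random `"none"`, `"intercept"` or `"intercept_slope"`.
#' @param score name of the numeric demand-score column (needed for the
#'   random slope).
#' @param nodes Gauss-Hermite nodes per dimension.
#' @param by_cluster return the per-hospital contributions instead of the sum.
#' @return The log-likelihood (scalar, or per-cluster vector).
#' @export
aft_loglik <- function(theta, data, formula, cluster = "hospital_id",
                       random = c("none", "intercept", "intercept_slope"),
                       score = NULL, nodes = 9, by_cluster = FALSE) {
  random <- match.arg(random)
  parts <- build_aft_parts(data, formula, cluster, random, score, nodes)
  aft_marginal_ll(theta, parts, by_cluster = by_cluster)
}

# ---- fitting ------------------------------------------------------------

#' Fit the interval-censored log-normal AFT model
#'
#' Maximum marginal likelihood for day-grid interval-censored times on the
#' log scale, with optional hospital random effects (random intercept, and a
#' random slope on the ordinal demand score 0..3) integrated by adaptive
#' Gauss-Hermite quadrature. Optimization is quasi-Newton (BFGS) on the
#' unconstrained parameterization `(beta, log sigma, log tau)`. Both the
#' model-based covariance (inverse observed information) and a clustered
#' sandwich covariance with the small-sample factor `G/(G-1)` are returned.
#'
#' @param data data frame with `lower`/`upper` day-scale bounds (from
#'   [build_intervals()] or [sim_interval_data()]), covariates and the
#'   cluster column. `lower <= 0` marks left censoring, `upper = Inf` right
#'   censoring, `lower == upper` an exactly observed time.
#' @param formula model formula, e.g. `cbind(lower, upper) ~ demand + sex`.
#' @param cluster hospital id column name (string).
#' @param random random-effects structure: `"intercept_slope"` (default when
#'   a score is available), `"intercept"`, or `"none"`.
#' @param score numeric demand-score column name for the random slope;
#'   defaults to `"demand_score"` when present in `data`.
#' @param nodes Gauss-Hermite nodes per dimension (default 9).
#' @param start optional starting `theta`.
#' @param control passed to [stats::optim()] (defaults tighten `reltol`).
#' @return An object of class `hw_aft` with coefficients, `sigma`, random
#'   effect SDs, model-based and sandwich covariances, log-likelihood and
#'   convergence diagnostics. Methods: [tidy()], [glance()], `print()`,
#'   `vcov()`, `logLik()`, [percent_change()], [predicted_median()].
#' @export
aft_intreg <- function(data, formula, cluster = "hospital_id",
                       random = NULL, score = NULL, nodes = 9,
                       start = NULL, control = list()) {
  if (is.null(score) && "demand_score" %in% names(data)) score <- "demand_score"
  if (is.null(random)) {
    random <- if (is.null(score)) "intercept" else "intercept_slope"
  }
  random <- match.arg(random, c("none", "intercept", "intercept_slope"))
  if (random == "intercept_slope" && is.null(score)) random <- "intercept"
  parts <- build_aft_parts(data, formula, cluster, random, score, nodes)
  if (random != "none" && parts$G < 2) {
    abort("random effects require at least 2 hospitals.")
  }
  p <- ncol(parts$X)
  if (qr(parts$X)$rank < p) abort("design matrix is rank deficient.")

  if (is.null(start)) {
    ymid <- ifelse(parts$kind == 0L, parts$logL,
            ifelse(parts$kind == 1L, (parts$logL + parts$logU) / 2,
            ifelse(parts$kind == 2L, parts$logU - 0.5, parts$logL + 0.5)))
    fit0 <- stats::lm.wfit(parts$X, ymid, parts$w)
    s0 <- sqrt(sum(parts$w * fit0$residuals^2) / sum(parts$w)) + 0.05
    start <- c(fit0$coefficients, log(s0),
               rep(log(0.1), n_var_par(random)))
  }
  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-12), control)
  negll <- function(th) -aft_marginal_ll(th, parts, on_nonfinite = "penalize")
  opt <- optim(start, negll, method = "BFGS", control = ctl)
  theta <- opt$par
  pr <- split_theta(theta, parts)

  big <- which(abs(pr$beta) > 10 & names(pr$beta) != "(Intercept)")
  if (length(big) > 0) {
    abort(sprintf("possible separation: coefficient '%s' diverged (|beta| > 10).",
                  names(pr$beta)[big[1]]))
  }

  A <- optimHess(theta, negll)           # observed information
  vcov_full <- tryCatch(solve(A), error = function(e) {
    warn("observed information is singular; using a pseudo-inverse.")
    pinv_sym(A)
  })
  grad <- numeric(length(theta))
  hstep <- 1e-6 * pmax(abs(theta), 1)
  for (j in seq_along(theta)) {
    ej <- numeric(length(theta)); ej[j] <- hstep[j]
    grad[j] <- (negll(theta + ej) - negll(theta - ej)) / (2 * hstep[j])
  }

  nm <- c(colnames(parts$X), "log(sigma)",
          c("log(tau0)", "log(tau1)")[seq_len(n_var_par(random))])
  dimnames(vcov_full) <- list(nm, nm)
  names(theta) <- nm

  fit <- structure(list(
    coefficients = setNames(pr$beta, colnames(parts$X)),
    sigma = pr$sigma, tau0 = pr$tau0 %||% 0, tau1 = pr$tau1 %||% 0,
    theta = theta, loglik = -opt$value,
    vcov_model = vcov_full,
    parts = parts, random = random, nodes = nodes,
    n = parts$n_obs, n_clusters = parts$G,
    convergence = list(code = opt$convergence, counts = opt$counts,
                       gradient_norm = sqrt(sum(grad^2))),
    formula = formula, cluster = cluster, score = score,
    call = match.call()
  ), class = "hw_aft")
  if (parts$G >= 2) {
    fit$vcov_sandwich <- sandwich_vcov(fit)
  } else {
    warn("single cluster: sandwich covariance unavailable, using the model-based covariance.")
    fit$vcov_sandwich <- vcov_full
  }
  fit
}

# symmetric pseudo-inverse
pinv_sym <- function(A, tol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' Clustered sandwich covariance for an AFT fit
#'
#' Computes `A^{-1} B A^{-1}` where `A` is the observed information and `B`
#' the outer-product sum of per-hospital score vectors (numerical
#' derivatives of the per-cluster marginal log-likelihood), with the
#' small-sample correction `G/(G-1)`.
#'
#' @param fit an [aft_intreg()] object.
#' @param cluster optional alternative cluster assignment (vector with one
#'   entry per observation); only allowed for fixed-effects fits, where the
#'   likelihood factors by observation.
#' @return Covariance matrix for the full parameter vector.
#' @export
sandwich_vcov <- function(fit, cluster = NULL) {
  parts <- fit$parts
  theta <- fit$theta
  if (!is.null(cluster)) {
    if (fit$random != "none") {
      abort("re-clustering requires a fixed-effects fit; the random-effects likelihood only factors by hospital.")
    }
    if (length(cluster) != parts$n_obs) {
      abort("`cluster` must have one entry per observation.")
    }
    per_row <- tapply(as.character(cluster), parts$agg_map,
                      function(v) if (length(unique(v)) == 1L) v[1] else NA_character_)
    if (anyNA(per_row)) {
      abort("the alternative clustering splits pooled identical observations; refit with this cluster column instead.")
    }
    cl <- factor(per_row[as.character(seq_along(parts$cl))])
    parts <- utils::modifyList(parts, list(cl = as.integer(cl), G = nlevels(cl),
                                           cluster_levels = levels(cl)))
  }
  G <- parts$G
  if (G < 2) abort("the sandwich estimator needs at least 2 clusters.")
  np <- length(theta)
  S <- matrix(0, G, np)
  hstep <- 1e-5 * pmax(abs(theta), 1)
  for (j in seq_len(np)) {
    ej <- numeric(np); ej[j] <- hstep[j]
    lp <- aft_marginal_ll(theta + ej, parts, by_cluster = TRUE)
    lm_ <- aft_marginal_ll(theta - ej, parts, by_cluster = TRUE)
    S[, j] <- (lp - lm_) / (2 * hstep[j])
  }
  B <- crossprod(S) * G / (G - 1)
  Ainv <- fit$vcov_model
  V <- Ainv %*% B %*% Ainv
  dimnames(V) <- dimnames(Ainv)
  (V + t(V)) / 2
}

# ---- reporting from a fit ----------------------------------------------

#' Percent change in median time to surgery
#'
#' Transforms AFT coefficients to percent changes in the median:
#' `(exp(beta) - 1) * 100`, with Wald 95% limits transformed the same way,
#' `(exp(beta +/- z * se) - 1) * 100`.
#'
#' @param fit an [aft_intreg()] object.
#' @param terms coefficient names to transform; defaults to all demand-level
#'   coefficients (names starting with `"demand"`).
#' @param vcov_type `"sandwich"` (default) or `"model"`.
#' @param conf.level confidence level.
#' @return Tibble with `term`, `estimate` (log scale), `std.error`,
#'   `pct_change`, `conf.low`, `conf.high` (percent scale).
#' @export
percent_change <- function(fit, terms = NULL, vcov_type = c("sandwich", "model"),
                           conf.level = 0.95) {
  vcov_type <- match.arg(vcov_type)
  V <- if (vcov_type == "sandwich") fit$vcov_sandwich else fit$vcov_model
  cf <- fit$coefficients
  if (is.null(terms)) terms <- names(cf)[startsWith(names(cf), "demand")]
  if (length(terms) == 0) abort("no matching coefficients; give `terms` explicitly.")
  se <- sqrt(diag(V)[terms])
  z <- qnorm(1 - (1 - conf.level) / 2)
  b <- cf[terms]
  tibble(
    term = terms, estimate = unname(b), std.error = unname(se),
    pct_change = unname((exp(b) - 1) * 100),
    conf.low = unname((exp(b - z * se) - 1) * 100),
    conf.high = unname((exp(b + z * se) - 1) * 100)
  )
}

#' Predicted median time to surgery for a covariate profile
#'
#' The log-normal median at the linear predictor, `exp(x'beta)` (random
#' effects at zero), with a Wald interval transformed from the log scale.
#'
#' @param fit an [aft_intreg()] object.
#' @param newdata data frame of covariate profiles (one row per profile);
#'   must cover every model covariate, at levels seen in fitting.
#' @param vcov_type `"sandwich"` (default) or `"model"`.
#' @param conf.level confidence level.
#' @return Tibble with `median_days`, `conf.low`, `conf.high` per row of
#'   `newdata`.
#' @export
predicted_median <- function(fit, newdata, vcov_type = c("sandwich", "model"),
                             conf.level = 0.95) {
  vcov_type <- match.arg(vcov_type)
  parts <- fit$parts
  X <- model.matrix(parts$terms, data = newdata, xlev = parts$xlevels)
  cf <- fit$coefficients
  V <- (if (vcov_type == "sandwich") fit$vcov_sandwich else fit$vcov_model)
  Vb <- V[names(cf), names(cf), drop = FALSE]
  eta <- unname(drop(X %*% cf))
  se <- unname(sqrt(rowSums((X %*% Vb) * X)))
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble(median_days = exp(eta),
         conf.low = exp(eta - z * se), conf.high = exp(eta + z * se))
}

#' Modal covariate profile of a cohort
#'
#' One-row data frame holding each model covariate at its most frequent
#' value, used as the reference profile for adjusted medians.
#'
#' @param data the model data.
#' @param vars covariate column names.
#' @return One-row tibble.
#' @export
modal_profile <- function(data, vars) {
  out <- lapply(vars, function(v) {
    x <- data[[v]]
    tb <- sort(table(x), decreasing = TRUE)
    val <- names(tb)[1]
    if (is.factor(x)) factor(val, levels = levels(x))
    else if (is.logical(x)) as.logical(val)
    else if (is.numeric(x)) as.numeric(val)
    else val
  })
  names(out) <- vars
  as_tibble(out)
}

# ---- methods ------------------------------------------------------------

#' @export
print.hw_aft <- function(x, ...) {
  cat("Interval-censored log-normal AFT model\n")
  cat(sprintf("  n = %d, hospitals = %d, random effects: %s\n",
              x$n, x$n_clusters, x$random))
  cat(sprintf("  logLik = %.3f, sigma = %.4f", x$loglik, x$sigma))
  if (x$random != "none") cat(sprintf(", tau0 = %.4f", x$tau0))
  if (x$random == "intercept_slope") cat(sprintf(", tau1 = %.4f", x$tau1))
  cat("\nCoefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
vcov.hw_aft <- function(object, type = c("sandwich", "model"), ...) {
  type <- match.arg(type)
  if (type == "sandwich") object$vcov_sandwich else object$vcov_model
}

#' @export
logLik.hw_aft <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' @export
coef.hw_aft <- function(object, ...) object$coefficients

#' Tidy an interval-censored AFT fit
#'
#' @param x an [aft_intreg()] object.
#' @param conf.int add Wald confidence limits.
#' @param conf.level confidence level.
#' @param robust use the clustered sandwich covariance (default) rather than
#'   the model-based one.
#' @param ... unused.
#' @return A tibble with one row per fixed-effect coefficient.
#' @exportS3Method generics::tidy
tidy.hw_aft <- function(x, conf.int = FALSE, conf.level = 0.95,
                        robust = TRUE, ...) {
  cf <- x$coefficients
  V <- if (robust) x$vcov_sandwich else x$vcov_model
  se <- sqrt(diag(V)[names(cf)])
  stat <- cf / se
  out <- tibble(term = names(cf), estimate = unname(cf),
                std.error = unname(se), statistic = unname(stat),
                p.value = unname(2 * pnorm(-abs(stat))))
  if (conf.int) {
    z <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' Glance at an interval-censored AFT fit
#'
#' @param x an [aft_intreg()] object.
#' @param ... unused.
#' @return A one-row tibble of fit summaries.
#' @exportS3Method generics::glance
glance.hw_aft <- function(x, ...) {
  tibble(
    logLik = x$loglik, sigma = x$sigma,
    tau_intercept = x$tau0, tau_slope = x$tau1,
    nobs = x$n, n_clusters = x$n_clusters,
    converged = x$convergence$code == 0,
    gradient_norm = x$convergence$gradient_norm,
    nodes = x$nodes
  )
}
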