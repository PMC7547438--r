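# Nonparametric maximum-likelihood estimation of the time-to-surgery
# distribution from interval-censored data (Turnbull self-consistency EM).
# Observations are half-open intervals (L, U] on the day scale; L = U marks
# an exactly observed time, U = Inf a right-censored one.

#' Turnbull support intervals
#'
#' The NPMLE of an interval-censored distribution places all mass on the
#' "innermost" intervals `(q, p]`: `q` is some observation's left endpoint,
#' `p` the smallest right endpoint at or after it, and no other endpoint lies
#' strictly between. Exactly observed times contribute degenerate point
#' supports.
#'
#' @param lower,upper numeric vectors of day-scale bounds; `lower == upper`
#'   for exact times, `upper = Inf` for right censoring.
#' @return Tibble with columns `q`, `p` (ordered, disjoint support
#'   intervals; a row with `q == p` is a point mass, `p = Inf` the
#'   right-censored tail).
#' @export
turnbull_support <- function(lower, upper) {
  if (length(lower) == 0L) abort("no observations.")
  if (any(lower > upper)) abort("found `lower` > `upper`.")
  exact <- lower == upper
  pts <- sort(unique(lower[exact]))
  Ls <- sort(unique(lower[!exact]))
  Us <- sort(unique(upper[!exact]))
  ends <- sort(unique(c(lower, upper)))

  sup <- list()
  for (q in Ls) {
    cand <- Us[Us > q]
    if (length(cand) == 0L) next
    p <- cand[1]
    inner <- ends[ends > q & ends < p]
    if (length(inner) == 0L) sup[[length(sup) + 1L]] <- c(q, p)
  }
  out <- rbind(
    if (length(pts)) cbind(q = pts, p = pts),
    if (length(sup)) do.call(rbind, sup)
  )
  if (is.null(out)) abort("no support intervals (empty input?).")
  colnames(out) <- c("q", "p")
  out <- out[!duplicated(out), , drop = FALSE]
  as_tibble(out) %>% arrange(.data$q, .data$p)
}

#' Fit the Turnbull NPMLE
#'
#' Self-consistency EM on the Turnbull support intervals, iterated until the
#' largest mass change falls below `tol`. The log-likelihood is
#' non-decreasing across EM iterations; the fit records the full trace so
#' this can be verified.
#'
#' @param lower,upper day-scale interval bounds as in [turnbull_support()].
#' @param tol convergence tolerance on the masses (default 1e-8).
#' @param max_iter iteration cap (default 1e5); exceeded = error.
#' @return Object of class `hw_npmle`: support tibble with masses, number of
#'   observations, iterations, and the log-likelihood trace. The mass on a
#'   support with `p = Inf` is the right-censored deficit beyond the horizon.
#' @export
fit_npmle <- function(lower, upper, tol = 1e-8, max_iter = 1e5) {
  if (all(is.infinite(upper))) {
    abort("all observations are right-censored; the NPMLE needs at least one finite interval.")
  }
  sup <- turnbull_support(lower, upper)
  m <- nrow(sup)
  n <- length(lower)
  # membership: support j feasible for observation i
  A <- matrix(FALSE, n, m)
  for (j in seq_len(m)) {
    qj <- sup$q[j]; pj <- sup$p[j]
    A[, j] <- ifelse(lower == upper,
                     lower == qj & qj == pj,           # exact obs vs point support
                     lower <= qj & pj <= upper & !(qj == pj & qj <= lower))
  }
  if (any(rowSums(A) == 0L)) abort("an observation is compatible with no support interval.")

  p <- rep(1 / m, m)
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    denom <- drop(A %*% p)
    ll_trace <- c(ll_trace, sum(log(denom)))
    p_new <- p * drop(crossprod(A, 1 / denom)) / n
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      ll_trace <- c(ll_trace, sum(log(drop(A %*% p))))
      sup$mass <- p
      return(structure(list(support = sup,
                            n = n, iterations = it, loglik = tail(ll_trace, 1),
                            loglik_trace = ll_trace, tol = tol),
                       class = "hw_npmle"))
    }
  }
  abort(sprintf("Turnbull EM did not converge in %d iterations (last mass change %.3g).",
                as.integer(max_iter), delta))
}

#' Evaluate the NPMLE cumulative distribution function
#'
#' Right-continuous CDF: the cumulative mass of supports lying wholly at or
#' before `t`. The NPMLE is undefined strictly inside a support interval; such
#' evaluation points return `NA` with a warning reporting the interval.
#'
#' @param curve an `hw_npmle` object.
#' @param t evaluation times (days).
#' @return Numeric vector of probabilities.
#' @export
npmle_cdf <- function(curve, t) {
  sup <- curve$support
  vapply(t, function(ti) {
    inside <- sup$q < ti & ti < sup$p & is.finite(sup$p)
    if (any(inside)) {
      j <- which(inside)[1]
      warn(sprintf("CDF undefined inside support interval (%g, %g]; returning NA.",
                   sup$q[j], sup$p[j]))
      return(NA_real_)
    }
    sum(sup$mass[sup$p <= ti])
  }, numeric(1))
}

#' @export
print.hw_npmle <- function(x, ...) {
  cat(sprintf("Turnbull NPMLE: %d observations, %d support interval(s), %d EM iteration(s)\n",
              x$n, nrow(x$support), x$iterations))
  print(x$support)
  invisible(x)
}

#' Tidy a Turnbull NPMLE
#'
#' @param x an `hw_npmle` object.
#' @param ... unused.
#' @return Tibble with the support bounds, masses and the CDF at each
#'   support's right endpoint.
#' @exportS3Method generics::tidy
tidy.hw_npmle <- function(x, ...) {
  x$support %>%
    mutate(cdf = cumsum(.data$mass))
}

#' Surgery curves by group
#'
#' Fits a Turnbull NPMLE per group and evaluates the cumulative probability
#' of surgery at the requested days since admission.
#'
#' @param data tibble with `lower`/`upper` interval bounds (see
#'   [build_intervals()]) and a grouping column.
#' @param group name of the grouping column (e.g. `"demand"`).
#' @param times evaluation days (default `c(2, 4, 7)`).
#' @return Tibble with `group`, `t`, `cdf` and the group size `n`.
#' @export
surgery_curves <- function(data, group = "demand", times = c(2, 4, 7)) {
  data %>%
    mutate(.g = .data[[group]]) %>%
    group_by(.data$.g) %>%
    dplyr::group_modify(function(d, key) {
      fit <- fit_npmle(d$lower, d$upper)
      tibble(t = times, cdf = npmle_cdf(fit, times), n = nrow(d))
    }) %>%
    ungroup() %>%
    rename(!!group := ".g")
}

#' Plot NPMLE surgery curves
#'
#' Step plot of the cumulative probability of surgery by time since
#' admission, one line per group.
#'
#' @param curves output of [surgery_curves()] evaluated on a day grid, or a
#'   single `hw_npmle` via [autoplot.hw_npmle()].
#' @param group the grouping column name.
#' @return A ggplot object.
#' @export
plot_surgery_curves <- function(curves, group = "demand") {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$t, y = .data$cdf,
                               colour = .data[[group]])) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Days since admission",
                  y = "Cumulative probability of surgery",
                  colour = group) +
    ggplot2::theme_minimal()
}

#' Autoplot a Turnbull NPMLE
#'
#' @param object an `hw_npmle` object.
#' @param ... unused.
#' @return A ggplot step plot of the CDF at the support right endpoints.
#' @exportS3Method ggplot2::autoplot
autoplot.hw_npmle <- function(object, ...) {
  d <- tidy(object) %>% filter(is.finite(.data$p))
  ggplot2::ggplot(bind_rows(tibble(p = 0, cdf = 0), d[c("p", "cdf")]),
                  ggplot2::aes(x = .data$p, y = .data$cdf)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Days since admission",
                  y = "Cumulative probability of surgery") +
    ggplot2::theme_minimal()
}
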