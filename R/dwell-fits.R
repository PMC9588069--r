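#' Biexponential fit of a dwell-time survival curve
#'
#' Fits `S(t) = a * exp(-k1 * t) + b * exp(-k2 * t)` by nonlinear least
#' squares with `k1 > k2 > 0` and `a, b >= 0`. `k1` is interpreted as the
#' off rate of fast, non-specific interactions and `k2` as the off rate of
#' slow, specific binding; the residence time is `tau = 1 / k2`. Rates are
#' reported as positive magnitudes.
#'
#' Initialization is a deterministic multi-start over a log-spaced rate grid
#' between `1 / max(t)` and `1 / (2 * dt)` (no RNG, so the fit is
#' reproducible); the best converged start by residual sum of squares wins.
#' As in [fit_power_law()], time points backed by fewer than `min_events`
#' surviving dwells are excluded: the deep tail of an empirical survival
#' curve is a staircase of single-event atoms that otherwise biases the
#' slowest rate (curves built directly from model values, with large
#' `n_at_risk`, are unaffected).
#'
#' @param curve a `survival_curve` with at least 6 distinct time points.
#' @param min_events tail guard: minimum `n_at_risk` per fitted point.
#' @return an object of class `biexp_fit`: list with `a`, `b`, `k1`, `k2`,
#'   `tau`, asymptotic standard errors `se` (named vector), `vcov`, `rss`,
#'   `n` (events behind the curve), `frame_interval`, and placeholders
#'   `k_bias`, `k2_true`, `tau_corrected` filled by [correct_kbias()].
#'   A degeneracy warning is attached (attribute `degenerate`) when
#'   `k1 / k2 < 3`.
#' @export
fit_biexponential <- function(curve, min_events = 10L) {
  stopifnot(inherits(curve, "survival_curve"))
  use <- curve$n_at_risk >= min_events
  if (sum(use) < 6) stop("need at least 6 distinct time points")
  t <- curve$t_s[use]
  y <- curve$survival[use]
  grid <- rate_grid(curve)
  starts <- list()
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      if (grid[i] > grid[j] * 2) {
        starts[[length(starts) + 1L]] <-
          list(a = 0.5, b = 0.5, k1 = grid[i], k2 = grid[j])
      }
    }
  }
  best <- multistart_nls(
    y ~ a * exp(-k1 * t) + b * exp(-k2 * t),
    data = list(t = t, y = y), starts = starts,
    lower = c(a = 0, b = 0, k1 = 1e-9, k2 = 1e-9)
  )
  if (is.null(best)) {
    stop("biexponential fit failed to converge from any of ",
         length(starts), " starts (n = ", nrow(curve), " points, t range ",
         signif(min(t), 3), "-", signif(max(t), 3), " s)")
  }
  p <- stats::coef(best)
  v <- stats::vcov(best)
  # enforce the k1 > k2 labelling by swapping components if needed
  if (p[["k1"]] < p[["k2"]]) {
    p <- p[c("b", "a", "k2", "k1")]
    names(p) <- c("a", "b", "k1", "k2")
    v <- v[c("b", "a", "k2", "k1"), c("b", "a", "k2", "k1")]
    dimnames(v) <- list(names(p), names(p))
  }
  se <- sqrt(diag(v))
  out <- structure(list(
    a = p[["a"]], b = p[["b"]], k1 = p[["k1"]], k2 = p[["k2"]],
    tau = 1 / p[["k2"]],
    se = se, vcov = v, rss = sum(stats::resid(best)^2),
    n = attr(curve, "n", exact = TRUE),
    frame_interval = attr(curve, "frame_interval", exact = TRUE),
    k_bias = NA_real_, k2_true = NA_real_, tau_corrected = NA_real_,
    tau_corrected_se = NA_real_
  ), class = "biexp_fit")
  if (p[["k1"]] / p[["k2"]] < 3) {
    attr(out, "degenerate") <- TRUE
    warning("biexponential components poorly separated (k1/k2 = ",
            signif(p[["k1"]] / p[["k2"]], 3), " < 3)")
  }
  out
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("<biexp_fit> S(t) = a e^(-k1 t) + b e^(-k2 t)\n")
  cat(sprintf("  a = %.3g, k1 = %.4g /s; b = %.3g, k2 = %.4g /s\n",
              x$a, x$k1, x$b, x$k2))
  cat(sprintf("  tau = 1/k2 = %.4g s\n", x$tau))
  if (!is.na(x$tau_corrected)) {
    cat(sprintf("  k_bias = %.4g /s -> k2_true = %.4g /s, tau_corrected = %.4g s\n",
                x$k_bias, x$k2_true, x$tau_corrected))
  }
  invisible(x)
}

# deterministic log-spaced initialization grid between 1/(max dwell) and
# 1/(2 dt); falls back to the observed time range when dt is unknown.
rate_grid <- function(curve, n = 6L) {
  dt <- attr(curve, "frame_interval", exact = TRUE)
  t_max <- max(curve$t_s)
  fast <- if (!is.null(dt) && is.finite(dt)) 1 / (2 * dt) else 1 / (2 * min(curve$t_s))
  slow <- 1 / t_max
  exp(seq(log(slow), log(fast), length.out = n))
}

multistart_nls <- function(formula, data, starts, lower, upper = NULL) {
  best <- NULL
  best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }
  best
}

#' Photobleaching correction of the slow off rate (H2B rate bias)
#'
#' The slow rate `k2` of a dwell-time fit is inflated by photobleaching.
#' Histone H2B, taken as stably bound on the acquisition timescale, is
#' imaged at the same frame rate; the slow rate of its biexponential fit
#' estimates the bleaching bias: `k_bias = k2_H2B`. The corrected rate and
#' residence time are `k2_true = k2 - k_bias` and
#' `tau_corrected = 1 / k2_true`. Uncertainty is propagated in quadrature
#' from the two asymptotic standard errors.
#'
#' @param fit_tf `biexp_fit` of the factor of interest.
#' @param fit_h2b `biexp_fit` of H2B at the same frame interval (mismatched
#'   intervals are rejected, since bleaching per frame depends on it).
#' @return `fit_tf` with `k_bias`, `k2_true`, `tau_corrected` and
#'   `tau_corrected_se` populated.
#' @export
correct_kbias <- function(fit_tf, fit_h2b) {
  stopifnot(inherits(fit_tf, "biexp_fit"), inherits(fit_h2b, "biexp_fit"))
  dt1 <- fit_tf$frame_interval
  dt2 <- fit_h2b$frame_interval
  if (!is.null(dt1) && !is.null(dt2) && !isTRUE(all.equal(dt1, dt2))) {
    stop("frame intervals differ (", dt1, " vs ", dt2,
         " s); k_bias must come from H2B acquired at the same frame rate")
  }
  k_bias <- fit_h2b$k2
  k2_true <- fit_tf$k2 - k_bias
  if (k2_true <= 0) {
    stop("k2 (", signif(fit_tf$k2, 4), ") <= k_bias (", signif(k_bias, 4),
         "): dwell indistinguishable from photobleaching")
  }
  se <- sqrt(fit_tf$se[["k2"]]^2 + fit_h2b$se[["k2"]]^2)
  fit_tf$k_bias <- k_bias
  fit_tf$k2_true <- k2_true
  fit_tf$tau_corrected <- 1 / k2_true
  fit_tf$tau_corrected_se <- se / k2_true^2   # delta method on 1/x
  fit_tf
}

#' Triple-exponential fit of an H2B survival curve
#'
#' Fits `S(t) = f1 e^(-g1 t) + f2 e^(-g2 t) + f3 e^(-g3 t)` with
#' `g1 > g2 > g3 > 0`, `f1 + f2 + f3 = 1` and `f_i >= 0`. The two faster
#' rates reflect histone dynamics; the slowest, `gamma3`, is the
#' photobleaching rate used by [correct_survival_powerlaw()]. The
#' fractions are kept on the simplex by a stick-breaking parametrization;
#' initialization is a deterministic multi-start over log-spaced rate
#' triples. The `min_events` tail guard works as in [fit_biexponential()].
#'
#' For empirical curves built from dwell times with a minimum-length
#' filter, the observed survival is left-truncated: at the smallest
#' retained dwell it equals 1 by construction, where a mixture anchored at
#' t = 0 would need amplitudes summing to more than 1 (each component
#' inflated by `exp(gamma_i * t_min)`). The simplex constraint then biases
#' the rates. Setting `t_origin` to the first fitted time point fits
#' `S(t) = sum f_i exp(-gamma_i (t - t_origin))`, the exact model for a
#' left-truncated exponential mixture; the rates keep their meaning and the
#' fractions describe the composition at `t_origin`. The default
#' `t_origin = 0` is the model in its customary form, appropriate for
#' curves that genuinely start at t = 0.
#'
#' @param curve a `survival_curve` with at least 9 distinct time points.
#' @param min_events tail guard: minimum `n_at_risk` per fitted point.
#' @param t_origin time anchor of the mixture (seconds); use
#'   `t_origin = "first"` for the first fitted time point.
#' @return an object of class `triexp_fit`: list with `f` (length-3
#'   fractions), `gamma` (length-3 rates, decreasing), `gamma3`, `se`
#'   (named; fraction standard errors by the delta method), `rss`, `n`,
#'   `frame_interval`. A degeneracy warning is attached when adjacent rates
#'   are within a factor of 2.
#' @export
fit_triple_exponential <- function(curve, min_events = 10L, t_origin = 0) {
  stopifnot(inherits(curve, "survival_curve"))
  use <- curve$n_at_risk >= min_events
  if (sum(use) < 9) stop("need at least 9 distinct time points")
  if (identical(t_origin, "first")) t_origin <- min(curve$t_s[use])
  t <- curve$t_s[use] - t_origin
  y <- curve$survival[use]
  grid <- rate_grid(curve, n = 5L)
  starts <- list()
  ng <- length(grid)
  for (i in seq_len(ng)) for (j in seq_len(ng)) for (k in seq_len(ng)) {
    if (grid[i] > 2 * grid[j] && grid[j] > 2 * grid[k]) {
      starts[[length(starts) + 1L]] <- list(
        u1 = 1 / 3, u2 = 0.5, g1 = grid[i], g2 = grid[j], g3 = grid[k]
      )
    }
  }
  # stick-breaking parameters keep (f1, f2, f3) on the simplex:
  # f1 = u1, f2 = (1 - u1) u2, f3 = (1 - u1)(1 - u2).
  # nls.lm is driven directly (not via nlsLM) because near-degenerate
  # optima (collapsed rates) make the post-hoc nlsModel refuse the fit.
  triexp_model <- function(p) {
    p[["u1"]] * exp(-p[["g1"]] * t) +
      (1 - p[["u1"]]) * p[["u2"]] * exp(-p[["g2"]] * t) +
      (1 - p[["u1"]]) * (1 - p[["u2"]]) * exp(-p[["g3"]] * t)
  }
  best <- NULL
  best_dev <- Inf
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = unlist(st), fn = function(p) y - triexp_model(p),
        lower = c(u1 = 0, u2 = 0, g1 = 1e-9, g2 = 1e-9, g3 = 1e-9),
        upper = c(u1 = 1, u2 = 1, g1 = Inf, g2 = Inf, g3 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$info %in% 1:4) next
    if (fit$deviance < best_dev) {
      best <- fit
      best_dev <- fit$deviance
    }
  }
  if (is.null(best)) {
    stop("triple-exponential fit failed to converge from any of ",
         length(starts), " starts")
  }
  p <- best$par
  u1 <- p[["u1"]]
  u2 <- p[["u2"]]
  f <- c(u1, (1 - u1) * u2, (1 - u1) * (1 - u2))
  g <- c(p[["g1"]], p[["g2"]], p[["g3"]])
  # asymptotic covariance from the analytic Jacobian at the optimum;
  # near-singular (degenerate) fits get NA standard errors
  e1 <- exp(-g[1] * t); e2 <- exp(-g[2] * t); e3 <- exp(-g[3] * t)
  jac <- cbind(
    u1 = e1 - u2 * e2 - (1 - u2) * e3,
    u2 = (1 - u1) * (e2 - e3),
    g1 = -u1 * t * e1,
    g2 = -(1 - u1) * u2 * t * e2,
    g3 = -(1 - u1) * (1 - u2) * t * e3
  )
  sigma2 <- best_dev / max(length(t) - 5L, 1L)
  v <- tryCatch(sigma2 * solve(crossprod(jac)),
                error = function(e) matrix(NA_real_, 5, 5,
                                           dimnames = list(colnames(jac),
                                                           colnames(jac))))
  se_g <- sqrt(diag(v))[c("g1", "g2", "g3")]
  grad_f <- rbind(c(1, 0), c(-u2, 1 - u1), c(-(1 - u2), -(1 - u1)))
  vu <- v[c("u1", "u2"), c("u1", "u2")]
  se_f <- sqrt(pmax(diag(grad_f %*% vu %*% t(grad_f)), 0))
  ord <- order(g, decreasing = TRUE)
  out <- structure(list(
    f = f[ord], gamma = g[ord], gamma3 = g[ord][3],
    se = c(f = unname(se_f[ord]), gamma = unname(se_g[ord])),
    rss = best_dev,
    n = attr(curve, "n", exact = TRUE),
    frame_interval = attr(curve, "frame_interval", exact = TRUE)
  ), class = "triexp_fit")
  if (any(g[ord][-3] / g[ord][-1] < 2)) {
    attr(out, "degenerate") <- TRUE
    warning("triple-exponential rates poorly separated (adjacent ratio < 2)")
  }
  out
}

#' @export
print.triexp_fit <- function(x, ...) {
  cat("<triexp_fit> S(t) = sum_i f_i e^(-gamma_i t)\n")
  cat(sprintf("  f = (%.3g, %.3g, %.3g)\n", x$f[1], x$f[2], x$f[3]))
  cat(sprintf("  gamma = (%.4g, %.4g, %.4g) /s; bleaching gamma3 = %.4g /s\n",
              x$gamma[1], x$gamma[2], x$gamma[3], x$gamma3))
  invisible(x)
}

#' Power-law fit of a (bleach-corrected) survival curve
#'
#' Fits `S(t) = A * t^(-beta)` by linear least squares of `log S` on
#' `log t`. `beta` measures the skewness of the underlying continuum of
#' binding affinities: smaller `beta`, heavier tail, longer-lived binding.
#' To guard against tail noise, the fit is restricted to time points with
#' at least `min_events` surviving dwells; points with non-positive
#' survival after correction are excluded (and counted in the result).
#'
#' @param curve a `survival_curve`, typically after
#'   [correct_survival_powerlaw()]; all times must be > 0.
#' @param min_events tail guard: minimum `n_at_risk` per fitted point.
#' @return an object of class `powerlaw_fit`: list with `A`, `beta`,
#'   standard errors (`A_se` by the delta method), `fit_range` (time span
#'   actually fitted), `n_points`, `n_excluded`.
#' @export
fit_power_law <- function(curve, min_events = 10L) {
  stopifnot(inherits(curve, "survival_curve"))
  if (any(curve$t_s <= 0)) stop("power-law fit requires all times > 0")
  use <- curve$n_at_risk >= min_events
  nonpos <- use & curve$survival <= 0
  if (any(nonpos)) {
    message(sum(nonpos), " point(s) with non-positive survival excluded ",
            "from the power-law fit")
    use <- use & !nonpos
  }
  if (sum(use) < 5) stop("need at least 5 usable points for the power-law fit")
  lt <- log(curve$t_s[use])
  ls <- log(curve$survival[use])
  fit <- stats::lm(ls ~ lt)
  co <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))  # perfect-fit warning
  A <- exp(co[[1]])
  structure(list(
    A = A, beta = -co[[2]],
    A_se = A * se[[1]], beta_se = se[[2]],
    fit_range = range(curve$t_s[use]),
    n_points = sum(use), n_excluded = sum(nonpos)
  ), class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("<powerlaw_fit> S(t) = A t^(-beta)\n")
  cat(sprintf("  A = %.4g +/- %.2g, beta = %.4g +/- %.2g\n",
              x$A, x$A_se, x$beta, x$beta_se))
  cat(sprintf("  fitted %d points over %.3g-%.3g s (%d excluded)\n",
              x$n_points, x$fit_range[1], x$fit_range[2], x$n_excluded))
  invisible(x)
}
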