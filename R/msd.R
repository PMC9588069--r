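#' Time-averaged MSD of a single trajectory
#'
#' Computes the overlapping-window (time-averaged) mean squared displacement
#' over lags `1..max_lag`:
#' `MSD(n dt) = mean_i ||r(i + n) - r(i)||^2` over all start indices `i`
#' across the entire length of the track.
#'
#' @param traj a single-track [spt_tracks()] table, or a numeric position
#'   matrix (rows = frames, columns = coordinates in um).
#' @param max_lag largest lag in frames; must be < track length.
#' @param frame_interval frame interval, seconds (taken from `traj` when it
#'   is an `spt_tracks` table).
#' @return a tibble of class `msd_curve` with columns `lag_s`, `msd_um2`,
#'   `n_pairs`, `sem` and `ci95` (95% half-width, 1.96 * SEM over pairs).
#' @export
compute_msd <- function(traj, max_lag, frame_interval = NULL) {
  if (inherits(traj, "spt_tracks")) {
    ids <- unique(traj$track)
    if (length(ids) != 1L) {
      stop("compute_msd() expects a single trajectory; got ", length(ids),
           " (use aggregate_msd() for ensembles)")
    }
    frame_interval <- frame_interval %||% frame_interval(traj)
    m <- as.matrix(traj[pos_cols(track_dims(traj))])
    label <- as.character(ids)
  } else {
    m <- as.matrix(traj)
    label <- "<matrix>"
  }
  if (is.null(frame_interval)) frame_interval <- 1
  n <- nrow(m)
  if (max_lag < 1 || max_lag >= n) {
    stop("max_lag (", max_lag, ") must be in [1, length-1] for track ",
         label, " of length ", n)
  }
  msd <- numeric(max_lag)
  sem <- numeric(max_lag)
  n_pairs <- integer(max_lag)
  for (lag in seq_len(max_lag)) {
    d <- m[(lag + 1L):n, , drop = FALSE] - m[1:(n - lag), , drop = FALSE]
    sq <- rowSums(d^2)
    msd[lag] <- mean(sq)
    n_pairs[lag] <- length(sq)
    sem[lag] <- if (length(sq) > 1) stats::sd(sq) / sqrt(length(sq)) else NA_real_
  }
  new_msd_curve(lag_s = seq_len(max_lag) * frame_interval, msd_um2 = msd,
                n_pairs = n_pairs, sem = sem, n_trajectories = 1L)
}

new_msd_curve <- function(lag_s, msd_um2, n_pairs, sem, n_trajectories) {
  out <- tibble::tibble(lag_s = lag_s, msd_um2 = msd_um2,
                        n_pairs = n_pairs, sem = sem, ci95 = 1.96 * sem)
  structure(out, class = c("msd_curve", class(out)),
            n_trajectories = n_trajectories)
}

#' Ensemble-averaged MSD curve
#'
#' Averages the per-trajectory time-averaged MSD over all trajectories at
#' each of the first `n_lags` lags (the default 9 displacements correspond
#' to the first 10 frames of each trajectory, matching the usual minimum
#' track-length filter of 10 frames). The dispersion at each lag is the
#' SEM across trajectories; `ci95` is the 1.96 * SEM half-width.
#'
#' @param tracks an [spt_tracks()] table; every track must have at least
#'   `n_lags + 1` frames (apply [filter_min_length()] first).
#' @param n_lags number of lags to average (default 9).
#' @return an `msd_curve` tibble (`lag_s`, `msd_um2`, `n_pairs`, `sem`,
#'   `ci95`) with attribute `n_trajectories`; `n_pairs` is the total pair
#'   count summed over trajectories. With a single track the SEM across
#'   trajectories is undefined and reported as `NA`.
#' @export
aggregate_msd <- function(tracks, n_lags = 9L) {
  stopifnot(inherits(tracks, "spt_tracks"))
  mats <- track_matrices(tracks)
  if (length(mats) == 0) stop("no trajectories to aggregate")
  short <- vapply(mats, nrow, integer(1)) < n_lags + 1L
  if (any(short)) {
    stop(sum(short), " track(s) shorter than n_lags + 1 = ", n_lags + 1L,
         " frames; apply filter_min_length() first")
  }
  dt <- frame_interval(tracks)
  per_track <- matrix(NA_real_, nrow = length(mats), ncol = n_lags)
  pairs <- matrix(0L, nrow = length(mats), ncol = n_lags)
  for (i in seq_along(mats)) {
    cur <- compute_msd(mats[[i]], max_lag = n_lags, frame_interval = dt)
    per_track[i, ] <- cur$msd_um2
    pairs[i, ] <- cur$n_pairs
  }
  m <- colMeans(per_track)
  n_traj <- nrow(per_track)
  sem <- if (n_traj > 1) apply(per_track, 2L, stats::sd) / sqrt(n_traj) else
    rep(NA_real_, n_lags)
  out <- new_msd_curve(lag_s = seq_len(n_lags) * dt, msd_um2 = m,
                       n_pairs = colSums(pairs), sem = sem,
                       n_trajectories = n_traj)
  attr(out, "per_track_msd") <- per_track
  out
}

#' Fit the anomalous diffusion model to an MSD curve
#'
#' Fits `MSD = gamma * D * t^alpha` with `gamma = 2 * dims` held fixed, by
#' linear least squares in log-log space:
#' `log MSD = log(gamma * D) + alpha * log t`. When the curve carries
#' per-lag SEMs, lags are weighted by the inverse squared relative SEM
#' `(msd / sem)^2`; otherwise the fit is unweighted. 95% confidence
#' intervals come from the linear-fit covariance (t distribution), with the
#' interval for `D` obtained by exponentiating the intercept interval.
#'
#' @param curve an `msd_curve` (at least 3 lags, all MSD values > 0).
#' @param dims spatial dimensionality (2 or 3): `gamma = 2 * dims`.
#' @param weighted use SEM-based weights when available.
#' @return an object of class `diffusion_fit`: a list with `D` (um^2/s),
#'   `alpha`, `gamma`, their standard errors and 95% CIs, and
#'   `n_trajectories`.
#' @export
fit_anomalous <- function(curve, dims, weighted = TRUE) {
  stopifnot(dims %in% c(2L, 3L))
  if (nrow(curve) < 3) stop("need at least 3 lags to fit (D, alpha)")
  if (any(curve$msd_um2 <= 0)) {
    stop("all MSD values must be > 0 for the log-log fit")
  }
  gamma <- 2 * dims
  df <- data.frame(x = log(curve$lag_s), y = log(curve$msd_um2))
  w <- NULL
  if (weighted && !is.null(curve$sem) && all(is.finite(curve$sem)) &&
      all(curve$sem > 0)) {
    w <- (curve$msd_um2 / curve$sem)^2
  }
  fit <- if (is.null(w)) stats::lm(y ~ x, data = df) else
    stats::lm(y ~ x, data = df, weights = w)
  co <- stats::coef(fit)
  if (anyNA(co)) stop("singular design in MSD fit")
  # suppressWarnings: summary.lm warns on exactly model-generated curves
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  D <- exp(co[[1]]) / gamma
  structure(list(
    D = D, alpha = co[[2]], gamma = gamma,
    D_se = D * se[[1]],                 # delta method on the intercept
    alpha_se = se[[2]],
    D_ci = exp(ci[1, ]) / gamma,
    alpha_ci = ci[2, ],
    n_lags = nrow(curve),
    n_trajectories = attr(curve, "n_trajectories", exact = TRUE) %||% NA_integer_
  ), class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("<diffusion_fit> MSD = gamma * D * t^alpha, gamma =", x$gamma, "\n")
  cat(sprintf("  D     = %.4g um^2/s  [95%% CI %.4g, %.4g]\n",
              x$D, x$D_ci[1], x$D_ci[2]))
  cat(sprintf("  alpha = %.4g         [95%% CI %.4g, %.4g]\n",
              x$alpha, x$alpha_ci[1], x$alpha_ci[2]))
  cat(sprintf("  %s lags, %s trajectories\n", x$n_lags, x$n_trajectories))
  invisible(x)
}

#' Split trajectories into subdiffusive and superdiffusive populations
#'
#' Fits the anomalous diffusion model to each trajectory individually over
#' lags `1..n_lags` (unweighted log-log fit, the same window as the
#' aggregate curve so per-track and aggregate alphas are comparable) and
#' labels tracks with `alpha <= 1` subdiffusive and `alpha > 1`
#' superdiffusive (the tie at exactly 1 — measure zero — goes to
#' subdiffusive). Each subset is then refit in aggregate.
#'
#' @param tracks an [spt_tracks()] table passing the min-length filter.
#' @param dims spatial dimensionality.
#' @param n_lags per-track fit window (default 9).
#' @return a list of class `alpha_split`: `alpha_table` (tibble with one
#'   row per input track: `track`, `alpha`, `D`, `class`, `status`),
#'   `subdiffusive` / `superdiffusive` (`spt_tracks` subsets),
#'   `fit_sub` / `fit_super` (aggregate `diffusion_fit`s, `NULL` when a
#'   subset has no tracks). Tracks whose individual fit fails are excluded
#'   from both subsets but retained in `alpha_table` with a `status`
#'   explaining the exclusion.
#' @export
classify_by_alpha <- function(tracks, dims = track_dims(tracks), n_lags = 9L) {
  stopifnot(inherits(tracks, "spt_tracks"))
  mats <- track_matrices(tracks)
  dt <- frame_interval(tracks)
  ids <- unique(tracks$track)
  res <- vector("list", length(mats))
  for (i in seq_along(mats)) {
    fit <- tryCatch({
      curve <- compute_msd(mats[[i]], max_lag = n_lags, frame_interval = dt)
      f <- fit_anomalous(curve, dims = dims, weighted = FALSE)
      list(alpha = f$alpha, D = f$D, status = "ok")
    }, error = function(e) list(alpha = NA_real_, D = NA_real_,
                                status = conditionMessage(e)))
    res[[i]] <- fit
  }
  alpha <- vapply(res, `[[`, numeric(1), "alpha")
  tab <- tibble::tibble(
    track = ids,
    alpha = alpha,
    D = vapply(res, `[[`, numeric(1), "D"),
    class = ifelse(is.na(alpha), NA_character_,
                   ifelse(alpha <= 1, "subdiffusive", "superdiffusive")),
    status = vapply(res, `[[`, character(1), "status")
  )
  n_failed <- sum(tab$status != "ok")
  if (n_failed > 0) {
    message(n_failed, " track(s) excluded from the alpha split ",
            "(per-track fit failure); see alpha_table$status")
  }
  subset_tracks <- function(cls) {
    keep <- tab$track[!is.na(tab$class) & tab$class == cls]
    out <- tracks[tracks$track %in% keep, , drop = FALSE]
    spt_tracks(out, dt, track_dims(tracks))
  }
  sub <- subset_tracks("subdiffusive")
  super <- subset_tracks("superdiffusive")
  refit <- function(tr) {
    if (length(unique(tr$track)) == 0) return(NULL)
    fit_anomalous(aggregate_msd(tr, n_lags = n_lags), dims = dims)
  }
  structure(list(alpha_table = tab,
                 subdiffusive = sub, superdiffusive = super,
                 fit_sub = refit(sub), fit_super = refit(super)),
            class = "alpha_split")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
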