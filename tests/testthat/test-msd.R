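test_that("compute_msd matches the brute-force double-loop oracle", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    dims <- sample(2:3, 1)
    m <- matrix(rnorm(n * dims), ncol = dims)
    curve <- compute_msd(m, max_lag = n - 1)
    expect_equal(curve$msd_um2, msd_brute(m, n - 1), tolerance = 1e-12)
    expect_equal(curve$n_pairs, (n - 1):1)
  }
})

test_that("closed-form MSD cases: stationary and ballistic tracks", {
  still <- compute_msd(matrix(1.5, nrow = 8, ncol = 2), max_lag = 5)
  expect_true(all(still$msd_um2 == 0))
  ballistic <- compute_msd(matrix(c(0, 1, 2, 3), ncol = 1), max_lag = 3)
  expect_equal(ballistic$msd_um2, c(1, 4, 9))
  expect_error(compute_msd(matrix(0, 4, 2), max_lag = 4), "max_lag")
})

test_that("aggregate curve is the mean of per-track curves with SEM across tracks", {
  tracks <- mk_fbm_tracks(6, 15, D = 0.2, alpha = 1, seed = 44)
  agg <- aggregate_msd(tracks, n_lags = 9)
  per <- attr(agg, "per_track_msd")
  expect_equal(agg$msd_um2, colMeans(per))
  expect_equal(agg$sem, apply(per, 2, sd) / sqrt(6))
  expect_equal(agg$ci95, 1.96 * agg$sem)
  # single track: aggregate equals its own curve, dispersion undefined
  one <- spt_tracks(as.data.frame(tracks)[tracks$track == 1, ],
                    frame_interval = 0.04, dims = 3)
  agg1 <- aggregate_msd(one, n_lags = 9)
  expect_equal(agg1$msd_um2, compute_msd(one, 9)$msd_um2)
  expect_true(all(is.na(agg1$sem)))
})

test_that("aggregate_msd insists on the min-length precondition", {
  short <- mk_fbm_tracks(3, 8, 0.2, 1, seed = 4)
  expect_error(aggregate_msd(short, n_lags = 9), "filter_min_length")
})

test_that("confidence width shrinks as 1/sqrt(n)", {
  tracks <- mk_fbm_tracks(2000, 11, D = 0.25, alpha = 1, seed = 55)
  half <- spt_tracks(as.data.frame(tracks)[tracks$track <= 1000, ],
                     frame_interval = 0.04, dims = 3)
  ci_full <- mean(aggregate_msd(tracks, 9)$ci95)
  ci_half <- mean(aggregate_msd(half, 9)$ci95)
  expect_rel_error(ci_half / ci_full, sqrt(2), 0.10)
})

test_that("noiseless model curves invert exactly", {
  lags <- (1:9) * 0.04
  mk_curve <- function(msd) {
    structure(tibble::tibble(lag_s = lags, msd_um2 = msd,
                             n_pairs = 100L, sem = NA_real_, ci95 = NA_real_),
              class = c("msd_curve", class(tibble::tibble())),
              n_trajectories = 1L)
  }
  f1 <- fit_anomalous(mk_curve(6 * 0.3 * lags), dims = 3)
  expect_equal(f1$D, 0.3, tolerance = 1e-10)
  expect_equal(f1$alpha, 1, tolerance = 1e-10)
  f2 <- fit_anomalous(mk_curve(4 * 0.1 * lags^0.7), dims = 2)
  expect_equal(f2$D, 0.1, tolerance = 1e-10)
  expect_equal(f2$alpha, 0.7, tolerance = 1e-10)
  expect_error(fit_anomalous(mk_curve(c(-1, rep(1, 8))), dims = 2), "> 0")
})

test_that("coordinate scaling and time rescaling act on (D, alpha) as they must", {
  tracks <- mk_fbm_tracks(40, 15, 0.2, 0.9, seed = 66)
  fit <- fit_anomalous(aggregate_msd(tracks, 9), dims = 3)
  scaled_df <- as.data.frame(tracks)
  for (cl in c("x_um", "y_um", "z_um")) scaled_df[[cl]] <- 2 * scaled_df[[cl]]
  scaled <- spt_tracks(scaled_df, frame_interval = 0.04, dims = 3)
  fit_scaled <- fit_anomalous(aggregate_msd(scaled, 9), dims = 3)
  expect_equal(fit_scaled$alpha, fit$alpha, tolerance = 1e-9)
  expect_equal(fit_scaled$D, 4 * fit$D, tolerance = 1e-9)
  # doubling dt: alpha invariant, MSD values preserved at matching lags
  slow <- spt_tracks(as.data.frame(tracks), frame_interval = 0.08, dims = 3)
  agg_fast <- aggregate_msd(tracks, 9)
  agg_slow <- aggregate_msd(slow, 9)
  expect_equal(agg_slow$msd_um2, agg_fast$msd_um2)
  expect_equal(agg_slow$lag_s, 2 * agg_fast$lag_s)
  expect_equal(fit_anomalous(agg_slow, 3)$alpha, fit_anomalous(agg_fast, 3)$alpha,
               tolerance = 1e-9)
})

test_that("simulated Brownian ensemble recovers D from the aggregate fit", {
  tracks <- mk_fbm_tracks(500, 100, D = 0.25, alpha = 1, dt = 0.04, seed = 7)
  agg <- aggregate_msd(tracks, 9)
  expect_rel_error(agg$msd_um2[1], 6 * 0.25 * 0.04, 0.05)
  fit <- fit_anomalous(agg, dims = 3)
  expect_rel_error(fit$D, 0.25, 0.10)
  expect_lt(abs(fit$alpha - 1), 0.05)
  # cross-check the canonical log-log fit with a direct nonlinear fit
  nls_fit <- nls(msd_um2 ~ 6 * D * lag_s^alpha, data = as.data.frame(agg),
                 start = list(D = 0.1, alpha = 0.8))
  expect_rel_error(fit$D, coef(nls_fit)[["D"]], 0.05)
  expect_lt(abs(fit$alpha - coef(nls_fit)[["alpha"]]), 0.02)
})

test_that("classification separates obvious movers from stationary noise", {
  set.seed(9)
  ballistic <- cbind(x_um = seq(0, 2, length.out = 15), y_um = 0, z_um = 0)
  noisy_still <- matrix(rnorm(45, sd = 0.02), ncol = 3,
                        dimnames = list(NULL, c("x_um", "y_um", "z_um")))
  df <- rbind(tibble::tibble(track = 1L, frame = 0:14, as.data.frame(ballistic)),
              tibble::tibble(track = 2L, frame = 0:14, as.data.frame(noisy_still)))
  split_res <- classify_by_alpha(spt_tracks(df, 0.04, 3))
  tab <- split_res$alpha_table
  expect_identical(tab$class[tab$track == 1L], "superdiffusive")
  expect_identical(tab$class[tab$track == 2L], "subdiffusive")
})

test_that("a pure Brownian ensemble splits near 50/50", {
  tracks <- mk_fbm_tracks(1000, 50, D = 0.2, alpha = 1, seed = 10)
  split_res <- classify_by_alpha(tracks)
  prop_sub <- mean(split_res$alpha_table$class == "subdiffusive")
  expect_lt(abs(prop_sub - 0.5), 0.07)
})

test_that("a sub/super mixture is classified with < 10% error", {
  sub_tracks <- mk_fbm_tracks(500, 100, 0.2, 0.6, seed = 11)
  super_df <- as.data.frame(mk_fbm_tracks(500, 100, 0.2, 1.5, seed = 12))
  super_df$track <- super_df$track + 500L
  both <- spt_tracks(rbind(as.data.frame(sub_tracks), super_df), 0.04, 3)
  split_res <- classify_by_alpha(both)
  tab <- split_res$alpha_table
  truth <- ifelse(tab$track <= 500, "subdiffusive", "superdiffusive")
  expect_lt(mean(tab$class != truth), 0.10)
  expect_lt(split_res$fit_sub$alpha, 1)
  expect_gt(split_res$fit_super$alpha, 1)
})
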