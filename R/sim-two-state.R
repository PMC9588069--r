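#' Simulate two-state (bound/free) particle trajectories
#'
#' Each particle switches between a bound and a free state as a continuous-
#' time two-state Markov chain with rates `k_on` (free -> bound) and `k_off`
#' (bound -> free); the initial state is drawn from the stationary
#' distribution (`k_on / (k_on + k_off)` bound). Free episodes move as
#' fractional Brownian motion with `(D_free, alpha_free)`; bound episodes as
#' slow Brownian motion with `D_bound` (chromatin jiggle). Photobleaching
#' terminates a particle permanently: the number of observed frames is
#' geometric with per-frame survival `exp(-k_bleach * dt)`, capped at
#' `n_frames`.
#'
#' State switching is evaluated in continuous time; a frame interval that
#' straddles a switch moves with the state occupying the majority of the
#' interval. The per-frame `state` label is the latent state at the frame's
#' acquisition instant.
#'
#' One global seed feeds a per-particle substream, so increasing
#' `n_particles` extends the particle set without reshuffling existing
#' particles.
#'
#' @param config a [sim_config()].
#' @return a tibble of class `gt_tracks` with columns `particle`, `frame`
#'   (0-based), true positions `x_um`, `y_um` (`z_um` in 3D), `state`
#'   (`"bound"` or `"free"`) and `bleach_frame` (frames observed before
#'   bleaching/movie end, constant per particle). The complete list of
#'   latent state episodes (with right-censoring flags) is attached as
#'   attribute `"episodes"`; the config as `"config"`.
#' @export
simulate_two_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dt <- cfg$frame_interval
  # One particle per L'Ecuyer-CMRG substream: statistically sound splitting,
  # and adding particles never reshuffles existing ones.
  if (!exists(".Random.seed", envir = .GlobalEnv)) stats::runif(1)
  old_seed <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(cfg$seed)
  stream <- get(".Random.seed", envir = .GlobalEnv)
  p_stat_bound <- if (cfg$k_on + cfg$k_off > 0) {
    cfg$k_on / (cfg$k_on + cfg$k_off)
  } else 0
  out <- vector("list", cfg$n_particles)
  eps <- vector("list", cfg$n_particles)
  for (i in seq_len(cfg$n_particles)) {
    stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, envir = .GlobalEnv)
    n_obs <- rbleach_frames(cfg$k_bleach, dt, cfg$n_frames)
    state0 <- stats::runif(1) < p_stat_bound
    chain <- sim_state_chain(state0, cfg$k_on, cfg$k_off, n_obs, dt)
    origin <- stats::runif(cfg$dims) * cfg$box_size
    pos <- sim_switching_path(chain$step_bound, cfg, origin)
    out[[i]] <- tibble::tibble(
      particle = i, frame = 0:(n_obs - 1L),
      as.data.frame(pos),
      state = ifelse(chain$frame_bound, "bound", "free"),
      bleach_frame = n_obs
    )
    if (nrow(chain$episodes) > 0) {
      eps[[i]] <- cbind(particle = i, chain$episodes)
    }
  }
  res <- do.call(rbind, out)
  structure(res, class = c("gt_tracks", class(res)),
            config = cfg,
            episodes = tibble::as_tibble(do.call(rbind, eps)))
}

# Observed frame count before bleaching: geometric with per-frame survival
# exp(-k_bleach * dt), derived from a continuous exponential bleach time.
rbleach_frames <- function(k_bleach, dt, n_frames) {
  if (k_bleach <= 0) return(as.integer(n_frames))
  t_bleach <- stats::rexp(1, rate = k_bleach)
  min(as.integer(n_frames), as.integer(floor(t_bleach / dt)) + 1L)
}

# Continuous-time two-state chain over the observation window.
# Returns per-frame instantaneous state, per-step majority state, and the
# episode durations (censored = cut off by the window end).
sim_state_chain <- function(bound0, k_on, k_off, n_obs, dt) {
  horizon <- n_obs * dt
  t_switch <- numeric(0)  # switch times, increasing
  state_seq <- logical(0) # state entered at each episode start
  t <- 0
  bound <- bound0
  starts <- numeric(0)
  repeat {
    starts <- c(starts, t)
    state_seq <- c(state_seq, bound)
    rate <- if (bound) k_off else k_on
    dur <- if (rate > 0) stats::rexp(1, rate) else Inf
    t <- t + dur
    if (t >= horizon) break
    t_switch <- c(t_switch, t)
    bound <- !bound
  }
  ends <- c(t_switch, horizon)
  episodes <- data.frame(
    state = ifelse(state_seq, "bound", "free"),
    duration_s = ends - starts,
    censored = c(rep(FALSE, length(ends) - 1L), TRUE)
  )
  frame_times <- (0:(n_obs - 1L)) * dt
  # state at an instant: bound0 XOR (odd number of switches before t)
  n_before <- findInterval(frame_times, t_switch)
  frame_bound <- xor(bound0, n_before %% 2L == 1L)
  step_bound <- logical(max(n_obs - 1L, 0L))
  if (n_obs >= 2L) {
    # bound occupancy of [t_j, t_{j+1}) via integrated indicator
    occ <- bound_occupancy((0:(n_obs - 1L)) * dt, bound0, t_switch)
    step_bound <- diff(occ) >= dt / 2
  }
  list(frame_bound = frame_bound, step_bound = step_bound,
       episodes = episodes)
}

# Cumulative time spent bound on [0, t] for each t, given switch times.
bound_occupancy <- function(times, bound0, t_switch) {
  if (length(t_switch) == 0) {
    return(if (bound0) times else numeric(length(times)))
  }
  bounds <- c(0, t_switch)
  states <- xor(bound0, (seq_along(bounds) - 1L) %% 2L == 1L)
  seg_end <- c(t_switch, Inf)
  vapply(times, function(t) {
    dur <- pmin(seg_end, t) - bounds
    sum(dur[states & dur > 0])
  }, numeric(1))
}

# Piece together displacement increments: contiguous runs of free steps get
# an fBm segment (restarted at each switch), bound runs get Brownian steps.
sim_switching_path <- function(step_bound, cfg, origin) {
  n_obs <- length(step_bound) + 1L
  dims <- cfg$dims
  pos <- matrix(rep(origin, each = n_obs), nrow = n_obs)
  if (n_obs >= 2L) {
    dt <- cfg$frame_interval
    inc <- matrix(0, nrow = n_obs - 1L, ncol = dims)
    runs <- rle(step_bound)
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1L
    for (r in seq_along(runs$lengths)) {
      idx <- starts[r]:stops[r]
      len <- runs$lengths[r]
      if (runs$values[r]) {
        inc[idx, ] <- stats::rnorm(len * dims, sd = sqrt(2 * cfg$D_bound * dt))
      } else if (cfg$D_free > 0) {
        sd_step <- sqrt(2 * cfg$D_free * dt^cfg$alpha_free)
        if (len == 1L) {
          inc[idx, ] <- stats::rnorm(dims, sd = sd_step)
        } else {
          inc[idx, ] <- sd_step *
            sample_fgn(len, H = cfg$alpha_free / 2, n_paths = dims)
        }
      }
    }
    cum <- apply(inc, 2L, cumsum)
    if (n_obs == 2L) cum <- matrix(cum, nrow = 1L)
    pos[-1L, ] <- sweep(cum, 2L, origin, `+`)
  }
  colnames(pos) <- pos_cols(dims)
  pos
}

#' Emit a detection table from ground-truth tracks
#'
#' Applies the measurement model: independent Gaussian localization noise
#' (`loc_sigma_xy` laterally, `loc_sigma_z` axially) and a finite axial
#' detection slab — frames whose true z lies further than `axial_depth / 2`
#' from the slab centre (`box_size / 2`) are not detected. Rows are shuffled
#' within each frame so that linking cannot rely on input order.
#'
#' @param tracks a `gt_tracks` table from [simulate_two_state()].
#' @param config the [sim_config()] used to generate `tracks` (defaults to
#'   the one attached to `tracks`).
#' @param include_truth if `TRUE`, keep the generating `particle` id as an
#'   extra column (for validation against ground truth); linking ignores it.
#' @return a tibble with columns `frame`, `x_um`, `y_um` (`z_um` in 3D),
#'   ordered by frame, shuffled within frame.
#' @export
emit_detections <- function(tracks, config = attr(tracks, "config"),
                            include_truth = FALSE) {
  stopifnot(inherits(tracks, "gt_tracks"), inherits(config, "sim_config"))
  cfg <- config
  det <- flag_detected(tracks, cfg)
  det <- det[det$detected, , drop = FALSE]
  n <- nrow(det)
  if (n > 0) {
    det <- with_local_seed((cfg$seed + 1000003L) %% .Machine$integer.max, {
      det$x_um <- det$x_um + stats::rnorm(n, sd = cfg$loc_sigma_xy)
      det$y_um <- det$y_um + stats::rnorm(n, sd = cfg$loc_sigma_xy)
      if (cfg$dims == 3L && cfg$loc_sigma_z > 0) {
        det$z_um <- det$z_um + stats::rnorm(n, sd = cfg$loc_sigma_z)
      }
      det[order(det$frame, stats::runif(n)), , drop = FALSE]
    })
  }
  keep <- c("frame", pos_cols(cfg$dims), if (include_truth) "particle")
  out <- det[keep]
  # plain tibble: drop the simulator's ground-truth attributes
  for (a in setdiff(names(attributes(out)), c("names", "row.names", "class"))) {
    attr(out, a) <- NULL
  }
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname emit_detections
#' @return `flag_detected()` returns `tracks` with a logical `detected`
#'   column (inside the axial slab; in 2D every frame is detectable).
#' @export
flag_detected <- function(tracks, config = attr(tracks, "config")) {
  stopifnot(inherits(config, "sim_config"))
  if (config$dims == 3L && is.finite(config$axial_depth)) {
    centre <- config$box_size / 2
    tracks$detected <- abs(tracks$z_um - centre) <= config$axial_depth / 2
  } else {
    tracks$detected <- TRUE
  }
  tracks
}

#' Simulate bound-biased slow-acquisition tracks
#'
#' Emulates a HILO-style acquisition in which frame rates and tracking gates
#' bias detection to bound molecules: every emitted track is one bound
#' residence, observed from binding until unbinding, photobleaching, or the
#' end of the movie, whichever comes first. Track lengths in frames are
#' therefore geometric with per-frame survival
#' `exp(-(k_off + k_bleach) * dt)`. Positions jiggle as slow Brownian motion
#' (`D_bound`) plus localization noise.
#'
#' `k_off` may be a vector of component off-rates with mixture fractions
#' `f`: e.g. a fast non-specific component plus a slow specific one gives
#' the two-component decay the biexponential dwell model describes, and a
#' three-component histone-like population (fast exchange, intermediate
#' exchange, stable-but-bleaching) gives the regime of the
#' triple-exponential bleaching calibration.
#'
#' @param n_tracks number of tracks.
#' @param k_off unbinding rate(s), 1/s; scalar or a vector of component
#'   rates.
#' @param k_bleach photobleaching rate, 1/s.
#' @param f mixture fractions matching `k_off` (must sum to 1); ignored for
#'   a scalar `k_off`.
#' @param frame_interval frame interval, seconds.
#' @param D_bound bound-state diffusion coefficient, um^2/s.
#' @param loc_sigma_xy localization error sd, um.
#' @param dims dimensionality of the recorded coordinates.
#' @param n_frames_max movie length cap in frames (Inf for none).
#' @param seed integer seed.
#' @return an [spt_tracks()] table; the true per-track frame counts before
#'   capping are attached as attribute `"true_frames"`.
#' @export
simulate_bound_tracks <- function(n_tracks, k_off, k_bleach, frame_interval,
                                  D_bound = 0.002, loc_sigma_xy = 0.02,
                                  dims = 2L, n_frames_max = Inf,
                                  f = NULL, seed = 1L) {
  stopifnot(n_tracks >= 1, all(k_off >= 0), k_bleach >= 0,
            frame_interval > 0)
  if (is.null(f)) f <- rep(1 / length(k_off), length(k_off))
  stopifnot(length(f) == length(k_off), all(f >= 0),
            isTRUE(all.equal(sum(f), 1)))
  draws <- with_local_seed(seed, list(
    u_comp = stats::runif(n_tracks),
    e_end = stats::rexp(n_tracks, 1),
    noise_seed = sample.int(.Machine$integer.max - 1L, 1L)
  ))
  component <- findInterval(draws$u_comp, cumsum(f), left.open = TRUE) + 1L
  component <- pmin(component, length(k_off))
  rate <- k_off[component] + k_bleach
  t_end <- ifelse(rate > 0, draws$e_end / rate, Inf)
  n_fr <- pmin(floor(t_end / frame_interval) + 1, n_frames_max)
  n_fr <- as.integer(pmax(n_fr, 1L))
  total <- sum(n_fr)
  track <- rep(seq_len(n_tracks), n_fr)
  frame <- sequence(n_fr) - 1L
  sd_step <- sqrt(2 * D_bound * frame_interval)
  coords <- with_local_seed(draws$noise_seed, {
    m <- matrix(0, nrow = total, ncol = dims)
    origins <- matrix(stats::runif(n_tracks * dims, 0, 10), ncol = dims)
    for (d in seq_len(dims)) {
      steps <- stats::rnorm(total, sd = sd_step)
      # zero the first step of each track, cumulate within track
      first <- c(TRUE, diff(track) != 0)
      steps[first] <- 0
      cum <- cumsum(steps)
      cum <- cum - rep(cum[first], n_fr)
      m[, d] <- rep(origins[, d], n_fr) + cum +
        stats::rnorm(total, sd = loc_sigma_xy)
    }
    m
  })
  colnames(coords) <- pos_cols(dims)
  out <- spt_tracks(
    tibble::tibble(track = track, frame = frame, as.data.frame(coords)),
    frame_interval = frame_interval, dims = dims
  )
  attr(out, "true_frames") <- n_fr
  out
}
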