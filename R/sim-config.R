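#' Simulation configuration for synthetic SPT data
#'
#' Builds a validated parameter set for the two-state trajectory simulator.
#' Defaults emulate a fast 3D multifocus-microscopy (MFM) acquisition:
#' 40 ms frames, a ~3.9 um axial detection slab, and bleaching fast enough
#' that most tracks last well under 40 frames.
#'
#' @param n_particles number of particles to simulate.
#' @param n_frames maximum number of frames per particle.
#' @param frame_interval frame interval in seconds.
#' @param dims spatial dimensionality, 2 or 3.
#' @param box_size side length of the simulation box in um (per axis).
#' @param axial_depth detection slab thickness in um (3D only); particles
#'   whose true z lies outside the slab centred at `box_size / 2` are not
#'   detected in that frame. Use `Inf` for no axial gating.
#' @param D_free diffusion coefficient of the free state, um^2/s.
#' @param D_bound diffusion coefficient of the bound state, um^2/s. Bound
#'   molecules are modelled as slowly diffusing (chromatin motion), not
#'   strictly immobile.
#' @param alpha_free anomalous exponent of free motion, in (0, 2].
#' @param k_on binding rate free -> bound, 1/s.
#' @param k_off unbinding rate bound -> free, 1/s.
#' @param k_bleach photobleaching rate, 1/s; a bleached particle is gone for
#'   good (no blinking).
#' @param loc_sigma_xy lateral localization error (Gaussian sd), um.
#' @param loc_sigma_z axial localization error (Gaussian sd), um.
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_particles = 200L,
                       n_frames = 100L,
                       frame_interval = 0.04,
                       dims = 3L,
                       box_size = 8,
                       axial_depth = 3.9,
                       D_free = 0.3,
                       D_bound = 0.005,
                       alpha_free = 1,
                       k_on = 0.5,
                       k_off = 0.5,
                       k_bleach = 1.7,
                       loc_sigma_xy = 0.03,
                       loc_sigma_z = 0.06,
                       seed = 1L) {
  cfg <- list(
    n_particles = as.integer(n_particles), n_frames = as.integer(n_frames),
    frame_interval = frame_interval, dims = as.integer(dims),
    box_size = box_size, axial_depth = axial_depth,
    D_free = D_free, D_bound = D_bound, alpha_free = alpha_free,
    k_on = k_on, k_off = k_off, k_bleach = k_bleach,
    loc_sigma_xy = loc_sigma_xy, loc_sigma_z = loc_sigma_z,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' HILO-like slow-acquisition preset
#'
#' 2D acquisition at long frame intervals with detection biased towards
#' bound molecules: free molecules diffuse far between frames, so they blur
#' and fragment rather than form tracks. Defaults use the 2 Hz interval used
#' for slow, stably bound factors.
#'
#' @param frame_interval frame interval in seconds (0.1 for fast factors at
#'   10 Hz, 0.5 for slow factors at 2 Hz).
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_hilo <- function(frame_interval = 0.5, ...) {
  defaults <- list(
    n_frames = 2400L, frame_interval = frame_interval, dims = 2L,
    axial_depth = Inf, D_free = 3, D_bound = 0.002, alpha_free = 1,
    k_on = 2, k_off = 0.1, k_bleach = 0.1,
    loc_sigma_xy = 0.03, loc_sigma_z = 0
  )
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(sim_config, defaults)
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_particles >= 1L, cfg$n_frames >= 2L,
    cfg$frame_interval > 0, cfg$dims %in% c(2L, 3L),
    cfg$box_size > 0, cfg$axial_depth > 0
  )
  rates <- c(cfg$k_on, cfg$k_off, cfg$k_bleach)
  if (any(rates < 0)) stop("rates k_on, k_off, k_bleach must be >= 0")
  if (cfg$D_free < 0 || cfg$D_bound < 0) stop("diffusion coefficients must be >= 0")
  if (cfg$D_bound > cfg$D_free) stop("D_bound must not exceed D_free")
  if (cfg$alpha_free <= 0 || cfg$alpha_free > 2) {
    stop("alpha_free must lie in (0, 2]")
  }
  if (cfg$loc_sigma_xy < 0 || cfg$loc_sigma_z < 0) {
    stop("localization sigmas must be >= 0")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d particles x %d frames @ %g s, %dD, box %g um\n",
              x$n_particles, x$n_frames, x$frame_interval, x$dims, x$box_size))
  cat(sprintf("  free: D=%g um^2/s alpha=%g | bound: D=%g um^2/s\n",
              x$D_free, x$alpha_free, x$D_bound))
  cat(sprintf("  k_on=%g k_off=%g k_bleach=%g /s; sigma_xy=%g sigma_z=%g um; seed=%d\n",
              x$k_on, x$k_off, x$k_bleach, x$loc_sigma_xy, x$loc_sigma_z, x$seed))
  invisible(x)
}

#' Read / write simulator configuration files
#'
#' Flat key-value YAML mirroring the fields of [sim_config()].
#'
#' @param path file path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
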