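#' Dwell times from bound-biased tracks
#'
#' Under slow, bound-biased acquisition every detected track is taken to be
#' one binding event, so the dwell (residence) time of a track is its length
#' in frames times the frame interval. Tracks shorter than `min_frames` are
#' excluded (5 frames in the reference analysis).
#'
#' @param tracks an [spt_tracks()] table.
#' @param min_frames minimum track length in frames to qualify.
#' @param condition optional condition label carried through to outputs.
#' @return a tibble of class `dwell_set` with columns `track`, `n_frames`,
#'   `dwell_s`, and attributes `frame_interval`, `min_frames`, `condition`.
#' @export
compute_dwell_times <- function(tracks, min_frames = 5L, condition = NA_character_) {
  stopifnot(inherits(tracks, "spt_tracks"))
  dt <- frame_interval(tracks)
  len <- track_lengths(tracks)
  keep <- len >= min_frames
  out <- tibble::tibble(
    track = names(len)[keep],
    n_frames = unname(len[keep]),
    dwell_s = unname(len[keep]) * dt
  )
  structure(out, class = c("dwell_set", class(out)),
            frame_interval = dt, min_frames = as.integer(min_frames),
            condition = condition)
}

#' Empirical dwell-time survival curve (1 - CDF)
#'
#' `S(t) = (number of dwells >= t) / n`, evaluated at the sorted unique
#' dwell values. The curve starts at 1 and is non-increasing.
#'
#' @param dwells a `dwell_set`, or a bare numeric vector of dwell times in
#'   seconds (then `frame_interval` may be given explicitly).
#' @param frame_interval frame interval in seconds (metadata for
#'   downstream fits; taken from a `dwell_set` automatically).
#' @return a tibble of class `survival_curve` with columns `t_s`,
#'   `survival`, `n_at_risk` (count of dwells >= t) and attributes `n`,
#'   `frame_interval`.
#' @export
survival_curve <- function(dwells, frame_interval = NULL) {
  if (inherits(dwells, "dwell_set")) {
    frame_interval <- frame_interval %||% attr(dwells, "frame_interval")
    x <- dwells$dwell_s
  } else {
    x <- as.numeric(dwells)
  }
  if (length(x) == 0) stop("cannot build a survival curve from zero dwells")
  n <- length(x)
  t_s <- sort(unique(x))
  n_at_risk <- n - findInterval(t_s, sort(x), left.open = TRUE)
  out <- tibble::tibble(t_s = t_s, survival = n_at_risk / n,
                        n_at_risk = as.integer(n_at_risk))
  structure(out, class = c("survival_curve", class(out)),
            n = n, frame_interval = frame_interval)
}

#' Photobleaching correction by survival-curve division
#'
#' Divides a raw survival curve pointwise by the photobleaching survival
#' `exp(-gamma3 * t)`, where `gamma3` is the slowest rate of a
#' triple-exponential fit to H2B survival at the same frame rate (see
#' [fit_triple_exponential()]):
#' `S_real(t) = S(t) / exp(-gamma3 * t)`.
#' Corrected values can exceed 1 and the curve is deliberately not
#' re-monotonized; the downstream power-law fit handles it.
#'
#' @param curve a `survival_curve`.
#' @param gamma3 photobleaching rate, 1/s (>= 0; 0 is the identity).
#' @return the corrected `survival_curve` (attribute
#'   `bleach_corrected = gamma3`).
#' @export
correct_survival_powerlaw <- function(curve, gamma3) {
  stopifnot(inherits(curve, "survival_curve"), gamma3 >= 0)
  out <- curve
  out$survival <- curve$survival / exp(-gamma3 * curve$t_s)
  attr(out, "bleach_corrected") <- gamma3
  out
}
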