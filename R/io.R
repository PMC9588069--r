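#' Read and write trajectory tables
#'
#' Two CSV dialects are supported:
#' * `"native"`: columns `track,frame,x_um,y_um[,z_um]`, coordinates in um.
#' * `"mosaic"`: a Mosaic-suite-style export with columns
#'   `Trajectory,Frame,x,y[,z]`; coordinates are multiplied by
#'   `pixel_size` (um/px) when given, otherwise assumed to already be um.
#'
#' Frames must be consecutive within each track (link range 1, no gaps);
#' violations are reported as data errors.
#'
#' @param path CSV file path.
#' @param dialect `"native"` or `"mosaic"`.
#' @param frame_interval frame interval in seconds.
#' @param pixel_size um per pixel (mosaic dialect only).
#' @return `read_tracks()` returns an [spt_tracks()] table;
#'   `write_tracks()` writes the native dialect and returns `path`
#'   invisibly.
#' @export
read_tracks <- function(path, dialect = c("native", "mosaic"),
                        frame_interval = 1, pixel_size = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (dialect == "mosaic") {
    need <- c("Trajectory", "Frame", "x", "y")
    if (!all(need %in% names(df))) {
      stop("mosaic track file ", path, " lacks columns: ",
           paste(setdiff(need, names(df)), collapse = ", "),
           " (found: ", paste(names(df), collapse = ", "), ")")
    }
    scale <- if (is.null(pixel_size)) 1 else pixel_size
    out <- data.frame(track = df$Trajectory, frame = df$Frame,
                      x_um = df$x * scale, y_um = df$y * scale)
    if ("z" %in% names(df)) out$z_um <- df$z * scale
  } else {
    need <- c("track", "frame", "x_um", "y_um")
    if (!all(need %in% names(df))) {
      stop("track file ", path, " lacks columns: ",
           paste(setdiff(need, names(df)), collapse = ", "),
           " (found: ", paste(names(df), collapse = ", "), ")")
    }
    out <- df
  }
  num_cols <- setdiff(names(out), "track")
  vals <- vapply(out[num_cols],
                 function(col) suppressWarnings(as.numeric(col)),
                 numeric(nrow(out)))
  if (nrow(out) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(rowSums(!is.finite(vals)) > 0)
  if (length(bad) > 0) {
    stop("malformed row(s) in ", path, " at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out[num_cols] <- as.data.frame(vals)
  out$frame <- as.integer(out$frame)
  spt_tracks(out, frame_interval = frame_interval)
}

#' @rdname read_tracks
#' @param tracks an [spt_tracks()] table.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "spt_tracks"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# sptdyn trajectory table; coordinates in um, frames 0-based",
    sprintf("# frame_interval_s=%g dims=%d", frame_interval(tracks),
            track_dims(tracks))
  ), con)
  utils::write.csv(as.data.frame(tracks), con, row.names = FALSE)
  invisible(path)
}

#' Read and write detection tables
#'
#' Native detection CSV: columns `frame,x_um,y_um[,z_um]`, one row per
#' localization.
#'
#' @param path CSV file path.
#' @return `read_detections()` returns a tibble; `write_detections()`
#'   returns `path` invisibly.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frame", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("detection file ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$frame <- as.integer(df$frame)
  tibble::as_tibble(df)
}

#' @rdname read_detections
#' @param detections detection table.
#' @export
write_detections <- function(detections, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sptdyn detection table; coordinates in um, frames 0-based", con)
  utils::write.csv(as.data.frame(detections), con, row.names = FALSE)
  invisible(path)
}

#' Analysis parameter set
#'
#' Bundles the gating and fitting parameters of the full pipeline with the
#' reference defaults: linking gate 0.5 um and a 10-frame minimum for fast
#' 3D (MFM-style) acquisitions, 0.3 um and 5 frames for slow 2D
#' (HILO-style) acquisitions, 9 MSD lags, a 0.2 um / 8-frame bound-segment
#' rule, and 500 discarded leading frames.
#'
#' @param modality `"mfm"` (fast 3D) or `"hilo"` (slow 2D); selects the
#'   matching defaults.
#' @param max_disp_um linking gate, um.
#' @param min_frames minimum track length, frames.
#' @param n_lags MSD lags used in fits.
#' @param r_max_um bound-segment displacement bound, um.
#' @param min_bound_frames minimum bound-event length, frames.
#' @param discard_first leading frames to drop.
#' @param frame_interval frame interval, seconds.
#' @param dims dimensionality.
#' @return a validated list of class `analysis_config`.
#' @export
analysis_config <- function(modality = c("mfm", "hilo"),
                            max_disp_um = NULL, min_frames = NULL,
                            n_lags = 9L, r_max_um = 0.2,
                            min_bound_frames = 8L, discard_first = 500L,
                            frame_interval = NULL, dims = NULL) {
  modality <- match.arg(modality)
  defaults <- if (modality == "mfm") {
    list(max_disp_um = 0.5, min_frames = 10L, frame_interval = 0.04, dims = 3L)
  } else {
    list(max_disp_um = 0.3, min_frames = 5L, frame_interval = 0.5, dims = 2L)
  }
  cfg <- list(
    modality = modality,
    max_disp_um = max_disp_um %||% defaults$max_disp_um,
    min_frames = as.integer(min_frames %||% defaults$min_frames),
    n_lags = as.integer(n_lags),
    r_max_um = r_max_um,
    min_bound_frames = as.integer(min_bound_frames),
    discard_first = as.integer(discard_first),
    frame_interval = frame_interval %||% defaults$frame_interval,
    dims = as.integer(dims %||% defaults$dims)
  )
  stopifnot(cfg$max_disp_um > 0, cfg$min_frames >= 2, cfg$n_lags >= 3,
            cfg$r_max_um > 0, cfg$min_bound_frames >= 1,
            cfg$discard_first >= 0, cfg$frame_interval > 0,
            cfg$dims %in% c(2L, 3L))
  structure(cfg, class = "analysis_config")
}

#' Per-condition run summary
#'
#' Collects the bookkeeping counts of a full analysis into one row per
#' condition: number of cells, total tracks, tracks entering the diffusion
#' analysis (passing the diffusion min-length filter), and number of dwell
#' times.
#'
#' @param conditions a named list; each element is a list with any of the
#'   components `cells` (list of per-cell `spt_tracks`), `tracks`
#'   (pooled `spt_tracks`), `tracks_diffusion` (`spt_tracks` after the
#'   diffusion filter), `dwells` (`dwell_set`). Missing components count
#'   as zero.
#' @return a tibble with columns `condition`, `n_cells`, `n_tracks`,
#'   `n_tracks_diffusion`, `n_dwell_times`.
#' @export
summarize_run <- function(conditions) {
  stopifnot(is.list(conditions), !is.null(names(conditions)))
  n_tracks_of <- function(x) {
    if (is.null(x)) 0L else length(unique(x$track))
  }
  rows <- lapply(names(conditions), function(cond) {
    el <- conditions[[cond]]
    n_cells <- if (!is.null(el$cells)) length(el$cells) else 0L
    n_tracks <- if (!is.null(el$tracks)) n_tracks_of(el$tracks) else
      sum(vapply(el$cells %||% list(), n_tracks_of, integer(1)))
    tibble::tibble(
      condition = cond,
      n_cells = n_cells,
      n_tracks = n_tracks,
      n_tracks_diffusion = n_tracks_of(el$tracks_diffusion),
      n_dwell_times = if (!is.null(el$dwells)) nrow(el$dwells) else 0L
    )
  })
  do.call(rbind, rows)
}
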