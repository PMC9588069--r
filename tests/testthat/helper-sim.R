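# Fixture builders and independent oracles shared across test files.

# Build an spt_tracks table of n independent fBm trajectories.
mk_fbm_tracks <- function(n, n_frames, D, alpha, dt = 0.04, dims = 3L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dfs <- lapply(seq_len(n), function(i) {
    p <- simulate_fbm_path(n_frames - 1L, D, alpha, dt, dims)
    tibble::tibble(track = i, frame = 0:(n_frames - 1L), as.data.frame(p))
  })
  spt_tracks(do.call(rbind, dfs), frame_interval = dt, dims = dims)
}

# Wrap a single position matrix as a one-track spt_tracks table.
mk_track <- function(m, dt = 1) {
  m <- as.matrix(m)
  dims <- ncol(m)
  colnames(m) <- c("x_um", "y_um", "z_um")[seq_len(dims)]
  spt_tracks(tibble::tibble(track = 1L, frame = 0:(nrow(m) - 1L),
                            as.data.frame(m)),
             frame_interval = dt, dims = dims)
}

# Brute-force double-loop time-averaged MSD oracle.
msd_brute <- function(m, max_lag) {
  n <- nrow(m)
  vapply(seq_len(max_lag), function(lag) {
    acc <- 0
    for (i in 1:(n - lag)) acc <- acc + sum((m[i + lag, ] - m[i, ])^2)
    acc / (n - lag)
  }, numeric(1))
}

# Construct a survival_curve object directly from model values (noiseless
# curve-level fixtures for the fit inversion tests).
model_survival <- function(t, s, dt = NULL, n = 100000L) {
  out <- tibble::tibble(t_s = t, survival = s,
                        n_at_risk = as.integer(round(pmin(pmax(s, 0), 1) * n)))
  structure(out,
            class = c("survival_curve", class(tibble::tibble())),
            n = n, frame_interval = dt)
}

# Exhaustive oracle for the gated assignment problem: maximize the number of
# admissible links, break ties by minimal total squared displacement.
# Returns list(n_links, cost).
lap_brute <- function(d2, gate2) {
  n1 <- nrow(d2)
  n2 <- ncol(d2)
  best <- list(n_links = -1L, cost = Inf)
  recurse <- function(row, used, links, cost) {
    if (row > n1) {
      if (links > best$n_links ||
          (links == best$n_links && cost < best$cost - 1e-12)) {
        best <<- list(n_links = links, cost = cost)
      }
      return(invisible())
    }
    recurse(row + 1L, used, links, cost)       # leave this row unmatched
    for (j in seq_len(n2)) {
      if (!used[j] && d2[row, j] <= gate2) {
        used[j] <- TRUE
        recurse(row + 1L, used, links + 1L, cost + d2[row, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, n2), 0L, 0)
  best
}

# Summarize the links produced by link_detections as (n_links, cost) per
# consecutive frame pair, for comparison against lap_brute.
links_summary <- function(tracks) {
  cols <- sptdyn::track_lengths(tracks)
  d <- as.data.frame(tracks)
  d <- d[order(d$track, d$frame), ]
  pc <- intersect(c("x_um", "y_um", "z_um"), names(d))
  same <- d$track[-1] == d$track[-nrow(d)]
  step <- as.matrix(d[-1, pc]) - as.matrix(d[-nrow(d), pc])
  list(n_links = sum(same), cost = sum(rowSums(step^2)[same]))
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
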