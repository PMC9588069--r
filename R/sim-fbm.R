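#' Autocovariance of fractional Gaussian noise
#'
#' Covariance at integer lags of unit-variance fGn with Hurst exponent H:
#' rho(k) = 0.5 * (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H)).
#'
#' @param lags integer lags >= 0.
#' @param H Hurst exponent in (0, 1].
#' @return numeric vector of covariances.
#' @keywords internal
fgn_acvf <- function(lags, H) {
  k <- abs(lags)
  0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
}

# Exact-covariance fGn sampler. Returns an n x n_paths matrix of
# unit-step-variance fractional Gaussian noise. "daviesharte" uses circulant
# embedding (O(n log n) per path); "cholesky" factorizes the n x n covariance
# (used as fallback when the embedding is not nonnegative-definite, and as
# the independent reference in tests).
sample_fgn <- function(n, H, n_paths = 1L,
                       method = c("auto", "daviesharte", "cholesky")) {
  method <- match.arg(method)
  stopifnot(n >= 1, H > 0, H <= 1, n_paths >= 1)
  if (abs(H - 0.5) < 1e-12) {
    return(matrix(stats::rnorm(n * n_paths), nrow = n))
  }
  if (abs(H - 1) < 1e-12) {
    # Degenerate fully-correlated case: ballistic increments.
    return(matrix(rep(stats::rnorm(n_paths), each = n), nrow = n))
  }
  if (method != "cholesky") {
    lam <- fgn_circulant_eigenvalues(n, H)
    if (!is.null(lam)) {
      return(fgn_sample_daviesharte(n, lam, n_paths))
    }
    if (method == "daviesharte") {
      stop("circulant embedding not nonnegative-definite for n=", n, ", H=", H)
    }
  }
  fgn_sample_cholesky(n, H, n_paths)
}

fgn_circulant_eigenvalues <- function(n, H) {
  r <- fgn_acvf(0:n, H)
  circ <- c(r, rev(r[2:n]))          # length 2n, lags 0..n, n-1..1
  lam <- Re(stats::fft(circ))
  if (min(lam) < -1e-9 * max(abs(lam))) return(NULL)
  pmax(lam, 0)
}

fgn_sample_daviesharte <- function(n, lam, n_paths) {
  m <- 2L * n
  out <- matrix(0, nrow = n, ncol = n_paths)
  for (p in seq_len(n_paths)) {
    z <- complex(length.out = m)
    z[1] <- sqrt(lam[1]) * stats::rnorm(1)
    z[n + 1] <- sqrt(lam[n + 1]) * stats::rnorm(1)
    re <- stats::rnorm(n - 1)
    im <- stats::rnorm(n - 1)
    idx <- 2:n
    z[idx] <- sqrt(lam[idx] / 2) * complex(real = re, imaginary = im)
    z[m - idx + 2L] <- Conj(z[idx])
    x <- Re(stats::fft(z)) / sqrt(m)
    out[, p] <- x[1:n]
  }
  out
}

fgn_sample_cholesky <- function(n, H, n_paths) {
  sigma <- stats::toeplitz(fgn_acvf(0:(n - 1), H))
  u <- chol(sigma)
  crossprod(u, matrix(stats::rnorm(n * n_paths), nrow = n))
}

#' Simulate a fractional Brownian motion path
#'
#' Generates an exact-covariance fractional Brownian motion (fBm) trajectory
#' whose ensemble mean squared displacement follows
#' `MSD(t) = 2 * dims * D * t^alpha`, i.e. Hurst exponent `H = alpha / 2`.
#' `alpha = 1` gives ordinary Brownian motion; `alpha < 1` subdiffusion;
#' `alpha > 1` superdiffusion. Each spatial coordinate is an independent fBm
#' with per-step variance `2 * D * dt^alpha`.
#'
#' @param n_steps number of steps (>= 2); the returned path has
#'   `n_steps + 1` positions, starting at the origin.
#' @param D generalized diffusion coefficient, um^2/s^alpha (um^2/s when
#'   `alpha = 1`). `D = 0` yields a path fixed at the origin.
#' @param alpha anomalous exponent, in (0, 2].
#' @param dt time step, seconds.
#' @param dims spatial dimensionality (1, 2 or 3).
#' @param seed optional integer seed (set locally; the caller's RNG state is
#'   advanced as with any random draw when `seed` is `NULL`).
#' @param method covariance construction: circulant embedding
#'   (Davies-Harte), Cholesky factorization, or automatic.
#'
#' @return numeric matrix of `n_steps + 1` rows and `dims` columns
#'   (positions in um at times `0, dt, ..., n_steps * dt`).
#' @examples
#' p <- simulate_fbm_path(100, D = 0.3, alpha = 1, dt = 0.04, dims = 3, seed = 1)
#' dim(p)
#' @export
simulate_fbm_path <- function(n_steps, D, alpha, dt, dims = 3L, seed = NULL,
                              method = c("auto", "daviesharte", "cholesky")) {
  method <- match.arg(method)
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (alpha <= 0 || alpha > 2) stop("alpha must lie in (0, 2]")
  if (D < 0) stop("D must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  stopifnot(dims %in% 1:3)
  pos <- matrix(0, nrow = n_steps + 1L, ncol = dims)
  if (D > 0) {
    sd_step <- sqrt(2 * D * dt^alpha)
    draw <- function() sd_step * sample_fgn(n_steps, H = alpha / 2,
                                            n_paths = dims, method = method)
    inc <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
    pos[-1L, ] <- apply(inc, 2L, cumsum)
  }
  colnames(pos) <- c("x_um", "y_um", "z_um")[seq_len(dims)]
  pos
}
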