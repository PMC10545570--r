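#' Second-order (quadratic) detrend
#'
#' Subtracts the least-squares quadratic polynomial in time, leaving residuals
#' orthogonal to the constant, linear and quadratic basis. Removes parabolic
#' trends such as a slow facilitation-inhibition-release arc before spectral
#' analysis.
#'
#' @param y Series to detrend.
#' @param t Time points (defaults to the sample index; residuals are identical
#'   for any affine transform of `t`).
#' @return Detrended residual series.
#' @export
detrend2 <- function(y, t = seq_along(y)) {
  n <- length(y)
  if (n < 4L) stop("second-order detrending needs at least 4 points",
                   call. = FALSE)
  stopifnot(length(t) == n)
  X <- cbind(1, t, t^2)
  stats::lm.fit(X, y)$residuals
}

# residual-maker matrix of the quadratic basis; precomputed for the
# permutation loop (detrending is linear, so it commutes with averaging)
detrend2_matrix <- function(n) {
  t <- seq_len(n)
  Q <- qr.Q(qr(cbind(1, t, t^2)))
  diag(n) - tcrossprod(Q)
}

#' One-sided FFT amplitude spectrum
#'
#' Discrete Fourier transform of an `N`-point series on a uniform grid with
#' spacing `dt`; amplitudes are `2*|X_k|/N` for the non-DC bins
#' `k = 1..floor(N/2)` at frequencies `k/(N*dt)`, so a unit-amplitude sinusoid
#' sitting exactly on a bin has amplitude 1.
#'
#' @param y Series (typically detrended).
#' @param dt Grid spacing in seconds.
#' @return Data frame with `freq` (Hz) and `amplitude` (input units).
#' @export
amplitude_spectrum <- function(y, dt) {
  stopifnot(length(dt) == 1L, dt > 0)
  n <- length(y)
  ks <- seq_len(n %/% 2)
  X <- stats::fft(y)
  data.frame(freq = ks / (n * dt),
             amplitude = 2 * Mod(X[ks + 1]) / n)
}

#' Max-amplitude permutation test for rhythmicity
#'
#' Tests each frequency bin of the detrended grand-average spectrum against
#' the null distribution of the *maximum* amplitude across bins, which
#' controls the familywise error over bins. Each permutation shuffles the
#' CTOA labels independently within every participant (preserving each
#' participant's value distribution while destroying temporal structure),
#' re-averages, re-detrends and re-transforms.
#'
#' @param mat Participants x CTOAs matrix of per-participant cell means for
#'   one condition (or of paired differences).
#' @param dt CTOA grid spacing in seconds.
#' @param n_perm Number of permutations; fewer than 999 triggers a warning
#'   (p resolution too coarse for alpha = .05 with max-correction).
#' @param seed Integer seed; the test is reproducible under it.
#' @param condition Label stored in the result.
#' @return Object of class `spectrum_test`: `condition`, `detrended`
#'   (grand-average residual series), `freq`, `amplitude`, `max_dist`
#'   (permutation maxima), `threshold_95` (95th percentile of `max_dist`),
#'   `p` per bin computed as `(1 + #{max >= amp}) / (n_perm + 1)` (the
#'   observed data counts as one ordering, so p is never 0), `n_perm`, `seed`.
#' @export
spectrum_permutation_test <- function(mat, dt, n_perm = 10000L, seed,
                                      condition = "series") {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("cell-mean matrix must be complete", call. = FALSE)
  if (n_perm < 999)
    warning("n_perm < 999: p-value resolution too coarse for alpha = .05",
            call. = FALSE)
  n_sub <- nrow(mat); n_t <- ncol(mat)
  R <- detrend2_matrix(n_t)
  obs <- amplitude_spectrum(drop(R %*% colMeans(mat)), dt)

  rng <- local_rng(seed)
  ks <- seq_len(n_t %/% 2)
  max_dist <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    avg <- numeric(n_t)
    for (i in seq_len(n_sub)) avg <- avg + mat[i, rng$sample(n_t)]
    avg <- drop(R %*% (avg / n_sub))
    max_dist[p] <- max(2 * Mod(stats::fft(avg)[ks + 1]) / n_t)
  }
  pvals <- vapply(obs$amplitude, function(a)
    (1 + sum(max_dist >= a)) / (n_perm + 1), numeric(1))
  structure(list(condition = condition,
                 detrended = drop(R %*% colMeans(mat)),
                 freq = obs$freq, amplitude = obs$amplitude,
                 max_dist = max_dist,
                 threshold_95 = stats::quantile(max_dist, 0.95, names = FALSE),
                 p = pvals, n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "spectrum_test")
}

#' Spectral battery: valid, invalid and difference courses
#'
#' Runs the max-amplitude permutation test on the valid condition, the invalid
#' condition, and the invalid-minus-valid difference, sharing `n_perm`; the
#' per-condition seeds are `seed`, `seed + 1`, `seed + 2`.
#'
#' @param cm A [cell_means()] result.
#' @param n_perm Permutations per condition.
#' @param seed Master seed.
#' @return Named list (class `spectral_battery`) of three `spectrum_test`
#'   objects: `valid`, `invalid`, `difference`.
#' @export
run_spectral_battery <- function(cm, n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(cm, "cell_means"))
  dt <- unique(round(diff(cm$ctoa), 10))
  if (length(dt) != 1L)
    stop("spectral analysis needs a uniform CTOA grid", call. = FALSE)
  v <- matrix(cm$cells[, , "valid"], nrow = length(cm$participants))
  iv <- matrix(cm$cells[, , "invalid"], nrow = length(cm$participants))
  out <- list(
    valid = spectrum_permutation_test(v, dt, n_perm, seed, "valid"),
    invalid = spectrum_permutation_test(iv, dt, n_perm, seed + 1L, "invalid"),
    difference = spectrum_permutation_test(iv - v, dt, n_perm, seed + 2L,
                                           "difference (invalid - valid)"))
  class(out) <- "spectral_battery"
  out
}
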