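#' @export
print.ior_fit <- function(x, digits = 4, ...) {
  cat("Difference time-course model: ", x$model, "\n", sep = "")
  print(round(x$coefficients, digits))
  cat(sprintf("n = %d, k = %d, RSS = %.4g, AICc = %.2f, BIC = %.2f\n",
              x$n, x$k, x$rss, x$aicc, x$bic))
  if (!is.null(x$fbounds) && x$f_at_bound)
    cat("note: frequency estimate at the lower bound (",
        x$fbounds$f_min, " Hz)\n", sep = "")
  if (!x$converged) cat("warning: optimizer did not converge; best grid/polish value returned\n")
  invisible(x)
}

#' @export
summary.ior_fit <- function(object, ...) {
  out <- list(model = object$model, coefficients = object$coefficients,
              rss = object$rss, n = object$n, k = object$k,
              sigma = sqrt(object$rss / object$n),
              aicc = object$aicc, bic = object$bic,
              r_squared = 1 - object$rss / sum((object$y - mean(object$y))^2),
              converged = object$converged, f_at_bound = object$f_at_bound)
  class(out) <- "summary.ior_fit"
  out
}

#' @export
print.summary.ior_fit <- function(x, ...) {
  cat("Model:", x$model, "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("RSS %.4g  sigma %.3f  R^2 %.3f  AICc %.2f  BIC %.2f  (n=%d, k=%d)\n",
              x$rss, x$sigma, x$r_squared, x$aicc, x$bic, x$n, x$k))
  invisible(x)
}

#' @export
coef.ior_fit <- function(object, ...) object$coefficients

#' @export
fitted.ior_fit <- function(object, ...) object$fitted

#' @export
residuals.ior_fit <- function(object, ...) object$residuals

#' Predict from a fitted difference-course model
#'
#' @param object An [ior_fit()].
#' @param newdata Optional numeric vector of times (seconds); defaults to the
#'   fitted grid.
#' @param ... Unused.
#' @return Predicted z-unit differences.
#' @export
predict.ior_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$t else as.numeric(newdata)
  model_predict(object$model, object$coefficients, t)
}

#' Simulate series from a fitted model
#'
#' Draws `nsim` new series at the fitted time points: model prediction plus
#' Gaussian noise with the residual standard deviation `sqrt(rss/n)`.
#'
#' @param object An [ior_fit()].
#' @param nsim Number of series.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Matrix `length(t)` x `nsim`.
#' @export
simulate.ior_fit <- function(object, nsim = 1, seed = NULL, ...) {
  rng <- local_rng(if (is.null(seed)) 1L else seed)
  mu <- object$fitted
  s <- sqrt(object$rss / object$n)
  matrix(mu + rng$rnorm(length(mu) * nsim, 0, s), ncol = nsim)
}

#' Plot a fitted difference-course model
#'
#' Observed points and the model curve over a fine time grid; the zero line
#' separates facilitation (positive) from inhibition (negative).
#'
#' @param x An [ior_fit()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ior_fit <- function(x, ...) {
  tt <- seq(min(x$t), max(x$t), length.out = 200)
  graphics::plot(x$t, x$y, pch = 16, xlab = "CTOA (s)",
                 ylab = "Difference (z), invalid - valid",
                 main = paste("Model:", x$model), ...)
  graphics::abline(h = 0, lty = 3, col = "grey50")
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
print.ior_fit_set <- function(x, digits = 3, ...) {
  cat("Candidate-model comparison (", nrow(x$comparison), " models)\n", sep = "")
  tab <- x$comparison
  tab$rss <- signif(tab$rss, digits)
  tab$aicc <- round(tab$aicc, 2); tab$bic <- round(tab$bic, 2)
  tab$delta_aicc <- round(tab$delta_aicc, 2)
  tab$akaike_weight <- signif(tab$akaike_weight, 3)
  tab$bf_best_vs_model <- signif(tab$bf_best_vs_model, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
print.winner_tally <- function(x, ...) {
  cat("Per-participant winner counts (n =", x$n_participants, ")\n")
  print(x$counts)
  invisible(x)
}

#' @export
print.spectrum_test <- function(x, ...) {
  cat("Max-amplitude permutation test:", x$condition, "\n")
  cat(sprintf("n_perm = %d, threshold(95%%) = %.4f\n", x$n_perm, x$threshold_95))
  sig <- x$p < 0.05
  tab <- data.frame(freq_hz = round(x$freq, 3),
                    amplitude = round(x$amplitude, 4),
                    p = round(x$p, 4),
                    sig = ifelse(sig, "*", ""))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot a spectrum test result
#'
#' Left: detrended grand-average series. Right: amplitude spectrum with the
#' 95th-percentile maximum-amplitude threshold; significant bins are starred.
#'
#' @param x A `spectrum_test`.
#' @param ... Unused.
#' @export
plot.spectrum_test <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$detrended, type = "b", pch = 16, xlab = "CTOA index",
                 ylab = "Detrended z-RT", main = x$condition)
  graphics::abline(h = 0, lty = 3, col = "grey50")
  graphics::plot(x$freq, x$amplitude, type = "h", lwd = 3, xlab = "Frequency (Hz)",
                 ylab = "Amplitude (z)", main = "Amplitude spectrum")
  graphics::abline(h = x$threshold_95, lty = 2, col = "grey40")
  sig <- x$p < 0.05
  if (any(sig))
    graphics::points(x$freq[sig], x$amplitude[sig] * 1.05, pch = 8)
  invisible(x)
}

#' @export
print.spectral_battery <- function(x, ...) {
  for (s in x) { print(s); cat("\n") }
  invisible(x)
}
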