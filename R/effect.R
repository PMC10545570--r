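#' Generative invalid-minus-valid effect curve parameters
#'
#' Parameters of the hybrid difference curve used by the simulator:
#' an offset plus exponential decay (inhibitory tagging) plus a sinusoid
#' (rhythmic sampling),
#' \deqn{d(t) = b_0 + N_0 e^{-t/\tau} + a \sin(2\pi f t + \phi).}
#' Positive values mean faster valid responses (facilitation); negative values
#' mean inhibition of the cued location. Defaults are the reference
#' grand-average hybrid estimates.
#'
#' @param b0 Offset, z-units.
#' @param N0 Initial exponential quantity, z-units.
#' @param tau Exponential time constant, seconds (> 0).
#' @param a Sinusoid amplitude, z-units (>= 0).
#' @param f Sinusoid frequency, Hz (>= 0).
#' @param phi Sinusoid phase, radians; reduced to [0, 2*pi).
#' @return An object of class `effect_params`.
#' @export
effect_params <- function(b0 = -0.48, N0 = 0.82, tau = 0.18,
                          a = 0.14, f = 1.05, phi = 0.72) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (a < 0) stop("amplitude a must be >= 0", call. = FALSE)
  if (f < 0) stop("frequency f must be >= 0", call. = FALSE)
  p <- list(b0 = b0, N0 = N0, tau = tau, a = a, f = f,
            phi = phi %% (2 * pi))
  class(p) <- "effect_params"
  p
}

#' Evaluate the generative difference curve
#'
#' @param t Times (CTOAs) in seconds, all >= 0.
#' @param p An [effect_params()].
#' @return `b0 + N0*exp(-t/tau) + a*sin(2*pi*f*t + phi)`, elementwise, z-units.
#' @examples
#' difference_curve(c(0, 0.5, 1), effect_params())
#' @export
difference_curve <- function(t, p) {
  stopifnot(inherits(p, "effect_params"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p$b0 + p$N0 * exp(-t / p$tau) + p$a * sin(2 * pi * p$f * t + p$phi)
}

#' Reaction-time noise model for the simulator
#'
#' The simulator draws a non-catch trial RT as
#' `base + intercept_i + s_i * (rt_sd_ref * c * d(t)/2 + trial_sd * eps)`,
#' where `intercept_i ~ N(0, participant_intercept_sd)` and
#' `s_i = exp(N(0, participant_scale_sd))` vary per participant,
#' `c` is -1 for valid and +1 for invalid trials so the expected
#' invalid-minus-valid difference equals `d(t)` in reference units, and `eps`
#' is standard normal or shifted-lognormal trial noise. `rt_sd_ref` is the
#' fixed scale (seconds per z-unit) that maps the z-unit effect curve to
#' seconds; it equals the default `trial_sd` so that after within-participant
#' z-scaling the effect reappears at (approximately) its nominal z magnitude.
#'
#' @param base_rt_mean Mean detection RT, seconds.
#' @param participant_intercept_sd SD of per-participant RT offsets, seconds.
#' @param participant_scale_sd SD of per-participant log scale factors.
#' @param trial_sd Trial-to-trial RT noise SD, seconds.
#' @param rt_distribution `"normal"` or `"shifted-lognormal"` trial noise.
#' @param false_alarm_rate Probability of responding on a catch trial.
#' @param miss_rate Probability of missing a target.
#' @param rt_sd_ref Fixed z-unit-to-seconds conversion for the effect, seconds.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(base_rt_mean = 0.32, participant_intercept_sd = 0.05,
                         participant_scale_sd = 0.15, trial_sd = 0.08,
                         rt_distribution = c("normal", "shifted-lognormal"),
                         false_alarm_rate = 0.05, miss_rate = 0.02,
                         rt_sd_ref = 0.08) {
  rt_distribution <- match.arg(rt_distribution)
  stopifnot(participant_intercept_sd >= 0, participant_scale_sd >= 0,
            trial_sd >= 0, rt_sd_ref > 0)
  if (false_alarm_rate < 0 || false_alarm_rate > 1 ||
      miss_rate < 0 || miss_rate > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  p <- list(base_rt_mean = base_rt_mean,
            participant_intercept_sd = participant_intercept_sd,
            participant_scale_sd = participant_scale_sd,
            trial_sd = trial_sd, rt_distribution = rt_distribution,
            false_alarm_rate = false_alarm_rate, miss_rate = miss_rate,
            rt_sd_ref = rt_sd_ref)
  class(p) <- "noise_params"
  p
}
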