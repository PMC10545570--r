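#' Small-sample corrected Akaike information criterion
#'
#' Gaussian-likelihood form from a least-squares residual sum of squares:
#' `n*log(rss/n) + 2k + 2k(k+1)/(n-k-1)`. The additive constant
#' `n*log(2*pi) + n` is omitted (identically in [bic()]), so only differences
#' across models are meaningful.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of fitted points.
#' @param k Effective parameter count: free model parameters plus one for the
#'   residual variance.
#' @return AICc value.
#' @export
aicc <- function(rss, n, k) {
  if (any(rss <= 0)) stop("rss must be > 0 (perfect fits are degenerate here)",
                          call. = FALSE)
  if (any(n <= k + 1)) stop("AICc needs n > k + 1", call. = FALSE)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Bayesian information criterion
#'
#' Same Gaussian-likelihood convention as [aicc()]: `n*log(rss/n) + k*log(n)`.
#'
#' @inheritParams aicc
#' @return BIC value.
#' @export
bic <- function(rss, n, k) {
  if (any(rss <= 0)) stop("rss must be > 0", call. = FALSE)
  n * log(rss / n) + k * log(n)
}

#' Akaike weights over a model set
#'
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` with deltas taken relative
#' to the minimum criterion value. Interpretable as the probability of each
#' model being the best in the set.
#'
#' @param ic Vector of AICc (or other IC) values, one per model.
#' @return Weights summing to 1, same names as `ic`.
#' @examples
#' akaike_weights(c(intercept = 6.71, hybrid = -57.41))
#' @export
akaike_weights <- function(ic) {
  d <- ic - min(ic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' BIC-approximate Bayes factor
#'
#' Large-sample approximation `BF_ab = exp((bic_b - bic_a)/2)` in favor of
#' model `a` over model `b`.
#'
#' @param bic_a,bic_b BIC values of the two models.
#' @return Bayes factor in favor of `a`.
#' @export
bic_bayes_factor <- function(bic_a, bic_b) exp((bic_b - bic_a) / 2)

#' Model-comparison table
#'
#' @param fits Named list of [ior_fit()] objects (or an `ior_fit_set`).
#' @return Data frame with one row per model: `model`, `k`, `rss`, `aicc`,
#'   `bic`, `delta_aicc` (vs the AICc-best model), `akaike_weight`, and
#'   `bf_best_vs_model` (BIC-approximate Bayes factor of the BIC-best model
#'   over this one).
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "ior_fit_set")) fits <- fits$fits
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "ior_fit")))
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    k = vapply(fits, `[[`, integer(1), "k"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    stringsAsFactors = FALSE
  )
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$akaike_weight <- akaike_weights(tab$aicc)
  tab$bf_best_vs_model <- bic_bayes_factor(min(tab$bic), tab$bic)
  rownames(tab) <- NULL
  tab
}

winner_class <- function(model) {
  switch(model, intercept = "intercept", linear = "ior", exponential = "ior",
         rhythmic = "rhythmic", hybrid = "hybrid")
}

#' Per-participant winner tally
#'
#' Fits the candidate set to every participant's difference series and counts,
#' separately for AICc and BIC, how often each model class (intercept, IOR =
#' linear or exponential, rhythmic, hybrid) is among the winners. Exact ties
#' (criterion within 1e-9 of the minimum) are counted for every tied model.
#'
#' @param dc A [difference_course()].
#' @param fbounds A [frequency_bounds()].
#' @param models Candidate models.
#' @param ... Passed to [ior_fit()].
#' @return Object of class `winner_tally`: `counts` (classes x criteria
#'   matrix), `winners` (per-participant data frame), `n_participants`.
#' @export
per_participant_winners <- function(dc, fbounds = frequency_bounds("full"),
                                    models = ior_models(), ...) {
  stopifnot(inherits(dc, "difference_course"))
  classes <- c("intercept", "ior", "rhythmic", "hybrid")
  counts <- matrix(0L, nrow = length(classes), ncol = 2,
                   dimnames = list(classes, c("aicc", "bic")))
  rows <- vector("list", nrow(dc$per_participant))
  for (i in seq_len(nrow(dc$per_participant))) {
    fs <- ior_fit_models(as.numeric(dc$per_participant[i, ]), t = dc$ctoa,
                         models = models, fbounds = fbounds, ...)
    tab <- fs$comparison
    win <- list()
    for (crit in c("aicc", "bic")) {
      v <- tab[[crit]]
      tied <- tab$model[v - min(v) < 1e-9]
      cls <- unique(vapply(tied, winner_class, character(1)))
      counts[cls, crit] <- counts[cls, crit] + 1L
      win[[crit]] <- paste(tied, collapse = "+")
    }
    rows[[i]] <- data.frame(
      participant_id = rownames(dc$per_participant)[i],
      winner_aicc = win$aicc, winner_bic = win$bic, stringsAsFactors = FALSE)
  }
  structure(list(counts = counts,
                 winners = do.call(rbind, rows),
                 n_participants = nrow(dc$per_participant)),
            class = "winner_tally")
}
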