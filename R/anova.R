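#' Select the classic-replication CTOA subset
#'
#' Maps the target CTOAs of the original two-location cueing studies
#' (50, 100, 200, 300, 500 ms by default) onto the nearest values of a denser
#' grid, ties broken downward. On the default 42 ms grid this yields
#' 42, 84, 210, 294 and 504 ms.
#'
#' @param grid CTOA grid in seconds.
#' @param targets Target CTOAs in seconds.
#' @return Selected grid values (seconds), one per target.
#' @export
select_replication_ctoas <- function(grid,
                                     targets = c(0.050, 0.100, 0.200, 0.300, 0.500)) {
  if (any(targets < min(grid) | targets > max(grid)))
    stop("target CTOA outside the grid range", call. = FALSE)
  vapply(targets, function(tt) {
    d <- abs(grid - tt)
    cand <- grid[d == min(d)]
    min(cand)  # ties broken downward
  }, numeric(1))
}

# orthonormal polynomial-free contrast basis for m levels ((m-1) x m)
orth_contrasts <- function(m) {
  C <- stats::contr.helmert(m)
  t(qr.Q(qr(C)))
}

# Box / Greenhouse-Geisser epsilon from the covariance of the effect's
# orthonormalized contrast scores: eps = tr(S)^2 / (df * tr(S^2))
gg_epsilon_from_cov <- function(S) {
  df <- nrow(S)
  sum(diag(S))^2 / (df * sum(S * S))
}

#' Two-way fully within-subject ANOVA (validity x CTOA)
#'
#' Classical repeated-measures decomposition on per-participant cell means,
#' with Greenhouse-Geisser sphericity correction for every within effect with
#' more than one numerator df and generalized eta squared for fully
#' within-subject designs (all subject-related variance in the denominator).
#'
#' @param cm A [cell_means()] result.
#' @param ctoas CTOA values (seconds) to analyze; defaults to the replication
#'   subset via [select_replication_ctoas()].
#' @return Data frame (class `rm_anova`) with one row per effect (`validity`,
#'   `ctoa`, `validity:ctoa`): sums of squares, `F`, uncorrected dfs, GG
#'   epsilon, corrected dfs, GG-corrected `p`, and `ges` (generalized eta
#'   squared).
#' @export
rm_anova_validity_ctoa <- function(cm, ctoas = NULL) {
  stopifnot(inherits(cm, "cell_means"))
  if (is.null(ctoas)) ctoas <- select_replication_ctoas(cm$ctoa)
  idx <- match(ctoas, cm$ctoa)
  if (anyNA(idx)) stop("requested CTOAs not on the grid", call. = FALSE)
  Y <- cm$cells[, idx, , drop = FALSE]  # n x b x a, a = validity (2)
  if (anyNA(Y)) stop("missing cells; the ANOVA needs a complete design",
                     call. = FALSE)
  n <- dim(Y)[1]; b <- dim(Y)[2]; a <- dim(Y)[3]
  if (n < 2) stop("need at least 2 participants", call. = FALSE)

  grand <- mean(Y)
  m_s <- apply(Y, 1, mean)
  m_A <- apply(Y, 3, mean)
  m_B <- apply(Y, 2, mean)
  m_AB <- apply(Y, c(2, 3), mean)            # b x a
  m_sA <- apply(Y, c(1, 3), mean)            # n x a
  m_sB <- apply(Y, c(1, 2), mean)            # n x b

  ss_total <- sum((Y - grand)^2)
  ss_s <- a * b * sum((m_s - grand)^2)
  ss_A <- n * b * sum((m_A - grand)^2)
  ss_B <- n * a * sum((m_B - grand)^2)
  ss_AB <- n * sum((m_AB - outer(m_B, rep(1, a)) -
                      outer(rep(1, b), m_A) + grand)^2)
  ss_As <- b * sum((m_sA - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_A) + grand)^2)
  ss_Bs <- a * sum((m_sB - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_B) + grand)^2)
  ss_ABs <- ss_total - ss_s - ss_A - ss_B - ss_AB - ss_As - ss_Bs

  df_A <- a - 1; df_B <- b - 1; df_AB <- df_A * df_B
  df_As <- df_A * (n - 1); df_Bs <- df_B * (n - 1); df_ABs <- df_AB * (n - 1)

  # epsilons from contrast-score covariances
  flat <- matrix(Y, nrow = n)               # n x (b*a), ctoa fastest
  Sigma <- stats::cov(flat)
  cA <- orth_contrasts(a)                    # 1 x a
  cB <- orth_contrasts(b)                    # (b-1) x b
  ones_a <- rep(1, a) / sqrt(a); ones_b <- rep(1, b) / sqrt(b)
  C_A <- kronecker(cA, matrix(ones_b, nrow = 1))
  C_B <- kronecker(matrix(ones_a, nrow = 1), cB)
  C_AB <- kronecker(cA, cB)
  eps <- c(validity = 1,
           ctoa = gg_epsilon_from_cov(C_B %*% Sigma %*% t(C_B)),
           `validity:ctoa` = gg_epsilon_from_cov(C_AB %*% Sigma %*% t(C_AB)))

  ss_eff <- c(ss_A, ss_B, ss_AB)
  df_eff <- c(df_A, df_B, df_AB)
  ss_err <- c(ss_As, ss_Bs, ss_ABs)
  df_err <- c(df_As, df_Bs, df_ABs)
  Fv <- (ss_eff / df_eff) / (ss_err / df_err)
  denom_ges <- ss_s + ss_As + ss_Bs + ss_ABs
  out <- data.frame(
    effect = c("validity", "ctoa", "validity:ctoa"),
    ss = ss_eff, ss_error = ss_err,
    F = Fv, df1 = df_eff, df2 = df_err,
    gg_epsilon = as.numeric(eps),
    df1_gg = df_eff * as.numeric(eps), df2_gg = df_err * as.numeric(eps),
    p_gg = stats::pf(Fv, df_eff * as.numeric(eps), df_err * as.numeric(eps),
                     lower.tail = FALSE),
    ges = ss_eff / (ss_eff + denom_ges),
    stringsAsFactors = FALSE
  )
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Bonferroni-corrected paired post-hoc tests per CTOA
#'
#' One two-sided paired t-test (invalid minus valid) per CTOA level, df =
#' n - 1; p-values are multiplied by the number of levels tested and capped at
#' 1. Positive t means faster valid responses (facilitation of the cued
#' location); negative t means inhibition.
#'
#' @param cm A [cell_means()] result.
#' @param ctoas CTOA values (seconds); defaults to the replication subset.
#' @return Data frame: `ctoa`, `mean_diff` (invalid - valid), `t`, `df`,
#'   `p_raw`, `p_bonferroni`, `significant` (at .05).
#' @export
posthoc_bonferroni <- function(cm, ctoas = NULL) {
  stopifnot(inherits(cm, "cell_means"))
  if (is.null(ctoas)) ctoas <- select_replication_ctoas(cm$ctoa)
  idx <- match(ctoas, cm$ctoa)
  if (anyNA(idx)) stop("requested CTOAs not on the grid", call. = FALSE)
  m <- length(ctoas)
  rows <- lapply(seq_along(idx), function(j) {
    d <- cm$cells[, idx[j], "invalid"] - cm$cells[, idx[j], "valid"]
    n <- length(d)
    se <- stats::sd(d) / sqrt(n)
    # manual paired t so that identical conditions give t = 0, p = 1
    tstat <- if (se == 0) { if (mean(d) == 0) 0 else sign(mean(d)) * Inf }
             else mean(d) / se
    p_raw <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
    p_adj <- min(1, p_raw * m)
    data.frame(ctoa = ctoas[j], mean_diff = mean(d),
               t = tstat, df = n - 1L,
               p_raw = p_raw, p_bonferroni = p_adj,
               significant = p_adj < 0.05, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
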