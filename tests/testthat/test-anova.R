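test_that("replication CTOAs are the nearest grid values, ties downward", {
  grid <- ctoa_grid(design_config())
  expect_equal(select_replication_ctoas(grid),
               c(0.042, 0.084, 0.210, 0.294, 0.504))
  grid50 <- seq(0.05, 0.5, by = 0.05)
  expect_equal(select_replication_ctoas(grid50),
               c(0.05, 0.10, 0.20, 0.30, 0.50))
  # exact tie: targets 0.15 between 0.1 and 0.2 -> lower value
  expect_equal(select_replication_ctoas(c(0.1, 0.2), targets = 0.15), 0.1)
  expect_error(select_replication_ctoas(grid50, targets = 0.9),
               "outside the grid")
})

# random fully-within fixture as a cell_means object: n participants,
# b CTOAs, 2 validities, with correlated cells
random_cells <- function(n, b, seed) {
  set.seed(seed)
  arr <- array(rnorm(n * b * 2), dim = c(n, b, 2),
               dimnames = list(sprintf("S%02d", 1:n), NULL,
                               c("valid", "invalid")))
  subj <- rnorm(n, sd = 0.8)
  arr <- arr + array(rep(subj, b * 2), dim = dim(arr))
  structure(list(ctoa = seq(0.042, by = 0.042, length.out = b),
                 participants = sprintf("S%02d", 1:n), cells = arr,
                 time_courses = NULL), class = "cell_means")
}

test_that("F statistics match an independent aov() error decomposition", {
  cm <- random_cells(12, 5, seed = 101)
  res <- rm_anova_validity_ctoa(cm, ctoas = cm$ctoa)
  long <- do.call(rbind, lapply(1:2, function(a)
    do.call(rbind, lapply(1:5, function(b)
      data.frame(id = cm$participants, y = cm$cells[, b, a],
                 validity = c("valid", "invalid")[a],
                 ctoa = factor(b))))))
  fit <- stats::aov(y ~ validity * ctoa + Error(id / (validity * ctoa)),
                    data = long)
  s <- summary(fit)
  f_aov <- c(s[["Error: id:validity"]][[1]]["validity", "F value"],
             s[["Error: id:ctoa"]][[1]]["ctoa", "F value"],
             s[["Error: id:validity:ctoa"]][[1]]["validity:ctoa", "F value"])
  expect_equal(res$F, unname(f_aov), tolerance = 1e-8)
})

test_that("GG epsilon matches the double-centering formula and car::Anova", {
  skip_if_not_installed("car")
  for (seed in c(7, 8)) {
    cm <- random_cells(15, 5, seed = seed)
    res <- rm_anova_validity_ctoa(cm, ctoas = cm$ctoa)
    # independent oracle 1: Box's double-centered covariance formula for the
    # CTOA main effect (levels averaged over validity)
    B <- (cm$cells[, , 1] + cm$cells[, , 2]) / 2
    S <- cov(B)
    Sstar <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
    eps_box <- sum(diag(Sstar))^2 / ((ncol(B) - 1) * sum(Sstar^2))
    expect_equal(res$gg_epsilon[res$effect == "ctoa"], eps_box,
                 tolerance = 1e-8)
    # independent oracle 2: car's multivariate repeated-measures machinery
    Y <- cbind(matrix(cm$cells[, , "valid"], nrow = 15),
               matrix(cm$cells[, , "invalid"], nrow = 15))
    idata <- expand.grid(ctoa = factor(1:5), validity = factor(1:2))
    mlm <- lm(Y ~ 1)
    A <- suppressWarnings(  # car warns when its HF epsilon exceeds 1
      summary(car::Anova(mlm, idata = idata,
                         idesign = ~ validity * ctoa, type = 3),
              multivariate = FALSE))
    uni <- A$univariate.tests
    eps <- A$pval.adjustments
    expect_equal(res$F[res$effect == "validity"],
                 unname(uni["validity", "F value"]), tolerance = 1e-8)
    expect_equal(res$F[res$effect == "ctoa"],
                 unname(uni["ctoa", "F value"]), tolerance = 1e-8)
    expect_equal(res$F[res$effect == "validity:ctoa"],
                 unname(uni["validity:ctoa", "F value"]), tolerance = 1e-8)
    expect_equal(res$gg_epsilon[res$effect == "ctoa"],
                 unname(eps["ctoa", "GG eps"]), tolerance = 1e-8)
    expect_equal(res$gg_epsilon[res$effect == "validity:ctoa"],
                 unname(eps["validity:ctoa", "GG eps"]), tolerance = 1e-8)
    expect_equal(res$p_gg[res$effect == "validity:ctoa"],
                 unname(eps["validity:ctoa", "Pr(>F[GG])"]), tolerance = 1e-8)
  }
})

test_that("near-spherical data yields epsilon near one", {
  cm <- random_cells(300, 5, seed = 55)  # iid cells -> sphericity holds
  res <- rm_anova_validity_ctoa(cm, ctoas = cm$ctoa)
  expect_gt(res$gg_epsilon[res$effect == "ctoa"], 0.9)
  expect_lte(max(res$gg_epsilon), 1 + 1e-12)
  # lower bound of epsilon is 1/(levels - 1)
  expect_gte(min(res$gg_epsilon), 1 / 4)
})

test_that("generalized eta squared is shift-invariant and bounded", {
  cm <- random_cells(12, 5, seed = 13)
  r1 <- rm_anova_validity_ctoa(cm, ctoas = cm$ctoa)
  cm$cells <- cm$cells + 100
  r2 <- rm_anova_validity_ctoa(cm, ctoas = cm$ctoa)
  expect_equal(r1$ges, r2$ges, tolerance = 1e-9)
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
  expect_true(all(r1$ges >= 0 & r1$ges <= 1))
  expect_equal(r1$df1_gg, r1$df1 * r1$gg_epsilon)
})

test_that("post-hoc Bonferroni uses a x5 multiplier capped at one", {
  # consistency with the published report: t(38) = 1.82 -> adjusted p ~ .38
  p_adj <- min(1, 2 * pt(1.82, 38, lower.tail = FALSE) * 5)
  expect_equal(round(p_adj, 2), 0.38)

  cm <- random_cells(10, 5, seed = 3)
  ph <- posthoc_bonferroni(cm, ctoas = cm$ctoa)
  expect_equal(nrow(ph), 5)
  expect_true(all(ph$p_bonferroni >= ph$p_raw))
  expect_true(all(ph$p_bonferroni <= 1))
  expect_equal(ph$p_bonferroni, pmin(1, ph$p_raw * 5))
  # identical conditions: t = 0, adjusted p = 1
  cm$cells[, , "invalid"] <- cm$cells[, , "valid"]
  ph0 <- posthoc_bonferroni(cm, ctoas = cm$ctoa)
  expect_equal(ph0$t, rep(0, 5))
  expect_equal(ph0$p_bonferroni, rep(1, 5))
})

test_that("a simulated cohort shows the facilitation-to-inhibition signature", {
  trials <- simulate_cohort(design_config(n_participants = 12L),
                            hybrid_truth(), noise_params(), master_seed = 23)
  prep <- preprocess(trials)
  res <- rm_anova_validity_ctoa(prep$cell_means)
  expect_lt(res$p_gg[res$effect == "validity:ctoa"], 0.001)
  ph <- posthoc_bonferroni(prep$cell_means)
  expect_gt(ph$t[1], 0)              # faster valid at the shortest CTOA
  expect_lt(ph$t[nrow(ph)], 0)       # inhibition at 504 ms
})
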