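# minimal hand-built trial frame: one participant, n_catch catch trials with
# n_fa responses, plus a few real trials
mini_trials <- function(id = "P01", n_catch = 60, n_fa = 12) {
  catch <- data.frame(participant_id = id, block = 1L,
                      trial = seq_len(n_catch), ctoa = NA_real_,
                      validity = NA_character_, is_catch = TRUE,
                      responded = c(rep(TRUE, n_fa), rep(FALSE, n_catch - n_fa)),
                      rt = NA_real_, stringsAsFactors = FALSE)
  catch$rt[catch$responded] <- 0.3
  real <- data.frame(participant_id = id, block = 1L,
                     trial = n_catch + 1:4, ctoa = c(0.042, 0.042, 0.084, 0.084),
                     validity = rep(c("valid", "invalid"), 2), is_catch = FALSE,
                     responded = TRUE, rt = c(0.30, 0.35, 0.32, 0.40),
                     stringsAsFactors = FALSE)
  rbind(catch, real)
}

test_that("screening applies the strictly-greater 20% false-alarm rule", {
  tr <- rbind(mini_trials("P01", 60, 12),   # rate exactly 0.20 -> retained
              mini_trials("P02", 60, 13),   # 0.2167 -> excluded
              mini_trials("P03", 60, 0))    # 0 -> retained
  sc <- screen_participants(tr)
  expect_equal(sc$false_alarm_rate, c(0.20, 13 / 60, 0))
  expect_identical(sc$excluded, c(FALSE, TRUE, FALSE))
  # no catch trials -> rate undefined, flagged with a reason
  no_catch <- mini_trials("P04", 60, 0)
  no_catch <- no_catch[!no_catch$is_catch, ]
  sc2 <- screen_participants(no_catch)
  expect_true(sc2$excluded)
  expect_true(is.na(sc2$false_alarm_rate))
  expect_match(sc2$reason, "undefined")
})

test_that("trial filters drop catch, misses and out-of-range RTs", {
  tr <- mini_trials()
  tr$rt[nrow(tr)] <- 2.4                    # beyond the deadline
  tr$rt[nrow(tr) - 1] <- 0.10               # anticipation
  out <- filter_trials(tr, filter_rules(min_rt = 0.15, max_rt = 2.0))
  expect_true(all(!out$is_catch))
  expect_true(all(out$responded))
  expect_true(all(out$rt >= 0.15 & out$rt <= 2.0))
  log <- attr(out, "filter_log")
  expect_equal(unname(log["catch"]), 60)
  expect_equal(unname(log["rt_range"]), 2)
  # an empty rule set is the identity
  id_rules <- filter_rules(drop_catch = FALSE, drop_misses = FALSE,
                           min_rt = 0, max_rt = Inf)
  expect_equal(nrow(filter_trials(tr, id_rules)), nrow(tr))
})

test_that("z-scaling is per participant, exact, and idempotent", {
  tr <- data.frame(participant_id = rep(c("A", "B"), each = 3),
                   block = 1L, trial = 1:6, ctoa = 0.042, validity = "valid",
                   is_catch = FALSE, responded = TRUE,
                   rt = c(1, 2, 3, 10, 20, 30), stringsAsFactors = FALSE)
  z <- zscore_rts(tr)
  expect_equal(z$z_rt[1:3], c(-1, 0, 1))            # sample SD convention
  # scale invariance: B is A times 10, so z-distributions are identical
  expect_equal(z$z_rt[4:6], z$z_rt[1:3])
  for (id in c("A", "B")) {
    expect_lt(abs(mean(z$z_rt[z$participant_id == id])), 1e-12)
    expect_equal(sd(z$z_rt[z$participant_id == id]), 1)
  }
  # idempotence: z-scaling already-z-scaled values changes nothing
  z2 <- z; z2$rt <- z$z_rt
  expect_equal(zscore_rts(z2)$z_rt, z$z_rt, tolerance = 1e-12)
  # degenerate inputs are rejected with a diagnostic
  flat <- tr; flat$rt <- 1
  expect_error(zscore_rts(flat), "zero RT variance")
})

test_that("cell means demand a complete grid and honor the Morey correction", {
  cfg <- small_design(4L)
  trials <- simulate_cohort(cfg, hybrid_truth(), noise_params(), master_seed = 9)
  prep <- preprocess(trials)
  cm <- prep$cell_means
  expect_equal(dim(cm$cells), c(4, 25, 2))
  # grand average is the unweighted mean over participants
  tc_valid <- cm$time_courses[cm$time_courses$condition == "valid", ]
  expect_equal(tc_valid$mean, colMeans(cm$cells[, , "valid"]))
  # additive participant offsets leave the within-subject SE unchanged
  tr2 <- prep$trials
  offs <- c(0, 0.5, -0.3, 1.2)[match(tr2$participant_id, unique(tr2$participant_id))]
  tr2$z_rt <- tr2$z_rt + offs
  cm2 <- cell_means(tr2)
  expect_equal(cm2$time_courses$se, cm$time_courses$se, tolerance = 1e-10)
  # single participant: SE is zero by convention
  one <- preprocess(simulate_cohort(small_design(1L), hybrid_truth(),
                                    noise_params(false_alarm_rate = 0.05),
                                    master_seed = 2))
  expect_true(all(one$cell_means$time_courses$se == 0))
  # an emptied cell aborts with a diagnostic
  tr3 <- prep$trials
  tr3 <- tr3[!(tr3$participant_id == tr3$participant_id[1] &
                 tr3$ctoa == 0.042 & tr3$validity == "valid"), ]
  expect_error(cell_means(tr3), "empty design cells")
})

test_that("difference course is linear in participants with the right sign", {
  cfg <- small_design(4L)
  dc <- sim_diff_course(cfg, hybrid_truth(), noise_params(), seed = 9)
  # grand average equals the mean of per-participant differences
  expect_equal(dc$diff, unname(colMeans(dc$per_participant)))
  # faster valid responses at the shortest CTOA -> positive difference
  expect_gt(dc$diff[1], 0)
  # identical conditions -> exactly zero difference
  tr <- data.frame(participant_id = rep(c("A", "B"), each = 8),
                   block = 1L, trial = 1:16,
                   ctoa = rep(rep(c(0.042, 0.084), each = 2), 4),
                   validity = rep(c("valid", "invalid"), 8),
                   is_catch = FALSE, responded = TRUE,
                   rt = rep(c(0.3, 0.3, 0.4, 0.4), 4),
                   stringsAsFactors = FALSE)
  z <- zscore_rts(tr)
  dc0 <- difference_course(cell_means(z))
  expect_equal(dc0$diff, rep(0, 2))
})

test_that("excluding one participant never changes another's cells", {
  cfg <- small_design(3L)
  trials <- simulate_cohort(cfg, hybrid_truth(), noise_params(), master_seed = 4)
  cm_all <- preprocess(trials)$cell_means
  drop_id <- cm_all$participants[1]
  cm_sub <- preprocess(trials[trials$participant_id != drop_id, ])$cell_means
  keep <- setdiff(cm_all$participants, drop_id)
  expect_equal(cm_all$cells[keep, , ], cm_sub$cells[keep, , ])
})
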