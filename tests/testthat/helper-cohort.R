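# shared fixture builders -- everything is generated in code at test time

# reference design (25 CTOAs x 2 x 12 + 60 catch = 660 trials, 39 participants)
ref_design <- function(...) design_config(...)

# small design for fast pipeline-level tests
small_design <- function(n_participants = 6L) {
  design_config(n_ctoas = 25L, trials_per_cell = 6L, n_catch = 12L,
                n_blocks = 6L, n_participants = n_participants)
}

# deterministic, noise-free generator settings
noise_free <- function() {
  noise_params(participant_intercept_sd = 0, participant_scale_sd = 0,
               trial_sd = 0, false_alarm_rate = 0, miss_rate = 0)
}

# simulate + preprocess a cohort, returning the difference course
sim_diff_course <- function(cfg, effect, noise = noise_params(), seed = 1L) {
  trials <- simulate_cohort(cfg, effect, noise, master_seed = seed)
  preprocess(trials)$diff_course
}

# reference grand-average hybrid estimates (difference curve of record)
hybrid_truth <- function() effect_params(b0 = -0.48, N0 = 0.82, tau = 0.18,
                                         a = 0.14, f = 1.05, phi = 0.72)

exp_truth <- function() effect_params(b0 = -0.51, N0 = 1.10, tau = 0.18,
                                      a = 0, f = 0, phi = 0)
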