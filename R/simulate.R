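#' Simulate one participant's session
#'
#' Draws trial-level responses for a realized schedule. Non-catch RTs are the
#' participant's baseline plus the condition effect (`-d(t)/2` for valid,
#' `+d(t)/2` for invalid, so invalid minus valid equals `d(t)` in expectation)
#' plus trial noise; targets are missed with probability `miss_rate`. Catch
#' trials are responded to with probability `false_alarm_rate`. RTs are
#' clipped to `(0, response_deadline]`. Fully reproducible under a seed.
#'
#' @param schedule Output of [build_schedule()].
#' @param effect An [effect_params()].
#' @param noise A [noise_params()].
#' @param seed Integer seed for the response draws.
#' @param participant_id Identifier stored in the output.
#' @param response_deadline Response window in seconds.
#' @return The schedule with columns `participant_id`, `responded` (logical)
#'   and `rt` (seconds, `NA` when no response) appended.
#' @export
simulate_participant <- function(schedule, effect, noise, seed,
                                 participant_id = "P01",
                                 response_deadline = 2.0) {
  stopifnot(inherits(effect, "effect_params"), inherits(noise, "noise_params"))
  n <- nrow(schedule)
  rng <- local_rng(seed)

  b_i <- rng$rnorm(1, 0, noise$participant_intercept_sd)
  s_i <- exp(rng$rnorm(1, 0, noise$participant_scale_sd))
  eps <- if (noise$rt_distribution == "normal") {
    rng$rnorm(n)
  } else {
    # standardized shifted lognormal (sdlog 0.5): right-skewed, mean 0, sd 1
    x <- rng$rlnorm(n, meanlog = 0, sdlog = 0.5)
    (x - exp(0.125)) / sqrt((exp(0.25) - 1) * exp(0.25))
  }
  u_resp <- rng$runif(n)

  cond <- ifelse(schedule$validity == "invalid", 1, -1)
  d <- rep(0, n)
  ok <- !schedule$is_catch
  d[ok] <- difference_curve(schedule$ctoa[ok], effect)

  rt <- noise$base_rt_mean + b_i +
    s_i * (noise$rt_sd_ref * ifelse(ok, cond, 0) * d / 2 + noise$trial_sd * eps)
  rt <- pmin(pmax(rt, 1e-3), response_deadline)

  responded <- ifelse(ok, u_resp >= noise$miss_rate, u_resp < noise$false_alarm_rate)
  rt[!responded] <- NA_real_

  out <- schedule
  out$participant_id <- as.character(participant_id)
  out$responded <- responded
  out$rt <- rt
  out[, c("participant_id", "block", "trial", "ctoa", "validity",
          "is_catch", "responded", "rt")]
}

#' Simulate a full cohort
#'
#' Builds a fresh counterbalanced schedule and response set per participant.
#' Per-participant seeds are derived from the master seed by a fixed rule:
#' schedule seed `master_seed + i`, response seed `master_seed + 500000 + i`
#' for participant index `i`, so cohorts are reproducible piecewise.
#'
#' @param cfg A [design_config()].
#' @param effect An [effect_params()].
#' @param noise A [noise_params()].
#' @param master_seed Integer master seed (keep below ~2^30).
#' @param participant_ids Optional character vector of ids; defaults to
#'   `"P01"`, `"P02"`, ... Duplicates are rejected.
#' @return Trial data frame for all participants (rows stacked by participant).
#' @examples
#' trials <- simulate_cohort(design_config(n_participants = 2),
#'                           effect_params(), noise_params(), master_seed = 7)
#' table(trials$participant_id)
#' @export
simulate_cohort <- function(cfg, effect = effect_params(),
                            noise = noise_params(), master_seed = 1L,
                            participant_ids = NULL) {
  validate_design(cfg)
  if (is.null(participant_ids))
    participant_ids <- sprintf("P%02d", seq_len(cfg$n_participants))
  if (anyDuplicated(participant_ids))
    stop("duplicate participant ids", call. = FALSE)
  if (length(participant_ids) != cfg$n_participants)
    stop("participant_ids length must equal n_participants", call. = FALSE)

  out <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    sch <- build_schedule(cfg, seed = master_seed + i)
    out[[i]] <- simulate_participant(
      sch, effect, noise, seed = master_seed + 500000L + i,
      participant_id = participant_ids[i],
      response_deadline = cfg$response_deadline)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write trials to the package CSV dialect
#'
#' Columns, in order: `participant_id`, `block`, `trial`, `ctoa_ms` (integer,
#' empty for catch), `validity` (`valid`/`invalid`, empty for catch),
#' `is_catch` (0/1), `responded` (0/1), `rt_ms` (float, empty when no
#' response). CTOAs are stored in milliseconds on disk and converted to
#' seconds when read back. Output is byte-stable for identical input.
#'
#' @param trials Trial data frame as produced by [simulate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  df <- data.frame(
    participant_id = trials$participant_id,
    block = trials$block,
    trial = trials$trial,
    ctoa_ms = ifelse(is.na(trials$ctoa), "", as.character(as.integer(round(trials$ctoa * 1000)))),
    validity = ifelse(is.na(trials$validity), "", trials$validity),
    is_catch = as.integer(trials$is_catch),
    responded = as.integer(trials$responded),
    rt_ms = ifelse(is.na(trials$rt), "", sprintf("%.3f", trials$rt * 1000)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read trials from the package CSV dialect
#'
#' @param path CSV file written by [write_trials_csv()] (or any file in the
#'   same dialect).
#' @return Trial data frame with `ctoa` and `rt` in seconds and logical
#'   `is_catch`/`responded` columns.
#' @export
read_trials_csv <- function(path) {
  needed <- c("participant_id", "block", "trial", "ctoa_ms", "validity",
              "is_catch", "responded", "rt_ms")
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  missing <- setdiff(needed, header)
  if (length(missing))
    stop("malformed trial CSV; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       validity = "character"))
  data.frame(
    participant_id = df$participant_id,
    block = as.integer(df$block),
    trial = as.integer(df$trial),
    ctoa = suppressWarnings(as.numeric(df$ctoa_ms)) / 1000,
    validity = ifelse(df$validity == "" | is.na(df$validity), NA_character_, df$validity),
    is_catch = as.integer(df$is_catch) == 1L,
    responded = as.integer(df$responded) == 1L,
    rt = suppressWarnings(as.numeric(df$rt_ms)) / 1000,
    stringsAsFactors = FALSE
  )
}
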