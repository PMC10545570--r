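#' Screen participants by catch-trial false alarms
#'
#' The false-alarm rate is the proportion of catch trials with a response.
#' Participants whose rate strictly exceeds the criterion are flagged for
#' exclusion; participants with no catch trials have an undefined rate and are
#' flagged with a reason.
#'
#' @param trials Trial data frame (see [simulate_cohort()] / [read_trials_csv()]).
#' @param max_false_alarm Exclusion criterion; rates strictly greater are
#'   excluded. Default 0.20.
#' @return Data frame with one row per participant: `participant_id`,
#'   `n_catch`, `n_false_alarms`, `false_alarm_rate`, `excluded`, `reason`.
#' @export
screen_participants <- function(trials, max_false_alarm = 0.20) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id & trials$is_catch, ]
    n_catch <- nrow(tr)
    n_fa <- sum(tr$responded)
    if (n_catch == 0L) {
      data.frame(participant_id = id, n_catch = 0L, n_false_alarms = 0L,
                 false_alarm_rate = NA_real_, excluded = TRUE,
                 reason = "no catch trials: false-alarm rate undefined",
                 stringsAsFactors = FALSE)
    } else {
      rate <- n_fa / n_catch
      excl <- rate > max_false_alarm
      data.frame(participant_id = id, n_catch = n_catch, n_false_alarms = n_fa,
                 false_alarm_rate = rate, excluded = excl,
                 reason = if (excl)
                   sprintf("false-alarm rate %.3f > %.2f", rate, max_false_alarm)
                 else "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trial filtering rules
#'
#' @param drop_catch Drop catch trials (they carry no RT of interest).
#' @param drop_misses Drop non-catch trials without a response.
#' @param min_rt Anticipation threshold in seconds; responded trials faster
#'   than this are dropped.
#' @param max_rt Upper RT limit in seconds (the response deadline).
#' @return A list of class `filter_rules`.
#' @export
filter_rules <- function(drop_catch = TRUE, drop_misses = TRUE,
                         min_rt = 0.15, max_rt = 2.0) {
  structure(list(drop_catch = drop_catch, drop_misses = drop_misses,
                 min_rt = min_rt, max_rt = max_rt), class = "filter_rules")
}

#' Filter trials before normalization
#'
#' Applies the configured rules in a fixed order (catch, misses, RT range) and
#' records how many trials each rule removed in the `"filter_log"` attribute.
#'
#' @param trials Trial data frame.
#' @param rules A [filter_rules()].
#' @return Retained trials, with a `filter_log` attribute (named integer
#'   vector of removal counts).
#' @export
filter_trials <- function(trials, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  log <- c(catch = 0L, miss = 0L, rt_range = 0L)
  keep <- rep(TRUE, nrow(trials))
  if (rules$drop_catch) {
    drop <- trials$is_catch
    log["catch"] <- sum(keep & drop); keep <- keep & !drop
  }
  if (rules$drop_misses) {
    drop <- !trials$is_catch & !trials$responded
    log["miss"] <- sum(keep & drop); keep <- keep & !drop
  }
  drop <- !is.na(trials$rt) & (trials$rt < rules$min_rt | trials$rt > rules$max_rt)
  log["rt_range"] <- sum(keep & drop); keep <- keep & !drop
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- log
  out
}

#' Z-scale RTs within participants
#'
#' Each participant's retained RTs are centered on that participant's mean and
#' divided by that participant's (sample) standard deviation, pooling over all
#' CTOAs and validity conditions.
#'
#' @param trials Filtered trial data frame (responded, non-catch).
#' @return `trials` with a `z_rt` column added.
#' @export
zscore_rts <- function(trials) {
  if (any(is.na(trials$rt)))
    stop("zscore_rts expects responded trials only; filter first", call. = FALSE)
  out <- trials
  out$z_rt <- NA_real_
  for (id in unique(trials$participant_id)) {
    idx <- trials$participant_id == id
    if (sum(idx) < 2L)
      stop("participant ", id, " has fewer than 2 retained trials", call. = FALSE)
    s <- stats::sd(trials$rt[idx])
    if (s == 0)
      stop("participant ", id, " has zero RT variance; cannot z-scale", call. = FALSE)
    out$z_rt[idx] <- (trials$rt[idx] - mean(trials$rt[idx])) / s
  }
  out
}

#' Per-participant cell means and condition time courses
#'
#' Averages a value column per participant, CTOA and validity, then forms the
#' grand-average time course per condition (unweighted mean over participants)
#' with Cousineau-Morey within-subject standard errors: each participant's
#' cells are centered on their own mean over all cells and shifted to the
#' grand mean, the per-cell SD over participants is divided by sqrt(n), and
#' the result is inflated by sqrt(M/(M-1)) with M the number of cells.
#'
#' @param trials Trial data frame with a `z_rt` column (or set
#'   `value = "rt"` to average raw RTs).
#' @param value Name of the column to average.
#' @return List of class `cell_means`: `ctoa` (grid, seconds), `participants`,
#'   `cells` (3-d array participant x ctoa x validity), and `time_courses`,
#'   a data frame (`condition`, `ctoa`, `mean`, `se`, `n_participants`).
#' @export
cell_means <- function(trials, value = "z_rt") {
  if (!value %in% names(trials))
    stop("column '", value, "' not found; run zscore_rts() first?", call. = FALSE)
  keep <- !trials$is_catch
  tr <- trials[keep, , drop = FALSE]
  grid <- sort(unique(tr$ctoa))
  ids <- unique(tr$participant_id)
  conds <- c("valid", "invalid")
  arr <- array(NA_real_, dim = c(length(ids), length(grid), 2),
               dimnames = list(ids, NULL, conds))
  means <- tapply(tr[[value]],
                  list(factor(tr$participant_id, ids),
                       factor(tr$ctoa, grid),
                       factor(tr$validity, conds)),
                  mean)
  arr[] <- means
  if (anyNA(arr)) {
    bad <- which(is.na(arr), arr.ind = TRUE)
    stop("empty design cells (no retained trials), e.g. participant ",
         ids[bad[1, 1]], ", CTOA ", round(grid[bad[1, 2]] * 1000), " ms, ",
         conds[bad[1, 3]], "; the analyses need a complete grid", call. = FALSE)
  }

  n <- length(ids); M <- length(grid) * 2
  # Cousineau normalization over all M cells, then Morey's M/(M-1) inflation
  subj_mean <- apply(arr, 1, mean)
  grand <- mean(arr)
  centered <- sweep(arr, 1, subj_mean) + grand
  se <- apply(centered, c(2, 3), function(x)
    if (n > 1) stats::sd(x) / sqrt(n) else 0) * sqrt(M / (M - 1))
  tc <- do.call(rbind, lapply(conds, function(cc)
    data.frame(condition = cc, ctoa = grid,
               mean = apply(arr[, , cc, drop = FALSE], 2, mean),
               se = se[, cc], n_participants = n,
               stringsAsFactors = FALSE)))
  rownames(tc) <- NULL
  structure(list(ctoa = grid, participants = ids, cells = arr,
                 time_courses = tc), class = "cell_means")
}

#' Invalid-minus-valid difference time course
#'
#' @param cm A [cell_means()] result.
#' @return List of class `difference_course`: `ctoa` (seconds), `diff` (grand
#'   average invalid minus valid, columnwise mean of `per_participant`), `se`
#'   (between-participant SE of the paired differences), `per_participant`
#'   (participants x CTOAs matrix), `n_participants`. Positive values mean
#'   faster valid than invalid responses (facilitation of the cued location).
#' @export
difference_course <- function(cm) {
  stopifnot(inherits(cm, "cell_means"))
  per <- cm$cells[, , "invalid", drop = FALSE][, , 1] -
    cm$cells[, , "valid", drop = FALSE][, , 1]
  per <- matrix(per, nrow = length(cm$participants),
                dimnames = list(cm$participants, NULL))
  n <- nrow(per)
  structure(list(
    ctoa = cm$ctoa,
    diff = colMeans(per),
    se = if (n > 1) apply(per, 2, stats::sd) / sqrt(n) else rep(0, ncol(per)),
    per_participant = per,
    n_participants = n
  ), class = "difference_course")
}

#' One-call preprocessing pipeline
#'
#' Screens participants on catch-trial false alarms, drops excluded
#' participants, filters trials, z-scales RTs within participants, and builds
#' condition time courses and the invalid-minus-valid difference course.
#'
#' @param trials Trial data frame.
#' @param rules A [filter_rules()].
#' @param max_false_alarm Screening criterion (strictly-greater exclusion).
#' @return List: `screen`, `filter_log`, `trials` (retained, z-scaled),
#'   `cell_means`, `diff_course`.
#' @export
preprocess <- function(trials, rules = filter_rules(), max_false_alarm = 0.20) {
  screen <- screen_participants(trials, max_false_alarm)
  keep_ids <- screen$participant_id[!screen$excluded]
  if (!length(keep_ids))
    stop("all participants excluded during screening", call. = FALSE)
  tr <- trials[trials$participant_id %in% keep_ids, , drop = FALSE]
  tr <- filter_trials(tr, rules)
  log <- attr(tr, "filter_log")
  tr <- zscore_rts(tr)
  cm <- cell_means(tr, value = "z_rt")
  list(screen = screen, filter_log = log, trials = tr,
       cell_means = cm, diff_course = difference_course(cm))
}
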