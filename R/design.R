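#' Experimental design configuration
#'
#' Describes a dense-sampling exogenous cueing detection experiment: a uniform
#' grid of cue-target onset asynchronies (CTOAs), two cue-validity conditions,
#' a fixed number of trials per CTOA-by-validity cell, and target-absent catch
#' trials, all counterbalanced at block level.
#'
#' Defaults reproduce the reference design: 25 CTOAs from 42 ms to 1050 ms in
#' 42 ms steps, 12 trials per cell, 60 catch trials (9.1%), 6 blocks,
#' 39 participants, 2 s response deadline -- 660 trials per participant.
#'
#' @param ctoa_min First CTOA in seconds.
#' @param ctoa_step CTOA grid spacing in seconds.
#' @param n_ctoas Number of CTOAs on the grid.
#' @param trials_per_cell Trials per CTOA-by-validity cell (must be divisible
#'   by `n_blocks`).
#' @param n_catch Number of catch (target-absent) trials (must be divisible by
#'   `n_blocks`).
#' @param n_blocks Number of blocks for counterbalancing.
#' @param n_participants Cohort size.
#' @param response_deadline Response window in seconds.
#' @return An object of class `design_config`.
#' @examples
#' cfg <- design_config()
#' length(ctoa_grid(cfg))       # 25
#' n_trials_total(cfg)          # 660
#' @export
design_config <- function(ctoa_min = 0.042, ctoa_step = 0.042, n_ctoas = 25L,
                          trials_per_cell = 12L, n_catch = 60L, n_blocks = 6L,
                          n_participants = 39L, response_deadline = 2.0) {
  cfg <- list(
    ctoa_min = as.numeric(ctoa_min), ctoa_step = as.numeric(ctoa_step),
    n_ctoas = as.integer(n_ctoas), trials_per_cell = as.integer(trials_per_cell),
    validities = c("valid", "invalid"),
    n_catch = as.integer(n_catch), n_blocks = as.integer(n_blocks),
    n_participants = as.integer(n_participants),
    response_deadline = as.numeric(response_deadline)
  )
  class(cfg) <- "design_config"
  validate_design(cfg)
  cfg
}

validate_design <- function(cfg) {
  stopifnot(inherits(cfg, "design_config"))
  if (cfg$ctoa_min <= 0 || cfg$ctoa_step <= 0)
    stop("CTOA grid must be strictly positive", call. = FALSE)
  if (cfg$n_ctoas < 1L || cfg$trials_per_cell < 1L || cfg$n_blocks < 1L)
    stop("counts must be positive", call. = FALSE)
  if (cfg$n_catch < 0L)
    stop("n_catch must be non-negative", call. = FALSE)
  if (max(ctoa_grid(cfg)) >= cfg$response_deadline)
    stop("longest CTOA must fall inside the response deadline", call. = FALSE)
  invisible(cfg)
}

#' CTOA grid of a design
#'
#' @param cfg A [design_config()].
#' @return Numeric vector of CTOAs in seconds, `ctoa_min + (0:(n_ctoas-1)) * ctoa_step`.
#' @export
ctoa_grid <- function(cfg) {
  cfg$ctoa_min + (seq_len(cfg$n_ctoas) - 1L) * cfg$ctoa_step
}

#' Total trials per participant implied by a design
#'
#' @param cfg A [design_config()].
#' @return Integer count: cells times trials per cell, plus catch trials.
#' @export
n_trials_total <- function(cfg) {
  cfg$n_ctoas * length(cfg$validities) * cfg$trials_per_cell + cfg$n_catch
}

#' Build a counterbalanced, seeded trial schedule
#'
#' Produces the realized trial list for one participant. Every block contains
#' an equal share of each CTOA-by-validity cell and of catch trials; the order
#' within each block is a seeded random permutation, so two calls with the same
#' seed are identical.
#'
#' @param cfg A [design_config()].
#' @param seed Integer seed for the within-block shuffles.
#' @return A data frame with one row per trial: `block`, `trial` (within
#'   block), `ctoa` (seconds, `NA` for catch trials), `validity`
#'   (`"valid"`/`"invalid"`, `NA` for catch), `is_catch` (logical).
#' @examples
#' sch <- build_schedule(design_config(), seed = 1)
#' nrow(sch)            # 660
#' sum(sch$is_catch)    # 60
#' @export
build_schedule <- function(cfg, seed) {
  validate_design(cfg)
  if (cfg$trials_per_cell %% cfg$n_blocks != 0L)
    stop("trials_per_cell (", cfg$trials_per_cell,
         ") is not divisible by n_blocks (", cfg$n_blocks,
         "); cells cannot be counterbalanced across blocks", call. = FALSE)
  if (cfg$n_catch %% cfg$n_blocks != 0L)
    stop("n_catch (", cfg$n_catch, ") is not divisible by n_blocks (",
         cfg$n_blocks, "); catch trials cannot be spread equally", call. = FALSE)

  grid <- ctoa_grid(cfg)
  per_block_cell <- cfg$trials_per_cell %/% cfg$n_blocks
  per_block_catch <- cfg$n_catch %/% cfg$n_blocks

  block_ctoa <- rep(rep(grid, each = length(cfg$validities)), times = per_block_cell)
  block_validity <- rep(rep(cfg$validities, times = cfg$n_ctoas), times = per_block_cell)
  block_ctoa <- c(block_ctoa, rep(NA_real_, per_block_catch))
  block_validity <- c(block_validity, rep(NA_character_, per_block_catch))
  block_catch <- c(rep(FALSE, length(block_ctoa) - per_block_catch),
                   rep(TRUE, per_block_catch))

  rng <- local_rng(seed)
  blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
    ord <- rng$sample(length(block_ctoa))
    data.frame(
      block = b,
      trial = seq_along(ord),
      ctoa = block_ctoa[ord],
      validity = block_validity[ord],
      is_catch = block_catch[ord],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

# Self-contained RNG stream: isolates package randomness from the caller's
# .Random.seed and makes derived streams explicit.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  }
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr
  }
  list(
    sample = function(n, size = n) with_state(sample.int(n, size)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    rlnorm = function(n, meanlog = 0, sdlog = 1) with_state(stats::rlnorm(n, meanlog, sdlog)),
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max))
  )
}
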