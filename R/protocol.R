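#' Protocol specification for a 2AFC frequency-discrimination block
#'
#' Describes one experimental protocol for two-tone frequency discrimination.
#' In the reference-containing protocols every trial pairs a constant
#' reference tone with a staircase-controlled comparison tone; the protocols
#' differ in where the reference may appear and whether the comparison may be
#' lower as well as higher:
#'
#' * `"reference_lower"`: the reference is always the lower tone; its
#'   interval (first or second) is randomized per trial.
#' * `"reference"`: both the reference interval and whether the comparison is
#'   higher or lower are randomized independently, so the reference interval
#'   and the higher interval are uncorrelated.
#' * `"reference_first"`: the reference always occupies the first interval;
#'   the comparison may be higher or lower.
#' * `"reference_higher"`: the reference is always the higher tone; its
#'   interval is randomized.
#' * `"no_reference"`: no repeated reference; one tone is drawn uniformly
#'   from `no_reference_range_hz` and the other differs by the
#'   staircase-controlled percentage.
#'
#' @param name Protocol name, one of the five above.
#' @param reference_hz Frequency of the constant reference tone in Hz.
#' @param block_length Number of trials per block.
#' @param no_reference_range_hz Length-2 numeric, the uniform sampling range
#'   (Hz) for the base tone in the no-reference protocol.
#' @return An object of class `protocol_spec`.
#' @examples
#' protocol_spec("reference_lower")
#' @export
protocol_spec <- function(name = c("reference_lower", "reference", "no_reference",
                                   "reference_first", "reference_higher"),
                          reference_hz = 1000,
                          block_length = 80,
                          no_reference_range_hz = c(800, 1200)) {
  name <- match.arg(name)
  if (!is.numeric(reference_hz) || length(reference_hz) != 1 || reference_hz <= 0)
    stop("`reference_hz` must be a single positive number", call. = FALSE)
  if (!is.numeric(block_length) || length(block_length) != 1 || block_length < 1)
    stop("`block_length` must be a positive trial count", call. = FALSE)
  if (length(no_reference_range_hz) != 2 ||
      no_reference_range_hz[1] >= no_reference_range_hz[2] ||
      no_reference_range_hz[1] <= 0)
    stop("`no_reference_range_hz` must be (low, high) with 0 < low < high", call. = FALSE)
  structure(
    list(name = name,
         reference_hz = reference_hz,
         block_length = as.integer(block_length),
         no_reference_range_hz = as.numeric(no_reference_range_hz)),
    class = "protocol_spec"
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol_spec>", x$name,
      sprintf("| reference %g Hz | %d trials/block\n", x$reference_hz, x$block_length))
  invisible(x)
}

#' Initialize a 3-down-1-up adaptive staircase
#'
#' The staircase tracks the percent frequency difference between the two
#' tones of a trial. Difficulty decreases (difference shrinks) after three
#' consecutive correct responses and increases after every error, converging
#' on the stimulus level at which p^3 = 0.5, i.e. 79.4% correct. The step
#' size shrinks after every fourth reversal of movement direction, walking
#' down `step_schedule`.
#'
#' @param initial_diff_percent Starting frequency difference, percent of the
#'   reference (default 20).
#' @param step_schedule Strictly decreasing step sizes in percent; the
#'   default schedule is 4.5, 2, 1, 0.5, 0.1.
#' @param min_diff_percent Floor for the tracked difference, by default the
#'   smallest schedule step. Prevents non-positive differences.
#' @param max_diff_percent Ceiling for the tracked difference (default 99).
#'   Keeps a comparison tone placed below the reference at a positive
#'   frequency even when a near-chance responder drives the track upward.
#' @return A `staircase_state` list with fields `diff_percent`,
#'   `step_percent`, `step_index`, `n_reversals`, `consecutive_correct`,
#'   `last_direction` (`"none"`, `"up"` or `"down"`), `step_schedule`,
#'   `min_diff_percent`.
#' @export
init_staircase <- function(initial_diff_percent = 20,
                           step_schedule = c(4.5, 2, 1, 0.5, 0.1),
                           min_diff_percent = min(step_schedule),
                           max_diff_percent = 99) {
  if (!is.numeric(initial_diff_percent) || length(initial_diff_percent) != 1 ||
      initial_diff_percent <= 0)
    stop("`initial_diff_percent` must be a single positive percentage", call. = FALSE)
  if (length(step_schedule) < 1 || any(step_schedule <= 0) ||
      (length(step_schedule) > 1 && any(diff(step_schedule) >= 0)))
    stop("`step_schedule` must be non-empty, positive and strictly decreasing",
         call. = FALSE)
  structure(
    list(diff_percent = initial_diff_percent,
         step_percent = step_schedule[1],
         step_index = 1L,
         n_reversals = 0L,
         consecutive_correct = 0L,
         last_direction = "none",
         step_schedule = step_schedule,
         min_diff_percent = min_diff_percent,
         max_diff_percent = max_diff_percent),
    class = "staircase_state"
  )
}

#' Advance the staircase after one response
#'
#' An incorrect response moves the track up by the current step; a third
#' consecutive correct response moves it down by the current step (never
#' below the floor); other correct responses only increment the run counter.
#' A reversal is counted whenever a movement's direction differs from the
#' previous movement's (the first movement sets the direction without
#' counting one). After the 4th, 8th, 12th and 16th reversal the step size
#' advances to the next schedule entry, taking effect on the following
#' movement; it stays at the last entry thereafter.
#'
#' @param state A `staircase_state` from [init_staircase()].
#' @param correct Logical, was the response correct?
#' @return The updated `staircase_state`.
#' @export
update_staircase <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct), length(correct) == 1,
            !is.na(correct))
  direction <- NULL
  if (!correct) {
    state$diff_percent <- min(state$max_diff_percent,
                              state$diff_percent + state$step_percent)
    state$consecutive_correct <- 0L
    direction <- "up"
  } else if (state$consecutive_correct == 2L) {
    state$diff_percent <- max(state$min_diff_percent,
                              state$diff_percent - state$step_percent)
    state$consecutive_correct <- 0L
    direction <- "down"
  } else {
    state$consecutive_correct <- state$consecutive_correct + 1L
  }
  if (!is.null(direction)) {
    if (state$last_direction != "none" && direction != state$last_direction) {
      state$n_reversals <- state$n_reversals + 1L
      if (state$n_reversals %% 4L == 0L)
        state$step_index <- min(state$step_index + 1L, length(state$step_schedule))
      state$step_percent <- state$step_schedule[state$step_index]
    }
    state$last_direction <- direction
  }
  state
}

#' Generate the two tones of one trial
#'
#' Draws the per-trial stimulus configuration for the given protocol at the
#' current staircase difference. The percent difference is applied
#' multiplicatively to the reference (comparison = ref * (1 +/- d/100)); in
#' the no-reference protocol the uniformly drawn base tone plays the
#' reference's role in that formula. Uses the current R random stream for the
#' per-trial coins.
#'
#' @param protocol A [protocol_spec()].
#' @param diff_percent Current frequency difference, percent (> 0).
#' @return A list with `x1`, `x2` (natural-log frequencies), `ref_position`
#'   (`"first"`, `"second"` or `"none"`), and `ref_hz` (the denominator tone
#'   for percent-difference bookkeeping). Responses are not filled in.
#' @export
make_trial <- function(protocol, diff_percent) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (!is.numeric(diff_percent) || length(diff_percent) != 1 || diff_percent <= 0)
    stop("`diff_percent` must be a single positive percentage", call. = FALSE)
  ref <- protocol$reference_hz
  d <- diff_percent / 100
  switch(protocol$name,
    reference_lower = {
      nonref <- ref * (1 + d)
      ref_first <- stats::runif(1) < 0.5
      list(x1 = log(if (ref_first) ref else nonref),
           x2 = log(if (ref_first) nonref else ref),
           ref_position = if (ref_first) "first" else "second",
           ref_hz = ref)
    },
    reference = {
      nonref <- ref * (1 + if (stats::runif(1) < 0.5) d else -d)
      ref_first <- stats::runif(1) < 0.5
      list(x1 = log(if (ref_first) ref else nonref),
           x2 = log(if (ref_first) nonref else ref),
           ref_position = if (ref_first) "first" else "second",
           ref_hz = ref)
    },
    reference_first = {
      nonref <- ref * (1 + if (stats::runif(1) < 0.5) d else -d)
      list(x1 = log(ref), x2 = log(nonref), ref_position = "first", ref_hz = ref)
    },
    reference_higher = {
      nonref <- ref * (1 - d)
      ref_first <- stats::runif(1) < 0.5
      list(x1 = log(if (ref_first) ref else nonref),
           x2 = log(if (ref_first) nonref else ref),
           ref_position = if (ref_first) "first" else "second",
           ref_hz = ref)
    },
    no_reference = {
      base <- stats::runif(1, protocol$no_reference_range_hz[1],
                           protocol$no_reference_range_hz[2])
      other <- base * (1 + if (stats::runif(1) < 0.5) d else -d)
      base_first <- stats::runif(1) < 0.5
      list(x1 = log(if (base_first) base else other),
           x2 = log(if (base_first) other else base),
           ref_position = "none",
           ref_hz = base)
    },
    stop("unknown protocol: ", protocol$name, call. = FALSE)
  )
}

#' Just-noticeable difference from a staircase block
#'
#' The discrimination threshold is estimated as the mean percent frequency
#' difference over the last 20 trials of the block, the conventional summary
#' for a staircase that has converged. The percent difference of a trial is
#' `100 * |f2 - f1| / ref_hz`, with the per-trial base tone serving as the
#' denominator in no-reference blocks.
#'
#' @param block A block data frame with columns `x1`, `x2` (log-Hz) and
#'   `ref_hz`, e.g. from [simulate_block()].
#' @param n_last Number of final trials to average (default 20).
#' @return The JND in percent.
#' @export
jnd_from_block <- function(block, n_last = 20) {
  stopifnot(is.data.frame(block))
  if (nrow(block) < n_last)
    stop("block has fewer than ", n_last, " trials", call. = FALSE)
  tail_idx <- seq.int(nrow(block) - n_last + 1L, nrow(block))
  with(block[tail_idx, ], mean(100 * abs(exp(x2) - exp(x1)) / ref_hz))
}
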