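#' Default contraction weights for the memory-trace observer
#'
#' The memory-trace model compares the second tone against a weighted
#' combination of the current first tone, the first tones of the `K` most
#' recent trials, and the running mean of all first tones in the block. The
#' weight vector shipped here is a package default, not an empirical
#' estimate: it is constrained to translation invariance in log-frequency
#' (a0 + sum(a_k) + c = 1 with b = -1, so adding a constant to every
#' log-frequency leaves choice probabilities unchanged) and parameterized by
#' the total contraction fraction gamma = sum(a_k) + c drawn away from the
#' current tone, the share of that contraction carried by the running mean,
#' and a geometric decay across lags.
#'
#' @param contraction Total weight gamma moved from the current first tone to
#'   history terms (default 0.35).
#' @param trace_share Fraction of `contraction` assigned to the running-mean
#'   term `c` (default 0.5).
#' @param decay Geometric decay ratio of the lag weights a_1..a_K (default 0.6).
#' @param n_lags Number of lag terms K (default 3).
#' @return A `trace_weights` list with fields `a0`, `a_hist`, `b`, `c`.
#' @examples
#' w <- default_trace_weights()
#' w$a0 + sum(w$a_hist) + w$c # translation invariance: equals -w$b
#' @export
default_trace_weights <- function(contraction = 0.35, trace_share = 0.5,
                                  decay = 0.6, n_lags = 3) {
  stopifnot(contraction >= 0, contraction < 1,
            trace_share >= 0, trace_share <= 1,
            decay > 0, n_lags >= 0)
  cc <- contraction * trace_share
  hist_total <- contraction - cc
  a_hist <- if (n_lags > 0) {
    raw <- decay^(seq_len(n_lags) - 1)
    raw / sum(raw) * hist_total
  } else numeric(0)
  trace_weights(a0 = 1 - contraction, a_hist = a_hist, b = -1, c = cc)
}

#' Construct an explicit weight vector for the linear history model
#'
#' @param a0 Weight on the current trial's first-tone log-frequency.
#' @param a_hist Ordered weights on the first tones of the 1..K most recent
#'   previous trials (most recent first); may be empty.
#' @param b Weight on the current second tone (negative for a comparison).
#' @param c Weight on the running mean of past first tones.
#' @return A `trace_weights` list.
#' @export
trace_weights <- function(a0, a_hist = numeric(0), b = -1, c = 0) {
  stopifnot(is.numeric(a0), length(a0) == 1, is.numeric(a_hist),
            is.numeric(b), length(b) == 1, is.numeric(c), length(c) == 1)
  structure(list(a0 = a0, a_hist = as.numeric(a_hist), b = b, c = c),
            class = "trace_weights")
}

#' Empty memory state for the start of a block
#'
#' Tracks the running mean of first-tone log-frequencies over completed
#' trials and the last `n_lags` first tones. Memory resets at block start;
#' blocks are modeled as independent.
#'
#' @param n_lags How many lagged first tones to retain.
#' @return A `memory_state` list with fields `m` (running mean, `NA` before
#'   the first trial), `n_seen`, and `x1_history` (most recent first).
#' @export
memory_state <- function(n_lags = 3) {
  structure(list(m = NA_real_, n_seen = 0L, x1_history = numeric(0),
                 n_lags = as.integer(n_lags)),
            class = "memory_state")
}

#' Update the memory state with a completed trial's first tone
#'
#' @param memstate A [memory_state()].
#' @param x1 Log-frequency of the first tone just heard.
#' @return The updated `memory_state`.
#' @export
update_memory <- function(memstate, x1) {
  stopifnot(inherits(memstate, "memory_state"), is.finite(x1))
  n <- memstate$n_seen
  memstate$m <- if (n == 0L) x1 else (n * memstate$m + x1) / (n + 1)
  memstate$n_seen <- n + 1L
  memstate$x1_history <- utils::head(c(x1, memstate$x1_history), memstate$n_lags)
  memstate
}

# Linear decision variable of the history model for a single trial.
# History terms that are not yet available early in the block (lags beyond
# the trials completed, and the running mean before any trial) self-anchor
# on the current x1: their weight falls on the tone itself, so trial 1 is
# exactly history-free and early trials are unbiased for weight vectors
# with a0 + sum(a_k) + c = -b.
linear_drive <- function(weights, memstate, x1, x2) {
  k <- length(weights$a_hist)
  avail <- min(k, length(memstate$x1_history))
  hist_term <- 0
  if (avail > 0)
    hist_term <- sum(weights$a_hist[seq_len(avail)] *
                       memstate$x1_history[seq_len(avail)])
  if (avail < k)
    hist_term <- hist_term + sum(weights$a_hist[seq.int(avail + 1, k)]) * x1
  m_term <- weights$c * (if (memstate$n_seen == 0L) x1 else memstate$m)
  weights$a0 * x1 + hist_term + weights$b * x2 + m_term
}

#' Choice probability of the full linear history model
#'
#' Probability that the observer reports "first tone higher" as the standard
#' normal CDF of a linear combination of the current tones, the recent first
#' tones, and the running mean of past first tones. Noise is absorbed in the
#' overall scale of the weights: larger weights mean a more deterministic
#' observer. History terms that do not exist yet early in the block
#' self-anchor on the current first tone, so trial 1 is history-free.
#'
#' @param weights A [trace_weights()] object.
#' @param memstate Memory state reflecting trials *before* the current one.
#' @param x1,x2 Log-frequencies of the current first and second tones.
#' @return Probability in (0, 1).
#' @export
p_first_higher_full <- function(weights, memstate, x1, x2) {
  stats::pnorm(linear_drive(weights, memstate, x1, x2))
}

#' Choice probability of the memory-trace observer
#'
#' One-parameter model: the linear combination is evaluated with a fixed
#' weight vector and divided by the observer's noise `sigma`; only `sigma`
#' is free when fitting.
#'
#' @param weights Fixed `trace_weights` (see [default_trace_weights()]).
#' @param sigma Observer noise in log-frequency units (> 0).
#' @inheritParams p_first_higher_full
#' @return Probability in (0, 1).
#' @export
p_first_higher_memory_trace <- function(weights, sigma, memstate, x1, x2) {
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  stats::pnorm(linear_drive(weights, memstate, x1, x2) / sigma)
}

#' Choice probability of the naive (history-free) observer
#'
#' @param sigma Observer noise in log-frequency units (> 0).
#' @param x1,x2 Log-frequencies of the two tones.
#' @return `pnorm((x1 - x2) / sigma)`.
#' @export
p_first_higher_naive <- function(sigma, x1, x2) {
  if (!is.numeric(sigma) || any(sigma <= 0))
    stop("`sigma` must be positive", call. = FALSE)
  stats::pnorm((x1 - x2) / sigma)
}

#' Choice probability of the response-bias observer
#'
#' History-free observer with a constant additive bias `beta` toward
#' responding "first tone higher" (a horizontal shift of the psychometric
#' function).
#'
#' @param sigma Observer noise (> 0).
#' @param beta Additive response bias on the probit scale.
#' @param x1,x2 Log-frequencies of the two tones.
#' @return `pnorm((x1 - x2) / sigma + beta)`.
#' @export
p_first_higher_response_bias <- function(sigma, beta, x1, x2) {
  if (!is.numeric(sigma) || any(sigma <= 0))
    stop("`sigma` must be positive", call. = FALSE)
  stats::pnorm((x1 - x2) / sigma + beta)
}

#' Sample a Bernoulli response from a choice probability
#'
#' @param probability Probability of responding "first tone higher", in \[0, 1\].
#' @return Logical: `TRUE` means the observer responded "first higher".
#' @export
sample_response <- function(probability) {
  if (!is.numeric(probability) || length(probability) != 1 ||
      is.na(probability) || probability < 0 || probability > 1)
    stop("`probability` must be a single value in [0, 1]", call. = FALSE)
  stats::runif(1) < probability
}

#' Construct a stochastic observer
#'
#' Bundles a model family with its parameters behind a single
#' probability-of-first-higher contract, so the block simulator and the
#' fitter are model-agnostic.
#'
#' @param model One of `"naive"`, `"memory_trace"`, `"response_bias"`,
#'   `"full_ln"`.
#' @param sigma Observer noise (required for all but `"full_ln"`).
#' @param beta Response bias (only `"response_bias"`).
#' @param weights `trace_weights` (only `"memory_trace"` and `"full_ln"`);
#'   defaults to [default_trace_weights()] for the memory-trace model.
#' @return An `observer` object.
#' @export
observer <- function(model = c("naive", "memory_trace", "response_bias", "full_ln"),
                     sigma = NULL, beta = 0, weights = NULL) {
  model <- match.arg(model)
  if (model != "full_ln") {
    if (is.null(sigma) || sigma <= 0)
      stop("`sigma` must be a positive number for the ", model, " observer",
           call. = FALSE)
  }
  if (model %in% c("memory_trace", "full_ln") && is.null(weights))
    weights <- default_trace_weights()
  structure(list(model = model, sigma = sigma, beta = beta, weights = weights),
            class = "observer")
}

#' Choice probability of an observer for the current trial
#'
#' @param obs An [observer()].
#' @param memstate Memory state over the block's previous trials.
#' @param x1,x2 Current log-frequencies.
#' @return Probability of responding "first tone higher".
#' @export
observer_probability <- function(obs, memstate, x1, x2) {
  stopifnot(inherits(obs, "observer"))
  switch(obs$model,
    naive = p_first_higher_naive(obs$sigma, x1, x2),
    memory_trace = p_first_higher_memory_trace(obs$weights, obs$sigma,
                                               memstate, x1, x2),
    response_bias = p_first_higher_response_bias(obs$sigma, obs$beta, x1, x2),
    full_ln = p_first_higher_full(obs$weights, memstate, x1, x2)
  )
}
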