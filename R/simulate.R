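# Closed-loop simulation of staircase experiments: the stand-in for raw
# behavioral data. Each block interleaves trial generation (protocol +
# staircase), the observer's stochastic response, and the staircase update,
# exactly as the analysis expects real sessions to have been run.

#' Simulate one 80-trial staircase block
#'
#' Runs the full closed loop: at each trial the current staircase difference
#' generates the two tones, the observer produces a response from its choice
#' probability given the block's stimulus history, correctness feeds back
#' into the 3-down-1-up staircase, and the first tone is appended to the
#' observer's memory. Memory resets at block start.
#'
#' @param protocol A [protocol_spec()].
#' @param obs An [observer()].
#' @param seed Integer seed for this block's random stream.
#' @param participant_id,block_id Labels recorded in the output.
#' @param initial_diff_percent,step_schedule Staircase settings (defaults:
#'   start 20%, steps 4.5/2/1/0.5/0.1%).
#' @return A data.frame with one row per trial: `participant`, `block`,
#'   `trial`, `x1`, `x2` (log-Hz), `ref_hz`, `ref_position`, `diff_percent`
#'   (the staircase level the trial was generated at),
#'   `response_first_higher`, `correct`. The block seed is attached as
#'   attribute `"seed"`.
#' @export
simulate_block <- function(protocol, obs, seed = NULL,
                           participant_id = "p1", block_id = 1L,
                           initial_diff_percent = 20,
                           step_schedule = c(4.5, 2, 1, 0.5, 0.1)) {
  stopifnot(inherits(protocol, "protocol_spec"), inherits(obs, "observer"))
  if (!is.null(seed)) set.seed(seed)
  n <- protocol$block_length
  sc <- init_staircase(initial_diff_percent, step_schedule)
  n_lags <- if (!is.null(obs$weights)) length(obs$weights$a_hist) else 0
  mem <- memory_state(n_lags = max(1, n_lags))
  x1 <- x2 <- ref_hz <- diff_percent <- numeric(n)
  ref_position <- character(n)
  resp <- corr <- logical(n)
  for (t in seq_len(n)) {
    tr <- make_trial(protocol, sc$diff_percent)
    p <- observer_probability(obs, mem, tr$x1, tr$x2)
    r <- sample_response(p)
    is_correct <- r == (tr$x1 > tr$x2)
    x1[t] <- tr$x1; x2[t] <- tr$x2
    ref_hz[t] <- tr$ref_hz; ref_position[t] <- tr$ref_position
    diff_percent[t] <- sc$diff_percent
    resp[t] <- r; corr[t] <- is_correct
    sc <- update_staircase(sc, is_correct)
    mem <- update_memory(mem, tr$x1)
  }
  out <- data.frame(participant = participant_id, block = block_id,
                    trial = seq_len(n), x1 = x1, x2 = x2,
                    ref_hz = ref_hz, ref_position = ref_position,
                    diff_percent = diff_percent,
                    response_first_higher = resp, correct = corr,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}

# deterministic per-block seed below 2^31, unique per (participant, block)
# for a fixed master seed
derive_seed <- function(master_seed, participant_index, block_index) {
  as.integer((as.double(master_seed) %% 65011 * 33013 +
                participant_index * 509 + block_index) %% 2147483647)
}

#' Simulate a complete multi-participant experiment
#'
#' Generates `n_participants * blocks_per_participant` blocks with
#' deterministic per-block seeds derived from `master_seed`, so the same
#' master seed reproduces the dataset bit-identically. The defaults mirror
#' the two study designs: 49 participants x 2 blocks (reference-lower) and
#' 152 participants x 1 block (reference).
#'
#' @param protocol A [protocol_spec()].
#' @param obs An [observer()], or a function `function(participant_index)`
#'   returning one (e.g. to give each simulated participant their own fitted
#'   noise).
#' @param n_participants Number of simulated participants.
#' @param blocks_per_participant Blocks per participant.
#' @param master_seed Integer master seed.
#' @param ... Passed to [simulate_block()] (staircase settings).
#' @return A trial table (rows from all blocks). The manifest — protocol,
#'   per-block seeds, observer description — is attached as attribute
#'   `"manifest"`.
#' @export
simulate_experiment <- function(protocol, obs, n_participants,
                                blocks_per_participant = 1,
                                master_seed = 1L, ...) {
  obs_for <- if (is.function(obs)) obs else function(i) obs
  rows <- vector("list", n_participants * blocks_per_participant)
  manifest <- data.frame(participant = character(0), block = integer(0),
                         seed = integer(0))
  k <- 0L
  for (i in seq_len(n_participants)) {
    pid <- sprintf("p%03d", i)
    obs_i <- obs_for(i)
    for (b in seq_len(blocks_per_participant)) {
      k <- k + 1L
      s <- derive_seed(master_seed, i, b)
      rows[[k]] <- simulate_block(protocol, obs_i, seed = s,
                                  participant_id = pid, block_id = b, ...)
      manifest <- rbind(manifest,
                        data.frame(participant = pid, block = b, seed = s))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest") <- list(protocol = protocol, master_seed = master_seed,
                                blocks = manifest)
  out
}

#' Simulate fitted observers and compare their splits to the source data
#'
#' The model-validation loop: for every block of the input datasets, fit the
#' memory-trace observer's noise by maximum likelihood; then re-run the full
#' staircase experiment with one simulated participant per real participant,
#' each using their own fitted noise (averaged over their blocks); finally
#' compute the reference-position and higher-tone splits on both the
#' simulated and the input data, side by side.
#'
#' @param tab_reference_lower Trial table from the reference-lower protocol.
#' @param tab_reference Trial table from the reference protocol.
#' @param weights Fixed `trace_weights` of the memory-trace model.
#' @param n_starts Multistart count per fit (default 100).
#' @param master_seed Seed for the simulations.
#' @param fit_seed Seed for the fitters' start draws.
#' @return Nested list: for each protocol (`reference_lower`, `reference`),
#'   `data` and `simulated` split reports (`by_reference`, `by_higher_tone`)
#'   plus the per-participant fitted `sigma` values.
#' @export
resimulate_fitted_observers <- function(tab_reference_lower, tab_reference,
                                        weights = default_trace_weights(),
                                        n_starts = 100, master_seed = 1L,
                                        fit_seed = 1L) {
  one_leg <- function(tab, protocol, leg_offset) {
    sig <- fit_sigmas_by_participant(tab, weights, n_starts, fit_seed + leg_offset)
    sim <- simulate_experiment(
      protocol,
      function(i) observer("memory_trace", sigma = sig$sigma[i], weights = weights),
      n_participants = nrow(sig),
      blocks_per_participant = max(tab$block),
      master_seed = master_seed + leg_offset)
    list(fitted_sigma = sig,
         data = list(by_reference = percent_correct_by_reference(tab),
                     by_higher_tone = percent_correct_by_higher_tone(tab)),
         simulated = list(by_reference = percent_correct_by_reference(sim),
                          by_higher_tone = percent_correct_by_higher_tone(sim)))
  }
  list(
    reference_lower = one_leg(tab_reference_lower, protocol_spec("reference_lower"), 0L),
    reference = one_leg(tab_reference, protocol_spec("reference"), 1000L)
  )
}

# fit the memory-trace sigma per block and average within participant
fit_sigmas_by_participant <- function(tab, weights, n_starts, fit_seed) {
  blocks <- split(tab, interaction(tab$participant, tab$block, drop = TRUE))
  sig <- vapply(seq_along(blocks), function(j) {
    b <- blocks[[j]][order(blocks[[j]]$trial), , drop = FALSE]
    fit_block("memory_trace", b, weights = weights, n_starts = n_starts,
              seed = fit_seed + j)$sigma
  }, numeric(1))
  pid <- vapply(blocks, function(b) as.character(b$participant[1]), character(1))
  per <- vapply(split(sig, pid), mean, numeric(1))
  data.frame(participant = names(per), sigma = unname(per),
             stringsAsFactors = FALSE)
}
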