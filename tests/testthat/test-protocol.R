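test_that("staircase initialization follows the start difference and schedule", {
  st <- init_staircase(20, c(4.5, 2, 1, 0.5, 0.1))
  expect_equal(st$diff_percent, 20)
  expect_equal(st$step_percent, 4.5)
  expect_equal(st$n_reversals, 0L)
  expect_equal(st$consecutive_correct, 0L)
  expect_equal(st$last_direction, "none")

  single <- init_staircase(20, 4.5)
  expect_equal(single$step_percent, 4.5)

  expect_error(init_staircase(0, 4.5), "positive")
  expect_error(init_staircase(20, numeric(0)), "non-empty")
  expect_error(init_staircase(20, c(1, 2)), "decreasing")
})

test_that("3-down and 1-up rules move the difference by the current step", {
  st <- init_staircase(20, c(4.5, 2, 1, 0.5, 0.1))
  st$consecutive_correct <- 2L
  down <- update_staircase(st, TRUE)
  expect_equal(down$diff_percent, 15.5)
  expect_equal(down$consecutive_correct, 0L)
  expect_equal(down$last_direction, "down")

  up <- update_staircase(init_staircase(20), FALSE)
  expect_equal(up$diff_percent, 24.5)
  expect_equal(up$consecutive_correct, 0L)
  expect_equal(up$last_direction, "up")

  # two correct responses only advance the run counter
  st2 <- update_staircase(update_staircase(init_staircase(20), TRUE), TRUE)
  expect_equal(st2$diff_percent, 20)
  expect_equal(st2$consecutive_correct, 2L)
})

test_that("reversals are counted on direction changes and shrink the step every four", {
  st <- init_staircase(20)
  move_down <- function(s) update_staircase(
    update_staircase(update_staircase(s, TRUE), TRUE), TRUE)
  st <- move_down(st)                       # first movement: no reversal
  expect_equal(st$n_reversals, 0L)
  st <- update_staircase(st, FALSE)         # down -> up: reversal 1
  expect_equal(st$n_reversals, 1L)
  st <- move_down(st)                       # reversal 2
  st <- update_staircase(st, FALSE)         # reversal 3
  expect_equal(st$step_percent, 4.5)
  st <- move_down(st)                       # reversal 4: step advances next move
  expect_equal(st$n_reversals, 4L)
  expect_equal(st$step_percent, 2)
  diff_before <- st$diff_percent
  st <- update_staircase(st, FALSE)
  expect_equal(st$diff_percent, diff_before + 2)
})

test_that("the difference is floored and monotone under deterministic responders", {
  # always correct: marches to the floor and stays there
  st <- init_staircase(20)
  trace <- numeric(400)
  for (i in 1:400) {
    st <- update_staircase(st, TRUE)
    trace[i] <- st$diff_percent
  }
  expect_true(all(diff(trace) <= 0))
  expect_equal(min(trace), 0.1)
  expect_equal(trace[400], 0.1)

  # always incorrect: increases monotonically up to the ceiling
  st <- init_staircase(20)
  trace <- numeric(50)
  for (i in 1:50) {
    st <- update_staircase(st, FALSE)
    trace[i] <- st$diff_percent
  }
  expect_true(all(diff(trace) >= 0))
  expect_true(all(diff(trace[trace < 99]) > 0))
  expect_equal(max(trace), 99)
})

test_that("trial generation matches each protocol's stimulus rules", {
  set.seed(1)
  rl <- protocol_spec("reference_lower")
  for (i in 1:50) {
    tr <- make_trial(rl, 5)
    freqs <- sort(exp(c(tr$x1, tr$x2)))
    expect_equal(freqs, c(1000, 1050), tolerance = 1e-12)
    expect_equal(tr$ref_position,
                 if (abs(exp(tr$x1) - 1000) < 1e-9) "first" else "second")
  }

  rp <- protocol_spec("reference")
  seen <- replicate(200, {
    tr <- make_trial(rp, 5)
    nonref <- if (tr$ref_position == "first") exp(tr$x2) else exp(tr$x1)
    expect_true(abs(nonref - 1050) < 1e-9 || abs(nonref - 950) < 1e-9)
    nonref
  })
  expect_true(any(abs(seen - 950) < 1e-9) && any(abs(seen - 1050) < 1e-9))

  rf <- make_trial(protocol_spec("reference_first"), 5)
  expect_equal(rf$ref_position, "first")
  expect_equal(exp(rf$x1), 1000, tolerance = 1e-12)

  rh <- make_trial(protocol_spec("reference_higher"), 5)
  nonref <- if (rh$ref_position == "first") exp(rh$x2) else exp(rh$x1)
  expect_equal(nonref, 950, tolerance = 1e-9)

  nr <- make_trial(protocol_spec("no_reference"), 5)
  expect_equal(nr$ref_position, "none")
  expect_true(nr$ref_hz >= 800 && nr$ref_hz <= 1200)
  expect_equal(100 * abs(exp(nr$x2) - exp(nr$x1)) / nr$ref_hz, 5, tolerance = 1e-9)

  expect_error(make_trial(rl, 0), "positive")
})

test_that("in the reference protocol the four trial configurations are equally likely and independent", {
  set.seed(42)
  rp <- protocol_spec("reference")
  n <- 10000
  ref_first <- logical(n)
  f1_higher <- logical(n)
  for (i in seq_len(n)) {
    tr <- make_trial(rp, 5)
    ref_first[i] <- tr$ref_position == "first"
    f1_higher[i] <- tr$x1 > tr$x2
  }
  counts <- table(ref_first, f1_higher)
  expect_true(all(abs(counts / n - 0.25) < 3 * sqrt(0.25 * 0.75 / n) + 0.01))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("the JND is the mean percent difference over the last 20 trials", {
  b <- make_block(rep(1000, 25), rep(1030, 25), correct = rep(TRUE, 25))
  expect_equal(jnd_from_block(b), 3.0)

  f2 <- c(rep(1030, 5), rep(1020, 10), rep(1040, 10))
  b2 <- make_block(rep(1000, 25), f2, correct = rep(TRUE, 25))
  expect_equal(jnd_from_block(b2), 3.0)

  expect_error(jnd_from_block(make_block(rep(1000, 5), rep(1030, 5),
                                         correct = rep(TRUE, 5))),
               "fewer than")
})

test_that("the staircase tracks its 79.4% convergence point for a smooth observer", {
  # accuracy measured over the converged portion of each block (the
  # deterministic approach phase from the 20% start is excluded)
  obs <- observer("naive", sigma = 0.04)
  tab <- simulate_experiment(protocol_spec("reference_lower"), obs,
                             n_participants = 40, blocks_per_participant = 2,
                             master_seed = 71)
  pc <- 100 * mean(tab$correct[tab$trial > 30])
  expect_lt(abs(pc - 79.4), 2)
})
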