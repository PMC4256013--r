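test_that("percent correct by reference counts per participant and pairs across groups", {
  f1 <- c(rep(1000, 4), rep(1050, 4))
  f2 <- c(rep(1050, 4), rep(1000, 4))
  correct <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  tab <- make_block(f1, f2, correct = correct)
  sr <- percent_correct_by_reference(tab)
  expect_equal(sr$pc_group1, 75)  # 3/4 correct in Ref1 trials
  expect_equal(sr$pc_group2, 50)  # 2/4 correct in Ref2 trials

  tab_all <- make_block(f1, f2, correct = rep(TRUE, 8))
  tab_all2 <- tab_all
  tab_all2$participant <- "p2"
  sr_all <- percent_correct_by_reference(rbind(tab_all, tab_all2))
  expect_equal(sr_all$pc_group1, 100)
  expect_equal(sr_all$pc_group2, 100)
  expect_true(sr_all$degenerate)
  expect_equal(sr_all$t_stat, 0)

  tab_none <- make_block(c(900, 950), c(930, 970), correct = c(TRUE, TRUE))
  expect_error(percent_correct_by_reference(tab_none), "first or second")
})

test_that("in reference-lower data the higher-tone split is the reference split with groups swapped", {
  set.seed(40)
  tab <- simulate_experiment(protocol_spec("reference_lower"),
                             observer("memory_trace", sigma = 0.04),
                             10, 2, master_seed = 91)
  by_ref <- percent_correct_by_reference(tab)
  by_high <- percent_correct_by_higher_tone(tab)
  expect_equal(by_high$pc_group1, by_ref$pc_group2)  # f1 higher <=> ref second
  expect_equal(by_high$pc_group2, by_ref$pc_group1)
  expect_equal(by_high$p_value, by_ref$p_value)

  # pooled percent correct across groups equals the overall rate
  per <- by_ref$per_participant
  pooled <- (per$pc1 * per$n1 + per$pc2 * per$n2) / (per$n1 + per$n2)
  overall <- percent_correct_overall(tab)$per_participant
  expect_equal(unname(pooled[order(per$participant)]),
               unname(overall[order(names(overall))]), tolerance = 1e-10)
})

test_that("exclusion of early trials drops them from the split", {
  f1 <- rep(1000, 40)
  f2 <- rep(1050, 40)
  correct <- c(rep(TRUE, 30), rep(FALSE, 10))
  tab <- make_block(f1, f2, correct = correct)
  tab$ref_position <- rep(c("first", "second"), 20)
  sr <- percent_correct_by_reference(tab, exclude_first_n = 30)
  expect_equal(sr$pc_group1, 0)
  expect_equal(sr$pc_group2, 0)
  expect_equal(sum(sr$per_participant$n1 + sr$per_participant$n2), 10)
})

test_that("the first-higher response rate averages per-participant percentages", {
  tab <- make_block(c(1000, 1000, 1050, 1050), c(1050, 1050, 1000, 1000),
                    response_first_higher = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(response_rate_first_higher(tab)$rate, 75)

  # an observer whose bias dwarfs the stimulus term responds "first higher"
  # nearly always, even at the large differences the staircase climbs to
  tab_b <- simulate_experiment(protocol_spec("reference"),
                               observer("response_bias", sigma = 0.5, beta = 20),
                               5, 1, master_seed = 92)
  expect_gt(response_rate_first_higher(tab_b)$rate, 95)

  # an unbiased naive observer sits at 50% in the reference protocol
  tab_n <- simulate_experiment(protocol_spec("reference"),
                               observer("naive", sigma = 0.03),
                               30, 1, master_seed = 93)
  expect_lt(abs(response_rate_first_higher(tab_n)$rate - 50), 2.5)
})

test_that("bias labels follow the geometry of contraction toward the running mean", {
  # trial 1 neutral; trial 2: m = x1(1)
  b <- make_block(c(1100, 1050, 1000, 1060), c(1000, 1020, 1080, 1060.5),
                  correct = rep(TRUE, 4), ref_hz = 1000)
  lab <- classify_bias_trials(b)
  expect_equal(lab[1], "neutral")
  # t=2: m = log(1100) > x1 = log(1050) > x2 = log(1020): contraction up, helps
  expect_equal(lab[2], "bias_plus")
  # t=3: m > x1 and x1 < x2: contraction away from the correct direction
  expect_equal(lab[3], "bias_minus")
  # t=4: m = mean(log(1100), log(1050), log(1000)) ~ log(1049.2) < x1, x1 < x2
  expect_equal(lab[4], "bias_plus")

  b_eq <- make_block(c(1000, 1000), c(1050, 1040), correct = c(TRUE, TRUE))
  expect_equal(classify_bias_trials(b_eq)[2], "neutral")  # m == x1
})

test_that("repeat labels track repetition of the correct response", {
  b_alt <- make_block(c(1000, 1050, 1000, 1050), c(1050, 1000, 1050, 1000),
                      correct = rep(TRUE, 4))
  expect_equal(classify_repeat_trials(b_alt), c(NA, "alternate", "alternate", "alternate"))
  b_rep <- make_block(rep(1000, 4), rep(1050, 4), correct = rep(TRUE, 4))
  expect_equal(classify_repeat_trials(b_rep), c(NA, "repeat", "repeat", "repeat"))
})

test_that("response repetition is confounded with the protocol in reference-lower blocks but dissociates in no-reference blocks", {
  mt <- observer("memory_trace", sigma = 0.04)
  # reference-lower: repeating the correct response repeats the reference
  # position, so the contraction observer shows a repetition advantage here
  tab_rl <- simulate_experiment(protocol_spec("reference_lower"), mt, 40, 2,
                                master_seed = 94)
  sp_rl <- percent_correct_by_repeat(tab_rl)
  expect_gt(sp_rl$pc_group1 - sp_rl$pc_group2, 1)
  # no-reference: the repetition account collapses (near-zero gap) while the
  # contraction-benefit split stays large
  tab_nr <- simulate_experiment(protocol_spec("no_reference"), mt, 60, 1,
                                master_seed = 97)
  sp_nr <- percent_correct_by_repeat(tab_nr)
  sb_nr <- percent_correct_by_bias(tab_nr)
  expect_lt(abs(sp_nr$pc_group1 - sp_nr$pc_group2),
            (sb_nr$pc_group1 - sb_nr$pc_group2) / 3)
  expect_gt(sb_nr$pc_group1 - sb_nr$pc_group2, 10)
})

test_that("subset JND ratios are symmetric, scale-equivariant and directionally correct", {
  # identical behavior in both subsets: r = 1
  set.seed(42)
  n <- 120
  d <- runif(n, 0.5, 12)
  correct <- runif(n) < pnorm(d / 3)
  tab <- make_block(rep(1000, 2 * n), 1000 * (1 + rep(d, 2) / 100),
                    correct = rep(correct, 2))
  tab$ref_position <- rep(c("first", "second"), each = n)
  jr <- jnd_ratio(tab)
  expect_equal(jr$median_r, 1, tolerance = 1e-6)

  # doubling all differences doubles both subset JNDs, r is invariant
  tab2 <- tab
  tab2$x2 <- log(1000 * (1 + 2 * rep(d, 2) / 100))
  jr2 <- jnd_ratio(tab2)
  expect_equal(jr2$per_participant$jnd_ref1, 2 * jr$per_participant$jnd_ref1,
               tolerance = 1e-4)
  expect_equal(jr2$median_r, jr$median_r, tolerance = 1e-6)

  # contraction observer: thresholds higher in Ref1 in the reference-lower
  # protocol and lower in Ref1 in the reference protocol
  tab_rl <- simulate_experiment(protocol_spec("reference_lower"),
                                observer("memory_trace", sigma = 0.04),
                                40, 2, master_seed = 95)
  tab_r <- simulate_experiment(protocol_spec("reference"),
                               observer("memory_trace", sigma = 0.03),
                               40, 1, master_seed = 96)
  expect_gt(jnd_ratio(tab_rl)$median_r, 1)
  expect_lt(jnd_ratio(tab_r)$median_r, 1)
})

test_that("the paired test matches hand-computed statistics and flags degenerate input", {
  pt <- paired_test(c(2, 3, 4, 5), c(1, 1, 1, 1))
  expect_equal(pt$t, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-4)
  expect_equal(round(pt$t, 3), 3.873)
  expect_equal(round(pt$d, 3), 1.936)

  same <- paired_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$d, 0)

  shifted <- paired_test(c(1, 2, 3), c(0, 1, 2))
  expect_true(shifted$degenerate)
  expect_true(is.na(shifted$t))
})
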