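# Behavioral statistics for interval-bias analyses. All functions operate on
# a "trial table": a data.frame with one row per trial and columns
# participant, block, trial, x1, x2 (log-Hz), ref_hz, ref_position
# ("first"/"second"/"none"), response_first_higher (logical), correct
# (logical). simulate_experiment() produces this layout; read_dataset_s1()
# decodes deposited data into it.

# per-participant percent correct in two trial groups, population summary and
# paired test
split_report <- function(tab, group, split_name, labels) {
  stopifnot(is.data.frame(tab), length(group) == nrow(tab))
  keep <- !is.na(group)
  tab <- tab[keep, , drop = FALSE]
  group <- group[keep]
  per <- do.call(rbind, lapply(split(seq_len(nrow(tab)), tab$participant), function(idx) {
    g <- group[idx]
    corr <- tab$correct[idx]
    data.frame(participant = tab$participant[idx[1]],
               pc1 = 100 * mean(corr[g == labels[1]]),
               pc2 = 100 * mean(corr[g == labels[2]]),
               n1 = sum(g == labels[1]), n2 = sum(g == labels[2]))
  }))
  incomplete <- per$n1 == 0 | per$n2 == 0
  paired <- per[!incomplete, , drop = FALSE]
  pt <- if (nrow(paired) >= 2) paired_test(paired$pc1, paired$pc2)
        else list(t = NA_real_, p = NA_real_, d = NA_real_, degenerate = TRUE)
  structure(
    list(split_name = split_name,
         labels = labels,
         per_participant = per,
         n_participants = nrow(paired),
         n_excluded = sum(incomplete),
         pc_group1 = mean(paired$pc1), sem1 = sem(paired$pc1),
         pc_group2 = mean(paired$pc2), sem2 = sem(paired$pc2),
         t_stat = pt$t, p_value = pt$p, cohens_d = pt$d,
         degenerate = pt$degenerate,
         fraction_group1_better = mean(paired$pc1 > paired$pc2) +
           0.5 * mean(paired$pc1 == paired$pc2)),
    class = "split_report"
  )
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' @export
print.split_report <- function(x, ...) {
  cat(sprintf("<split_report> %s (n = %d participants%s)\n", x$split_name,
              x$n_participants,
              if (x$n_excluded > 0) sprintf(", %d excluded", x$n_excluded) else ""))
  cat(sprintf("  %s: %.1f%% +/- %.1f%%   %s: %.1f%% +/- %.1f%%\n",
              x$labels[1], x$pc_group1, x$sem1, x$labels[2], x$pc_group2, x$sem2))
  if (!x$degenerate)
    cat(sprintf("  paired t = %.3f, p = %.3g, d = %.3f\n", x$t_stat, x$p_value, x$cohens_d))
  else cat("  paired test degenerate (zero-variance differences)\n")
  invisible(x)
}

#' Percent correct split by the interval of the reference tone
#'
#' For each participant, percent correct over trials in which the reference
#' occupied the first interval (Ref1) versus the second (Ref2), pooling the
#' participant's blocks. Population summary is the mean +/- SEM across
#' participants with a two-sided paired t-test and Cohen's d
#' (mean difference / SD of differences). Participants lacking trials in
#' either group are excluded from the paired statistics and counted in
#' `n_excluded`.
#'
#' @param tab A trial table (see [simulate_experiment()]).
#' @param exclude_first_n Drop this many initial trials of every block before
#'   computing the split (the conventional stability control uses 30).
#' @return A `split_report`.
#' @export
percent_correct_by_reference <- function(tab, exclude_first_n = 0) {
  if (!all(tab$ref_position %in% c("first", "second")))
    stop("reference split requires every trial to have the reference first or second",
         call. = FALSE)
  tab <- tab[tab$trial > exclude_first_n, , drop = FALSE]
  split_report(tab, tab$ref_position, "ref1_vs_ref2", c("first", "second"))
}

#' Percent correct split by which tone was higher
#'
#' Same aggregation as [percent_correct_by_reference()], with trials grouped
#' by the correct response: first tone higher versus second tone higher. In
#' the reference-lower protocol this split is the reference split with the
#' groups swapped; in the reference protocol the two splits are independent,
#' which is what makes this a control for response bias.
#'
#' @inheritParams percent_correct_by_reference
#' @return A `split_report`.
#' @export
percent_correct_by_higher_tone <- function(tab, exclude_first_n = 0) {
  tab <- tab[tab$trial > exclude_first_n, , drop = FALSE]
  grp <- ifelse(tab$x1 > tab$x2, "f1_higher", "f2_higher")
  split_report(tab, grp, "f1high_vs_f2high", c("f1_higher", "f2_higher"))
}

#' Rate of "first tone higher" responses
#'
#' Mean across participants of the per-participant percentage of trials
#' answered "first tone higher", with SEM. A value near 50 in the reference
#' protocol rules out a blanket response bias. Missing responses are
#' reconstructed from correctness and which tone was higher.
#'
#' @param tab A trial table.
#' @return List with `rate` (percent), `sem`, and `per_participant`.
#' @export
response_rate_first_higher <- function(tab) {
  resp <- tab$response_first_higher
  if (is.null(resp) || anyNA(resp)) {
    recon <- tab$correct == (tab$x1 > tab$x2)
    resp <- if (is.null(resp)) recon else ifelse(is.na(resp), recon, resp)
  }
  per <- vapply(split(resp, tab$participant), function(r) 100 * mean(r), numeric(1))
  list(rate = mean(per), sem = sem(per), per_participant = per)
}

#' Classify trials by whether contraction toward the memory trace helps
#'
#' The remembered first tone is pulled toward m(t), the running mean of the
#' first tones of the preceding trials. When that pull enlarges the perceived
#' difference in the correct direction the trial benefits (`"bias_plus"`);
#' when it shrinks or reverses it the trial is penalized (`"bias_minus"`).
#' Formally the label is the sign of `(m(t) - x1) * (x1 - x2)`. Trial 1 (no
#' history) and exact zeros are `"neutral"`.
#'
#' @param block A single block's trials in presentation order (columns `x1`,
#'   `x2`).
#' @return Character vector of labels, one per trial.
#' @export
classify_bias_trials <- function(block) {
  x1 <- block$x1
  x2 <- block$x2
  n <- length(x1)
  lab <- rep("neutral", n)
  if (n > 1) {
    m <- cumsum(x1)[-n] / seq_len(n - 1)  # mean of prior first tones
    s <- (m - x1[-1]) * (x1[-1] - x2[-1])
    lab[-1] <- ifelse(s > 0, "bias_plus", ifelse(s < 0, "bias_minus", "neutral"))
  }
  lab
}

#' Classify trials by repetition of the correct response
#'
#' A trial is a `"repeat"` when its correct response (which interval is
#' higher) matches the previous trial's, `"alternate"` otherwise. Trial 1 is
#' unlabeled (`NA`).
#'
#' @param block A single block's trials in presentation order.
#' @return Character vector of labels (`NA` for trial 1).
#' @export
classify_repeat_trials <- function(block) {
  s <- sign(block$x1 - block$x2)
  n <- length(s)
  if (n < 2) return(rep(NA_character_, n))
  c(NA_character_, ifelse(s[-1] == s[-n], "repeat", "alternate"))
}

# apply a per-block classifier over a trial table, preserving row order
classify_table <- function(tab, classifier) {
  lab <- rep(NA_character_, nrow(tab))
  for (idx in split(seq_len(nrow(tab)), interaction(tab$participant, tab$block, drop = TRUE))) {
    ord <- idx[order(tab$trial[idx])]
    lab[ord] <- classifier(tab[ord, , drop = FALSE])
  }
  lab
}

#' Percent correct split by contraction benefit (Bias+ vs Bias-)
#'
#' @param tab A trial table.
#' @return A `split_report` comparing `bias_plus` against `bias_minus`
#'   trials; neutral trials are excluded.
#' @export
percent_correct_by_bias <- function(tab) {
  lab <- classify_table(tab, classify_bias_trials)
  lab[lab == "neutral"] <- NA
  split_report(tab, lab, "biasplus_vs_biasminus", c("bias_plus", "bias_minus"))
}

#' Percent correct split by response repetition (Repeat vs Alternate)
#'
#' @param tab A trial table.
#' @return A `split_report` comparing `repeat` against `alternate` trials.
#' @export
percent_correct_by_repeat <- function(tab) {
  lab <- classify_table(tab, classify_repeat_trials)
  split_report(tab, lab, "repeat_vs_alternate", c("repeat", "alternate"))
}

#' Overall percent correct, averaged across participants
#'
#' @param tab A trial table.
#' @return List with `pc` (mean across participants, percent), `sem`, and
#'   `per_participant`.
#' @export
percent_correct_overall <- function(tab) {
  per <- vapply(split(tab$correct, tab$participant),
                function(x) 100 * mean(x), numeric(1))
  list(pc = mean(per), sem = sem(per), per_participant = per)
}

#' Mean JND across participants
#'
#' Computes [jnd_from_block()] for every block, averages blocks within
#' participant, and summarizes across participants.
#'
#' @param tab A trial table.
#' @return List with `jnd` (mean percent), `sem`, and `per_participant`.
#' @export
mean_jnd <- function(tab) {
  per_block <- vapply(
    split(tab, interaction(tab$participant, tab$block, drop = TRUE)),
    function(b) jnd_from_block(b[order(b$trial), , drop = FALSE]),
    numeric(1))
  pid <- vapply(split(tab$participant, interaction(tab$participant, tab$block, drop = TRUE)),
                function(p) as.character(p[1]), character(1))
  per <- vapply(split(per_block, pid), mean, numeric(1))
  list(jnd = mean(per), sem = sem(per), per_participant = per)
}

# Probit-GLM psychometric fit P(correct | d) = pnorm(b0 + b1 * d) and the
# difference at which accuracy crosses the criterion:
# JND = (qnorm(criterion) - b0) / b1. The free intercept absorbs the
# displaced point of subjective equality that history effects induce (subset
# accuracy need not be 0.5 at d = 0). d in percent; returns NA for
# non-convergent fits. The crossing is only identified within the range of
# differences the staircase actually sampled, so estimates outside [min(d),
# max(d)] — including those from flat or non-increasing fits, which arise
# when contraction decouples subset accuracy from difficulty — are censored
# to the range limits (below the range when accuracy beats the criterion
# overall, above it otherwise).
psychometric_jnd <- function(d, correct, criterion = 0.794) {
  fit <- tryCatch(
    suppressWarnings(stats::glm(correct ~ d,
                                family = stats::binomial(link = "probit"))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NA_real_)
  b <- stats::coef(fit)
  if (!all(is.finite(b))) return(NA_real_)
  crossing <- if (b[2] > 0) (stats::qnorm(criterion) - b[1]) / b[2]
              else if (mean(correct) >= criterion) -Inf else Inf
  unname(min(max(crossing, min(d)), max(d)))
}

#' Subset JND ratio r = JND(Ref1) / JND(Ref2)
#'
#' A staircase block yields one aggregate threshold, so subset thresholds for
#' Ref1 and Ref2 trials are estimated from psychometric fits instead: for
#' each participant and subset, a cumulative-normal psychometric function
#' `P(correct) = pnorm(d / s)` is fitted by maximum likelihood to the
#' (percent difference, correctness) pairs, and the subset JND is the percent
#' difference at the staircase's 79.4% convergence point. `r < 1` means
#' better (lower) thresholds when the reference is first.
#'
#' @param tab A trial table from a reference-containing protocol.
#' @param criterion Performance criterion defining the JND (default 0.794).
#' @param min_trials Minimum trials per subset for a participant to be fitted
#'   (default 10).
#' @return List with `per_participant` (data.frame of `jnd_ref1`, `jnd_ref2`,
#'   `r`), `median_r`, and `n_excluded` (participants with too few trials or
#'   non-convergent fits).
#' @export
jnd_ratio <- function(tab, criterion = 0.794, min_trials = 10) {
  if (!all(tab$ref_position %in% c("first", "second")))
    stop("jnd_ratio requires a reference-containing protocol", call. = FALSE)
  d_all <- 100 * abs(exp(tab$x2) - exp(tab$x1)) / tab$ref_hz
  per <- do.call(rbind, lapply(split(seq_len(nrow(tab)), tab$participant), function(idx) {
    i1 <- idx[tab$ref_position[idx] == "first"]
    i2 <- idx[tab$ref_position[idx] == "second"]
    j1 <- if (length(i1) >= min_trials)
      psychometric_jnd(d_all[i1], tab$correct[i1], criterion) else NA_real_
    j2 <- if (length(i2) >= min_trials)
      psychometric_jnd(d_all[i2], tab$correct[i2], criterion) else NA_real_
    data.frame(participant = tab$participant[idx[1]],
               jnd_ref1 = j1, jnd_ref2 = j2, r = j1 / j2)
  }))
  ok <- is.finite(per$r)
  list(per_participant = per,
       median_r = stats::median(per$r[ok]),
       n_excluded = sum(!ok))
}

#' Two-sided paired t-test with Cohen's d
#'
#' @param values_group1,values_group2 Paired numeric vectors of equal length
#'   (n >= 2).
#' @return List with `t`, `p`, `d` (mean difference / SD of differences) and
#'   a `degenerate` flag set when the differences have zero variance (no test
#'   is computed).
#' @export
paired_test <- function(values_group1, values_group2) {
  stopifnot(length(values_group1) == length(values_group2),
            length(values_group1) >= 2)
  diffs <- values_group1 - values_group2
  if (stats::sd(diffs) == 0) {
    # identical vectors: no effect and no variance; report the null values but
    # flag that no test was run. Constant nonzero differences are undefined.
    if (all(diffs == 0))
      return(list(t = 0, p = 1, d = 0, degenerate = TRUE))
    return(list(t = NA_real_, p = NA_real_, d = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(values_group1, values_group2, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       d = mean(diffs) / stats::sd(diffs), degenerate = FALSE)
}
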