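PROB_CLIP <- 1e-12  # likelihood floor keeping log-probabilities finite

# Vectorized linear decision variable of the memory-trace model over a whole
# block: D(t) = a0*x1(t) + sum_k a_k*x1(t-k) + b*x2(t) + c*m(t), where m(t)
# is the mean of x1 over trials 1..t-1. History terms not yet available
# (lags beyond the completed trials; the mean at t = 1) self-anchor on the
# current x1. Equivalent to building the memory state trial by trial, but in
# closed form.
trace_drive_block <- function(block, weights) {
  x1 <- block$x1
  x2 <- block$x2
  n <- length(x1)
  m <- c(x1[1], if (n > 1) cumsum(x1)[-n] / seq_len(n - 1))
  drive <- weights$a0 * x1 + weights$b * x2 + weights$c * m
  for (k in seq_along(weights$a_hist)) {
    lagged <- c(x1[seq_len(min(k, n))], x1[seq_len(max(0, n - k))])
    drive <- drive + weights$a_hist[k] * lagged
  }
  drive
}

#' Log-likelihood of a block of responses under an observer model
#'
#' Sums the log-probability of the *observed* response on every trial, with
#' the memory state built sequentially from the block's actual stimulus
#' sequence. Probabilities are clipped to `[1e-12, 1 - 1e-12]` so the
#' log-likelihood stays finite.
#'
#' @param model `"naive"`, `"memory_trace"` or `"response_bias"`.
#' @param params Named list or vector with `sigma` (and `beta` for the
#'   response-bias model).
#' @param block Block data frame with columns `x1`, `x2` and
#'   `response_first_higher` (logical).
#' @param weights Fixed `trace_weights` for the memory-trace model.
#' @return The log-likelihood in nats (always <= 0).
#' @export
block_log_likelihood <- function(model, params, block,
                                 weights = default_trace_weights()) {
  model <- match.arg(model, c("naive", "memory_trace", "response_bias"))
  resp <- block$response_first_higher
  if (is.null(resp) || anyNA(resp))
    stop("block has missing responses", call. = FALSE)
  sigma <- params[["sigma"]]
  if (is.null(sigma) || sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  drive <- switch(model,
    naive = (block$x1 - block$x2) / sigma,
    memory_trace = trace_drive_block(block, weights) / sigma,
    response_bias = (block$x1 - block$x2) / sigma + params[["beta"]]
  )
  p <- stats::pnorm(drive)
  p_obs <- ifelse(resp, p, 1 - p)
  sum(log(pmin(pmax(p_obs, PROB_CLIP), 1 - PROB_CLIP)))
}

#' Bayesian information criterion
#'
#' @param log_likelihood Maximized log-likelihood in nats.
#' @param n_free_params Number of free parameters.
#' @param n_trials Number of observations.
#' @return `n_free_params * log(n_trials) - 2 * log_likelihood`; lower is
#'   better.
#' @export
bic <- function(log_likelihood, n_free_params, n_trials) {
  stopifnot(n_trials >= 1, n_free_params >= 0)
  n_free_params * log(n_trials) - 2 * log_likelihood
}

#' Fit an observer model to one block by maximum likelihood
#'
#' Maximizes [block_log_likelihood()] over the observer noise `sigma` (and
#' the bias `beta` for the response-bias model) with a multistart
#' derivative-free local search: `n_starts` starting points drawn from
#' Normal(`start_center`, `start_sd`) in the fitted-parameter space, where
#' `sigma` is optimized on the log scale to enforce positivity. One-parameter
#' models use Brent line search in a window around each start; the
#' two-parameter model uses the Nelder-Mead simplex.
#'
#' @param model `"naive"`, `"memory_trace"` or `"response_bias"`.
#' @param block Block data frame with stimuli and responses.
#' @param weights Fixed `trace_weights` for the memory-trace model.
#' @param n_starts Number of random starting points (default 100).
#' @param start_center,start_sd Center and spread of the start distribution
#'   (defaults 0 and 10).
#' @param seed Optional integer seed for the start draws.
#' @return A `fit_result` list: `model`, `sigma`, `beta` (`NA` unless the
#'   response-bias model), `log_likelihood`, `bic`, `n_trials`,
#'   `n_free_params`, `n_starts`, `best_start_index`, `converged`.
#' @export
fit_block <- function(model = c("naive", "memory_trace", "response_bias"),
                      block, weights = default_trace_weights(),
                      n_starts = 100, start_center = 0, start_sd = 10,
                      seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(block)
  resp <- block$response_first_higher
  if (is.null(resp) || anyNA(resp))
    stop("block has missing responses", call. = FALSE)
  # precompute the sigma-free decision variable once per block
  base_drive <- if (model == "memory_trace") trace_drive_block(block, weights)
                else block$x1 - block$x2
  negll <- if (model == "response_bias") {
    function(par) {
      drive <- base_drive / exp(par[1]) + par[2]
      p <- stats::pnorm(drive)
      p_obs <- ifelse(resp, p, 1 - p)
      -sum(log(pmin(pmax(p_obs, PROB_CLIP), 1 - PROB_CLIP)))
    }
  } else {
    function(par) {
      p <- stats::pnorm(base_drive / exp(par[1]))
      p_obs <- ifelse(resp, p, 1 - p)
      -sum(log(pmin(pmax(p_obs, PROB_CLIP), 1 - PROB_CLIP)))
    }
  }
  k <- if (model == "response_bias") 2L else 1L
  starts <- matrix(stats::rnorm(n_starts * k, start_center, start_sd),
                   nrow = n_starts, ncol = k)
  best <- NULL
  best_i <- NA_integer_
  any_converged <- FALSE
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      if (k == 1L) {
        stats::optim(starts[i, ], negll, method = "Brent",
                     lower = starts[i, 1] - 30, upper = starts[i, 1] + 30)
      } else {
        stats::optim(starts[i, ], negll, method = "Nelder-Mead",
                     control = list(maxit = 1000, reltol = 1e-10))
      },
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    conv <- fit$convergence == 0
    any_converged <- any_converged || conv
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best_i <- i
    }
  }
  if (is.null(best))
    stop("fit failed: no starting point produced a finite optimum (model = ",
         model, ", n_starts = ", n_starts, ")", call. = FALSE)
  ll <- -best$value
  structure(
    list(model = model,
         sigma = exp(best$par[1]),
         beta = if (k == 2L) best$par[2] else NA_real_,
         log_likelihood = ll,
         bic = bic(ll, k, n),
         n_trials = n,
         n_free_params = k,
         n_starts = n_starts,
         best_start_index = best_i,
         converged = any_converged),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: sigma = %.4g%s, logLik = %.2f, BIC = %.2f (n = %d)\n",
              x$model, x$sigma,
              if (!is.na(x$beta)) sprintf(", beta = %.3f", x$beta) else "",
              x$log_likelihood, x$bic, x$n_trials))
  invisible(x)
}

#' Compare two model fits across the same set of blocks
#'
#' Given paired per-block fits of model A and model B, reports per-block BIC
#' differences, the fraction of blocks in which A wins, a paired t-test on
#' the per-block criteria, and (optionally) Pearson and Spearman correlations
#' of the BIC difference against each block's interval-bias magnitude. When
#' the two models have the same number of free parameters the win is decided
#' on raw log-likelihood; when they differ, on BIC. Ties count 0.5 to each
#' model.
#'
#' @param fits_a,fits_b Lists of `fit_result` objects of equal length, fitted
#'   to identical blocks in the same order.
#' @param bias_magnitude Optional numeric vector (one per block) of
#'   interval-bias magnitudes to correlate with the BIC difference.
#' @return A `model_comparison` list with `delta_bic` (A - B),
#'   `win_fraction_a`, `criterion` (`"bic"` or `"log_likelihood"`),
#'   `t_test` (or `NULL` if degenerate), and `correlation` (list with
#'   `pearson`, `spearman`, and a `degenerate` flag when the magnitudes have
#'   zero variance).
#' @export
compare_models_across_blocks <- function(fits_a, fits_b, bias_magnitude = NULL) {
  if (length(fits_a) != length(fits_b) || length(fits_a) == 0)
    stop("`fits_a` and `fits_b` must be non-empty paired lists of equal length",
         call. = FALSE)
  n_a <- vapply(fits_a, function(f) f$n_trials, numeric(1))
  n_b <- vapply(fits_b, function(f) f$n_trials, numeric(1))
  if (!all(n_a == n_b))
    stop("fits are not paired on identical blocks (trial counts differ)",
         call. = FALSE)
  bic_a <- vapply(fits_a, function(f) f$bic, numeric(1))
  bic_b <- vapply(fits_b, function(f) f$bic, numeric(1))
  k_a <- vapply(fits_a, function(f) f$n_free_params, numeric(1))
  k_b <- vapply(fits_b, function(f) f$n_free_params, numeric(1))
  same_k <- all(k_a == k_b)
  crit_a <- if (same_k) -vapply(fits_a, function(f) f$log_likelihood, numeric(1)) else bic_a
  crit_b <- if (same_k) -vapply(fits_b, function(f) f$log_likelihood, numeric(1)) else bic_b
  wins <- ifelse(crit_a < crit_b, 1, ifelse(crit_a > crit_b, 0, 0.5))
  delta <- crit_a - crit_b
  tt <- if (stats::sd(delta) > 0) stats::t.test(crit_a, crit_b, paired = TRUE) else NULL
  correlation <- NULL
  if (!is.null(bias_magnitude)) {
    stopifnot(length(bias_magnitude) == length(fits_a))
    if (stats::sd(bias_magnitude) == 0 || stats::sd(bic_a - bic_b) == 0) {
      correlation <- list(pearson = NA_real_, spearman = NA_real_, degenerate = TRUE)
    } else {
      correlation <- list(
        pearson = stats::cor(bic_a - bic_b, bias_magnitude, method = "pearson"),
        spearman = stats::cor(bic_a - bic_b, bias_magnitude, method = "spearman"),
        degenerate = FALSE)
    }
  }
  structure(
    list(delta_bic = bic_a - bic_b,
         win_fraction_a = mean(wins),
         criterion = if (same_k) "log_likelihood" else "bic",
         t_test = tt,
         degenerate_t = is.null(tt),
         correlation = correlation),
    class = "model_comparison"
  )
}
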