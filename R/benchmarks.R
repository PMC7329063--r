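# systematic (low-variance) resampling; returns particle indices
systematic_resample <- function(wt) {
  n <- length(wt)
  u <- (runif(1) + seq_len(n) - 1) / n
  findInterval(u, cumsum(wt) / sum(wt)) + 1L
}

normalise_weights <- function(logw, t) {
  logw <- logw - max(logw)
  wt <- exp(logw)
  s <- sum(wt)
  if (!is.finite(s) || s <= 0)
    stop("particle weights degenerated to zero at trial ", t)
  wt / s
}

#' Rao-Blackwellized particle filter under the volatility-process model
#'
#' Near-exact sequential Monte Carlo reference for the Gaussian VKF:
#' samples precision paths `z_t` (multiplicative Beta diffusion) and,
#' conditional on each path, runs an exact Kalman filter for the latent
#' mean. Weights are the per-particle Gaussian predictive likelihoods;
#' systematic resampling is triggered when the effective sample size drops
#' below half the particle count.
#'
#' @param observations Numeric outcomes.
#' @param lambda,v0,sigma2 Process parameters (as in [vkf_params()]).
#' @param n_particles Number of particles (>= 2; 10000 for printed-quality
#'   benchmarks).
#' @param shape Beta concentration of the precision noise (matches
#'   [simulate_vkf_process()]).
#' @param m0,w0 Initial conditional mean and variance (defaults 0 and 0:
#'   the generative process starts at a known latent value).
#' @return Data frame with per-trial `prediction` (posterior mean of the
#'   latent state), `volatility` (inverse posterior-mean precision) and
#'   `ess`; class `"pf_trajectory"`.
#' @export
rbpf_vkf <- function(observations, lambda, v0, sigma2, n_particles = 10000,
                     shape = 10, m0 = 0, w0 = 0) {
  check_obs(observations)
  if (n_particles < 2) stop("need at least 2 particles")
  T <- length(observations)
  N <- n_particles
  z <- rep(1 / v0, N)
  m <- rep(m0, N)
  w <- rep(w0, N)
  wt <- rep(1 / N, N)
  pred <- vol <- ess <- numeric(T)
  for (t in seq_len(T)) {
    pv <- w + 1 / z
    S <- pv + sigma2
    logw <- log(wt) + dnorm(observations[t], m, sqrt(S), log = TRUE)
    wt <- normalise_weights(logw, t)
    K <- pv / S
    m <- m + K * (observations[t] - m)
    w <- (1 - K) * pv
    pred[t] <- sum(wt * m)
    # volatility estimate before propagating the (data-uninformed) next
    # precision-noise draw, matching the information set of the filter's v_t
    vol[t] <- 1 / sum(wt * z)
    z <- z * sample_precision_noise(N, lambda, shape)
    ess[t] <- 1 / sum(wt^2)
    if (ess[t] < N / 2) {
      idx <- systematic_resample(wt)
      z <- z[idx]; m <- m[idx]; w <- w[idx]
      wt <- rep(1 / N, N)
    }
  }
  structure(data.frame(trial = seq_len(T), prediction = pred,
                       volatility = vol, ess = ess),
            class = c("pf_trajectory", "data.frame"),
            n_particles = N, kind = "rbpf_vkf")
}

#' Rao-Blackwellized particle filter under the HGF generative cascade
#'
#' Samples third-level paths `x3` from their Gaussian walk and
#' marginalizes the second level with an exact Kalman filter. The
#' observation at trial `t` informs `x2(t-1)` and the second level then
#' diffuses by `exp(kappa * x3(t) + omega)`, matching
#' [simulate_hgf_process()].
#'
#' @inheritParams rbpf_vkf
#' @param nu,kappa,omega,sigma2 HGF generative parameters.
#' @param mu2_0,mu3_0 Initial latent values (defaults 0 and 1, known).
#' @return As [rbpf_vkf()]; `volatility` is the posterior mean of
#'   `exp(kappa * x3 + omega)`.
#' @export
rbpf_hgf <- function(observations, nu, kappa, omega, sigma2,
                     n_particles = 10000, mu2_0 = 0, mu3_0 = 1) {
  check_obs(observations)
  if (n_particles < 2) stop("need at least 2 particles")
  T <- length(observations)
  N <- n_particles
  x3 <- rep(mu3_0, N)
  m2 <- rep(mu2_0, N)
  s2 <- rep(0, N)
  wt <- rep(1 / N, N)
  pred <- vol <- ess <- numeric(T)
  for (t in seq_len(T)) {
    S <- s2 + sigma2
    logw <- log(wt) + dnorm(observations[t], m2, sqrt(S), log = TRUE)
    wt <- normalise_weights(logw, t)
    K <- s2 / S
    m2 <- m2 + K * (observations[t] - m2)
    s2 <- (1 - K) * s2
    pred[t] <- sum(wt * m2)
    x3 <- x3 + rnorm(N, 0, sqrt(nu))
    q <- exp(pmin(kappa * x3 + omega, 700))
    s2 <- s2 + q
    vol[t] <- sum(wt * q)
    ess[t] <- 1 / sum(wt^2)
    if (ess[t] < N / 2) {
      idx <- systematic_resample(wt)
      x3 <- x3[idx]; m2 <- m2[idx]; s2 <- s2[idx]
      wt <- rep(1 / N, N)
    }
  }
  structure(data.frame(trial = seq_len(T), prediction = pred,
                       volatility = vol, ess = ess),
            class = c("pf_trajectory", "data.frame"),
            n_particles = N, kind = "rbpf_hgf")
}

#' Bootstrap particle filter for binary outcomes
#'
#' Joint sequential Monte Carlo over both latent chains (mean and
#' precision) with Bernoulli likelihood weights; no Rao-Blackwellization is
#' possible because the sigmoid observation model breaks conjugacy.
#'
#' @inheritParams rbpf_vkf
#' @param observations 0/1 outcomes.
#' @return Data frame with `prediction` (posterior mean outcome
#'   probability `E[s(x_t)]`), `volatility` (inverse posterior-mean
#'   precision) and `ess`; class `"pf_trajectory"`.
#' @export
pf_binary <- function(observations, lambda, v0, n_particles = 10000,
                      shape = 10, m0 = 0) {
  check_obs(observations, binary = TRUE)
  if (n_particles < 2) stop("need at least 2 particles")
  T <- length(observations)
  N <- n_particles
  x <- rep(m0, N)
  z <- rep(1 / v0, N)
  wt <- rep(1 / N, N)
  pred <- vol <- ess <- numeric(T)
  for (t in seq_len(T)) {
    x <- x + rnorm(N, 0, sqrt(1 / z))
    p <- sigmoid(x)
    logw <- log(wt) +
      if (observations[t] > 0.5) log(p) else log1p(-p)
    wt <- normalise_weights(logw, t)
    pred[t] <- sum(wt * p)
    vol[t] <- 1 / sum(wt * z)
    z <- z * sample_precision_noise(N, lambda, shape)
    ess[t] <- 1 / sum(wt^2)
    if (ess[t] < N / 2) {
      idx <- systematic_resample(wt)
      x <- x[idx]; z <- z[idx]
      wt <- rep(1 / N, N)
    }
  }
  structure(data.frame(trial = seq_len(T), prediction = pred,
                       volatility = vol, ess = ess),
            class = c("pf_trajectory", "data.frame"),
            n_particles = N, kind = "pf_binary")
}

#' Relative error of a filter against a near-exact benchmark
#'
#' `median(|pred_model - x_true|) / median(|pred_benchmark - x_true|) - 1`:
#' the model's excess state-estimation error as a fraction of the
#' benchmark's unavoidable error. Zero means the model matches the
#' benchmark; 0.23 means 23% more error.
#'
#' @param pred_model,pred_benchmark,x_true Equal-length numeric vectors.
#' @return A single fraction (>= -1 by construction).
#' @export
relative_error <- function(pred_model, pred_benchmark, x_true) {
  stopifnot(length(pred_model) == length(x_true),
            length(pred_benchmark) == length(x_true))
  eb <- median(abs(pred_benchmark - x_true))
  if (eb == 0) stop("benchmark error is zero; relative error undefined")
  median(abs(pred_model - x_true)) / eb - 1
}

#' Correlation between two signals, and Fisher averaging across runs
#'
#' `correlation_summary()` computes a single-run correlation (Spearman by
#' default, since filter signals are rarely normal); a constant series has
#' no defined correlation and yields `NA` with a warning. `fisher_average()`
#' averages correlation coefficients across runs on the Fisher-z scale and
#' transforms back.
#'
#' @param a,b Paired numeric vectors (length >= 3 after removing `NA`s).
#' @param method `"spearman"` or `"pearson"`.
#' @param r Vector of correlation coefficients (`NA`s dropped).
#' @return A single coefficient in `[-1, 1]`.
#' @examples
#' fisher_average(c(0.2, 0.8))  # ~0.5493, not 0.5
#' @export
correlation_summary <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("need at least 3 paired finite points")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
    warning("constant series: correlation undefined")
    return(NA_real_)
  }
  cor(a[ok], b[ok], method = method)
}

#' @rdname correlation_summary
#' @export
fisher_average <- function(r) {
  r <- r[is.finite(r)]
  if (!length(r)) return(NA_real_)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tanh(mean(atanh(r)))
}

#' Accuracy experiment: filter versus its own particle-filter reference
#'
#' Repeats the protocol "generate from a model's own generative process,
#' run the approximate filter with the true parameters, score its state
#' predictions against ground truth relative to a matched
#' Rao-Blackwellized particle filter" and aggregates the per-repetition
#' [relative_error()]. HGF repetitions whose inference trajectory fails
#' numerically are excluded from the error average and counted.
#'
#' Default generative regimes: `lambda = 0.15, v0 = 1, sigma2 = 1` for the
#' volatility process and `nu = 0.5, kappa = 1, omega = -3, sigma2 = 1`
#' (initial means 0 and 1) for the HGF cascade, 100 trials per repetition.
#'
#' @param generator `"vkf"` or `"hgf"`: which generative model (and which
#'   matched inference filter) to study.
#' @param n_reps Number of repetitions.
#' @param n_trials Trials per repetition (default 100).
#' @param n_particles Particles in the benchmark filter.
#' @param params Optional named list overriding the generative parameters.
#' @param seed Optional integer seed.
#' @return A list of class `"benchmark_report"`: per-rep `rel_errors`,
#'   `mean`, `se` (SD over valid runs / sqrt(valid runs)), `n_invalid`,
#'   `n_valid`, and the settings used.
#' @export
accuracy_experiment <- function(generator = c("vkf", "hgf"), n_reps = 100,
                                n_trials = 100, n_particles = 2000,
                                params = list(), seed = NULL) {
  generator <- match.arg(generator)
  if (!is.null(seed)) set.seed(seed)
  defaults <- if (generator == "vkf")
    list(lambda = 0.15, v0 = 1, sigma2 = 1, shape = 10)
  else
    list(nu = 0.5, kappa = 1, omega = -3, sigma2 = 1, mu2_0 = 0, mu3_0 = 1)
  p <- modifyList(defaults, params)
  rel <- rep(NA_real_, n_reps)
  invalid <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    if (generator == "vkf") {
      g <- simulate_vkf_process(n_trials, p$lambda, p$v0, p$sigma2,
                                shape = p$shape)
      f <- run_filter("vkf", vkf_params(p$lambda, p$v0, sigma2 = p$sigma2),
                      g$outcome)
      b <- rbpf_vkf(g$outcome, p$lambda, p$v0, p$sigma2, n_particles,
                    shape = p$shape)
      rel[r] <- relative_error(f$m, b$prediction, g$x_true)
    } else {
      g <- simulate_hgf_process(n_trials, p$nu, p$kappa, p$omega, p$sigma2,
                                p$mu2_0, p$mu3_0)
      f <- hgf2_filter(g$outcome, p$nu, p$kappa, p$omega, p$sigma2,
                       mu2_0 = p$mu2_0, mu3_0 = p$mu3_0)
      if (detect_numerical_problem(f)$failed) {
        invalid[r] <- TRUE
        next
      }
      b <- rbpf_hgf(g$outcome, p$nu, p$kappa, p$omega, p$sigma2,
                    n_particles, p$mu2_0, p$mu3_0)
      rel[r] <- relative_error(f$mu2, b$prediction, g$x_true)
    }
  }
  ok <- !is.na(rel)
  structure(list(rel_errors = rel, mean = mean(rel[ok]),
                 se = sd(rel[ok]) / sqrt(sum(ok)),
                 n_invalid = sum(invalid), n_valid = sum(ok),
                 generator = generator, n_reps = n_reps,
                 n_trials = n_trials, n_particles = n_particles,
                 params = p, seed = seed),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>", x$generator, "generator |", x$n_reps,
      "reps x", x$n_trials, "trials |", x$n_particles, "particles\n")
  cat(sprintf("mean relative error: %.1f%% (SE %.1f%%), valid runs %d, invalid %d\n",
              100 * x$mean, 100 * x$se, x$n_valid, x$n_invalid))
  invisible(x)
}

#' Write a benchmark report to JSON and CSV
#'
#' @param report A `"benchmark_report"`.
#' @param stem Output path stem; writes `<stem>.json` (summary) and
#'   `<stem>.csv` (per-repetition errors).
#' @return The two paths, invisibly.
#' @export
write_benchmark_report <- function(report, stem) {
  jf <- paste0(stem, ".json")
  cf <- paste0(stem, ".csv")
  jsonlite::write_json(
    list(generator = report$generator, mean = report$mean, se = report$se,
         n_valid = report$n_valid, n_invalid = report$n_invalid,
         n_reps = report$n_reps, n_trials = report$n_trials,
         n_particles = report$n_particles, seed = report$seed),
    jf, auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(rep = seq_along(report$rel_errors),
                       rel_error = report$rel_errors,
                       valid = !is.na(report$rel_errors)),
            cf, row.names = FALSE)
  invisible(c(jf, cf))
}
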