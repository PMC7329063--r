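#' Multiplicative precision-diffusion noise
#'
#' Draws the positive noise factor that diffuses the latent precision in
#' the volatility process: `eps = eta / (1 - lambda)` with
#' `eta ~ Beta((1 - lambda) * shape, lambda * shape)`. The factor has mean
#' exactly 1 (the precision is a martingale in the mean) and support
#' `(0, (1 - lambda)^-1)`; larger `lambda` gives faster diffusion. The
#' construction preserves Gamma conjugacy: if `z ~ Gamma(shape, rate)` then
#' `z * eps ~ Gamma((1 - lambda) * shape, (1 - lambda) * rate)`.
#'
#' @param n Number of draws.
#' @param lambda Diffusion (volatility update) rate, strictly inside (0, 1).
#' @param shape Concentration of the Beta noise (> 0); larger values give
#'   tighter noise around 1. Default 10.
#' @return Numeric vector of `n` positive draws.
#' @export
sample_precision_noise <- function(n, lambda, shape = 10) {
  if (lambda <= 0 || lambda >= 1)
    stop("lambda must lie strictly inside (0, 1)")
  if (shape <= 0) stop("shape must be positive")
  rbeta(n, (1 - lambda) * shape, lambda * shape) / (1 - lambda)
}

new_gen_process <- function(df, switch_times = integer(0), seed = NULL,
                            kind = "gen_process", extra = list()) {
  attr(df, "switch_times") <- switch_times
  attr(df, "seed") <- seed
  attr(df, "kind") <- kind
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("gen_process", "data.frame")
  df
}

#' @export
print.gen_process <- function(x, ...) {
  cat("<gen_process>", attr(x, "kind"), "| trials:", nrow(x), "\n")
  sw <- attr(x, "switch_times")
  if (length(sw)) cat("switch times:", paste(sw, collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Simulate the volatility-process generative model
#'
#' Samples the two interconnected latent chains of the volatile
#' environment: a precision `z_t = z_{t-1} * eps_t` diffusing by
#' multiplicative Beta noise (see [sample_precision_noise()]), and a mean
#' `x_t ~ Normal(x_{t-1}, 1 / z_{t-1})` diffusing at the speed set by the
#' precision. Outcomes are `Normal(x_t, sigma2)` (Gaussian emission) or
#' `Bernoulli(s(x_t))` (binary emission).
#'
#' @param n_trials Number of trials.
#' @param lambda Volatility diffusion rate in (0, 1).
#' @param v0 Initial volatility; the initial precision is `1 / v0`.
#' @param sigma2 Observation variance (Gaussian emission only).
#' @param emission `"gaussian"` or `"bernoulli"`.
#' @param x0 Initial latent mean.
#' @param shape Beta concentration of the precision noise.
#' @param seed Optional integer seed (`set.seed()` is called when given).
#' @return A `"gen_process"` data frame with columns `trial`, `x_true`,
#'   `z_true`, `outcome`.
#' @examples
#' p <- simulate_vkf_process(100, lambda = 0.15, v0 = 1, sigma2 = 1, seed = 1)
#' @export
simulate_vkf_process <- function(n_trials, lambda, v0, sigma2 = 1,
                                 emission = c("gaussian", "bernoulli"),
                                 x0 = 0, shape = 10, seed = NULL) {
  emission <- match.arg(emission)
  if (v0 <= 0) stop("v0 must be positive")
  if (!is.null(seed)) set.seed(seed)
  eps <- sample_precision_noise(n_trials, lambda, shape)
  z <- numeric(n_trials)
  x <- numeric(n_trials)
  zc <- 1 / v0
  xc <- x0
  for (t in seq_len(n_trials)) {
    x[t] <- rnorm(1, xc, sqrt(1 / zc))
    z[t] <- zc * eps[t]
    xc <- x[t]
    zc <- z[t]
  }
  o <- if (emission == "gaussian") rnorm(n_trials, x, sqrt(sigma2))
       else rbinom(n_trials, 1, sigmoid(x))
  new_gen_process(
    data.frame(trial = seq_len(n_trials), x_true = x, z_true = z,
               outcome = o),
    seed = seed, kind = paste0("vkf_process/", emission))
}

#' Simulate the hierarchical Gaussian filter generative cascade
#'
#' Three hierarchically coupled chains: `x3(t) ~ Normal(x3(t-1), nu)`,
#' `x2(t) ~ Normal(x2(t-1), exp(kappa * x3(t) + omega))` and the observed
#' outcome `o_t = x1(t) ~ Normal(x2(t-1), sigma2)`, sampled exactly in this
#' form. The scored latent variable is `x2`.
#'
#' @param n_trials Number of trials.
#' @param nu Variance of the third-level walk (> 0).
#' @param kappa Coupling from level 3 to level 2 (> 0).
#' @param omega Tonic log-variance at level 2.
#' @param sigma2 Observation variance.
#' @param mu2_0,mu3_0 Initial values of levels 2 and 3 (defaults 0 and 1).
#' @param seed Optional integer seed.
#' @return A `"gen_process"` data frame with columns `trial`, `x_true`
#'   (level 2), `x3_true`, `outcome`.
#' @export
simulate_hgf_process <- function(n_trials, nu = 0.5, kappa = 1, omega = -3,
                                 sigma2 = 1, mu2_0 = 0, mu3_0 = 1,
                                 seed = NULL) {
  if (nu <= 0 || kappa <= 0) stop("nu and kappa must be positive")
  if (!is.null(seed)) set.seed(seed)
  x3 <- numeric(n_trials)
  x2 <- numeric(n_trials)
  o <- numeric(n_trials)
  x3c <- mu3_0
  x2c <- mu2_0
  for (t in seq_len(n_trials)) {
    x3[t] <- rnorm(1, x3c, sqrt(nu))
    ex <- kappa * x3[t] + omega
    if (ex > 700) stop("diffusion variance overflow at trial ", t)
    o[t] <- rnorm(1, x2c, sqrt(sigma2))
    x2[t] <- rnorm(1, x2c, sqrt(exp(ex)))
    x3c <- x3[t]
    x2c <- x2[t]
  }
  new_gen_process(
    data.frame(trial = seq_len(n_trials), x_true = x2, x3_true = x3,
               outcome = o),
    seed = seed, kind = "hgf_process")
}

#' Switching probabilistic task
#'
#' Piecewise-constant hidden state that reverses between two levels at
#' block boundaries, emitting either Gaussian outcomes around the state or
#' Bernoulli outcomes at the state's reward probability. The default
#' schedule mirrors the reversal tasks used to probe volatility learning:
#' a long stable block followed by several short (volatile) blocks.
#'
#' @param block_lengths Integer vector of block lengths; total trials is
#'   their sum. Default `c(100, 25, 25, 25, 25)` (four reversals).
#' @param emission `"gaussian"` or `"binary"`.
#' @param states The two alternating hidden-state values (Gaussian
#'   emission). Default `c(1, -1)`.
#' @param emission_sd Gaussian emission standard deviation (default 0.1).
#' @param probs The two alternating reward probabilities (binary emission).
#'   Default `c(0.8, 0.2)`.
#' @param seed Optional integer seed.
#' @return A `"gen_process"` data frame with columns `trial`, `x_true`
#'   (state value or reward probability), `outcome`, `is_switch`; switch
#'   times (1-based first trial of each new block) in
#'   `attr(, "switch_times")`.
#' @examples
#' task <- simulate_switching_task(emission = "binary", seed = 1)
#' @export
simulate_switching_task <- function(block_lengths = c(100, 25, 25, 25, 25),
                                    emission = c("gaussian", "binary"),
                                    states = c(1, -1), emission_sd = 0.1,
                                    probs = c(0.8, 0.2), seed = NULL) {
  emission <- match.arg(emission)
  if (any(block_lengths < 1)) stop("block lengths must be positive")
  if (emission == "binary" && any(probs <= 0 | probs >= 1))
    stop("reward probabilities must lie strictly inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- length(block_lengths)
  level <- rep(rep_len(if (emission == "gaussian") states else probs,
                       n_blocks), block_lengths)
  T <- length(level)
  o <- if (emission == "gaussian") rnorm(T, level, emission_sd)
       else rbinom(T, 1, level)
  switch_times <- if (n_blocks > 1)
    as.integer(cumsum(block_lengths)[-n_blocks]) + 1L else integer(0)
  is_switch <- seq_len(T) %in% switch_times
  new_gen_process(
    data.frame(trial = seq_len(T), x_true = level, outcome = o,
               is_switch = is_switch),
    switch_times = switch_times, seed = seed,
    kind = paste0("switching_task/", emission),
    extra = list(block_lengths = block_lengths))
}

#' Export a generated process as delimited text
#'
#' Columns: `trial`, `x_true`, `z_true` (or `x3_true` when present),
#' `outcome`, `is_switch`.
#'
#' @param proc A `"gen_process"`.
#' @param file CSV path.
#' @return The path, invisibly.
#' @export
write_gen_process <- function(proc, file) {
  df <- as.data.frame(proc)
  if (is.null(df$is_switch))
    df$is_switch <- df$trial %in% attr(proc, "switch_times")
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Generate synthetic go/no-go subjects from the binary VKF
#'
#' Emulates the multi-cue probabilistic go/no-go design: each subject
#' carries an independent binary VKF per cue; on each trial the outcome is
#' drawn from the agent's own one-step-ahead prediction
#' `Bernoulli(s(m_{t-1}))` and the choice from a softmax on `m_{t-1}` with
#' decision noise `beta`. Subject-level parameters are drawn around the
#' group values in unconstrained (raw) space with standard deviation
#' `subject_sd`, then mapped through the fitting transforms (see
#' [transform_params()]).
#'
#' @param n_subjects Number of subjects (default 50).
#' @param n_cues Cues per subject (default 4).
#' @param n_trials Trials per cue (default 120).
#' @param group_params Named group-truth parameters on the natural scale:
#'   `lambda`, `v0`, `omega`, `beta`.
#' @param subject_sd Standard deviation of subject draws in raw space
#'   (default 0.5; 0 makes all subjects identical).
#' @param mean_step Binary-VKF mean-step convention for the simulated
#'   agents (see [vkf_params()]).
#' @param seed Optional integer seed.
#' @return A list of subjects; each has `raw` and `natural` parameter
#'   vectors and `data` (lists `outcomes` and `choices`, one 0/1 vector per
#'   cue). Use [subjects_to_frame()] for a flat per-trial table.
#' @export
generate_synthetic_subjects <- function(n_subjects = 50, n_cues = 4,
                                        n_trials = 120,
                                        group_params = c(lambda = 0.2,
                                                         v0 = 5, omega = 1,
                                                         beta = 1),
                                        subject_sd = 0.5,
                                        mean_step = c("variance", "sd"),
                                        seed = NULL) {
  mean_step <- match.arg(mean_step)
  if (!is.null(seed)) set.seed(seed)
  kinds <- vkf_choice_transforms()
  group_raw <- untransform_params(group_params, kinds)
  lapply(seq_len(n_subjects), function(s) {
    raw <- group_raw + rnorm(length(group_raw), 0, subject_sd)
    nat <- transform_params(raw, kinds)
    dat <- lapply(seq_len(n_cues), function(cue) {
      cpp_simulate_gonogo(n_trials, nat[["lambda"]], nat[["v0"]],
                          nat[["omega"]], nat[["beta"]], 0, nat[["omega"]],
                          identical(mean_step, "sd"))
    })
    list(id = s, raw = raw, natural = nat,
         data = list(outcomes = lapply(dat, `[[`, "outcome"),
                     choices = lapply(dat, `[[`, "choice")))
  })
}

#' Flatten synthetic subjects into a per-trial table
#'
#' @param subjects Output of [generate_synthetic_subjects()].
#' @return Data frame with columns `subject`, `trial`, `cue`, `emotion`,
#'   `valence`, `value`, `outcome`, `choice`. The four cues are tagged with
#'   the 2 x 2 emotion/valence combinations (recycled beyond four cues);
#'   `value` is `NA` for this design.
#' @export
subjects_to_frame <- function(subjects) {
  emo <- c("happy", "angry", "happy", "angry")
  val <- c("reward", "reward", "punish", "punish")
  do.call(rbind, lapply(subjects, function(s) {
    do.call(rbind, lapply(seq_along(s$data$outcomes), function(cue) {
      o <- s$data$outcomes[[cue]]
      data.frame(subject = s$id, trial = seq_along(o), cue = cue,
                 emotion = emo[(cue - 1L) %% 4L + 1L],
                 valence = val[(cue - 1L) %% 4L + 1L],
                 value = NA_real_, outcome = o,
                 choice = s$data$choices[[cue]])
    }))
  }))
}
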