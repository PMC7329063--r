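#' Parameter containers for the filtering algorithms
#'
#' Constructors validate and bundle the parameters of the Kalman filter,
#' the (binary) volatile Kalman filter and the Rescorla-Wagner rule.
#'
#' For the VKF, `lambda` is the volatility update rate: the step size of the
#' second error-correcting rule that tracks the process variance. `lambda = 0`
#' is the Kalman degenerate case in which the volatility stays at `v0`
#' forever. Exactly one of `sigma2` (Gaussian observations) or `omega`
#' (binary observations, an inference-only noise parameter) must be given.
#' Initial conditions default to a scale-matched neutral start: `m0 = 0` and
#' `w0 = sigma2` (Gaussian) or `w0 = omega` (binary).
#'
#' @param v Process variance of the Kalman filter (> 0).
#' @param sigma2 Observation variance (> 0).
#' @param m0 Initial posterior mean.
#' @param w0 Initial posterior variance (> 0).
#' @param lambda Volatility update rate, in `[0, 1)`.
#' @param v0 Initial volatility (> 0).
#' @param omega Noise parameter of the binary VKF (> 0).
#' @param alpha Fixed learning rate of the Rescorla-Wagner rule, in (0, 1).
#' @param init Initial value of the Rescorla-Wagner rule.
#' @param mean_step Step-size convention for the binary VKF's mean update:
#'   `"variance"` (default) uses `alpha = w + v`; `"sd"` uses
#'   `alpha = sqrt(w + v)`, the scale that moment matching yields for a
#'   Bernoulli observation of a wide Gaussian latent (the assumed-density
#'   update coefficient `s / sqrt(1 + pi * s / 8)` grows like `sqrt(s)`).
#'   The `"sd"` variant tracks switching tasks much more sharply at small
#'   `omega` and is the convention under which the particle-filter
#'   benchmark agreement figures are reproduced; see the methods vignette.
#' @return A named list of validated parameters with class
#'   `"kalman_params"`, `"vkf_params"` or `"rw_params"`.
#' @examples
#' kalman_params(v = 1, sigma2 = 2)
#' vkf_params(lambda = 0.1, v0 = 0.1, sigma2 = 0.1)
#' vkf_params(lambda = 0.1, v0 = 0.1, omega = 0.1)  # binary variant
#' @export
kalman_params <- function(v, sigma2, m0 = 0, w0 = sigma2) {
  stopifnot(is.numeric(v), is.numeric(sigma2))
  if (v <= 0) stop("process variance `v` must be positive")
  if (sigma2 <= 0) stop("observation variance `sigma2` must be positive")
  if (w0 <= 0) stop("initial variance `w0` must be positive")
  structure(list(v = v, sigma2 = sigma2, m0 = m0, w0 = w0),
            class = "kalman_params")
}

#' @rdname kalman_params
#' @export
vkf_params <- function(lambda, v0, sigma2 = NULL, omega = NULL,
                       m0 = 0, w0 = NULL,
                       mean_step = c("variance", "sd")) {
  mean_step <- match.arg(mean_step)
  if (lambda < 0 || lambda >= 1)
    stop("volatility update rate `lambda` must lie in [0, 1)")
  if (v0 <= 0) stop("initial volatility `v0` must be positive")
  if (is.null(sigma2) == is.null(omega))
    stop("give exactly one of `sigma2` (Gaussian) or `omega` (binary)")
  variant <- if (is.null(omega)) "vkf" else "binary_vkf"
  noise <- if (variant == "vkf") sigma2 else omega
  if (noise <= 0) stop("observation noise parameter must be positive")
  w0 <- w0 %||% noise
  if (w0 <= 0) stop("initial variance `w0` must be positive")
  structure(list(lambda = lambda, v0 = v0, sigma2 = sigma2, omega = omega,
                 m0 = m0, w0 = w0, variant = variant,
                 mean_step = mean_step),
            class = "vkf_params")
}

#' @rdname kalman_params
#' @export
rw_params <- function(alpha, init = 0) {
  if (alpha <= 0 || alpha >= 1)
    stop("Rescorla-Wagner learning rate must lie in (0, 1)")
  structure(list(alpha = alpha, init = init), class = "rw_params")
}

check_obs <- function(o, binary = FALSE) {
  if (length(o) == 0) stop("observation sequence is empty")
  bad <- which(!is.finite(o))
  if (length(bad))
    stop("non-finite observation at trial ", bad[1])
  if (binary && !all(o %in% c(0, 1)))
    stop("binary filter requires observations in {0, 1}")
  invisible(o)
}

#' Single-trial filter updates
#'
#' One step of the Kalman filter, the volatile Kalman filter (VKF), or the
#' binary VKF. Each takes the posterior summary carried over from the
#' previous trial, a new outcome, and a parameter object, and returns the
#' updated posterior summary. `run_filter()` applies these recursions over a
#' whole sequence; the step functions expose the algebra for a single trial.
#'
#' All three share the uncertainty bookkeeping of the Kalman filter: gain
#' `k = (w + v) / (w + v + noise)`, posterior variance `w' = (1 - k)(w + v)`
#' and autocovariance between consecutive states `cov = (1 - k) w`. The VKF
#' variants additionally update the volatility by a second error-correcting
#' rule, `v' = v + lambda * ((m' - m)^2 + w' + w - 2 cov - v)`, whose error
#' term is the expected squared state change minus the current volatility.
#' The binary VKF updates the mean with learning rate `alpha = w + v` on the
#' moment-matched prediction error `o - s(m)` where `s` is the logistic
#' sigmoid.
#'
#' @param state List with elements `m` (posterior mean), `w` (posterior
#'   variance) and, for the VKF variants, `v` (volatility).
#' @param o A single outcome; must be 0 or 1 for [binary_vkf_step()].
#' @param params A [kalman_params()] or [vkf_params()] object.
#' @return A list with the updated `m`, `w`, gain `k`, autocovariance
#'   `autocov`, plus `v` for VKF variants and learning rate `alpha` for the
#'   binary VKF.
#' @examples
#' kalman_step(list(m = 0, w = 1), 2, kalman_params(v = 1, sigma2 = 2))
#' vkf_step(list(m = 0, w = 1, v = 1), 1,
#'          vkf_params(lambda = 0.1, v0 = 1, sigma2 = 1))
#' @export
kalman_step <- function(state, o, params) {
  check_obs(o)
  if (state$w <= 0) stop("posterior variance must be positive")
  pv <- state$w + params$v
  k <- pv / (pv + params$sigma2)
  m <- state$m + k * (o - state$m)
  list(m = m, w = (1 - k) * pv, k = k, autocov = (1 - k) * state$w)
}

#' @rdname kalman_step
#' @export
vkf_step <- function(state, o, params) {
  check_obs(o)
  if (state$w <= 0 || state$v <= 0)
    stop("posterior variance and volatility must be positive")
  pv <- state$w + state$v
  k <- pv / (pv + params$sigma2)
  m <- state$m + k * (o - state$m)
  w <- (1 - k) * pv
  autocov <- (1 - k) * state$w
  v <- state$v + params$lambda *
    ((m - state$m)^2 + w + state$w - 2 * autocov - state$v)
  list(m = m, w = w, v = v, k = k, autocov = autocov)
}

#' @rdname kalman_step
#' @export
binary_vkf_step <- function(state, o, params) {
  check_obs(o, binary = TRUE)
  if (state$w <= 0 || state$v <= 0)
    stop("posterior variance and volatility must be positive")
  pv <- state$w + state$v
  k <- pv / (pv + params$omega)
  alpha <- if (identical(params$mean_step, "sd")) sqrt(pv) else pv
  m <- state$m + alpha * (o - sigmoid(state$m))
  w <- (1 - k) * pv
  autocov <- (1 - k) * state$w
  v <- state$v + params$lambda *
    ((m - state$m)^2 + w + state$w - 2 * autocov - state$v)
  list(m = m, w = w, v = v, k = k, alpha = alpha, autocov = autocov)
}

#' Track a known-mean process variance by exponential error correction
#'
#' The elementary volatility tracker underlying the VKF: when a latent
#' variable `x` with known mean `mu` is observed directly, the posterior
#' over its diffusion precision stays Gamma and its inverse mean `v` obeys
#' `v' = v + lambda * ((x - mu)^2 - v)` - an error-correcting rule on the
#' difference between observed and expected squared deviations.
#'
#' @param v Current variance estimate (> 0).
#' @param x Observed latent value.
#' @param mu Known mean of the latent variable.
#' @param lambda Update rate in (0, 1).
#' @return Updated variance estimate (always positive).
#' @examples
#' variance_tracker_step(1, x = 2, mu = 0, lambda = 0.2)  # 1.6
#' @export
variance_tracker_step <- function(v, x, mu, lambda) {
  if (v <= 0) stop("variance estimate must be positive")
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  check_obs(x)
  v + lambda * ((x - mu)^2 - v)
}

#' Run a filter over a full observation sequence
#'
#' Applies the chosen recursion (Kalman filter, VKF, binary VKF or
#' Rescorla-Wagner) forward over `observations` and returns the per-trial
#' posterior summaries as a data frame. Strictly filtering: no smoothing.
#'
#' @param variant One of `"kalman"`, `"vkf"`, `"binary_vkf"`, `"rw"`.
#' @param params Matching parameter object from [kalman_params()],
#'   [vkf_params()] or [rw_params()].
#' @param observations Numeric vector of outcomes; must be 0/1 for the
#'   binary variant. Non-finite values are rejected with the trial index.
#' @return A data frame of class `"filter_trajectory"` with columns
#'   `trial`, `observation`, `prediction` (one-step-ahead: `m_{t-1}`, or
#'   `s(m_{t-1})` for the binary variant), `m`, `w`, `v`, `k`, `alpha`,
#'   `autocov`. Columns not defined for a variant are `NA`. The variant and
#'   parameters are stored as attributes.
#' @examples
#' o <- rnorm(50)
#' run_filter("vkf", vkf_params(0.1, 0.5, sigma2 = 1), o)
#' @export
run_filter <- function(variant = c("kalman", "vkf", "binary_vkf", "rw"),
                       params, observations) {
  variant <- match.arg(variant)
  check_obs(observations, binary = identical(variant, "binary_vkf"))
  T <- length(observations)
  na <- rep(NA_real_, T)
  res <- switch(variant,
    kalman = {
      stopifnot(inherits(params, "kalman_params"))
      f <- cpp_kalman_filter(observations, params$v, params$sigma2,
                             params$m0, params$w0)
      data.frame(trial = seq_len(T), observation = observations,
                 prediction = f$m_pre, m = f$m, w = f$w,
                 v = rep(params$v, T), k = f$k, alpha = f$k,
                 autocov = f$autocov)
    },
    vkf = {
      stopifnot(inherits(params, "vkf_params"),
                identical(params$variant, "vkf"))
      f <- cpp_vkf_filter(observations, params$lambda, params$v0,
                          params$sigma2, params$m0, params$w0)
      data.frame(trial = seq_len(T), observation = observations,
                 prediction = f$m_pre, m = f$m, w = f$w, v = f$v,
                 k = f$k, alpha = f$k, autocov = f$autocov)
    },
    binary_vkf = {
      stopifnot(inherits(params, "vkf_params"),
                identical(params$variant, "binary_vkf"))
      f <- cpp_bvkf_filter(observations, params$lambda, params$v0,
                           params$omega, params$m0, params$w0,
                           identical(params$mean_step, "sd"))
      data.frame(trial = seq_len(T), observation = observations,
                 prediction = f$p_pre, m = f$m, w = f$w, v = f$v,
                 k = f$k, alpha = f$alpha, autocov = f$autocov)
    },
    rw = {
      stopifnot(inherits(params, "rw_params"))
      f <- cpp_rw_filter(observations, params$alpha, params$init)
      data.frame(trial = seq_len(T), observation = observations,
                 prediction = f$m_pre, m = f$m, w = na, v = na, k = na,
                 alpha = rep(params$alpha, T), autocov = na)
    })
  attr(res, "variant") <- variant
  attr(res, "params") <- params
  class(res) <- c("filter_trajectory", "data.frame")
  res
}

#' @export
print.filter_trajectory <- function(x, ...) {
  cat("<filter_trajectory> variant:", attr(x, "variant"),
      "| trials:", nrow(x), "\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more trials)\n", sep = "")
  invisible(x)
}

#' Implied learning rate in observation space
#'
#' For a binary-variant trajectory, the ratio of the update size to the
#' prediction-error size measured in outcome units:
#' `(s(m_t) - s(m_{t-1})) / (o_t - s(m_{t-1}))`. Trials on which the
#' prediction error is (numerically) zero have no defined ratio and are
#' returned as `NA` rather than fabricated; exclude them from summaries.
#'
#' @param traj A `"filter_trajectory"` from `run_filter("binary_vkf", ...)`.
#' @param observations Optional outcome vector; defaults to the trajectory's
#'   own `observation` column.
#' @param tol Prediction errors below `tol` in magnitude are flagged `NA`.
#' @return Numeric vector of per-trial implied learning rates with `NA` at
#'   undefined trials.
#' @export
implied_obs_learning_rate <- function(traj, observations = NULL,
                                      tol = 1e-12) {
  if (!identical(attr(traj, "variant"), "binary_vkf"))
    stop("implied observation-space learning rate requires a binary VKF trajectory")
  o <- observations %||% traj$observation
  pe <- o - traj$prediction
  out <- (sigmoid(traj$m) - traj$prediction) / pe
  out[abs(pe) < tol] <- NA_real_
  out
}

#' Export a filter trajectory as delimited text
#'
#' Writes the mandated CSV schema (`trial`, `observation`, `prediction`,
#' `m`, `w`, `v`, `k`, `alpha`, `autocov`; header row; 1-based trials).
#'
#' @param traj A `"filter_trajectory"`.
#' @param file Path of the CSV file to create.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  cols <- c("trial", "observation", "prediction", "m", "w", "v", "k",
            "alpha", "autocov")
  extra <- setdiff(names(traj), cols)
  write.csv(as.data.frame(traj)[, c(cols, extra)], file, row.names = FALSE)
  invisible(file)
}

#' Read a filter configuration from YAML or JSON
#'
#' Schema: `variant` (kalman | vkf | binary_vkf | rw), `lambda`, `v0`,
#' `sigma2` or `omega`, `m0`, `w0` (and `v` for the Kalman filter,
#' `alpha` for Rescorla-Wagner). Returns the matching parameter object.
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` file.
#' @return A parameter object plus the variant, as
#'   `list(variant = , params = )`.
#' @export
read_filter_config <- function(file) {
  cfg <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
    yaml::read_yaml(file)
  } else if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::fromJSON(file)
  } else stop("config must be a .yaml/.yml or .json file")
  if (is.null(cfg$variant)) stop("config is missing `variant`")
  params <- switch(cfg$variant,
    kalman = kalman_params(cfg$v, cfg$sigma2, cfg$m0 %||% 0,
                           cfg$w0 %||% cfg$sigma2),
    vkf = vkf_params(cfg$lambda, cfg$v0, sigma2 = cfg$sigma2,
                     m0 = cfg$m0 %||% 0, w0 = cfg$w0),
    binary_vkf = vkf_params(cfg$lambda, cfg$v0, omega = cfg$omega,
                            m0 = cfg$m0 %||% 0, w0 = cfg$w0),
    rw = rw_params(cfg$alpha, cfg$init %||% 0),
    stop("unknown variant: ", cfg$variant))
  list(variant = cfg$variant, params = params)
}
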