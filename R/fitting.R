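#' Parameter transforms between raw (unconstrained) and natural space
#'
#' Fitting is done in unconstrained raw space; each parameter is mapped to
#' its natural range by a named transform kind:
#' \describe{
#'   \item{`unit`}{logistic sigmoid, for rates bounded in (0, 1)
#'     (`lambda`, `nu`, `kappa`).}
#'   \item{`unit10`}{`10 * sigmoid(raw)`, for the binary VKF's initial
#'     volatility `v0` (upper bound 10).}
#'   \item{`pos`}{`exp(raw)`, for positive parameters (`beta`, VKF `omega`).}
#'   \item{`shift`}{`raw - 1`, for the HGF's tonic log-variance so the
#'     filter is well defined at a raw prior mean of 0 (natural -1).}
#'   \item{`real`}{identity, for unconstrained biases.}
#' }
#' Raw 0 therefore maps to `lambda = 0.5`, `v0 = 5`, `beta = 1`,
#' HGF `omega = -1`.
#'
#' @param raw Named numeric vector of raw parameters.
#' @param kinds Character vector of transform kinds, same length/names.
#' @param natural Named numeric vector of natural parameters (inverse map).
#' @return Numeric vector in the other space, names preserved.
#' @examples
#' transform_params(c(lambda = 0, v0 = 0), c(lambda = "unit", v0 = "unit10"))
#' @export
transform_params <- function(raw, kinds) {
  stopifnot(length(raw) == length(kinds))
  out <- numeric(length(raw))
  for (i in seq_along(raw)) {
    out[i] <- switch(kinds[i],
      unit = sigmoid(raw[i]),
      unit10 = 10 * sigmoid(raw[i]),
      pos = exp(raw[i]),
      shift = raw[i] - 1,
      real = raw[i],
      stop("unknown transform kind: ", kinds[i]))
  }
  names(out) <- names(kinds) %||% names(raw)
  out
}

#' @rdname transform_params
#' @export
untransform_params <- function(natural, kinds) {
  stopifnot(length(natural) == length(kinds))
  out <- numeric(length(natural))
  for (i in seq_along(natural)) {
    out[i] <- switch(kinds[i],
      unit = qlogis(natural[i]),
      unit10 = qlogis(natural[i] / 10),
      pos = log(natural[i]),
      shift = natural[i] + 1,
      real = natural[i],
      stop("unknown transform kind: ", kinds[i]))
  }
  names(out) <- names(kinds) %||% names(natural)
  out
}

#' Transform maps for the built-in models
#'
#' @return Named character vector of transform kinds suitable for
#'   [transform_params()].
#' @export
vkf_choice_transforms <- function() {
  c(lambda = "unit", v0 = "unit10", omega = "pos", beta = "pos")
}

#' @rdname vkf_choice_transforms
#' @export
hgf_choice_transforms <- function() {
  c(nu = "unit", kappa = "unit", omega = "shift", beta = "pos")
}

#' @rdname vkf_choice_transforms
#' @export
vkf_series_transforms <- function() {
  c(lambda = "unit", v0 = "unit10", omega = "pos")
}

#' @rdname vkf_choice_transforms
#' @export
hgf_series_transforms <- function() {
  c(nu = "unit", kappa = "unit", omega = "shift")
}

#' Go/no-go softmax response model with stimulus biases
#'
#' Probability of a go response given the learner's value signal:
#' `p(a1) = 1 / (1 + exp(-(beta * value + b(s))))` where the
#' value-independent bias `b(s)` depends on the stimulus's emotional
#' content and outcome valence through three free parameters: happy and
#' rewarding `be + bv + bi`; angry and punishing `-be - bv + bi`; happy
#' and punishing `be - bv - bi`; angry and rewarding `-be + bv + bi`.
#'
#' @param values Per-trial value signal fed to the softmax (the binary
#'   VKF's one-step-ahead mean, or `2 * muhat1 - 1` for the HGF).
#' @param emotion Character vector, `"happy"` or `"angry"` per trial.
#' @param valence Character vector, `"reward"` or `"punish"` per trial.
#' @param beta Decision noise (> 0).
#' @param b_e,b_v,b_i Emotional, valence and interaction biases.
#' @param choice Optional 0/1 vector (1 = go); when given, the returned
#'   list also carries the per-trial probability of the observed choice.
#' @return List with `p_go` and (if `choice` given) `p_choice`.
#' @export
go_nogo_likelihood <- function(values, emotion, valence, beta,
                               b_e = 0, b_v = 0, b_i = 0, choice = NULL) {
  if (beta < 0) stop("decision noise beta must be non-negative")
  if (!all(emotion %in% c("happy", "angry")))
    stop("unknown emotion tag: ",
         paste(unique(setdiff(emotion, c("happy", "angry"))), collapse = ", "))
  if (!all(valence %in% c("reward", "punish")))
    stop("unknown valence tag: ",
         paste(unique(setdiff(valence, c("reward", "punish"))), collapse = ", "))
  bias <- ifelse(emotion == "happy",
                 ifelse(valence == "reward", b_e + b_v + b_i, b_e - b_v - b_i),
                 ifelse(valence == "reward", -b_e + b_v + b_i, -b_e - b_v + b_i))
  p_go <- sigmoid(beta * values + bias)
  out <- list(p_go = p_go)
  if (!is.null(choice))
    out$p_choice <- ifelse(choice > 0.5, p_go, 1 - p_go)
  out
}

#' Gamble (play/pass) softmax response model
#'
#' Expected value of playing is `p_reward * trial_value - (1 - p_reward) *
#' 10` (a failed play loses 10 points); passing earns 0 and its
#' hypothetical feedback does not enter the likelihood. Expected values are
#' divided by 100 (the task's maximum trial value) before the softmax.
#'
#' @param p_reward Per-trial estimated reward probability.
#' @param trial_value Per-trial value of a successful play.
#' @param beta Decision noise (> 0).
#' @param loss Points lost on an unrewarded play (default 10).
#' @param choice Optional 0/1 vector (1 = play).
#' @return List with `p_play` and (if `choice` given) `p_choice`.
#' @export
gamble_likelihood <- function(p_reward, trial_value, beta, loss = 10,
                              choice = NULL) {
  if (beta < 0) stop("decision noise beta must be non-negative")
  ev_play <- p_reward * trial_value - (1 - p_reward) * loss
  p_play <- sigmoid(beta * (ev_play - 0) / 100)
  out <- list(p_play = p_play)
  if (!is.null(choice))
    out$p_choice <- ifelse(choice > 0.5, p_play, 1 - p_play)
  out
}

#' Maximum-a-posteriori fit in raw parameter space
#'
#' Minimizes `objective(raw) + 0.5 * sum((raw - prior_mean)^2 / prior_var)`
#' (a Gaussian prior in unconstrained space) by quasi-Newton (BFGS) with
#' multiple restarts: the prior mean plus random perturbations, plus an
#' optional explicit warm start. Optimizer failures are flagged, never
#' silent.
#'
#' @param objective Function of the raw parameter vector returning a
#'   negative log likelihood.
#' @param transforms Named transform-kind vector (see
#'   [transform_params()]); its length defines the dimension.
#' @param prior_mean,prior_var Prior mean(s) and variance(s) in raw space,
#'   recycled to the dimension. Defaults 0 and 6.25.
#' @param n_starts Number of optimizer starts (default 10).
#' @param start Optional explicit starting vector tried first.
#' @param hessian Compute the Hessian at the optimum (for Laplace
#'   evidence).
#' @return A list of class `"fit_result"`: `raw`, `natural`, `value`
#'   (negative log posterior), `convergence` (TRUE if the best start
#'   converged), `n_starts`, and optionally `hessian`.
#' @export
map_fit <- function(objective, transforms, prior_mean = 0, prior_var = 6.25,
                    n_starts = 10, start = NULL, hessian = FALSE) {
  k <- length(transforms)
  pm <- rep_len(prior_mean, k)
  pv <- rep_len(prior_var, k)
  if (any(pv <= 0)) stop("prior variances must be positive")
  fn <- function(raw) {
    val <- objective(raw) + 0.5 * sum((raw - pm)^2 / pv)
    if (!is.finite(val)) 1e12 else val
  }
  starts <- list(pm)
  if (n_starts > 1) {
    sdev <- pmin(sqrt(pv), 2)
    starts <- c(starts, lapply(seq_len(n_starts - 1), function(i)
      pm + rnorm(k, 0, sdev)))
  }
  if (!is.null(start)) starts <- c(list(rep_len(start, k)), starts)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, fn, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(optim(s, fn, method = "Nelder-Mead",
                            control = list(maxit = 2000)),
                      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  raw <- best$par
  names(raw) <- names(transforms)
  out <- list(raw = raw, natural = transform_params(raw, transforms),
              value = best$value, convergence = best$convergence == 0,
              n_starts = length(starts))
  if (hessian)
    out$hessian <- stats::optimHess(best$par, fn)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> -log posterior:", format(x$value),
      "| converged:", x$convergence, "\n")
  print(rbind(raw = x$raw, natural = x$natural))
  invisible(x)
}

#' Laplace approximation to the log model evidence
#'
#' `log p(data) ~ -value + (k/2) log(2*pi) - 0.5 log det(H)` at the MAP
#' optimum; a descriptive per-subject evidence for model comparison.
#'
#' @param fit A `"fit_result"` fitted with `hessian = TRUE`.
#' @return Approximate log evidence (scalar).
#' @export
laplace_evidence <- function(fit) {
  if (is.null(fit$hessian)) stop("fit was run without `hessian = TRUE`")
  k <- length(fit$raw)
  d <- determinant(fit$hessian, logarithm = TRUE)
  if (d$sign <= 0) return(NA_real_)
  -fit$value + 0.5 * k * log(2 * pi) - 0.5 * as.numeric(d$modulus)
}

#' Fit a learning model to a binary outcome time-series
#'
#' MAP fit of the binary VKF (`lambda`, `v0`, `omega`) or the 3-level
#' binary HGF (`nu`, `kappa`, `omega`) to an outcome sequence, scoring each
#' trial's one-step-ahead outcome prediction. Raw-space prior: mean 0
#' (which puts the HGF's `omega` at -1), variance 15.23.
#'
#' @param observations 0/1 outcome vector.
#' @param model `"vkf_binary"` or `"hgf_binary"`.
#' @param prior_var Raw-space prior variance (default 15.23).
#' @param n_starts Optimizer restarts (default 5).
#' @return A `"fit_result"`.
#' @export
fit_series <- function(observations, model = c("vkf_binary", "hgf_binary"),
                       prior_var = 15.23, n_starts = 5) {
  model <- match.arg(model)
  check_obs(observations, binary = TRUE)
  if (model == "vkf_binary") {
    tr <- vkf_series_transforms()
    obj <- function(raw) {
      nat <- transform_params(raw, tr)
      cpp_bvkf_nll(observations, nat[["lambda"]], nat[["v0"]],
                   nat[["omega"]], 0, nat[["omega"]])
    }
  } else {
    tr <- hgf_series_transforms()
    obj <- function(raw) {
      nat <- transform_params(raw, tr)
      cpp_hgf3bin_nll(observations, nat[["nu"]], nat[["kappa"]],
                      nat[["omega"]], 0, 1, 0.1, 1)
    }
  }
  map_fit(obj, tr, prior_mean = 0, prior_var = prior_var,
          n_starts = n_starts)
}

normalise_subject <- function(s) {
  if (!is.null(s$data)) s$data else s
}

#' Hierarchical empirical-Bayes group fit of the go/no-go choice model
#'
#' Iterated empirical Bayes: each subject's binary-VKF + softmax
#' parameters (`lambda`, `v0`, `omega`, `beta`) are fitted by MAP under a
#' Gaussian group prior in raw space; the group mean and variance are then
#' re-estimated and the subjects refitted (warm-started) until the group
#' means move less than `tol`. The first pass uses the fixed prior (mean
#' 0, variance 6.25). The group-variance update adds each subject's
#' Laplace posterior variance (inverse Hessian diagonal) to the spread of
#' the point estimates - the EM update for a Gaussian random-effects
#' model - which prevents the prior from collapsing onto the point
#' estimates; it is additionally floored at `var_floor`. The posterior
#' variances are computed once, on the first pass, and reused across
#' iterations (they change little once the fits are warm).
#'
#' @param subjects List of subjects, each either
#'   `list(outcomes = , choices = )` (one 0/1 vector per cue) or the
#'   structure produced by [generate_synthetic_subjects()].
#' @param init_prior_var First-pass prior variance (default 6.25).
#' @param max_iter Maximum empirical-Bayes iterations (default 20).
#' @param tol Convergence tolerance on the raw group means.
#' @param var_floor Lower bound on group variances (default 1e-6).
#' @param n_starts Optimizer starts for the first pass (default 2); later
#'   passes warm-start from the previous estimates.
#' @param mean_step Binary-VKF mean-step convention used in the subjects'
#'   learning model (see [vkf_params()]); must match how the data were
#'   generated.
#' @return A list of class `"group_fit"`: `raw` and `natural` per-subject
#'   matrices, `group_raw_mean`, `group_raw_var`, `group_natural_mean`
#'   (mean of per-subject natural parameters, the recovery summary),
#'   `iterations`, `converged`.
#' @export
hierarchical_fit <- function(subjects, init_prior_var = 6.25, max_iter = 20,
                             tol = 1e-3, var_floor = 1e-6, n_starts = 2,
                             mean_step = c("variance", "sd")) {
  if (length(subjects) < 2) stop("need at least 2 subjects")
  mean_step <- match.arg(mean_step)
  sd_step <- identical(mean_step, "sd")
  tr <- vkf_choice_transforms()
  dat <- lapply(subjects, normalise_subject)
  make_obj <- function(d) {
    force(d)
    function(raw) {
      nat <- transform_params(raw, tr)
      cpp_gonogo_nll(d$outcomes, d$choices, nat[["lambda"]], nat[["v0"]],
                     nat[["omega"]], nat[["beta"]], 0, nat[["omega"]],
                     sd_step)
    }
  }
  objs <- lapply(dat, make_obj)
  post_var <- function(f) {
    # Laplace posterior variances; zero (pure shrinkage) if the Hessian
    # is not usable
    v <- tryCatch(diag(solve(f$hessian)), error = function(e) NULL)
    if (is.null(v) || any(!is.finite(v)) || any(v < 0))
      rep(0, length(f$raw)) else v
  }
  fits <- lapply(objs, map_fit, transforms = tr, prior_mean = 0,
                 prior_var = init_prior_var, n_starts = n_starts,
                 hessian = TRUE)
  raw_mat <- do.call(rbind, lapply(fits, `[[`, "raw"))
  pv_mat <- do.call(rbind, lapply(fits, post_var))
  mu_g <- colMeans(raw_mat)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    var_g <- pmax(colMeans(sweep(raw_mat, 2, mu_g)^2) + colMeans(pv_mat),
                  var_floor)
    fits <- lapply(seq_along(objs), function(i)
      map_fit(objs[[i]], tr, prior_mean = mu_g, prior_var = var_g,
              n_starts = 1, start = raw_mat[i, ]))
    raw_mat <- do.call(rbind, lapply(fits, `[[`, "raw"))
    mu_new <- colMeans(raw_mat)
    moved <- max(abs(mu_new - mu_g))
    mu_g <- mu_new
    if (moved < tol) {
      converged <- TRUE
      break
    }
  }
  nat_mat <- t(apply(raw_mat, 1, transform_params, kinds = tr))
  structure(list(raw = raw_mat, natural = nat_mat,
                 group_raw_mean = mu_g,
                 group_raw_var = pmax(colMeans(sweep(raw_mat, 2, mu_g)^2) +
                                        colMeans(pv_mat), var_floor),
                 group_natural_mean = colMeans(nat_mat),
                 iterations = it, converged = converged,
                 mean_step = mean_step,
                 subject_converged = vapply(fits, `[[`, TRUE, "convergence")),
            class = "group_fit")
}

#' @export
print.group_fit <- function(x, ...) {
  cat("<group_fit>", nrow(x$raw), "subjects |", x$iterations,
      "EB iterations | converged:", x$converged, "\n")
  print(rbind(`group mean (natural)` = x$group_natural_mean))
  invisible(x)
}

#' Parameter-recovery experiment for the binary VKF choice model
#'
#' Repeats: simulate a group of synthetic subjects from the binary VKF +
#' softmax (group truths `lambda = 0.2`, `v0 = 5`, `omega = 1`,
#' `beta = 1`; subject draws with raw-space SD 0.5; 4 cues x 120 trials),
#' fit them with [hierarchical_fit()], and record the group mean of the
#' per-subject natural parameters. Reports quartiles of these group means
#' across repetitions.
#'
#' @param n_reps Number of repetitions.
#' @param n_subjects,n_cues,n_trials Design (defaults 50, 4, 120).
#' @param group_params Named natural-scale group truths.
#' @param subject_sd Raw-space subject SD (default 0.5).
#' @param mean_step Binary-VKF mean-step convention used for both
#'   generation and fitting (see [vkf_params()]).
#' @param seed Optional integer seed.
#' @param ... Passed to [hierarchical_fit()].
#' @return A list of class `"recovery_report"`: `estimates` (reps x
#'   parameters matrix of group means), `quantiles` (25/50/75% per
#'   parameter), `truth`.
#' @export
recovery_experiment <- function(n_reps = 50, n_subjects = 50, n_cues = 4,
                                n_trials = 120,
                                group_params = c(lambda = 0.2, v0 = 5,
                                                 omega = 1, beta = 1),
                                subject_sd = 0.5,
                                mean_step = c("variance", "sd"),
                                seed = NULL, ...) {
  mean_step <- match.arg(mean_step)
  if (!is.null(seed)) set.seed(seed)
  est <- matrix(NA_real_, n_reps, length(group_params),
                dimnames = list(NULL, names(group_params)))
  for (r in seq_len(n_reps)) {
    subs <- generate_synthetic_subjects(n_subjects, n_cues, n_trials,
                                        group_params, subject_sd,
                                        mean_step = mean_step)
    fit <- hierarchical_fit(subs, mean_step = mean_step, ...)
    est[r, ] <- fit$group_natural_mean
  }
  qs <- apply(est, 2, quantile, probs = c(0.25, 0.5, 0.75))
  structure(list(estimates = est, quantiles = qs, truth = group_params,
                 n_reps = n_reps, n_subjects = n_subjects,
                 n_cues = n_cues, n_trials = n_trials,
                 subject_sd = subject_sd, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$n_reps, "reps x", x$n_subjects, "subjects\n")
  print(rbind(truth = x$truth, x$quantiles))
  invisible(x)
}

#' Change-point-locked learning-rate analysis
#'
#' Aligns a per-trial learning-rate signal to contingency switches and
#' compares the mean over the `window` trials before each switch with the
#' mean over the `window` trials from the switch onward. Windows that
#' would cross the trajectory boundary or a neighbouring switch are
#' truncated, not skipped.
#'
#' @param lr Per-trial learning-rate signal.
#' @param switch_times 1-based indices of the first trial of each new
#'   block; at least one required.
#' @param window Window half-width in trials (default 5).
#' @return A list: `curve` (data frame of mean learning rate by offset,
#'   offset 0 = first post-switch trial), `pre_mean`, `post_mean`,
#'   `difference` (post - pre), and `per_switch` (per-switch pre/post
#'   means).
#' @export
changepoint_locked_learning_rate <- function(lr, switch_times, window = 5) {
  T <- length(lr)
  if (!length(switch_times)) stop("no switch times supplied")
  if (any(switch_times < 1 | switch_times > T))
    stop("switch times outside trajectory")
  switch_times <- sort(switch_times)
  offsets <- seq(-window, window - 1)
  per <- lapply(seq_along(switch_times), function(i) {
    s <- switch_times[i]
    lo <- if (i > 1) switch_times[i - 1] else 1L
    hi <- if (i < length(switch_times)) switch_times[i + 1] - 1L else T
    pre_idx <- seq(max(s - window, lo), s - 1)
    pre_idx <- pre_idx[pre_idx >= 1]
    post_idx <- seq(s, min(s + window - 1, hi))
    vals <- rep(NA_real_, length(offsets))
    for (j in seq_along(offsets)) {
      tt <- s + offsets[j]
      if (tt >= max(lo, 1) && tt <= hi) vals[j] <- lr[tt]
    }
    list(pre = mean(lr[pre_idx]), post = mean(lr[post_idx]), vals = vals)
  })
  mat <- do.call(rbind, lapply(per, `[[`, "vals"))
  curve <- data.frame(offset = offsets,
                      mean_lr = colMeans(mat, na.rm = TRUE),
                      n = colSums(!is.na(mat)))
  pre <- mean(vapply(per, `[[`, 0, "pre"), na.rm = TRUE)
  post <- mean(vapply(per, `[[`, 0, "post"), na.rm = TRUE)
  list(curve = curve, pre_mean = pre, post_mean = post,
       difference = post - pre,
       per_switch = data.frame(switch = switch_times,
                               pre = vapply(per, `[[`, 0, "pre"),
                               post = vapply(per, `[[`, 0, "post")))
}

#' Learning-rate/volatility correlation experiment
#'
#' Quantifies the qualitative signature separating the binary VKF from the
#' binary HGF: the correlation between the latent-space learning rate and
#' the volatility estimate across switching-task series. Two protocols:
#' \describe{
#'   \item{`fitted`}{generate `n_series` binary switching-task series, fit
#'     the model to each by MAP (raw prior mean 0, variance 15.23), and
#'     correlate the learning-rate and volatility trajectories at the
#'     fitted parameters.}
#'   \item{`random`}{fix one outcome sequence and draw `n_series` random
#'     parameter settings within the fitted bounds, recording the
#'     correlation sign per setting.}
#' }
#' For the VKF the learning rate is `alpha_t = w_{t-1} + v_{t-1}` and the
#' volatility is the prediction-time estimate `v_{t-1}` (both signals
#' describe trial `t`'s update); for the HGF they are the level-2 update
#' coefficient and the prediction-time diffusion variance
#' `exp(kappa * mu3_{t-1} + omega)`. HGF settings whose trajectory fails
#' numerically are excluded and counted. Fitted mode starts the optimizer
#' at the prior mean (single start), mirroring the usual MAP protocol for
#' these models.
#'
#' @param n_series Number of series (fitted mode) or parameter draws
#'   (random mode).
#' @param model `"vkf_binary"` or `"hgf_binary"`.
#' @param mode `"fitted"` or `"random"`.
#' @param block_lengths Switching-task schedule (see
#'   [simulate_switching_task()]).
#' @param prior_var Raw prior variance for fitted mode (default 15.23).
#' @param method Correlation method, `"spearman"` (default, matching the
#'   treatment of other non-normal filter signals) or `"pearson"`;
#'   multi-series averaging is always Fisher-z.
#' @param n_starts Optimizer starts per series in fitted mode (default 1:
#'   the prior mean).
#' @param seed Optional integer seed.
#' @return A list: per-series `r`, `fisher_mean`, `frac_positive`,
#'   `frac_negative`, `n_invalid`, plus the protocol settings.
#' @export
lr_volatility_correlation_experiment <- function(
    n_series = 100, model = c("vkf_binary", "hgf_binary"),
    mode = c("fitted", "random"),
    block_lengths = c(100, 25, 25, 25, 25), prior_var = 15.23,
    method = c("spearman", "pearson"), n_starts = 1, seed = NULL) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  signal_cor <- function(o, nat) {
    if (model == "vkf_binary") {
      f <- cpp_bvkf_filter(o, nat[["lambda"]], nat[["v0"]], nat[["omega"]],
                           0, nat[["omega"]], FALSE)
      v_pred <- c(nat[["v0"]], f$v[-length(f$v)])
      cor(f$alpha, v_pred, method = method)
    } else {
      f <- cpp_hgf3bin_filter(o, nat[["nu"]], nat[["kappa"]],
                              nat[["omega"]], 0, 1, 0.1, 1)
      if (!f$valid) return(NA_real_)
      cor(f$lr, f$vol, method = method)
    }
  }
  r <- rep(NA_real_, n_series)
  if (mode == "fitted") {
    for (i in seq_len(n_series)) {
      task <- simulate_switching_task(block_lengths, emission = "binary")
      fit <- fit_series(task$outcome, model, prior_var = prior_var,
                        n_starts = n_starts)
      r[i] <- signal_cor(task$outcome, fit$natural)
    }
  } else {
    task <- simulate_switching_task(block_lengths, emission = "binary")
    for (i in seq_len(n_series)) {
      nat <- if (model == "vkf_binary") {
        c(lambda = runif(1, 0.05, 0.95), v0 = runif(1, 0.5, 10),
          omega = exp(runif(1, log(0.1), log(10))))
      } else {
        c(nu = runif(1, 0.05, 0.95), kappa = runif(1, 0.05, 0.95),
          omega = runif(1, -5, 1))
      }
      r[i] <- signal_cor(task$outcome, nat)
    }
  }
  ok <- is.finite(r)
  list(r = r, fisher_mean = fisher_average(r[ok]),
       frac_positive = if (any(ok)) mean(r[ok] > 0) else NA_real_,
       frac_negative = if (any(ok)) mean(r[ok] < 0) else NA_real_,
       n_invalid = sum(!ok), n_series = n_series, model = model,
       mode = mode, method = method, seed = seed)
}
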