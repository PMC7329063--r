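experiment_registry <- function() {
  c("switching_demo", "high_volatility", "benchmark_gaussian",
    "benchmark_binary", "accuracy", "lr_volatility", "recovery",
    "parameter_effects")
}

write_log <- function(outdir, name, seed, started, extra = list()) {
  log <- c(list(experiment = name, seed = seed,
                started = format(started, usetz = TRUE),
                elapsed_s = as.numeric(difftime(Sys.time(), started,
                                                units = "secs")),
                r_version = as.character(getRversion()),
                rng_fingerprint = sum(as.numeric(.Random.seed[-1])) %% 1e9),
           extra)
  jsonlite::write_json(log, file.path(outdir, paste0(name, "_log.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Run a registered simulation experiment
#'
#' Ties the modules together into reproducible, seeded experiments that
#' write CSV/JSON outputs plus a log (seed, runtime, RNG fingerprint) to
#' `outdir`. Registered experiments:
#' \describe{
#'   \item{`switching_demo`}{(binary and Gaussian) VKF trajectories on the
#'     default switching task - volatility and learning rate rising after
#'     reversals.}
#'   \item{`high_volatility`}{same with short blocks throughout.}
#'   \item{`benchmark_gaussian` / `benchmark_binary`}{single-sequence
#'     comparison of the (binary) VKF against its particle-filter
#'     benchmark: correlations and relative error.}
#'   \item{`accuracy`}{the two-arm accuracy experiment (VKF and HGF, each
#'     against its own RBPF).}
#'   \item{`lr_volatility`}{fitted-mode learning-rate/volatility
#'     correlations for both binary models.}
#'   \item{`recovery`}{parameter-recovery quartiles.}
#'   \item{`parameter_effects`}{one-at-a-time parameter sweep of the
#'     binary VKF.}
#' }
#'
#' @param name Registered experiment name.
#' @param seed Integer seed (mandatory).
#' @param outdir Output directory (created if missing).
#' @param ... Overrides passed to the underlying functions (e.g. `n_reps`,
#'   `n_particles`, `n_series`).
#' @return The experiment's result object, invisibly.
#' @export
run_experiment <- function(name, seed, outdir = ".", ...) {
  if (!name %in% experiment_registry())
    stop("unknown experiment '", name, "'; registered: ",
         paste(experiment_registry(), collapse = ", "))
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  started <- Sys.time()
  dots <- list(...)
  res <- switch(name,
    switching_demo = {
      gt <- simulate_switching_task(emission = "gaussian")
      bt <- simulate_switching_task(emission = "binary")
      fg <- run_filter("vkf", vkf_params(0.1, 0.1, sigma2 = 0.1), gt$outcome)
      fb <- run_filter("binary_vkf", vkf_params(0.1, 0.1, omega = 0.1),
                       bt$outcome)
      write_gen_process(gt, file.path(outdir, "task_gaussian.csv"))
      write_gen_process(bt, file.path(outdir, "task_binary.csv"))
      write_trajectory(fg, file.path(outdir, "vkf_gaussian.csv"))
      write_trajectory(fb, file.path(outdir, "vkf_binary.csv"))
      list(gaussian = fg, binary = fb,
           switch_times = attr(gt, "switch_times"))
    },
    high_volatility = {
      blocks <- dots$block_lengths %||% rep(20, 10)
      gt <- simulate_switching_task(blocks, emission = "gaussian")
      bt <- simulate_switching_task(blocks, emission = "binary")
      fg <- run_filter("vkf", vkf_params(0.1, 0.1, sigma2 = 0.1), gt$outcome)
      fb <- run_filter("binary_vkf", vkf_params(0.1, 0.1, omega = 0.1),
                       bt$outcome)
      write_trajectory(fg, file.path(outdir, "vkf_gaussian_volatile.csv"))
      write_trajectory(fb, file.path(outdir, "vkf_binary_volatile.csv"))
      list(gaussian = fg, binary = fb)
    },
    benchmark_gaussian = {
      np <- dots$n_particles %||% 10000
      task <- simulate_switching_task(emission = "gaussian")
      f <- run_filter("vkf", vkf_params(0.1, 0.1, sigma2 = 0.1),
                      task$outcome)
      b <- rbpf_vkf(task$outcome, 0.1, 0.1, 0.1, np)
      out <- list(
        pred_cor = correlation_summary(f$m, b$prediction),
        vol_cor = correlation_summary(f$v, b$volatility),
        rel_error = relative_error(f$m, b$prediction, task$x_true),
        n_particles = np)
      jsonlite::write_json(out, file.path(outdir, "benchmark_gaussian.json"),
                           auto_unbox = TRUE, digits = NA)
      out
    },
    benchmark_binary = {
      np <- dots$n_particles %||% 10000
      task <- simulate_switching_task(emission = "binary")
      f <- run_filter("binary_vkf", vkf_params(0.1, 0.1, omega = 0.1),
                      task$outcome)
      b <- pf_binary(task$outcome, 0.1, 0.1, np)
      out <- list(
        pred_cor = correlation_summary(f$prediction, b$prediction),
        vol_cor = correlation_summary(f$v, b$volatility),
        rel_error = relative_error(f$prediction, b$prediction, task$x_true),
        n_particles = np)
      jsonlite::write_json(out, file.path(outdir, "benchmark_binary.json"),
                           auto_unbox = TRUE, digits = NA)
      out
    },
    accuracy = {
      nr <- dots$n_reps %||% 50
      np <- dots$n_particles %||% 2000
      vk <- accuracy_experiment("vkf", nr, n_particles = np)
      hg <- accuracy_experiment("hgf", nr, n_particles = np)
      write_benchmark_report(vk, file.path(outdir, "accuracy_vkf"))
      write_benchmark_report(hg, file.path(outdir, "accuracy_hgf"))
      list(vkf = vk, hgf = hg)
    },
    lr_volatility = {
      ns <- dots$n_series %||% 50
      vk <- lr_volatility_correlation_experiment(ns, "vkf_binary", "fitted")
      hg <- lr_volatility_correlation_experiment(ns, "hgf_binary", "fitted")
      out <- list(vkf_fisher_mean = vk$fisher_mean,
                  vkf_frac_positive = vk$frac_positive,
                  hgf_fisher_mean = hg$fisher_mean,
                  hgf_frac_negative = hg$frac_negative,
                  n_series = ns)
      jsonlite::write_json(out, file.path(outdir, "lr_volatility.json"),
                           auto_unbox = TRUE, digits = NA)
      list(vkf = vk, hgf = hg, summary = out)
    },
    recovery = {
      nr <- dots$n_reps %||% 20
      ns <- dots$n_subjects %||% 50
      rec <- recovery_experiment(nr, ns)
      write.csv(as.data.frame(rec$estimates),
                file.path(outdir, "recovery_estimates.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(truth = as.list(rec$truth),
             median = as.list(rec$quantiles["50%", ])),
        file.path(outdir, "recovery_summary.json"),
        auto_unbox = TRUE, digits = NA)
      rec
    },
    parameter_effects = {
      sw <- parameter_sweep()
      write.csv(sw, file.path(outdir, "parameter_sweep.csv"),
                row.names = FALSE)
      sw
    })
  write_log(outdir, name, seed, started)
  invisible(res)
}

#' One-at-a-time parameter sweep of the binary VKF
#'
#' Runs the binary VKF on a fixed switching task for a baseline parameter
#' setting and for alternative values of each parameter in turn, returning
#' the per-trial volatility, learning-rate and prediction series in long
#' format (for plotting the parameter effects: larger `lambda` amplifies
#' post-switch volatility excursions, larger `v0` acts early, `omega` sets
#' the overall scale). `lambda = 0` rows reproduce the constant-volatility
#' Kalman-style baseline.
#'
#' @param base Named baseline list: `lambda`, `v0`, `omega`.
#' @param sweep Named list of alternative values per parameter.
#' @param task A binary `"gen_process"`; default task is generated with
#'   the current RNG state.
#' @return Long data frame: `param`, `value`, `trial`, `m`, `v`, `alpha`,
#'   `prediction`. The baseline appears as `param = "baseline"`.
#' @export
parameter_sweep <- function(base = list(lambda = 0.1, v0 = 0.1, omega = 0.1),
                            sweep = list(lambda = c(0, 0.05, 0.2, 0.4),
                                         v0 = c(0.01, 0.5, 2),
                                         omega = c(0.01, 0.5, 2)),
                            task = NULL) {
  if (is.null(task)) task <- simulate_switching_task(emission = "binary")
  if (!all(names(sweep) %in% names(base)))
    stop("sweep names must be among: ", paste(names(base), collapse = ", "))
  one <- function(p, param, value) {
    f <- run_filter("binary_vkf",
                    vkf_params(p$lambda, p$v0, omega = p$omega),
                    task$outcome)
    data.frame(param = param, value = value, trial = f$trial, m = f$m,
               v = f$v, alpha = f$alpha, prediction = f$prediction)
  }
  out <- list(one(base, "baseline", NA_real_))
  for (nm in names(sweep)) {
    for (val in sweep[[nm]]) {
      p <- base
      p[[nm]] <- val
      out <- c(out, list(one(p, nm, val)))
    }
  }
  do.call(rbind, out)
}
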