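#' Hierarchical Gaussian filter (HGF) inference
#'
#' Comparator filters: a 2-level HGF for continuous observations and a
#' 3-level HGF for binary observations. Both track a latent mean (level 2)
#' whose diffusion variance is `exp(kappa * mu3 + omega)` with `mu3` itself
#' tracked by a Gaussian walk of variance `nu`. The volatility-level update
#' relies on a second-order Taylor step, which can yield a non-positive
#' posterior precision at the top level; such numerical failures are a
#' *result state*: the trajectory is flagged invalid, frozen at the failing
#' trial (remaining rows `NA`), and can be counted with
#' [detect_numerical_problem()].
#'
#' Initial conditions follow the conventions used for behavioural fits:
#' means 0 and 1, variances 0.1 and 1 at levels 2 and 3.
#'
#' @param observations Numeric outcomes (0/1 for the binary variant).
#' @param nu Third-level walk variance (> 0; bounded by 1 when fitted).
#' @param kappa Level-3 to level-2 coupling (> 0; bounded by 1 when fitted).
#' @param omega Tonic level-2 log-variance (real).
#' @param sigma2 Observation variance (continuous variant only).
#' @param mu2_0,mu3_0,s2_0,s3_0 Initial means and variances of levels 2
#'   and 3.
#' @return A data frame of class `"hgf_trajectory"` with per-trial columns
#'   `mu2`, `s2`, `mu3`, `s3`, `vol` (diffusion variance entering the
#'   trial's prediction) and, for the binary variant, `muhat1` (predicted
#'   outcome probability), `prediction` (the choice value `2 * muhat1 - 1`)
#'   and `lr` (latent-space learning rate, the coefficient on the level-1
#'   prediction error). Attributes: `valid`, `first_bad`, `params`.
#' @export
hgf2_filter <- function(observations, nu, kappa, omega, sigma2,
                        mu2_0 = 0, mu3_0 = 1, s2_0 = 0.1, s3_0 = 1) {
  check_obs(observations)
  if (nu <= 0 || kappa < 0) stop("nu must be positive and kappa non-negative")
  f <- cpp_hgf2_filter(observations, nu, kappa, omega, sigma2,
                       mu2_0, mu3_0, s2_0, s3_0)
  res <- data.frame(trial = seq_along(observations),
                    observation = observations,
                    mu2 = f$mu2, s2 = f$s2, mu3 = f$mu3, s3 = f$s3,
                    vol = f$vol)
  attr(res, "valid") <- f$valid
  attr(res, "first_bad") <- f$first_bad
  attr(res, "params") <- list(nu = nu, kappa = kappa, omega = omega,
                              sigma2 = sigma2)
  class(res) <- c("hgf_trajectory", "data.frame")
  res
}

#' @rdname hgf2_filter
#' @export
hgf3_binary_filter <- function(observations, nu, kappa, omega,
                               mu2_0 = 0, mu3_0 = 1, s2_0 = 0.1, s3_0 = 1) {
  check_obs(observations, binary = TRUE)
  if (nu <= 0 || kappa < 0) stop("nu must be positive and kappa non-negative")
  f <- cpp_hgf3bin_filter(observations, nu, kappa, omega,
                          mu2_0, mu3_0, s2_0, s3_0)
  res <- data.frame(trial = seq_along(observations),
                    observation = observations,
                    mu2 = f$mu2, s2 = f$s2, mu3 = f$mu3, s3 = f$s3,
                    muhat1 = f$muhat1, prediction = 2 * f$muhat1 - 1,
                    lr = f$lr, vol = f$vol)
  attr(res, "valid") <- f$valid
  attr(res, "first_bad") <- f$first_bad
  attr(res, "params") <- list(nu = nu, kappa = kappa, omega = omega)
  class(res) <- c("hgf_trajectory", "data.frame")
  res
}

#' @export
print.hgf_trajectory <- function(x, ...) {
  cat("<hgf_trajectory> trials:", nrow(x),
      "| valid:", attr(x, "valid"), "\n")
  if (!isTRUE(attr(x, "valid")))
    cat("numerical problem first at trial", attr(x, "first_bad"), "\n")
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Detect a numerical failure in an HGF trajectory
#'
#' TRUE iff the filter produced a non-positive posterior variance (or a
#' non-finite state) at any level on any trial.
#'
#' @param traj An `"hgf_trajectory"`.
#' @return List with `failed` (logical) and `trial` (first failing trial,
#'   `NA` if none).
#' @export
detect_numerical_problem <- function(traj) {
  if (!inherits(traj, "hgf_trajectory")) stop("not an hgf_trajectory")
  list(failed = !isTRUE(attr(traj, "valid")),
       trial = attr(traj, "first_bad"))
}

#' Export an HGF trajectory as delimited text
#'
#' Same schema as [write_trajectory()] with `level3_mean`, `level3_var`
#' and `valid` columns appended.
#'
#' @param traj An `"hgf_trajectory"`.
#' @param file CSV path.
#' @return The path, invisibly.
#' @export
write_hgf_trajectory <- function(traj, file) {
  df <- data.frame(trial = traj$trial, observation = traj$observation,
                   prediction = if (!is.null(traj$prediction))
                     traj$prediction else traj$mu2,
                   m = traj$mu2, w = traj$s2, v = traj$vol,
                   k = NA_real_,
                   alpha = if (!is.null(traj$lr)) traj$lr else NA_real_,
                   autocov = NA_real_,
                   level3_mean = traj$mu3, level3_var = traj$s3,
                   valid = isTRUE(attr(traj, "valid")))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
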