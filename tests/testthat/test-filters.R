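test_that("single-step updates reproduce hand-derived values", {
  s <- kalman_step(list(m = 0, w = 1), 2, kalman_params(v = 1, sigma2 = 2))
  expect_equal(s$k, 0.5, tolerance = 1e-12)
  expect_equal(s$m, 1, tolerance = 1e-12)
  expect_equal(s$w, 1, tolerance = 1e-12)
  expect_equal(s$autocov, 0.5, tolerance = 1e-12)

  s <- vkf_step(list(m = 0, w = 1, v = 1), 1,
                vkf_params(0.1, 1, sigma2 = 1))
  expect_equal(s$k, 2 / 3, tolerance = 1e-12)
  expect_equal(s$m, 2 / 3, tolerance = 1e-12)
  expect_equal(s$w, 2 / 3, tolerance = 1e-12)
  expect_equal(s$autocov, 1 / 3, tolerance = 1e-12)
  expect_equal(s$v, 1 + 0.1 * 4 / 9, tolerance = 1e-12)

  s <- binary_vkf_step(list(m = 0, w = 1, v = 1), 1,
                       vkf_params(0.1, 1, omega = 1))
  expect_equal(s$k, 2 / 3, tolerance = 1e-12)
  expect_equal(s$alpha, 2, tolerance = 1e-12)
  expect_equal(s$m, 1, tolerance = 1e-12)
  expect_equal(s$w, 2 / 3, tolerance = 1e-12)
  expect_equal(s$autocov, 1 / 3, tolerance = 1e-12)
  expect_equal(s$v, 1.1, tolerance = 1e-12)

  expect_equal(variance_tracker_step(1, 2, 0, 0.2), 1.6, tolerance = 1e-12)
})

test_that("step identities: zero error, noise-free limit, shrinkage", {
  # zero prediction error leaves the mean unchanged
  s <- kalman_step(list(m = 5, w = 0.7), 5, kalman_params(v = 2, sigma2 = 1))
  expect_equal(s$m, 5)
  # observation noise -> 0 drives the gain to 1 and the mean to the outcome
  s <- kalman_step(list(m = 0, w = 1), 3, kalman_params(v = 1, sigma2 = 1e-14))
  expect_equal(s$k, 1, tolerance = 1e-10)
  expect_equal(s$m, 3, tolerance = 1e-10)
  # binary step with o equal to the predicted rate leaves m unchanged
  # (realised here with a saturated prediction, s(m) = 1 to double precision)
  s <- binary_vkf_step(list(m = 50, w = 0.3, v = 0.2), 1,
                       vkf_params(0.2, 0.2, omega = 1))
  expect_equal(s$m, 50)
  # variance tracker with x = mu shrinks by (1 - lambda)
  expect_equal(variance_tracker_step(2, 1, 1, 0.3), 0.7 * 2)
})

test_that("VKF with lambda = 0 reproduces the Kalman filter bit-for-bit", {
  set.seed(101)
  o <- rnorm(10000, sd = 3)
  a <- run_filter("vkf", vkf_params(0, 0.7, sigma2 = 1.3, w0 = 0.5), o)
  b <- run_filter("kalman", kalman_params(0.7, 1.3, w0 = 0.5), o)
  expect_identical(a$m, b$m)
  expect_identical(a$w, b$w)
  expect_identical(a$k, b$k)
  expect_identical(a$autocov, b$autocov)
  expect_true(all(a$v == 0.7))
})

test_that("positivity and ordering invariants hold on randomized draws", {
  set.seed(202)
  for (i in 1:150) {
    T <- sample(20:80, 1)
    if (i %% 2 == 0) {
      lambda <- runif(1, 0, 0.95)
      v0 <- runif(1, 0.01, 5)
      noise <- runif(1, 0.01, 5)
      o <- rnorm(T, sd = runif(1, 0.1, 5))
      tr <- run_filter("vkf", vkf_params(lambda, v0, sigma2 = noise), o)
    } else {
      # stable domain for the binary variant (see acceptance suite)
      lambda <- runif(1, 0, 0.5)
      v0 <- runif(1, 0.01, 0.5)
      noise <- runif(1, 0.01, 0.5)
      o <- rbinom(T, 1, runif(1, 0.1, 0.9))
      tr <- run_filter("binary_vkf", vkf_params(lambda, v0, omega = noise), o)
    }
    w_prev <- c(attr(tr, "params")$w0, tr$w[-T])
    expect_true(all(tr$w > 0))
    expect_true(all(tr$v > 0))
    expect_true(all(tr$k > 0 & tr$k < 1))
    expect_true(all(tr$autocov > 0 & tr$autocov < w_prev))
  }
})

test_that("gain is strictly increasing in the volatility estimate", {
  vs <- seq(0.05, 4, length.out = 40)
  ks <- vapply(vs, function(v)
    vkf_step(list(m = 0, w = 0.5, v = v), 1,
             vkf_params(0.1, 1, sigma2 = 1))$k, 0)
  expect_true(all(diff(ks) > 0))
})

test_that("volatility change follows the error-correcting form exactly", {
  set.seed(33)
  o <- rnorm(300)
  tr <- run_filter("vkf", vkf_params(0.15, 0.5, sigma2 = 0.8), o)
  T <- nrow(tr)
  v_prev <- c(0.5, tr$v[-T])
  w_prev <- c(0.8, tr$w[-T])
  m_prev <- c(0, tr$m[-T])
  bracket <- (tr$m - m_prev)^2 + tr$w + w_prev - 2 * tr$autocov - v_prev
  expect_equal(tr$v - v_prev, 0.15 * bracket, tolerance = 1e-12)
})

test_that("variance tracker recovers the variance of iid centred draws", {
  set.seed(404)
  tau <- 2.3
  x <- rnorm(1e5, 0, sqrt(tau))
  vs <- numeric(length(x))
  v <- 1
  for (t in seq_along(x)) {
    v <- v + 0.01 * (x[t]^2 - v)
    vs[t] <- v
  }
  expect_equal(mean(vs[-(1:1000)]), tau, tolerance = 0.05)
})

test_that("run_filter validates inputs and handles edge cases", {
  p <- vkf_params(0.1, 1, sigma2 = 1)
  expect_error(run_filter("vkf", p, numeric(0)), "empty")
  expect_error(run_filter("vkf", p, c(1, 2, NaN, 4)), "trial 3")
  expect_error(run_filter("binary_vkf", vkf_params(0.1, 1, omega = 1),
                          c(0, 1, 0.5)), "0, 1")
  # length-1 sequence equals a single hand step from (m0, w0, v0)
  tr <- run_filter("vkf", p, 2)
  s <- vkf_step(list(m = 0, w = 1, v = 1), 2, p)
  expect_equal(tr$m, s$m)
  expect_equal(tr$v, s$v)
  # Rescorla-Wagner recursion matches a direct loop
  o <- rnorm(50)
  tr <- run_filter("rw", rw_params(0.3), o)
  m <- 0
  for (t in seq_along(o)) m <- m + 0.3 * (o[t] - m)
  expect_equal(tr$m[50], m)
})

test_that("RW with the converged Kalman gain tracks the Kalman mean", {
  set.seed(55)
  o <- rnorm(3000, 1.5, 1)
  kf <- run_filter("kalman", kalman_params(0.5, 1), o)
  k_inf <- kf$k[3000]
  rw <- run_filter("rw", rw_params(k_inf), o)
  late <- 2000:3000
  expect_lt(max(abs(kf$m[late] - rw$m[late])), 0.05)
})

test_that("binary VKF sd-step variant uses the root-variance step size", {
  set.seed(66)
  o <- rbinom(100, 1, 0.7)
  a <- run_filter("binary_vkf", vkf_params(0.1, 1, omega = 1), o)
  b <- run_filter("binary_vkf",
                  vkf_params(0.1, 1, omega = 1, mean_step = "sd"), o)
  expect_equal(b$alpha[1], sqrt(a$alpha[1]))
  s <- binary_vkf_step(list(m = 0, w = 1, v = 1), 1,
                       vkf_params(0.1, 1, omega = 1, mean_step = "sd"))
  expect_equal(s$alpha, sqrt(2))
  expect_equal(s$m, sqrt(2) * 0.5)
})

test_that("implied observation-space learning rate matches hand values", {
  task <- rand_binary_task()
  tr <- run_filter("binary_vkf", vkf_params(0.2, 1, omega = 1),
                   task$outcome)
  ilr <- implied_obs_learning_rate(tr)
  # manual first trial: prediction s(0) = 0.5
  expect_equal(ilr[1],
               (plogis(tr$m[1]) - 0.5) / (task$outcome[1] - 0.5))
  # hand value: m 0 -> 1 on outcome 1 gives (s(1) - 0.5) / 0.5
  expect_equal((plogis(1) - plogis(0)) / (1 - plogis(0)), 0.4621172,
               tolerance = 1e-6)
  # Gaussian trajectories are rejected
  g <- run_filter("vkf", vkf_params(0.1, 1, sigma2 = 1), rnorm(10))
  expect_error(implied_obs_learning_rate(g), "binary")
})

test_that("trajectory CSV export and config readers round-trip", {
  tr <- run_filter("vkf", vkf_params(0.1, 0.5, sigma2 = 1), rnorm(20))
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read.csv(f)
  expect_identical(names(back)[1:9],
                   c("trial", "observation", "prediction", "m", "w", "v",
                     "k", "alpha", "autocov"))
  expect_equal(back$m, tr$m)
  expect_equal(back$trial, 1:20)

  yf <- tempfile(fileext = ".yaml")
  writeLines(c("variant: binary_vkf", "lambda: 0.2", "v0: 1.5",
               "omega: 0.8"), yf)
  cfg <- read_filter_config(yf)
  expect_identical(cfg$variant, "binary_vkf")
  expect_equal(cfg$params$lambda, 0.2)
  expect_equal(cfg$params$w0, 0.8)

  jf <- tempfile(fileext = ".json")
  writeLines('{"variant": "kalman", "v": 1, "sigma2": 2}', jf)
  cfg <- read_filter_config(jf)
  expect_equal(cfg$params$v, 1)
  expect_error(read_filter_config(tempfile(fileext = ".txt")), "yaml")

  # the shipped example config parses
  ex <- system.file("extdata", "binary_vkf_example.yaml",
                    package = "vkfilter")
  cfg <- read_filter_config(ex)
  expect_identical(cfg$variant, "binary_vkf")
  expect_equal(cfg$params$omega, 0.1)
})

test_that("parameter constructors enforce domains", {
  expect_error(kalman_params(v = -1, sigma2 = 1), "positive")
  expect_error(vkf_params(1, 1, sigma2 = 1), "lambda")
  expect_error(vkf_params(0.1, -1, sigma2 = 1), "v0")
  expect_error(vkf_params(0.1, 1), "exactly one")
  expect_error(vkf_params(0.1, 1, sigma2 = 1, omega = 1), "exactly one")
  expect_error(rw_params(1.2), "\\(0, 1\\)")
})
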