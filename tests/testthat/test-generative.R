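test_that("precision noise has unit mean and the stated support bound", {
  set.seed(1)
  lam <- 0.3
  e <- sample_precision_noise(1e6, lam)
  se <- sd(e) / sqrt(length(e))
  expect_lt(abs(mean(e) - 1), 3 * se)
  expect_true(all(e > 0))
  expect_true(all(e < 1 / (1 - lam)))
  expect_error(sample_precision_noise(10, 0), "strictly inside")
  expect_error(sample_precision_noise(10, 1), "strictly inside")
})

test_that("multiplicative Beta noise preserves the Gamma family", {
  set.seed(2)
  a <- 10; b <- 2; lam <- 0.25
  z <- rgamma(1e5, a, rate = b)
  z2 <- z * rbeta(1e5, (1 - lam) * a, lam * a) / (1 - lam)
  ks <- suppressWarnings(
    ks.test(z2, pgamma, shape = (1 - lam) * a, rate = (1 - lam) * b))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(z2) - a / b), 0.05)
})

test_that("precision path is a martingale in the mean", {
  set.seed(3)
  lam <- 0.2
  n <- 5000; T <- 50
  eps <- matrix(sample_precision_noise(n * T, lam), n, T)
  z <- t(apply(eps, 1, cumprod)) * 2  # z0 = 2
  mean_final <- mean(z[, T])
  expect_lt(abs(mean_final - 2) / 2, 0.1)
})

test_that("volatility-process simulation is seeded and well-formed", {
  g1 <- simulate_vkf_process(100, 0.15, 1, 1, seed = 42)
  g2 <- simulate_vkf_process(100, 0.15, 1, 1, seed = 42)
  expect_identical(g1, g2)
  expect_true(all(g1$z_true > 0))
  gb <- simulate_vkf_process(200, 0.2, 1, emission = "bernoulli", seed = 1)
  expect_true(all(gb$outcome %in% c(0, 1)))
})

test_that("HGF cascade simulation matches its printed structure", {
  set.seed(4)
  # kappa -> 0 freezes the level-2 diffusion variance at exp(omega)
  g <- simulate_hgf_process(4000, nu = 0.5, kappa = 1e-12, omega = -1)
  dx2 <- diff(g$x_true)
  expect_equal(var(dx2), exp(-1), tolerance = 0.1)
  # third-level increments have variance nu
  g <- simulate_hgf_process(4000, nu = 0.5, kappa = 0.1, omega = -3)
  expect_equal(var(diff(g$x3_true)), 0.5, tolerance = 0.1)
  # diffusion overflow is reported with the trial index
  expect_error(simulate_hgf_process(50, nu = 1e6, kappa = 30, omega = 0,
                                    seed = 7), "trial")
})

test_that("switching task blocks match their stated probabilities", {
  set.seed(5)
  task <- simulate_switching_task(c(400, 400), emission = "binary",
                                  probs = c(0.8, 0.2))
  expect_identical(attr(task, "switch_times"), 401L)
  expect_type(attr(task, "switch_times"), "integer")
  r1 <- mean(task$outcome[1:400])
  r2 <- mean(task$outcome[401:800])
  expect_lt(abs(r1 - 0.8), 3 * sqrt(0.8 * 0.2 / 400))
  expect_lt(abs(r2 - 0.2), 3 * sqrt(0.8 * 0.2 / 400))
  # single block: stationary Bernoulli, no switches
  one <- simulate_switching_task(300, emission = "binary")
  expect_length(attr(one, "switch_times"), 0)
  # Gaussian variant: states alternate and emission sd is as configured
  gt <- simulate_switching_task(c(200, 200), emission = "gaussian",
                                emission_sd = 0.1)
  expect_identical(unique(gt$x_true), c(1, -1))
  expect_equal(sd(gt$outcome[1:200]), 0.1, tolerance = 0.15)
})

test_that("synthetic go/no-go subjects behave sensibly", {
  subs <- generate_synthetic_subjects(3, n_trials = 60, subject_sd = 0,
                                      seed = 6)
  nat <- do.call(rbind, lapply(subs, `[[`, "natural"))
  expect_true(all(apply(nat, 2, function(x) diff(range(x)) == 0)))
  expect_equal(unname(nat[1, ]), c(0.2, 5, 1, 1), tolerance = 1e-12)

  set.seed(7)
  subs <- generate_synthetic_subjects(10)
  df <- subjects_to_frame(subs)
  expect_identical(names(df), c("subject", "trial", "cue", "emotion",
                                "valence", "value", "outcome", "choice"))
  expect_equal(nrow(df), 10 * 4 * 120)
  # choices agree with outcomes above chance: both are driven by m_{t-1}
  expect_gt(mean(df$choice == df$outcome), 0.55)
})

test_that("generated processes export the stated CSV schema", {
  task <- simulate_switching_task(c(30, 30), emission = "binary", seed = 8)
  f <- tempfile(fileext = ".csv")
  write_gen_process(task, f)
  back <- read.csv(f)
  expect_true(all(c("trial", "x_true", "outcome", "is_switch") %in%
                    names(back)))
  expect_equal(which(back$is_switch), 31)
})
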