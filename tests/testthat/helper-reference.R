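# plain-R reference recursions used as independent oracles in property
# tests; deliberately written from the update equations, not shared with
# the package internals

ref_vkf_traj <- function(o, lambda, v0, sigma2, m0 = 0, w0 = sigma2) {
  T <- length(o)
  out <- matrix(NA_real_, T, 5,
                dimnames = list(NULL, c("m", "w", "v", "k", "autocov")))
  m <- m0; w <- w0; v <- v0
  for (t in seq_len(T)) {
    k <- (w + v) / (w + v + sigma2)
    m2 <- m + k * (o[t] - m)
    w2 <- (1 - k) * (w + v)
    cv <- (1 - k) * w
    v2 <- v + lambda * ((m2 - m)^2 + w2 + w - 2 * cv - v)
    out[t, ] <- c(m2, w2, v2, k, cv)
    m <- m2; w <- w2; v <- v2
  }
  out
}

rand_binary_task <- function(n_blocks = 4, len = 40, p = c(0.8, 0.2)) {
  simulate_switching_task(rep(len, n_blocks), emission = "binary",
                          probs = p)
}
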