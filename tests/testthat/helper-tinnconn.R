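# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as direct summations over the defining formulas,
# sharing no code with the package implementations they validate.

tone_rec <- function(freq, fs = 1000, dur = 2, amp = 1, phase = 0,
                     label = "c1") {
  t_ <- seq_len(round(fs * dur)) / fs
  eeg_recording(matrix(amp * sin(2 * pi * freq * t_ + phase), 1), fs, label)
}

multi_tone_rec <- function(freqs, amps, fs = 1000, dur = 2,
                           labels = paste0("c", seq_along(freqs))) {
  t_ <- seq_len(round(fs * dur)) / fs
  data <- t(vapply(seq_along(freqs),
                   function(i) amps[i] * sin(2 * pi * freqs[i] * t_),
                   numeric(length(t_))))
  eeg_recording(data, fs, labels)
}

two_channel_template <- function(kappa = 0, mix = 0, gain = 0, noise = 5,
                                 bands = c(alpha = 20)) {
  class_template("toy",
                 phase_coupling = matrix(c(1, kappa, kappa, 1), 2),
                 linear_mixing = matrix(c(1, mix, mix, 1), 2),
                 directed_gain = matrix(c(0, gain, 0, 0), 2, byrow = TRUE),
                 noise_sd = noise, band_profile = bands,
                 channel_labels = c("ch1", "ch2"))
}

sim_two_channel <- function(kappa = 0, mix = 0, gain = 0, seed = 1,
                            fs = 250, dur = 10, noise = 5,
                            bands = c(alpha = 20)) {
  tpl <- two_channel_template(kappa, mix, gain, noise, bands)
  cfg <- sim_config(fs, dur, epoch_s = dur, channel_labels = c("ch1", "ch2"),
                    seed = seed)
  simulate_recording(tpl, cfg, seed)
}

# Gaussian-blob features: k well-separated classes on p features
blob_features <- function(n_per = 30, k = 4, p = 20, sep = 4, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(k), function(cl) {
      mu <- numeric(p)
      mu[seq((cl - 1) * floor(p / k) + 1, cl * floor(p / k))] <- sep
      matrix(rnorm(n_per * p), n_per, p) + matrix(mu, n_per, p, byrow = TRUE)
    }))
    list(x = x, labels = rep(paste0("g", seq_len(k)), each = n_per))
  })
}

# ---- brute-force oracles ----------------------------------------------------

oracle_plv <- function(phi, phk) {
  s <- 0 + 0i
  for (t in seq_along(phi)) s <- s + exp(1i * (phi[t] - phk[t]))
  Mod(s / length(phi))
}

oracle_pli <- function(zi, zk) {
  s <- 0
  for (t in seq_along(zi)) s <- s + sign(Im(zi[t] * Conj(zk[t])))
  abs(s / length(zi))
}

oracle_pcc <- function(xi, xk) {
  T_ <- length(xi)
  mu_i <- sum(xi) / T_
  mu_k <- sum(xk) / T_
  sd_i <- sqrt(sum((xi - mu_i)^2) / T_)
  sd_k <- sqrt(sum((xk - mu_k)^2) / T_)
  (sum((xi - mu_i) * (xk - mu_k)) / T_) / (sd_i * sd_k)
}

# independent discretization (cut-based) + explicit probability sums
oracle_te <- function(xi, xk, bins, lag = 1) {
  disc <- function(x) {
    if (min(x) == max(x)) return(rep(1L, length(x)))
    as.integer(cut(x, breaks = seq(min(x), max(x), length.out = bins + 1),
                   include.lowest = TRUE))
  }
  a_full <- disc(xi)
  b_full <- disc(xk)
  T_ <- length(xk) - lag
  a <- a_full[1:T_]
  b <- b_full[1:T_]
  cc <- b_full[(1 + lag):(T_ + lag)]
  te <- 0
  for (ai in unique(a)) for (bi in unique(b)) for (ci in unique(cc)) {
    n_abc <- sum(a == ai & b == bi & cc == ci)
    if (n_abc == 0) next
    n_ab <- sum(a == ai & b == bi)
    n_bc <- sum(b == bi & cc == ci)
    n_b <- sum(b == bi)
    p_abc <- n_abc / T_
    te <- te + p_abc * log2((n_abc / n_ab) / (n_bc / n_b))
  }
  te
}

expect_rel_equal <- function(got, want, rel = 1e-12) {
  expect_lt(abs(got - want), rel * max(1, abs(want)))
}
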