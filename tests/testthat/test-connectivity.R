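# Connectivity estimators: oracle equivalence, closed-form limits,
# invariances, and the matrix builder contracts.

test_that("estimators match brute-force oracles on toy inputs", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(5:20, 1)
      phi <- runif(n, -pi, pi)
      phk <- runif(n, -pi, pi)
      expect_rel_equal(plv(phi, phk), oracle_plv(phi, phk))
      zi <- complex(real = rnorm(n), imaginary = rnorm(n))
      zk <- complex(real = rnorm(n), imaginary = rnorm(n))
      expect_rel_equal(pli(zi, zk), oracle_pli(zi, zk))
      xi <- rnorm(n)
      xk <- rnorm(n)
      expect_rel_equal(pcc(xi, xk), oracle_pcc(xi, xk))
      for (bins in 2:3) {
        expect_rel_equal(transfer_entropy(xi, xk, bins = bins),
                         oracle_te(xi, xk, bins = bins))
      }
    })
  }
})

test_that("PLV closed forms", {
  phi <- runif(50, -pi, pi)
  expect_equal(plv(phi, phi + pi / 4), 1.0, tolerance = 1e-12)
  # T = 2 with phase differences {0, pi}: |(1 + e^{i pi}) / 2| = 0
  expect_equal(plv(c(0, 0), c(0, pi)), 0.0, tolerance = 1e-12)
  withr::with_seed(1, {
    a <- runif(10000, -pi, pi)
    b <- runif(10000, -pi, pi)
    expect_lt(plv(a, b), 0.05)
  })
  expect_error(plv(1:3, 1:4), class = "tinnconn_input_error")
})

test_that("PLI closed forms and zero-lag insensitivity", {
  t_ <- seq_len(500)
  zi <- exp(1i * 0.1 * t_)
  expect_equal(pli(zi, zi * exp(-1i * pi / 2)), 1.0)
  expect_equal(pli(zi, zi), 0.0)                      # identical: Im = 0
  # alternating +/- pi/4 lags cancel
  lag <- rep(c(pi / 4, -pi / 4), 250)
  expect_equal(pli(zi, zi * exp(-1i * lag)), 0.0)
  expect_error(pli(Re(zi), Re(zi)), class = "tinnconn_input_error")
})

test_that("PCC closed forms and affine invariance", {
  withr::with_seed(2, x <- rnorm(1000))
  expect_equal(pcc(x, 2 * x + 3), 1.0, tolerance = 1e-12)
  expect_equal(pcc(x, -x), -1.0, tolerance = 1e-12)
  withr::with_seed(3, {
    a <- rnorm(10000)
    b <- rnorm(10000)
    expect_lt(abs(pcc(a, b)), 0.05)
  })
  # positive affine transform invariance; sign flip under negation
  expect_equal(pcc(5 * x - 2, x), 1.0, tolerance = 1e-12)
  expect_equal(pcc(x, x^3), pcc(2 * x + 1, x^3), tolerance = 1e-12)
  expect_equal(pcc(-x, x^3), -pcc(x, x^3), tolerance = 1e-12)
  expect_error(pcc(rep(1, 10), rnorm(10)), class = "tinnconn_input_error")
})

test_that("phase measures are amplitude invariant", {
  rec <- sim_two_channel(kappa = 0.5, seed = 4, dur = 4)
  ph <- analytic_phase(rec)
  z <- band_analytic_signal(rec)
  scaled <- rec
  scaled$data[1, ] <- 7.3 * scaled$data[1, ]
  scaled$data[2, ] <- 0.2 * scaled$data[2, ]
  ph_s <- analytic_phase(scaled)
  z_s <- band_analytic_signal(scaled)
  expect_equal(plv(ph_s[1, ], ph_s[2, ]), plv(ph[1, ], ph[2, ]),
               tolerance = 1e-9)
  expect_equal(pli(z_s[1, ], z_s[2, ]), pli(z[1, ], z[2, ]),
               tolerance = 1e-9)
})

test_that("TE: exact lag-1 binary copy carries exactly 1 bit", {
  # period-4 source with a circular lag-1 copy makes every joint cell
  # count exactly equal, so the plug-in estimate hits the closed form
  xi <- rep(c(0, 0, 1, 1), length.out = 397)   # T-1 = 396 = 4 * 99
  xk <- c(xi[396], xi[-397])
  expect_equal(transfer_entropy(xi, xk, bins = 2, lag = 1), 1.0,
               tolerance = 1e-12)
  expect_equal(oracle_te(xi, xk, bins = 2), 1.0, tolerance = 1e-12)
})

test_that("TE independence, symmetry-of-identical, and error contracts", {
  withr::with_seed(5, {
    a <- rnorm(10000)
    b <- rnorm(10000)
    expect_lt(transfer_entropy(a, b, bins = 4), 0.02)
  })
  x <- rnorm(500)
  expect_equal(transfer_entropy(x, x, bins = 3),
               transfer_entropy(x, x, bins = 3))
  expect_gte(transfer_entropy(a, b, bins = 4), 0)
  expect_error(transfer_entropy(a, b, bins = 1),
               class = "tinnconn_input_error")
  expect_error(transfer_entropy(1:5, 1:6), class = "tinnconn_input_error")
})

test_that("TE of a noisy lag-1 copy decreases as symbol noise grows", {
  te_at_noise <- function(noise_sd, seed) {
    withr::with_seed(seed, {
      x <- rnorm(4000)
      y <- c(0, x[-4000]) + noise_sd * rnorm(4000)
      transfer_entropy(x, y, bins = 4)
    })
  }
  means <- vapply(c(0.1, 0.5, 1.5, 4),
                  function(ns) mean(vapply(1:20, function(s)
                    te_at_noise(ns, s), 0)), 0)
  expect_true(all(diff(means) < 0))
})

test_that("connectivity_matrix honors per-measure invariants", {
  rec <- sim_two_channel(kappa = 0.4, mix = 0.3, gain = 0.4, seed = 6,
                         dur = 4)
  ep <- segment_epochs(rec, 4)[[1]]
  m_plv <- connectivity_matrix(ep, "plv")
  expect_true(isSymmetric(unclass(m_plv)))
  expect_equal(unname(diag(m_plv)), c(1, 1))
  expect_true(all(m_plv >= 0 & m_plv <= 1))
  m_pli <- connectivity_matrix(ep, "pli")
  expect_true(isSymmetric(unclass(m_pli)))
  expect_equal(unname(diag(m_pli)), c(0, 0))
  m_pcc <- connectivity_matrix(ep, "pcc")
  expect_true(all(abs(m_pcc) <= 1))
  m_te <- connectivity_matrix(ep, "te")
  expect_true(attr(m_te, "directed"))
  expect_true(all(m_te >= 0))
  expect_equal(unname(diag(m_te)), c(0, 0))
  expect_error(connectivity_matrix(ep, "nope"))
})

test_that("matrix builder matches pairwise calls and is permutation equivariant", {
  withr::with_seed(7, {
    data <- matrix(rnorm(3 * 200), 3, 200)
  })
  ep <- eeg_epoch(data, 100, c("A", "B", "C"))
  ph <- analytic_phase(ep)
  m <- connectivity_matrix(ep, "plv")
  for (i in 1:2) for (k in (i + 1):3) {
    expect_rel_equal(m[i, k], plv(ph[i, ], ph[k, ]))
  }
  perm <- c(3, 1, 2)
  ep_p <- eeg_epoch(data[perm, ], 100, c("C", "A", "B"))
  m_p <- connectivity_matrix(ep_p, "pcc")
  m_0 <- connectivity_matrix(ep, "pcc")
  expect_equal(unname(unclass(m_p)[1:3, 1:3]),
               unname(unclass(m_0)[perm, perm]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("flatten/unflatten round-trip both layouts", {
  withr::with_seed(8, {
    n <- 12
    s <- matrix(rnorm(n * n), n)
    sym <- (s + t(s)) / 2
    diag(sym) <- 1
  })
  v <- flatten_connectivity(sym, directed = FALSE)
  expect_length(v, 66)
  expect_identical(names(v)[1], "1-2")
  expect_equal(unflatten_connectivity(v, n, FALSE, 1), sym, tolerance = 1e-15)
  # row-major order: first n-1 entries are row 1
  expect_equal(unname(v[seq_len(n - 1)]), sym[1, 2:n])
  d <- s
  diag(d) <- 0
  vd <- flatten_connectivity(d, directed = TRUE)
  expect_length(vd, 132)
  expect_equal(unflatten_connectivity(vd, n, TRUE, 0), d, tolerance = 1e-15)
})
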