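# Synthetic-data generator: template validation, determinism, coupling
# controllability, and dataset assembly.

test_that("class_template validates its matrices", {
  expect_s3_class(two_channel_template(0.5, 0.3, 0.2), "class_template")
  bad_asym <- matrix(c(1, 0.2, 0.8, 1), 2)
  expect_error(class_template("x", phase_coupling = bad_asym,
                              channel_labels = c("a", "b")),
               class = "tinnconn_config_error")
  expect_error(class_template("x", phase_coupling = matrix(c(1, 2, 2, 1), 2),
                              channel_labels = c("a", "b")),
               class = "tinnconn_config_error")
  expect_error(class_template("x", directed_gain = matrix(-1, 2, 2),
                              channel_labels = c("a", "b")),
               class = "tinnconn_config_error")
  expect_error(class_template("x", band_profile = c(ultra = 1),
                              channel_labels = c("a", "b")),
               class = "tinnconn_config_error")
  expect_error(sim_config(sampling_rate = 150),
               class = "tinnconn_config_error")
  expect_error(sim_config(duration = 5, epoch_s = 10),
               class = "tinnconn_config_error")
})

test_that("simulation is deterministic and dimensioned correctly", {
  cfg <- sim_config(250, 20, epoch_s = 10, channel_labels = c("ch1", "ch2"),
                    seed = 7)
  tpl <- two_channel_template(0.5, 0.2, 0.1)
  a <- simulate_recording(tpl, cfg, seed = 7)
  b <- simulate_recording(tpl, cfg, seed = 7)
  expect_identical(a$data, b$data)
  expect_equal(dim(a$data), c(2L, 5000L))
  expect_equal(a$sampling_rate, 250)
  expect_identical(a$group_label, "toy")
  c_ <- simulate_recording(tpl, cfg, seed = 8)
  expect_false(identical(a$data, c_$data))
  # dimension mismatch between template and config
  cfg12 <- sim_config(250, 20, seed = 1)
  expect_error(simulate_recording(tpl, cfg12),
               class = "tinnconn_config_error")
})

test_that("fully independent channels show near-zero coupling at 600 s", {
  rec <- sim_two_channel(kappa = 0, mix = 0, gain = 0, seed = 30,
                         fs = 250, dur = 600)
  ph <- analytic_phase(rec)
  expect_lt(plv(ph[1, ], ph[2, ]), 0.05)
  expect_lt(abs(pcc(rec$data[1, ], rec$data[2, ])), 0.05)
  z <- band_analytic_signal(rec)
  expect_lt(pli(z[1, ], z[2, ]), 0.05)
  expect_lt(transfer_entropy(rec$data[1, ], rec$data[2, ], bins = 4), 0.02)
})

test_that("kappa = 1 gives full phase locking", {
  rec <- sim_two_channel(kappa = 1, noise = 1, seed = 31, dur = 30)
  ph <- analytic_phase(rec)
  expect_gt(plv(ph[1, ], ph[2, ]), 0.95)
})

test_that("realized PCC tracks linear_mixing and TE tracks directed_gain", {
  pcc_at <- function(mix) mean(vapply(1:8, function(s) {
    r <- sim_two_channel(mix = mix, seed = s, dur = 10)
    abs(pcc(r$data[1, ], r$data[2, ]))
  }, 0))
  expect_gt(pcc_at(0.9), pcc_at(0) + 0.03)
  te_at <- function(g) mean(vapply(1:8, function(s) {
    r <- sim_two_channel(gain = g, seed = s, dur = 10)
    transfer_entropy(r$data[1, ], r$data[2, ], bins = 4)
  }, 0))
  expect_gt(te_at(0.8), te_at(0) + 0.03)
})

test_that("scenario templates encode distinct class structure", {
  tps <- build_class_templates("default")
  expect_named(tps, c("healthy", "bilateral", "left", "right"))
  for (tp in tps) {
    expect_true(isSymmetric(tp$phase_coupling))
    expect_true(all(tp$phase_coupling >= 0 & tp$phase_coupling <= 1))
    expect_true(all(abs(tp$linear_mixing) <= 1))
    expect_true(all(tp$directed_gain >= 0))
  }
  # at least one template pair differs in >= 10 coupling entries
  n_diff <- sum(tps$healthy$phase_coupling != tps$right$phase_coupling)
  expect_gte(n_diff, 10)
  nul <- build_class_templates("null")
  for (f in c("phase_coupling", "linear_mixing", "directed_gain",
              "band_profile")) {
    expect_identical(nul$healthy[[f]], nul$left[[f]])
  }
  lh <- build_class_templates("lft_hft")
  expect_true(all(c("left_lft", "left_hft") %in% names(lh)))
  expect_identical(lh$left_lft$phase_coupling, lh$left_hft$phase_coupling)
  expect_false(identical(lh$left_lft$band_profile, lh$left_hft$band_profile))
  expect_error(build_class_templates("nope"),
               class = "tinnconn_input_error")
})

test_that("make_labeled_dataset counts, labels and determinism", {
  cfg <- sim_config(250, 40, epoch_s = 10, recordings_per_class = 2,
                    seed = 5)
  ds <- make_labeled_dataset(cfg)
  expect_length(ds$epochs, 4 * 2 * 4)      # classes x recordings x epochs
  expect_equal(nrow(ds$ground_truth), 8)
  expect_equal(as.integer(table(vapply(ds$epochs, `[[`, "", "label"))),
               rep(8L, 4))
  ds2 <- make_labeled_dataset(cfg)
  expect_identical(ds$epochs[[5]]$data, ds2$epochs[[5]]$data)
  expect_identical(ds$ground_truth, ds2$ground_truth)
  # uneven per-class recording counts reproduce a configured total
  cfg2 <- sim_config(250, 30, epoch_s = 10,
                     recordings_per_class = c(2, 1, 1, 1), seed = 5)
  ds3 <- make_labeled_dataset(cfg2)
  expect_length(ds3$epochs, (2 + 1 + 1 + 1) * 3)
})
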