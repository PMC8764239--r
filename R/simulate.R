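# Synthetic resting-state EEG with controlled class-conditional
# connectivity. Three independent knobs map one-to-one onto the estimator
# families:
#   * phase_coupling kappa(i,j): correlation of the per-band phase-noise
#     random walks -> phase synchrony (PLV/PLI),
#   * linear_mixing(i,j): correlation of the additive Gaussian noise
#     -> instantaneous correlation (PCC),
#   * directed_gain g(i->k): one-sample-lag linear influence of channel i
#     on channel k -> directed information flow (TE).
# Channels are sums of band-limited oscillators (one per EEG band) whose
# amplitudes follow band_profile, plus the mixed noise.

#' Class template for the synthetic generator
#'
#' Declares the generating structure of one group: target phase-coupling
#' strengths, instantaneous-correlation structure, directed lagged
#' influences, per-channel noise and the relative band amplitude profile.
#'
#' @param label Group name.
#' @param phase_coupling Symmetric n x n matrix in `[0,1]`, unit diagonal.
#' @param linear_mixing Symmetric n x n matrix in `[-1,1]`, unit diagonal.
#' @param directed_gain Non-negative n x n matrix, zero diagonal.
#' @param noise_sd Additive noise SD per channel (recycled), microvolts.
#' @param band_profile Named amplitudes (microvolts) for the six bands of
#'   [eeg_bands()]; bands may be omitted or zero.
#' @param channel_labels Channel names (default [auditory_channels()]).
#' @return An object of class `class_template`.
#' @export
class_template <- function(label,
                           phase_coupling = NULL,
                           linear_mixing = NULL,
                           directed_gain = NULL,
                           noise_sd = 5,
                           band_profile = default_band_profile(),
                           channel_labels = auditory_channels()) {
  n <- length(channel_labels)
  if (is.null(phase_coupling)) phase_coupling <- diag(n)
  if (is.null(linear_mixing)) linear_mixing <- diag(n)
  if (is.null(directed_gain)) directed_gain <- matrix(0, n, n)
  check_sym <- function(m, what, lo, hi, diag_val) {
    if (!is.matrix(m) || any(dim(m) != n)) {
      stop_config(what, " must be ", n, "x", n, " for ", n, " channels")
    }
    if (max(abs(m - t(m))) > 1e-12) stop_config(what, " must be symmetric")
    if (any(m < lo - 1e-12) || any(m > hi + 1e-12)) {
      stop_config(what, " entries must lie in [", lo, ", ", hi, "]")
    }
    if (any(abs(diag(m) - diag_val) > 1e-12)) {
      stop_config(what, " diagonal must be ", diag_val)
    }
  }
  check_sym(phase_coupling, "phase_coupling", 0, 1, 1)
  check_sym(linear_mixing, "linear_mixing", -1, 1, 1)
  if (!is.matrix(directed_gain) || any(dim(directed_gain) != n)) {
    stop_config("directed_gain must be ", n, "x", n)
  }
  if (any(directed_gain < 0) || any(diag(directed_gain) != 0)) {
    stop_config("directed_gain must be non-negative with zero diagonal")
  }
  bp <- default_band_profile()
  bp[] <- 0
  band_profile <- unlist(band_profile)
  unknown <- setdiff(names(band_profile), names(bp))
  if (length(unknown)) stop_config("unknown band(s) in band_profile: ",
                                   paste(unknown, collapse = ", "))
  bp[names(band_profile)] <- band_profile
  if (any(bp < 0)) stop_config("band_profile amplitudes must be >= 0")
  structure(
    list(label = label, phase_coupling = phase_coupling,
         linear_mixing = linear_mixing, directed_gain = directed_gain,
         noise_sd = rep_len(noise_sd, n), band_profile = bp,
         channel_labels = channel_labels),
    class = "class_template"
  )
}

#' Default resting-state band amplitude profile
#'
#' Alpha-dominant amplitudes (microvolts) typical of eyes-closed resting
#' EEG; the exact values only set relative band power and are documented in
#' the methods vignette.
#'
#' @return Named numeric vector over the six bands.
#' @export
default_band_profile <- function() {
  c(delta = 6, theta = 8, alpha = 20, beta = 5, gamma_low = 2.5,
    gamma_high = 1.5)
}

#' Simulation configuration
#'
#' @param sampling_rate Hz (default 1000, must exceed twice the highest
#'   band edge, 90 Hz).
#' @param duration Recording length in seconds (default 600).
#' @param epoch_s Epoch length used downstream (default 10); `duration`
#'   must cover at least one epoch.
#' @param channel_labels Channel names.
#' @param recordings_per_class Recordings simulated per template; recycled
#'   against the template list (default 1).
#' @param seed Base integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 1000, duration = 600, epoch_s = 10,
                       channel_labels = auditory_channels(),
                       recordings_per_class = 1, seed = 1) {
  if (sampling_rate <= 2 * 90) {
    stop_config("sampling_rate must exceed twice the highest band edge ",
                "(2 x 90 Hz); got ", sampling_rate)
  }
  if (duration < epoch_s) {
    stop_config("duration (", duration, " s) shorter than one epoch (",
                epoch_s, " s)")
  }
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 epoch_s = epoch_s, channel_labels = channel_labels,
                 recordings_per_class = recordings_per_class,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Phase deviations follow a mean-reverting (Ornstein-Uhlenbeck) process
# around the band carrier with stationary variance .PHASE_DEV_VAR (rad^2)
# and correlation time .PHASE_TAU_S (s). Cross-channel deviation
# correlation equals the template's phase_coupling, so the stationary
# phase-difference variance is 2 * .PHASE_DEV_VAR * (1 - kappa) and the
# expected PLV is approximately exp(-.PHASE_DEV_VAR * (1 - kappa)):
# ~0.02 for uncoupled pairs, exactly 1 for kappa = 1, monotone between.
.PHASE_DEV_VAR <- 4
.PHASE_TAU_S <- 0.1

# repair a correlation-like matrix to positive semi-definite (eigenvalue
# clamping), preserving the unit diagonal
.nearest_corr <- function(k) {
  e <- eigen((k + t(k)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 1e-8)
  m <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(m))
  m / tcrossprod(d)
}

#' Simulate one multichannel recording from a class template
#'
#' See the package source/vignette for the generative model. Deterministic
#' given `(template, config, seed)`.
#'
#' @param template A [class_template()].
#' @param config A [sim_config()].
#' @param seed Integer seed for this recording.
#' @return An [eeg_recording()] labeled with the template's group.
#' @export
simulate_recording <- function(template, config, seed = config$seed) {
  stopifnot(inherits(template, "class_template"), inherits(config, "sim_config"))
  n <- length(config$channel_labels)
  if (length(template$channel_labels) != n) {
    stop_config("template has ", length(template$channel_labels),
                " channels but config declares ", n)
  }
  fs <- config$sampling_rate
  nsamp <- round(config$duration * fs)
  if (nsamp < round(config$epoch_s * fs)) {
    stop_input("duration too short for one epoch")
  }
  bands <- eeg_bands()
  centers <- (bands$low_hz + bands$high_hz) / 2
  a_ou <- exp(-1 / (.PHASE_TAU_S * fs))
  innov_sd <- sqrt(.PHASE_DEV_VAR * (1 - a_ou^2))
  withr::with_seed(seed, {
    x <- matrix(0, n, nsamp)
    k_chol <- chol(.nearest_corr(template$phase_coupling))
    # smoothing kernel keeping the phase deviations differentiable (the
    # raw OU path is too rough for a meaningful instantaneous frequency)
    klen <- max(3L, round(.PHASE_TAU_S * fs))
    kern <- 0.5 - 0.5 * cos(2 * pi * seq_len(klen) / (klen + 1))
    kern <- kern / sum(kern)
    lagm <- abs(outer(seq_len(klen), seq_len(klen), "-"))
    shrink <- sum(tcrossprod(kern) * a_ou^lagm)   # variance after smoothing
    kfft <- fft(c(kern, numeric(nsamp - klen)))
    for (b in seq_len(nrow(bands))) {
      amp <- template$band_profile[bands$name[b]]
      if (amp <= 0) next
      # correlated mean-reverting phase deviations around a common carrier
      innov <- (matrix(rnorm(nsamp * n), nsamp, n) %*% k_chol) * innov_sd
      w0 <- drop(rnorm(n) %*% k_chol) * sqrt(.PHASE_DEV_VAR)
      dev <- vapply(seq_len(n), function(ci) {
        as.numeric(stats::filter(innov[, ci], a_ou, method = "recursive",
                                 init = w0[ci]))
      }, numeric(nsamp))
      dev <- Re(stats::mvfft(stats::mvfft(dev) * kfft, inverse = TRUE)) /
        (nsamp * sqrt(shrink))
      phase0 <- matrix(runif(n, -pi, pi), nsamp, n, byrow = TRUE)
      ph <- 2 * pi * centers[b] * (seq_len(nsamp) - 1) / fs + dev + phase0
      x <- x + amp * t(sin(ph))
    }
    m_chol <- chol(.nearest_corr(template$linear_mixing))
    noise <- t(matrix(rnorm(nsamp * n), nsamp, n) %*% m_chol) *
      template$noise_sd
    x <- x + noise
    # lagged directed influences, applied on the pre-influence signal
    g <- template$directed_gain
    if (any(g > 0)) {
      base <- x
      for (i in seq_len(n)) for (k in seq_len(n)) {
        if (g[i, k] > 0) {
          x[k, 2:nsamp] <- x[k, 2:nsamp] + g[i, k] * base[i, 1:(nsamp - 1)]
        }
      }
    }
    eeg_recording(x, fs, config$channel_labels,
                  subject_id = paste0("sim-", template$label, "-", seed),
                  group_label = template$label)
  })
}

#' Built-in class-template scenarios
#'
#' `"default"` encodes four groups whose similar-connectivity-activation
#' (SCA) patterns differ qualitatively: healthy has three interhemispheric
#' couplings between homologous auditory channels; bilateral keeps one
#' interhemispheric coupling plus a right-hemisphere cluster; left-sided
#' has two right-hemisphere clusters and one left cluster; right-sided has
#' two left-hemisphere clusters (one including a right channel). Linear
#' mixing mirrors the coupling pattern and each tinnitus group carries a
#' distinct directed edge so all four estimator families discriminate.
#' `"lft_hft"` additionally splits the left-sided class into low- and
#' high-frequency-tinnitus variants differing only in `band_profile`.
#' `"null"` returns four identical templates for type-I-error testing.
#'
#' @param scenario `"default"`, `"lft_hft"` or `"null"`.
#' @return Named list of [class_template()] objects.
#' @export
build_class_templates <- function(scenario = "default") {
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% c("default", "lft_hft", "null")) {
    stop_input("unknown scenario \"", paste(scenario, collapse = ","),
               "\"; use default, lft_hft or null")
  }
  ch <- auditory_channels()
  n <- length(ch)
  sym_with <- function(pairs, value) {
    m <- diag(n)
    for (p in pairs) {
      for (i in p) for (k in p) if (i != k) m[i, k] <- value
    }
    m
  }
  gain_with <- function(edges, value) {
    m <- matrix(0, n, n)
    for (e in edges) m[e[1], e[2]] <- value
    m
  }
  # channel indices: left = FT7 FC5 C5 T7 TP7 CP5 (1:6)
  #                  right = FC6 FT8 C6 T8 CP6 TP8 (7:12)
  # homologous pairs: FT7-FT8 (1,8), FC5-FC6 (2,7), C5-C6 (3,9),
  #                   T7-T8 (4,10), TP7-TP8 (5,12), CP5-CP6 (6,11)
  specs <- list(
    healthy = list(
      couple = list(c(1, 8), c(4, 10), c(6, 11)),        # 3 interhemispheric SCA
      gain = list()),
    bilateral = list(
      couple = list(c(4, 10), c(7, 8, 9)),               # 1 cross + right cluster
      gain = list(c(4, 10))),
    left = list(
      couple = list(c(7, 8), c(11, 12), c(1, 2)),        # 2 right + 1 left SCA
      gain = list(c(8, 7), c(11, 12))),
    right = list(
      couple = list(c(1, 2, 3), c(4, 5, 12)),            # 2 left SCA (one incl. TP8)
      gain = list(c(1, 2), c(4, 5), c(5, 4)))
  )
  make <- function(label, sp, band_profile = default_band_profile()) {
    class_template(
      label,
      phase_coupling = sym_with(sp$couple, 0.85),
      linear_mixing = sym_with(sp$couple, 0.7),
      directed_gain = gain_with(sp$gain, 0.6),
      noise_sd = 5,
      band_profile = band_profile,
      channel_labels = ch
    )
  }
  if (scenario == "null") {
    tpl <- make("healthy", specs$healthy)
    out <- list(healthy = tpl, bilateral = tpl, left = tpl, right = tpl)
    for (nm in names(out)) out[[nm]]$label <- nm
    return(out)
  }
  out <- lapply(names(specs), function(nm) make(nm, specs[[nm]]))
  names(out) <- names(specs)
  if (scenario == "lft_hft") {
    bp <- default_band_profile()
    bp_lft <- bp; bp_lft["delta"] <- bp["delta"] * 2.5
    bp_lft["theta"] <- bp["theta"] * 2; bp_lft["gamma_high"] <- 0.5
    bp_hft <- bp; bp_hft["gamma_high"] <- bp["gamma_high"] * 6
    bp_hft["gamma_low"] <- bp["gamma_low"] * 2; bp_hft["delta"] <- 3
    left_spec <- specs$left
    out$left <- NULL
    out$left_lft <- make("left_lft", left_spec, bp_lft)
    out$left_hft <- make("left_hft", left_spec, bp_hft)
    out <- out[c("healthy", "bilateral", "left_lft", "left_hft", "right")]
  }
  out
}

#' Generate a labeled epoch dataset
#'
#' Simulates `recordings_per_class` recordings per template, segments each
#' into epochs of `config$epoch_s`, and returns the labeled epochs plus a
#' ground-truth table. Per-recording seeds derive deterministically from
#' `config$seed`, so identical `(templates, config)` reproduce the dataset
#' bit for bit.
#'
#' @param config A [sim_config()].
#' @param templates List of templates (default the `"default"` scenario).
#' @return List with `epochs` (list of [eeg_epoch()]) and `ground_truth`
#'   (data.frame: recording id, label, seed).
#' @export
make_labeled_dataset <- function(config, templates = build_class_templates()) {
  stopifnot(inherits(config, "sim_config"))
  per_class <- rep_len(config$recordings_per_class, length(templates))
  epochs <- list()
  gt <- list()
  rec_i <- 0L
  for (t_i in seq_along(templates)) {
    tpl <- templates[[t_i]]
    for (r in seq_len(per_class[t_i])) {
      rec_i <- rec_i + 1L
      rec_seed <- (config$seed + 7919L * rec_i) %% .Machine$integer.max
      rec <- simulate_recording(tpl, config, seed = rec_seed)
      eps <- segment_epochs(rec, config$epoch_s)
      epochs <- c(epochs, eps)
      gt[[rec_i]] <- data.frame(recording = rec$subject_id,
                                label = tpl$label, seed = rec_seed,
                                n_epochs = length(eps),
                                stringsAsFactors = FALSE)
    }
  }
  list(epochs = epochs, ground_truth = do.call(rbind, gt))
}
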