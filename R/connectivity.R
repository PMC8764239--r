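# The four pairwise connectivity estimators. Each works on plain numeric
# vectors so it can be validated against a direct-summation oracle; the
# matrix builder below maps them over channel pairs.

#' Phase-locking value
#'
#' Magnitude of the time-averaged unit phasor of the phase difference,
#' `|mean(exp(j (phi_i - phi_k)))|`. 1 means a constant phase relation,
#' 0 a uniformly random one. Symmetric in its arguments.
#'
#' @param phase_i,phase_k Instantaneous phases in radians, equal length >= 2.
#' @return Value in `[0, 1]`.
#' @export
plv <- function(phase_i, phase_k) {
  if (length(phase_i) != length(phase_k)) {
    stop_input("phase vectors differ in length (", length(phase_i),
               " vs ", length(phase_k), ")")
  }
  if (length(phase_i) < 2L) stop_input("need at least 2 samples")
  Mod(mean(exp(1i * (phase_i - phase_k))))
}

#' Phase lag index
#'
#' Magnitude of the time-averaged sign of the imaginary part of the
#' cross-spectral sample, `|mean(sgn(Im(Z_i conj(Z_k))))|`. Consistent
#' non-zero phase lags give 1; zero-lag (volume-conduction) coupling
#' contributes nothing because `sgn(0) = 0`.
#'
#' @param z_i,z_k Complex band-limited analytic signals, equal length.
#' @return Value in `[0, 1]`.
#' @export
pli <- function(z_i, z_k) {
  if (length(z_i) != length(z_k)) {
    stop_input("signals differ in length")
  }
  if (!is.complex(z_i) || !is.complex(z_k)) {
    stop_input("PLI needs complex analytic signals; see band_analytic_signal()")
  }
  abs(mean(sign(Im(z_i * Conj(z_k)))))
}

#' Pearson correlation coefficient
#'
#' Normalized covariance of two signals; -1 and 1 are perfect negative and
#' positive linear relations, 0 no linear relation.
#'
#' @param x_i,x_k Numeric signals of equal length >= 2 and non-zero variance.
#' @return Value in `[-1, 1]`.
#' @export
pcc <- function(x_i, x_k) {
  if (length(x_i) != length(x_k)) stop_input("signals differ in length")
  if (length(x_i) < 2L) stop_input("need at least 2 samples")
  ci <- x_i - mean(x_i)
  ck <- x_k - mean(x_k)
  di <- sqrt(sum(ci^2))
  dk <- sqrt(sum(ck^2))
  if (di == 0 || dk == 0) {
    stop_input("zero-variance signal: correlation undefined")
  }
  v <- sum(ci * ck) / (di * dk)
  min(1, max(-1, v))
}

#' Transfer entropy (histogram plug-in estimator)
#'
#' Directed information flow from `x_i` to `x_k` in bits: the reduction in
#' uncertainty about `x_k`'s next sample given `x_i`'s present beyond what
#' `x_k`'s own present provides. Both signals are discretized into
#' `bins` equal-width amplitude bins over their own ranges; the joint
#' histogram of `(x_i^t, x_k^t, x_k^(t+lag))` then yields the plug-in
#' estimate `sum p log2( p(k'|i,k) / p(k'|k) )`. Empty cells follow the
#' `0 log 0 = 0` convention.
#'
#' @param x_i Source signal.
#' @param x_k Target signal, equal length.
#' @param bins Number of amplitude bins, >= 2 (default 4).
#' @param lag Prediction lag in samples (default 1).
#' @return Non-negative value in bits.
#' @export
transfer_entropy <- function(x_i, x_k, bins = 4, lag = 1) {
  if (length(x_i) != length(x_k)) stop_input("signals differ in length")
  if (bins < 2) stop_input("`bins` must be >= 2")
  if (lag < 1 || lag >= length(x_k)) stop_input("invalid `lag`")
  te_discrete(discretize_signal(x_i, bins), discretize_signal(x_k, bins),
              bins, lag)
}

# plug-in TE on already-discretized integer sequences
te_discrete <- function(a_full, b_full, bins, lag) {
  T_ <- length(b_full) - lag
  a <- a_full[seq_len(T_)]
  b <- b_full[seq_len(T_)]
  cc <- b_full[seq_len(T_) + lag]
  idx <- (a - 1L) + bins * (b - 1L) + bins * bins * (cc - 1L) + 1L
  n_abc <- tabulate(idx, nbins = bins^3)
  dim(n_abc) <- c(bins, bins, bins)
  n_ab <- apply(n_abc, c(1, 2), sum)
  n_bc <- apply(n_abc, c(2, 3), sum)
  n_b  <- apply(n_abc, 2, sum)
  te <- 0
  nz <- which(n_abc > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1]; j <- nz[r, 2]; k <- nz[r, 3]
    p_abc <- n_abc[i, j, k] / T_
    te <- te + p_abc * log2((n_abc[i, j, k] * n_b[j]) /
                            (n_ab[i, j] * n_bc[j, k]))
  }
  max(te, 0)
}

#' Discretize a signal into equal-width amplitude bins
#'
#' @param x Numeric signal.
#' @param bins Number of bins.
#' @return Integer bin indices in `1..bins`. A constant signal maps to bin 1.
#' @export
discretize_signal <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  i <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(i)
}

#' Connectivity matrix of an epoch
#'
#' Evaluates one connectivity measure on every channel pair of an epoch.
#' PLV, PLI and PCC are undirected (symmetric matrices); TE is directed and
#' evaluated on all ordered pairs. Diagonals are 1 for PLV/PCC and 0 for
#' PLI/TE.
#'
#' @param epoch A preprocessed [eeg_epoch()].
#' @param measure One of `"plv"`, `"pli"`, `"pcc"`, `"te"`.
#' @param band Band passed to the phase/analytic extraction (PLV, PLI);
#'   default `"broadband"`.
#' @param bins,lag TE discretization parameters.
#' @return A `connectivity_matrix`: the n x n `values` matrix with
#'   attributes `measure`, `directed` and `channel_labels`.
#' @export
connectivity_matrix <- function(epoch, measure = c("plv", "pli", "pcc", "te"),
                                band = "broadband", bins = 4, lag = 1) {
  stopifnot(inherits(epoch, "eeg_recording"))
  measure <- match.arg(measure)
  n <- nrow(epoch$data)
  labels <- epoch$channel_labels
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  if (measure == "plv") {
    ph <- analytic_phase(epoch, band)
    for (i in seq_len(n - 1)) for (k in (i + 1):n) {
      m[i, k] <- m[k, i] <- plv(ph[i, ], ph[k, ])
    }
    diag(m) <- 1
  } else if (measure == "pli") {
    z <- band_analytic_signal(epoch, band)
    for (i in seq_len(n - 1)) for (k in (i + 1):n) {
      m[i, k] <- m[k, i] <- pli(z[i, ], z[k, ])
    }
  } else if (measure == "pcc") {
    m <- stats::cor(t(epoch$data))
    dimnames(m) <- list(labels, labels)
  } else {
    disc <- lapply(seq_len(n), function(i) discretize_signal(epoch$data[i, ], bins))
    for (i in seq_len(n)) for (k in seq_len(n)) {
      if (i != k) m[i, k] <- te_discrete(disc[[i]], disc[[k]], bins, lag)
    }
  }
  new_connectivity_matrix(m, measure, labels)
}

new_connectivity_matrix <- function(values, measure, channel_labels) {
  structure(values,
            measure = measure,
            directed = identical(measure, "te"),
            channel_labels = channel_labels,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s (%s), %d channels\n",
              toupper(attr(x, "measure")),
              if (attr(x, "directed")) "directed" else "undirected",
              nrow(x)))
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Flatten a connectivity matrix into a feature vector
#'
#' Undirected matrices flatten to the upper triangle excluding the diagonal
#' in row-major order (length `n(n-1)/2`, 66 for 12 channels); directed
#' matrices to all off-diagonal entries in row-major order (length
#' `n(n-1)`). Element names record the channel pair; the layout scheme name
#' is attached as an attribute so downstream consumers can never misalign.
#'
#' @param m A `connectivity_matrix` (or plain matrix with `directed`).
#' @param directed Override directedness for plain matrices.
#' @return Named numeric vector with attribute `layout`.
#' @export
flatten_connectivity <- function(m, directed = NULL) {
  if (is.null(directed)) directed <- isTRUE(attr(m, "directed"))
  labels <- attr(m, "channel_labels")
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  n <- nrow(m)
  v <- unclass(m)
  if (!directed) {
    ut <- upper.tri(v)
    # row-major upper triangle: transpose, take lower triangle
    out <- t(v)[t(ut)]
    pairs <- which(ut, arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    names(out) <- paste0(labels[pairs[, 1]], "-", labels[pairs[, 2]])
    attr(out, "layout") <- "upper_tri_rowmajor_v1"
  } else {
    off <- row(v) != col(v)
    out <- t(v)[t(off)]
    pairs <- which(off, arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    names(out) <- paste0(labels[pairs[, 1]], "->", labels[pairs[, 2]])
    attr(out, "layout") <- "offdiag_rowmajor_v1"
  }
  out
}

#' Rebuild a matrix from a flattened connectivity vector
#'
#' Inverse of [flatten_connectivity()] for both layouts. The diagonal is
#' restored from the measure convention (`diag_value`).
#'
#' @param v Flattened vector from [flatten_connectivity()].
#' @param n Number of channels.
#' @param directed Whether `v` uses the directed layout.
#' @param diag_value Diagonal to restore (1 for PLV/PCC, 0 for PLI/TE).
#' @return An n x n matrix.
#' @export
unflatten_connectivity <- function(v, n, directed = FALSE, diag_value = 1) {
  m <- matrix(diag_value * diag(n), n, n)
  if (!directed) {
    stopifnot(length(v) == n * (n - 1) / 2)
    ut <- upper.tri(m)
    tm <- t(m)
    tm[t(ut)] <- v
    m <- t(tm)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  } else {
    stopifnot(length(v) == n * (n - 1))
    off <- row(m) != col(m)
    tm <- t(m)
    tm[t(off)] <- v
    m <- t(tm)
  }
  diag(m) <- diag_value
  m
}
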