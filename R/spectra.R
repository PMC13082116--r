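#' Welch cross-spectral density of a multichannel series
#'
#' Segment-averaged cross-spectra: the series is cut into `nperseg`-sample
#' segments with fractional `overlap`, each segment is constant-detrended,
#' windowed (Hann by default) and FFT'd, and outer products are averaged
#' across segments.  The empirical-comparison convention in this package is
#' 2048-sample segments, 50% overlap, Hann window, which yields 0.5 Hz
#' resolution at fs = 1024 Hz; for other sampling rates the FFT grid is
#' whatever `fs / nperseg` gives and downstream analysis maps analysis
#' frequencies to the nearest FFT bin.
#'
#' @param x channels x samples matrix, or a `ts_multi` object.
#' @param fs sampling rate, Hz (taken from `x` when it is a `ts_multi`).
#' @param nperseg segment length in samples (default 2048).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @param window window name; `"hann"` (default) or `"boxcar"`.
#' @return object of class `csd`: `S` (complex N x N x n_bins), `f` (FFT
#'   bin frequencies, one-sided), `fs`, `n_segments`, estimator metadata.
#' @export
welch_csd <- function(x, fs = NULL, nperseg = 2048, overlap = 0.5,
                      window = c("hann", "boxcar")) {
  window <- match.arg(window)
  if (inherits(x, "ts_multi")) { fs <- x$fs; x <- x$x }
  stopifnot(is.matrix(x), !is.null(fs))
  n <- nrow(x); ns <- ncol(x)
  if (ns < nperseg)
    ws_stop(sprintf("need at least one segment: %d samples < nperseg %d",
                    ns, nperseg), "walksum_error_samples")
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, ns - nperseg + 1L, by = step)
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / nperseg)
  else rep(1, nperseg)
  scale <- 1 / (fs * sum(w^2))
  nb <- floor(nperseg / 2) + 1L
  half <- seq_len(nb)
  # per-segment channel FFTs, then per-bin Gram matrices across segments
  Xs <- array(0i, dim = c(nb, n, length(starts)))
  for (s in seq_along(starts)) {
    seg <- x[, starts[s] + seq_len(nperseg) - 1L, drop = FALSE]
    seg <- seg - rowMeans(seg)                 # constant detrend
    segF <- stats::mvfft(t(seg * rep(w, each = n)))
    Xs[, , s] <- segF[half, , drop = FALSE]
  }
  S <- array(0i, dim = c(n, n, nb))
  for (b in seq_len(nb)) {
    Xb <- matrix(Xs[b, , ], nrow = n)          # n x n_segments
    S[, , b] <- (Xb %*% Conj(t(Xb))) * (scale / length(starts))
  }
  # one-sided density: double every bin except DC (and Nyquist when present)
  dbl <- rep(2, nb); dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nb] <- 1
  for (b in seq_len(nb)) S[, , b] <- S[, , b] * dbl[b]
  structure(list(S = S, f = (half - 1) * fs / nperseg, fs = fs,
                 n_segments = length(starts),
                 meta = list(nperseg = nperseg, overlap = overlap,
                             window = window)),
            class = "csd")
}

#' Complex coherency from a cross-spectral density
#'
#' `C_ij(f) = S_ij(f) / sqrt(S_ii(f) S_jj(f))`.
#'
#' @param csd a [welch_csd()] result.
#' @return object of class `coherency_field` with `H` (complex N x N x n_f,
#'   matching the accessor layout of `resolvent_field`), `f`, estimator
#'   metadata.
#' @export
coherency <- function(csd) {
  stopifnot(inherits(csd, "csd"))
  n <- dim(csd$S)[1]; nb <- dim(csd$S)[3]
  H <- array(0i, dim = c(n, n, nb))
  for (b in seq_len(nb)) {
    a <- Re(diag(csd$S[, , b]))
    if (any(a <= 0)) {
      bad <- which(a <= 0)[1]
      ws_stop(sprintf("zero auto-spectrum: channel %d at bin %d (%.3g Hz)",
                      bad, b, csd$f[b]), "walksum_error_autospectrum")
    }
    d <- 1 / sqrt(a)
    H[, , b] <- csd$S[, , b] * (d %o% d)
  }
  structure(list(H = H, f = csd$f, fs = csd$fs, n_segments = csd$n_segments,
                 meta = csd$meta),
            class = "coherency_field")
}

#' Restrict a coherency field to an analysis grid (nearest FFT bin)
#'
#' @param coh a `coherency_field`.
#' @param f target frequencies, Hz.
#' @return a `coherency_field` on the target grid; `f_actual` records the
#'   FFT bin frequency each target mapped to.
#' @export
coherency_on_grid <- function(coh, f = seq(1, 45, by = 0.5)) {
  idx <- vapply(f, function(fr) which.min(abs(coh$f - fr)), integer(1))
  out <- coh
  out$H <- coh$H[, , idx, drop = FALSE]
  out$f <- f
  out$f_actual <- coh$f[idx]
  out
}

#' Coherency implied by a transfer function under white-noise input
#'
#' For unit-variance independent node noise filtered by `H(f)`, the
#' cross-spectrum is `G = H H*` and the implied coherency is
#' `G_ij / sqrt(G_ii G_jj)` — the large-duration limit of the empirical
#' estimate on [make_timeseries()] output.
#'
#' @param field a `resolvent_field`.
#' @return a `coherency_field` on the same grid.
#' @export
implied_coherency <- function(field) {
  n <- field_n_nodes(field); nf <- length(field$f)
  H <- array(0i, dim = c(n, n, nf))
  for (k in seq_len(nf)) {
    G <- field$H[, , k] %*% Conj(t(field$H[, , k]))
    d <- 1 / sqrt(Re(diag(G)))
    H[, , k] <- G * (d %o% d)
  }
  structure(list(H = H, f = field$f, meta = list(source = "implied")),
            class = "coherency_field")
}

#' Channel report for an empirical coherency field
#'
#' Applies the channel battery ([evaluate_predictions()]) to a coherency
#' field with the empirical-side conventions: I = Re(C) and the Q statistic
#' defaults to `|Im(C)|`.
#'
#' @param coh a `coherency_field` (already on the analysis grid; see
#'   [coherency_on_grid()]).
#' @param distances distance matrix matching the channel count.
#' @param ... passed to [evaluate_predictions()].
#' @param q_stat Q statistic; empirical default `"abs"`.
#' @return a `channel_report`.
#' @export
empirical_channels <- function(coh, distances, q_stat = "abs", ...) {
  stopifnot(inherits(coh, "coherency_field"))
  evaluate_predictions(coh, distances, q_stat = q_stat, ...)
}

#' Dominance ratio of the spectral matrix at a frequency
#'
#' Ratio of the two largest singular values of the full complex matrix at
#' `f` (all entries retained).  A rank-one matrix returns `Inf`; the
#' identity gives 1.
#'
#' @param field a `resolvent_field` or `coherency_field`.
#' @param f frequency, Hz (nearest grid point).
#' @return scalar ratio (>= 1, possibly `Inf`).
#' @export
dominance_ratio <- function(field, f) {
  k <- which.min(abs(field$f - f))
  M <- field$H[, , k]
  sv <- svd(M, nu = 0, nv = 0)$d
  if (length(sv) < 2 || sv[2] < .Machine$double.eps * max(sv[1], 1))
    return(Inf)
  sv[1] / sv[2]
}

#' Communication dimensionality of the two-channel architecture
#'
#' Participation ratio `(sum s)^2 / sum s^2` of the singular values of the
#' 2 x P matrix whose rows are the I and Q pair profiles (band-averaged
#' when a band is given).  Equal-norm orthogonal channels give 2, a single
#' effective channel gives 1.  This construction is an explicit
#' interpretation of "communication dimensionality", and is labelled as
#' such wherever it is reported.
#'
#' @param field a `resolvent_field` or `coherency_field`.
#' @param f single frequency (Hz), or `NULL` to use `band`.
#' @param band length-2 numeric `c(f_lo, f_hi)`; profiles are averaged over
#'   grid frequencies inside the band.
#' @param q_abs use `|Im|` for the Q profile.
#' @return scalar in `[1, 2]`.
#' @export
communication_dimensionality <- function(field, f = NULL, band = NULL,
                                         q_abs = FALSE) {
  stopifnot(!is.null(f) || !is.null(band))
  sel <- if (!is.null(f)) which.min(abs(field$f - f))
  else which(field$f >= band[1] & field$f <= band[2])
  np <- field_n_nodes(field) * (field_n_nodes(field) - 1) / 2
  Ip <- rowMeans(vapply(sel, function(k) pair_values(Re(field$H[, , k])),
                        numeric(np)))
  Qp <- rowMeans(vapply(sel, function(k) pair_values(Im(field$H[, , k])),
                        numeric(np)))
  if (q_abs) Qp <- abs(Qp)
  sv <- svd(rbind(Ip, Qp), nu = 0, nv = 0)$d
  sv <- sv[sv > .Machine$double.eps * max(sv, 1)]
  if (length(sv) == 0) return(1)
  sum(sv)^2 / sum(sv^2)
}
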