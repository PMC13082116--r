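#' @keywords internal
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic connectome generator
#'
#' Defaults describe a desk-scale stand-in for consensus tractography with
#' the topological feature the channel analysis studies: hub-mediated
#' routing.  With `hub_fraction > 0` (the default) the network is a
#' core-periphery graph: peripheral nodes attach to spatially spread hubs
#' with an exponential distance rule (characteristic reach `decay_length`),
#' and hubs interconnect through long corridors (decay `corridor_length`).
#' Long-range communication then traverses a roughly fixed number of hops
#' (periphery - hub - hub - periphery) at any resolution, which is what
#' makes the routing-channel statistics stable under coarse-graining.
#' With `hub_fraction = 0` the generator instead produces a dense
#' distance-decay lattice (`weight = exp(-d / decay_length)`), a circulant
#' structure on the ring that is useful for degree / spectral tests.
#'
#' @param n_nodes number of nodes (>= 4; default 64).
#' @param geometry `"ring"` (nodes on a circle of radius `ring_radius`;
#'   spatially ordered, the test default) or `"box3d"` (uniform positions
#'   in a `box_mm` cube).
#' @param decay_length exponential decay length, mm (default 30: the scale
#'   over which cortico-cortical connection strength falls off).
#' @param hub_fraction fraction of nodes designated as hubs
#'   (default 0.125).
#' @param hub_boost multiplicative weight boost on hub-hub corridors
#'   (>= 1; default 1).
#' @param weight_noise_sd sd of the lognormal multiplicative weight noise
#'   (default 0.5, mimicking tractography weight dispersion).
#' @param ring_radius ring radius, mm (default 80: distances up to 160 mm,
#'   the fibre-tract range).
#' @param box_mm box edge, mm (default 150).
#' @param corridor_length decay length of hub-hub corridor weights, mm
#'   (default 100: long association tracts).
#' @param local_coupling relative strength of a direct
#'   periphery-periphery exponential lattice added on top of the hub
#'   routing (default 0: purely hub-mediated; nonzero values degrade the
#'   coarse-graining stability of the channel statistics).
#' @param seed integer RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_nodes = 64, geometry = c("ring", "box3d"),
                         decay_length = 30, hub_fraction = 0.125,
                         hub_boost = 1, weight_noise_sd = 0.5,
                         ring_radius = 80, box_mm = 150,
                         corridor_length = 100, local_coupling = 0,
                         seed = 1) {
  geometry <- match.arg(geometry)
  if (n_nodes < 4) ws_stop("n_nodes must be >= 4", "walksum_error_params")
  if (decay_length <= 0) ws_stop("decay_length must be positive",
                                 "walksum_error_params")
  if (hub_boost < 1) ws_stop("hub_boost must be >= 1", "walksum_error_params")
  structure(list(n_nodes = n_nodes, geometry = geometry,
                 decay_length = decay_length, hub_fraction = hub_fraction,
                 hub_boost = hub_boost, weight_noise_sd = weight_noise_sd,
                 ring_radius = ring_radius, box_mm = box_mm,
                 corridor_length = corridor_length,
                 local_coupling = local_coupling, seed = seed),
            class = "synth_config")
}

#' Generate a distance-embedded synthetic connectome
#'
#' Nodes are placed by the configured geometry; distances are Euclidean.
#' With hubs (default), hubs are spread over the embedding (even spacing on
#' the ring, greedy max-min placement in the box), peripheral nodes attach
#' to hubs under an exponential distance rule, and hub pairs are joined by
#' long-range corridors; with `hub_fraction = 0` every pair is weighted
#' `exp(-d / decay_length)`.  All weights carry lognormal noise and the
#' matrix is spectral-radius normalised.  The same seed always yields an
#' identical connectome.  Designated hubs are recorded in `attr(, "hubs")`.
#'
#' @param cfg a [synth_config()].
#' @return a [connectome]; attribute `hubs` holds hub node indices.
#' @export
make_connectome <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_nodes
    coords <- if (cfg$geometry == "ring") {
      th <- 2 * pi * (seq_len(n) - 1) / n
      cbind(cfg$ring_radius * cos(th), cfg$ring_radius * sin(th), 0)
    } else matrix(stats::runif(3 * n, 0, cfg$box_mm), ncol = 3)
    D <- as.matrix(stats::dist(coords))
    # coincident nodes would give zero distance off-diagonal: jitter them
    tries <- 0
    while (any(D[upper.tri(D)] < 1e-9) && tries < 20) {
      bad <- which(apply(D + diag(Inf, n), 1, min) < 1e-9)
      coords[bad, ] <- coords[bad, ] +
        matrix(stats::rnorm(3 * length(bad), sd = 0.5), ncol = 3)
      D <- as.matrix(stats::dist(coords))
      tries <- tries + 1
      message("jittered ", length(bad), " coincident node(s)")
    }
    lnoise <- function(m) exp(stats::rnorm(m, sd = cfg$weight_noise_sd))
    n_hub <- round(cfg$hub_fraction * n)
    hubs <- integer(0)
    if (n_hub == 0) {
      W <- exp(-D / cfg$decay_length) * 1
      E <- matrix(0, n, n)
      E[upper.tri(E)] <- stats::rnorm(n * (n - 1) / 2,
                                      sd = cfg$weight_noise_sd)
      W <- W * exp(E + t(E))
    } else {
      hubs <- if (cfg$geometry == "ring")
        round(seq(1, n, length.out = n_hub + 1))[seq_len(n_hub)]
      else {                               # greedy max-min spread
        h <- integer(n_hub); h[1] <- 1
        if (n_hub > 1) for (k in 2:n_hub)
          h[k] <- which.max(apply(D[, h[1:(k - 1)], drop = FALSE], 1, min))
        sort(h)
      }
      W <- matrix(0, n, n)
      for (h in hubs) for (i in setdiff(seq_len(n), h)) {
        w <- exp(-D[i, h] / cfg$decay_length) * lnoise(1)
        if (w > 0.05) {                    # sparsify negligible attachments
          W[i, h] <- W[i, h] + w
          W[h, i] <- W[i, h]
        }
      }
      for (a in hubs) for (b in hubs) if (a < b) {
        w <- cfg$hub_boost * exp(-D[a, b] / cfg$corridor_length) * lnoise(1)
        W[a, b] <- W[a, b] + w
        W[b, a] <- W[a, b]
      }
      if (cfg$local_coupling > 0) {
        iu <- which(upper.tri(D))
        con <- stats::runif(length(iu)) < exp(-D[iu] / cfg$decay_length)
        B <- matrix(0, n, n)
        B[iu[con]] <- cfg$local_coupling * lnoise(sum(con))
        W <- W + B + t(B)
      }
    }
    diag(W) <- 0
    conn <- connectome(W, D, coords = coords)
    attr(conn, "hubs") <- hubs
    conn
  })
}

#' Coarse-grain a connectome by merging contiguous node groups
#'
#' Nodes are merged in contiguous blocks of size `factor` (a remainder
#' shorter than `factor` forms its own final block); block weights are
#' summed (total weight preserved
#' before the final spectral-radius renormalisation) and block distances
#' averaged.  A parcellation-invariance test fixture: statistics of the
#' resolvent should be stable under this operation.
#'
#' @param conn a [connectome].
#' @param factor block size (>= 1, < N).
#' @return a coarser [connectome].
#' @export
coarse_grain <- function(conn, factor) {
  stopifnot(inherits(conn, "connectome"))
  n <- nrow(conn$weights)
  if (factor >= n) ws_stop("factor must be smaller than N",
                           "walksum_error_params")
  if (factor < 1) ws_stop("factor must be >= 1", "walksum_error_params")
  g <- ceiling(seq_len(n) / factor)           # blocks of `factor` nodes;
  m <- max(g)                                 # a short final block is kept
  A <- outer(seq_len(m), g, "==") * 1            # m x n membership
  W <- A %*% conn$weights %*% t(A)
  cnt <- A %*% matrix(1, n, n) %*% t(A)          # pair counts incl. within
  D <- (A %*% conn$distances %*% t(A)) / cnt
  diag(W) <- 0
  diag(D) <- 0
  coords <- if (is.null(conn$coords)) NULL else
    (A %*% conn$coords) / rowSums(A)
  connectome(W, D, coords = coords)
}

#' Network-filtered noise time series
#'
#' Generates multichannel signals whose cross-spectral structure is shaped
#' by the resolvent transfer function: per-node white noise is built in the
#' frequency domain, each positive-frequency bin is multiplied by `H(f)`
#' (bare, or dressed when `omega0`/`zeta` are given), and the result is
#' inverse-transformed (circular convolution — the exact realisation of the
#' resolvent as a transfer function).  Same seed, same series.
#'
#' @param conn a [connectome].
#' @param fs sampling rate, Hz (must be at least twice the maximum analysis
#'   frequency you intend to use).
#' @param duration seconds of signal.
#' @param omega0,zeta optional local-gain dressing parameters.
#' @param reading dressed-operator reading (see [dressed_resolvent()]).
#' @param T conduction delay, s.
#' @param phase_sign phase-sign convention (see [bare_resolvent()]).
#' @param noise_seed RNG seed.
#' @return `ts_multi` object: list with `x` (channels x samples), `fs`.
#' @export
make_timeseries <- function(conn, fs = 256, duration = 60, omega0 = NULL,
                            zeta = NULL, reading = "literal", T = 0.010,
                            phase_sign = -1, noise_seed = 1) {
  phase_sign <- check_phase_sign(phase_sign)
  stopifnot(inherits(conn, "connectome"))
  n <- nrow(conn$weights)
  ns <- round(fs * duration)
  if (ns < 2048)
    warning("duration shorter than one default Welch segment (2048 samples)",
            call. = FALSE)
  with_seed(noise_seed, {
    X <- matrix(stats::rnorm(n * ns), nrow = n)
    Xf <- t(stats::mvfft(t(X)))                  # n x ns, channel FFTs
    freqs <- (seq_len(ns) - 1) * fs / ns
    half <- floor(ns / 2)
    l <- function(f) if (is.null(omega0)) NULL else local_gain(f, omega0, zeta)
    for (k in seq_len(half + 1)) {
      f <- freqs[k]
      H <- if (f == 0) {
        solve(diag(n) - conn$weights)            # real DC transfer
      } else resolvent_matrix(conn$weights, f, T, l = l(f),
                              reading = reading, phase_sign = phase_sign)
      if ((ns %% 2 == 0) && k == half + 1) {
        # Nyquist bin must stay real for a real output signal
        Xf[, k] <- Re(H) %*% Re(Xf[, k])
      } else {
        Xf[, k] <- H %*% Xf[, k]
        if (k > 1) Xf[, ns - k + 2] <- Conj(Xf[, k])   # mirror bin
      }
    }
    x <- Re(t(stats::mvfft(t(Xf), inverse = TRUE))) / ns
    structure(list(x = x, fs = fs), class = "ts_multi")
  })
}

#' Write / read a multichannel series as delimited text with a sidecar
#' @param series a `ts_multi` object.
#' @param dir output directory.
#' @export
write_timeseries <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_file(series$x, file.path(dir, "series.tsv"))
  jsonlite::write_json(list(fs = series$fs, n_channels = nrow(series$x)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  x <- read_matrix_file(file.path(dir, "series.tsv"))
  structure(list(x = x, fs = meta$fs), class = "ts_multi")
}
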