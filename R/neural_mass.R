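#' Wilson-Cowan simulation parameters
#'
#' Two-population (excitatory/inhibitory) firing-rate model with logistic
#' sigmoid activation.  The default local parameters are the canonical
#' oscillatory set from the classic rate-model literature
#' (c1 = 16, c2 = 12, c3 = 15, c4 = 3; gains 1.3 / 2, thresholds 4 / 3.7)
#' with 10 ms time constants and constant excitatory drive P = 1.25.
#'
#' @param tau_e,tau_i population time constants, ms.
#' @param c1,c2,c3,c4 local coupling constants (E->E, I->E, E->I, I->I).
#' @param a_e,theta_e,a_i,theta_i sigmoid gain and threshold per population.
#' @param P constant input to the excitatory population.
#' @param G global coupling of the connectome into excitatory populations.
#' @param noise_sd additive noise sd (Euler-Maruyama, per sqrt(ms)).
#' @param drive_freq sinusoidal drive frequency, Hz (0 = none).
#' @param drive_amp drive amplitude.
#' @param drive_nodes integer indices receiving the drive.
#' @param dt Euler step, ms (default 0.1).
#' @param duration simulated time, s (default 10).
#' @param seed RNG seed.
#' @return list of class `wc_params`.
#' @export
wc_params <- function(tau_e = 10, tau_i = 10, c1 = 16, c2 = 12, c3 = 15,
                      c4 = 3, a_e = 1.3, theta_e = 4, a_i = 2,
                      theta_i = 3.7, P = 1.25, G = 0.5, noise_sd = 0.01,
                      drive_freq = 0, drive_amp = 0,
                      drive_nodes = integer(0), dt = 0.1, duration = 10,
                      seed = 1) {
  if (dt <= 0) ws_stop("dt must be positive", "walksum_error_params")
  structure(list(tau_e = tau_e, tau_i = tau_i, c1 = c1, c2 = c2, c3 = c3,
                 c4 = c4, a_e = a_e, theta_e = theta_e, a_i = a_i,
                 theta_i = theta_i, P = P, G = G, noise_sd = noise_sd,
                 drive_freq = drive_freq, drive_amp = drive_amp,
                 drive_nodes = drive_nodes, dt = dt, duration = duration,
                 seed = seed),
            class = "wc_params")
}

#' @keywords internal
wc_sigmoid <- function(x, a, theta) 1 / (1 + exp(-a * (x - theta)))

#' Simulate noise-driven Wilson-Cowan dynamics on a connectome
#'
#' Euler-Maruyama integration of coupled two-population rate units: the
#' connectome couples excitatory rates into excitatory inputs with gain
#' `G`, noise is additive Gaussian, and an optional sinusoid drives the
#' excitatory input of `drive_nodes`.  Identical seeds give identical
#' trajectories.  This model is the dynamical negative control: its
#' coherency patterns are *not* expected to reproduce the resolvent's
#' channel architecture.
#'
#' @param conn a [connectome].
#' @param p a [wc_params()].
#' @return `ts_multi` with excitatory rates (channels x samples) at the
#'   simulation rate `fs = 1000 / dt` Hz.
#' @export
simulate_wc <- function(conn, p = wc_params()) {
  stopifnot(inherits(conn, "connectome"), inherits(p, "wc_params"))
  C <- conn$weights
  n <- nrow(C)
  n_steps <- round(p$duration * 1000 / p$dt)
  drive_mask <- rep(0, n)
  drive_mask[p$drive_nodes] <- 1
  with_seed(p$seed, {
    E <- rep(0.1, n); I <- rep(0.1, n)
    out <- matrix(NA_real_, n, n_steps)
    sq <- p$noise_sd * sqrt(p$dt)
    w_dr <- 2 * pi * p$drive_freq / 1000          # per ms
    for (s in seq_len(n_steps)) {
      t_ms <- s * p$dt
      drive <- if (p$drive_amp != 0)
        p$drive_amp * sin(w_dr * t_ms) * drive_mask else 0
      inp_e <- p$c1 * E - p$c2 * I + p$G * as.vector(C %*% E) + p$P + drive
      inp_i <- p$c3 * E - p$c4 * I
      dE <- (-E + wc_sigmoid(inp_e, p$a_e, p$theta_e)) * (p$dt / p$tau_e)
      dI <- (-I + wc_sigmoid(inp_i, p$a_i, p$theta_i)) * (p$dt / p$tau_i)
      if (p$noise_sd > 0) {
        dE <- dE + sq * stats::rnorm(n)
        dI <- dI + sq * stats::rnorm(n)
      }
      E <- E + dE; I <- I + dI
      if (!all(is.finite(E)) || !all(is.finite(I)))
        ws_stop(sprintf("non-finite state at step %d (t = %.1f ms)", s, t_ms),
                "walksum_error_blowup")
      out[, s] <- E
    }
    structure(list(x = out, fs = 1000 / p$dt), class = "ts_multi")
  })
}

#' Downsample a multichannel series by block averaging
#' @param series a `ts_multi`.
#' @param fs_out target sampling rate (must divide `fs` after rounding).
#' @return a `ts_multi` at the reduced rate.
#' @export
downsample_ts <- function(series, fs_out) {
  fac <- round(series$fs / fs_out)
  if (fac <= 1) return(series)
  ns <- (ncol(series$x) %/% fac) * fac
  x <- series$x[, seq_len(ns), drop = FALSE]
  dim(x) <- c(nrow(x), fac, ns / fac)
  structure(list(x = colMeans(aperm(x, c(2, 1, 3))), fs = series$fs / fac),
            class = "ts_multi")
}

#' Spatial rank correlation between two pair profiles
#' @param a,b numeric vectors over the same unordered node pairs.
#' @return Spearman rho.
#' @export
spatial_rho <- function(a, b) spearman(a, b)

#' Default spatial input configurations for the negative-control sweep
#' @keywords internal
nc_drive_sets <- function(conn, seed) {
  deg <- weighted_degree(conn)
  n <- length(deg)
  k10 <- max(1L, round(0.1 * n))
  rnd <- with_seed(seed, sort(sample.int(n, k10)))
  list(single_hub = which.max(deg),
       single_peripheral = which.min(deg),
       all_nodes = seq_len(n),
       random_10pct = rnd,
       top_degree_10pct = order(deg, decreasing = TRUE)[seq_len(k10)],
       bottom_degree_10pct = order(deg)[seq_len(k10)])
}

#' Neural-mass negative-control sweep
#'
#' Runs the full condition grid (by default 8 driving frequencies x 6
#' spatial input configurations x 3 coupling strengths = 144 conditions),
#' estimates coherency from each simulation, and correlates the simulated
#' Re / |Im| pair profiles at the drive frequency against the resolvent's
#' I / Q pair profiles at the same frequency.  Near-zero grand-mean
#' correlations indicate that the transfer-function channel architecture is
#' not what a driven nonlinear simulation produces — the negative control.
#'
#' @param conn a [connectome].
#' @param field a `resolvent_field` on `conn` covering the drive
#'   frequencies.
#' @param frequencies driving frequencies, Hz (default 8 band-
#'   representative values 2-40 Hz).
#' @param couplings global coupling strengths (default 0.2, 0.5, 1.0).
#' @param configs named list of drive-node index sets (default: the six
#'   standard configurations from [nc_drive_sets]).
#' @param wc baseline [wc_params()] (drive and G fields are overridden per
#'   condition; shorten `duration` / enlarge `dt` for desk-scale runs).
#' @param fs_out analysis sampling rate after downsampling, Hz.
#' @param nperseg Welch segment length for the sweep.
#' @param seed master seed; per-condition seeds derive from it.
#' @return list of class `nc_sweep`: `table` (one row per condition with
#'   `r_I`, `r_Q`), `grand_mean_r_I`, `grand_mean_r_Q`, `grand_mean_abs`.
#' @export
negative_control_sweep <- function(conn, field,
                                   frequencies = c(2, 5, 7.5, 10, 13, 20, 30, 40),
                                   couplings = c(0.2, 0.5, 1.0),
                                   configs = NULL,
                                   wc = wc_params(),
                                   fs_out = 250, nperseg = 256,
                                   seed = 1) {
  stopifnot(inherits(conn, "connectome"))
  if (is.null(configs)) configs <- nc_drive_sets(conn, seed)
  rows <- list()
  cond <- 0L
  for (fr in frequencies) for (cg in names(configs)) for (G in couplings) {
    cond <- cond + 1L
    p <- wc
    p$drive_freq <- fr; p$drive_amp <- if (p$drive_amp > 0) p$drive_amp else 1
    p$drive_nodes <- configs[[cg]]
    p$G <- G
    p$seed <- (seed * 1000L + cond) %% .Machine$integer.max
    sim <- tryCatch(simulate_wc(conn, p), error = function(e)
      ws_stop(sprintf("condition %d (f = %g, %s, G = %g): %s",
                      cond, fr, cg, G, conditionMessage(e)),
              "walksum_error_blowup"))
    sim <- downsample_ts(sim, fs_out)
    coh <- coherency(welch_csd(sim, nperseg = nperseg))
    kb <- which.min(abs(coh$f - fr))
    km <- which.min(abs(field$f - fr))
    r_I <- spatial_rho(pair_values(Re(field$H[, , km])),
                       pair_values(Re(coh$H[, , kb])))
    r_Q <- spatial_rho(pair_values(Im(field$H[, , km])),
                       abs(pair_values(Im(coh$H[, , kb]))))
    rows[[cond]] <- data.frame(condition = cond, drive_freq = fr,
                               config = cg, G = G, r_I = r_I, r_Q = r_Q)
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 grand_mean_r_I = mean(tab$r_I, na.rm = TRUE),
                 grand_mean_r_Q = mean(tab$r_Q, na.rm = TRUE),
                 grand_mean_abs = mean(abs(c(tab$r_I, tab$r_Q)),
                                       na.rm = TRUE)),
            class = "nc_sweep")
}

#' @export
print.nc_sweep <- function(x, ...) {
  cat(sprintf("<nc_sweep> %d conditions\n", nrow(x$table)))
  cat(sprintf("  grand mean r_I = %.4f, r_Q = %.4f, mean |r| = %.4f\n",
              x$grand_mean_r_I, x$grand_mean_r_Q, x$grand_mean_abs))
  invisible(x)
}
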