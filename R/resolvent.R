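#' Analysis frequency grid
#'
#' The default grid is 1-45 Hz in 0.5 Hz steps (89 points) with a single
#' characteristic conduction delay T = 10 ms.  Frequencies are specified in
#' Hz throughout the package; the walk phase always uses the angular form
#' `omega * T = 2 * pi * f * T`.  The local gain [local_gain()] takes Hz
#' directly because it depends only on the ratio `f / f0` and the damping.
#' This Hz-vs-radian convention is the single most error-prone point of the
#' framework and is fixed package-wide by this constructor.
#'
#' @param f strictly increasing positive frequencies, Hz.
#' @param T conduction delay, seconds (default 0.010).
#' @return object of class `frequency_grid` with elements `f` and `T`.
#' @export
frequency_grid <- function(f = seq(1, 45, by = 0.5), T = 0.010) {
  f <- as.numeric(f)
  if (any(f <= 0) || is.unsorted(f, strictly = TRUE))
    ws_stop("frequencies must be positive and strictly increasing",
            "walksum_error_grid")
  if (T <= 0) ws_stop("delay T must be positive", "walksum_error_grid")
  structure(list(f = f, T = T), class = "frequency_grid")
}

#' Local gain of a damped harmonic oscillator node
#'
#' `l(f) = f0^2 / (f0^2 - f^2 + 2i * zeta * f0 * f)`.  The expression is
#' scale-invariant in `f / f0`, so natural frequency and the evaluation
#' frequency may both be given in Hz.  At `f = 0` the gain is exactly 1; at
#' resonance (`f = f0`) the magnitude is `1 / (2 * zeta)`.
#'
#' @param f frequency, Hz (vectorised, `f >= 0`).
#' @param omega0 natural frequency, Hz (> 0).
#' @param zeta damping ratio, dimensionless (> 0).
#' @return complex vector of gains.
#' @export
local_gain <- function(f, omega0, zeta) {
  if (omega0 <= 0 || zeta <= 0)
    ws_stop("omega0 and zeta must be positive", "walksum_error_params")
  omega0^2 / (omega0^2 - f^2 + 2i * zeta * omega0 * f)
}

#' @keywords internal
new_resolvent_field <- function(H, grid, dressing = NULL, reading = NULL,
                                phase_sign = -1) {
  structure(list(H = H, f = grid$f, T = grid$T,
                 dressing = dressing, reading = reading,
                 phase_sign = phase_sign),
            class = "resolvent_field")
}

#' @keywords internal
check_phase_sign <- function(phase_sign) {
  phase_sign <- as.numeric(phase_sign)
  if (!phase_sign %in% c(-1, 1))
    ws_stop("phase_sign must be -1 (delay/lag, default) or +1 (phase lead)",
            "walksum_error_params")
  phase_sign
}

#' @keywords internal
resolvent_matrix <- function(C, f, T, l = NULL, reading = "literal",
                             phase_sign = -1) {
  n <- nrow(C)
  z <- exp(phase_sign * 2i * pi * f * T)
  if (is.null(l)) {
    A <- diag(n) - z * C
  } else if (identical(reading, "literal")) {
    # (l I - l z C): both terms carry the gain, per the printed formula
    A <- diag(l, n) - (l * z) * C
  } else {                                  # "gain": l (I - l z C)^{-1}
    A <- diag(n) - (l * z) * C
  }
  H <- tryCatch(solve(A, diag(1 + 0i, n)),
                error = function(e)
                  ws_stop(sprintf("singular system at f = %g Hz", f),
                          "walksum_error_singular"))
  if (!is.null(l) && identical(reading, "gain")) H <- l * H
  H
}

#' Bare resolvent transfer function over a frequency grid
#'
#' Computes `H(f) = (I - e^{s i 2 pi f T} C)^{-1}` at every grid frequency
#' by a direct linear solve (one factorisation per frequency), summing the
#' geometric walk series exactly.  Requires spectral radius of the weights
#' strictly below 1 (guaranteed by [connectome()]).
#'
#' The phase-sign convention `s` is the package's second fixed convention:
#' the default `phase_sign = -1` treats each hop's conduction delay as a
#' phase lag (`e^{-i w T}`, the transfer function of a pure delay under the
#' engineering Fourier convention); `phase_sign = +1` gives the complex
#' conjugate field (identical I-channel, negated Q-channel).  All channel
#' statistics record which sign produced them via the field object.
#'
#' @param conn a [connectome].
#' @param grid a [frequency_grid] (default 1-45 Hz, T = 10 ms).
#' @param phase_sign `-1` (delay as phase lag, default) or `+1`
#'   (conjugate convention).
#' @return object of class `resolvent_field`: complex N x N x n_f array `H`
#'   plus grid metadata.  Use [channel_I()] / [channel_Q()] for the real
#'   (integrative) and imaginary (routing) channels.
#' @export
bare_resolvent <- function(conn, grid = frequency_grid(), phase_sign = -1) {
  phase_sign <- check_phase_sign(phase_sign)
  stopifnot(inherits(conn, "connectome"))
  C <- conn$weights
  rho <- spectral_radius(C)
  if (rho >= 1)
    ws_stop(sprintf("walk series does not converge: spectral radius %.4f >= 1",
                    rho), "walksum_error_singular")
  n <- nrow(C)
  H <- array(0i, dim = c(n, n, length(grid$f)))
  for (k in seq_along(grid$f))
    H[, , k] <- resolvent_matrix(C, grid$f[k], grid$T,
                                 phase_sign = phase_sign)
  new_resolvent_field(H, grid, phase_sign = phase_sign)
}

#' Dressed resolvent with a homogeneous local gain
#'
#' Dressing every node with the damped-harmonic-oscillator gain `l(f)` of
#' [local_gain()].  Two readings of the dressed operator are provided and
#' every result records which one produced it:
#' \describe{
#'   \item{`"literal"` (default)}{`H = (l(f) I - l(f) e^{i 2 pi f T} C)^{-1}`,
#'     the printed closed form; its zero-coupling limit is `I / l(f)`.}
#'   \item{`"gain"`}{`H = l(f) (I - l(f) e^{i 2 pi f T} C)^{-1}`, the walk
#'     series in which every node traversal contributes one factor of the
#'     gain (`sum_k l^{k+1} e^{i k 2 pi f T} C^k`); its zero-coupling limit
#'     is `l(f) I`.}
#' }
#'
#' @inheritParams bare_resolvent
#' @param omega0,zeta local gain parameters (see [local_gain()]).
#' @param reading `"literal"` or `"gain"` (see Details).
#' @param warn_series warn when `|l(f)| * rho(C) >= 1` somewhere on the grid
#'   (the series interpretation degrades; the inverse may still exist).
#' @return a `resolvent_field` with `dressing = c(omega0, zeta)`.
#' @export
dressed_resolvent <- function(conn, grid = frequency_grid(), omega0, zeta,
                              reading = c("literal", "gain"),
                              phase_sign = -1, warn_series = TRUE) {
  stopifnot(inherits(conn, "connectome"))
  reading <- match.arg(reading)
  phase_sign <- check_phase_sign(phase_sign)
  C <- conn$weights
  rho <- spectral_radius(C)
  l <- local_gain(grid$f, omega0, zeta)
  if (warn_series && reading == "gain" && any(Mod(l) * rho >= 1))
    warning("local gain magnitude times spectral radius reaches 1 on the grid; ",
            "walk-series interpretation is not guaranteed", call. = FALSE)
  n <- nrow(C)
  H <- array(0i, dim = c(n, n, length(grid$f)))
  for (k in seq_along(grid$f))
    H[, , k] <- resolvent_matrix(C, grid$f[k], grid$T, l = l[k],
                                 reading = reading, phase_sign = phase_sign)
  new_resolvent_field(H, grid, dressing = c(omega0 = omega0, zeta = zeta),
                      reading = reading, phase_sign = phase_sign)
}

#' Dressed resolvent with group-specific local gains
#'
#' The scalar gain becomes a diagonal matrix `L(f)` with node-wise entries
#' set by the node's degree group, under the same two readings as
#' [dressed_resolvent()]: `"literal"` inverts `L(f) - L(f) e^{i w T} C`,
#' `"gain"` computes `(I - L(f) e^{i w T} C)^{-1} L(f)`.
#'
#' @inheritParams dressed_resolvent
#' @param part a [partition_by_degree()] result.
#' @param params matrix or data.frame with one row per group (row order =
#'   group 0, 1, ...) and columns `omega0`, `zeta`.
#' @return a `resolvent_field`; `dressing` holds the per-group parameters.
#' @export
heterogeneous_dressed_resolvent <- function(conn, grid = frequency_grid(),
                                            part, params,
                                            reading = c("literal", "gain"),
                                            phase_sign = -1) {
  stopifnot(inherits(conn, "connectome"), inherits(part, "node_partition"))
  reading <- match.arg(reading)
  phase_sign <- check_phase_sign(phase_sign)
  params <- as.matrix(params)
  if (nrow(params) != part$n_groups)
    ws_stop("one (omega0, zeta) row required per group",
            "walksum_error_params")
  C <- conn$weights
  n <- nrow(C)
  gains <- vapply(seq_len(part$n_groups), function(g)
    local_gain(grid$f, params[g, "omega0"], params[g, "zeta"]),
    complex(length(grid$f)))                   # n_f x G
  dim(gains) <- c(length(grid$f), part$n_groups)
  H <- array(0i, dim = c(n, n, length(grid$f)))
  z <- exp(phase_sign * 2i * pi * grid$f * grid$T)
  for (k in seq_along(grid$f)) {
    lvec <- gains[k, part$group_of + 1L]
    if (reading == "literal") {
      A <- diag(lvec, n) - (lvec * z[k]) * C      # row-scale L (I - z C)
      H[, , k] <- solve(A, diag(1 + 0i, n))
    } else {
      A <- diag(n) - (lvec * z[k]) * C
      H[, , k] <- solve(A, diag(1 + 0i, n)) * rep(lvec, each = n)  # col scale: H L
    }
  }
  new_resolvent_field(H, grid, dressing = params, reading = reading,
                      phase_sign = phase_sign)
}

#' Truncated walk-sum oracle
#'
#' `sum_{k=0}^{K} e^{i k 2 pi f T} C^k` by iterated multiplication.  This is
#' a verification oracle for [bare_resolvent()] (geometric tail bound
#' `rho^{K+1} / (1 - rho)`), never the production path.  With gain
#' parameters it evaluates the `"gain"`-reading dressed series
#' `sum_k l^{k+1} (e^{i w T} C)^k`.
#'
#' @param conn a [connectome].
#' @param f single frequency, Hz.
#' @param T delay, s.
#' @param K truncation order (>= 0).
#' @param omega0,zeta optional local-gain parameters for the dressed series.
#' @param phase_sign phase-sign convention (see [bare_resolvent()]).
#' @return complex N x N matrix.
#' @export
walk_sum_truncated <- function(conn, f, T = 0.010, K, omega0 = NULL,
                               zeta = NULL, phase_sign = -1) {
  stopifnot(inherits(conn, "connectome"), K >= 0)
  phase_sign <- check_phase_sign(phase_sign)
  C <- conn$weights
  n <- nrow(C)
  z <- exp(phase_sign * 2i * pi * f * T)
  l <- if (is.null(omega0)) 1 + 0i else local_gain(f, omega0, zeta)
  term <- diag(l^(if (is.null(omega0)) 0 else 1) + 0i, n)  # k = 0 term
  S <- term
  M <- (l * z) * C
  if (K >= 1) for (k in seq_len(K)) {
    term <- term %*% M
    S <- S + term
  }
  S
}

#' Truncation order guaranteeing a walk-sum tail below a tolerance
#' @param rho spectral radius (< 1).
#' @param tol target max-norm tail bound (default 1e-10).
#' @param cap maximum order (default 10000).
#' @return integer K with `rho^(K+1) / (1 - rho) <= tol` (or `cap`).
#' @export
walk_sum_order <- function(rho, tol = 1e-10, cap = 10000L) {
  if (rho <= 0) return(0L)
  K <- ceiling(log(tol * (1 - rho)) / log(rho)) - 1
  as.integer(min(max(K, 0), cap))
}

#' Integrative (real) channel of a transfer or coherency field
#' @param field a `resolvent_field` or `coherency_field`.
#' @param f optional single frequency: return the N x N slice nearest it.
#' @return real array (N x N x n_f) or matrix slice.
#' @export
channel_I <- function(field, f = NULL) field_part(field, f, Re)

#' Routing (imaginary) channel of a transfer or coherency field
#' @inheritParams channel_I
#' @param abs return `|Im|` instead of signed Im (the empirical-side
#'   default elsewhere in the package).
#' @export
channel_Q <- function(field, f = NULL, abs = FALSE) {
  out <- field_part(field, f, Im)
  if (abs) abs(out) else out
}

#' @keywords internal
field_part <- function(field, f, fun) {
  stopifnot(is.array(field$H))
  if (is.null(f)) return(fun(field$H))
  k <- which.min(abs(field$f - f))
  fun(field$H[, , k])
}

#' @keywords internal
field_n_nodes <- function(field) dim(field$H)[1]

#' @export
print.resolvent_field <- function(x, ...) {
  cat(sprintf("<resolvent_field> %d nodes, %d frequencies (%.1f-%.1f Hz), T = %g ms\n",
              dim(x$H)[1], length(x$f), min(x$f), max(x$f), 1000 * x$T))
  if (is.null(x$dressing)) cat("  bare (no local gain)\n")
  else {
    cat("  dressed, reading =", x$reading, "\n")
    if (is.matrix(x$dressing)) {
      for (g in seq_len(nrow(x$dressing)))
        cat(sprintf("   group %d: omega0 = %g Hz, zeta = %g\n", g - 1,
                    x$dressing[g, "omega0"], x$dressing[g, "zeta"]))
    } else
      cat(sprintf("   omega0 = %g Hz, zeta = %g\n",
                  x$dressing[["omega0"]], x$dressing[["zeta"]]))
  }
  invisible(x)
}

#' Serialise a resolvent or coherency field to a directory
#'
#' Real and imaginary parts are written per frequency block into two
#' delimited files plus a JSON sidecar with the grid and conventions.
#' @param field a `resolvent_field` or `coherency_field`.
#' @param dir output directory.
#' @export
write_field <- function(field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(field$H)[1]; nf <- dim(field$H)[3]
  # layout: frequencies stacked as row-blocks of size n
  re <- do.call(rbind, lapply(seq_len(nf), function(k) Re(field$H[, , k])))
  im <- do.call(rbind, lapply(seq_len(nf), function(k) Im(field$H[, , k])))
  write_matrix_file(re, file.path(dir, "real.tsv"))
  write_matrix_file(im, file.path(dir, "imag.tsv"))
  jsonlite::write_json(list(f = field$f, T = field$T,
                            class = class(field)[1],
                            reading = field$reading,
                            dressing = field$dressing),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a field written by [write_field()]
#' @param dir directory produced by [write_field()].
#' @export
read_field <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  re <- read_matrix_file(file.path(dir, "real.tsv"))
  im <- read_matrix_file(file.path(dir, "imag.tsv"))
  nf <- length(meta$f); n <- ncol(re)
  H <- array(0i, dim = c(n, n, nf))
  for (k in seq_len(nf))
    H[, , k] <- re[(k - 1) * n + seq_len(n), ] +
      1i * im[(k - 1) * n + seq_len(n), ]
  out <- list(H = H, f = meta$f, T = meta$T,
              dressing = meta$dressing, reading = meta$reading)
  class(out) <- meta$class
  out
}
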