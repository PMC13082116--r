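#' Graph Laplacian of a connectome
#'
#' `"normalized"` (default): `I - D^{-1/2} C D^{-1/2}` with `D` the
#' weighted-degree diagonal; eigenvalues lie in `[0, 2]`.
#' `"combinatorial"`: `D - C`.  The full spectrum (ascending) and
#' orthonormal eigenvectors are returned.
#'
#' @param conn a [connectome].
#' @param kind `"normalized"` or `"combinatorial"`.
#' @return object of class `laplacian_eigen`: `L`, `values` (ascending),
#'   `vectors` (columns matching `values`), `kind`.
#' @export
laplacian <- function(conn, kind = c("normalized", "combinatorial")) {
  stopifnot(inherits(conn, "connectome"))
  kind <- match.arg(kind)
  C <- conn$weights
  deg <- rowSums(C)
  if (kind == "normalized" && any(deg == 0))
    ws_stop(sprintf("isolated node(s) %s have zero degree; normalized Laplacian undefined",
                    paste(which(deg == 0), collapse = ",")),
            "walksum_error_isolated")
  L <- if (kind == "normalized") {
    Dm <- 1 / sqrt(deg)
    diag(nrow(C)) - (Dm %o% Dm) * C
  } else diag(deg) - C
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  structure(list(L = L, values = e$values[ord],
                 vectors = e$vectors[, ord, drop = FALSE], kind = kind),
            class = "laplacian_eigen")
}

#' Project a field onto Laplacian eigenmodes
#'
#' Default: per-mode quadratic forms `p_m(f) = v_m' I(f) v_m` and
#' `q_m(f) = v_m' Q(f) v_m`.  The `"energy"` method instead returns the
#' expansion-coefficient energy `sum_{m'} (v_m' I(f) v_{m'})^2` per mode
#' (an alternative reading of per-mode content; the quadratic form is the
#' default).
#'
#' @param field a `resolvent_field` (or coherency field).
#' @param eig a [laplacian()] result with matching N.
#' @param method `"quadratic"` (default) or `"energy"`.
#' @return list with `p` and `q` (n_modes x n_f matrices), `values`
#'   (eigenvalues), `f`, `method`.
#' @export
project_modes <- function(field, eig, method = c("quadratic", "energy")) {
  method <- match.arg(method)
  V <- eig$vectors
  n <- field_n_nodes(field)
  if (nrow(V) != n) ws_stop("eigenbasis and field dimensions differ",
                            "walksum_error_dimension")
  nf <- length(field$f)
  p <- q <- matrix(NA_real_, n, nf)
  for (k in seq_len(nf)) {
    M <- field$H[, , k]
    if (method == "quadratic") {
      p[, k] <- colSums(V * (Re(M) %*% V))
      q[, k] <- colSums(V * (Im(M) %*% V))
    } else {
      CI <- t(V) %*% Re(M) %*% V
      CQ <- t(V) %*% Im(M) %*% V
      p[, k] <- rowSums(CI^2)
      q[, k] <- rowSums(CQ^2)
    }
  }
  list(p = p, q = q, values = eig$values, f = field$f, method = method)
}

#' Peak frequency of each eigenmode
#'
#' Per mode, the grid frequency maximising the mode's relative share
#' `|p_m(f)| / sum_m' |p_m'(f)|` (raw projections of I decay with frequency
#' for every mode, which would pin all peaks to the grid minimum; the
#' relative share isolates where a mode is most dominant).  Ties resolve to
#' the lowest frequency.
#'
#' @param proj a [project_modes()] result.
#' @param channel `"p"` (I-channel, default) or `"q"`.
#' @return numeric vector of peak frequencies (Hz), one per mode.
#' @export
peak_frequency_per_mode <- function(proj, channel = c("p", "q")) {
  channel <- match.arg(channel)
  A <- abs(proj[[channel]])
  share <- sweep(A, 2, colSums(A), "/")
  proj$f[apply(share, 1, which.max)]
}

#' Eigenvalue-peak-frequency rank correlation
#'
#' Spearman correlation between Laplacian eigenvalue and mode peak
#' frequency across modes, excluding the constant (lambda ~ 0) mode.
#'
#' @param eig a [laplacian()] result.
#' @param peak_f output of [peak_frequency_per_mode()].
#' @param zero_tol eigenvalues below this count as the constant mode.
#' @return Spearman rho.
#' @export
eigenmodel_correlation <- function(eig, peak_f, zero_tol = 1e-10) {
  keep <- eig$values > zero_tol
  if (sum(keep) < 3) ws_stop("fewer than 3 non-constant modes",
                             "walksum_error_dimension")
  spearman(eig$values[keep], peak_f[keep])
}

#' Cumulative eigenmode contribution to channel variance
#'
#' Fraction of the squared Frobenius norm of the off-diagonal I-channel at
#' frequency `f` captured by its expansion restricted to the `k`
#' lowest-eigenvalue modes (coefficients `c_mm' = v_m' A v_m'` with
#' `m, m' <= k`).
#'
#' @param field a `resolvent_field`.
#' @param eig a [laplacian()] result.
#' @param k number of modes (0..N), ascending eigenvalue order.
#' @param f single frequency (nearest grid point).
#' @return fraction in `[0, 1]`.
#' @export
cumulative_mode_variance <- function(field, eig, k, f) {
  n <- field_n_nodes(field)
  stopifnot(k >= 0, k <= n)
  if (k == 0) return(0)
  ki <- which.min(abs(field$f - f))
  A <- Re(field$H[, , ki]); diag(A) <- 0
  Cm <- t(eig$vectors) %*% A %*% eig$vectors
  sum(Cm[seq_len(k), seq_len(k)]^2) / sum(Cm^2)
}

#' Hub participation in the dominant communication mode
#'
#' The dominant mode is the eigenvector of the weight matrix with the
#' largest eigenvalue magnitude (identical to the resolvent's dominant mode
#' for symmetric weights); a node's participation is the absolute value of
#' its component.  Returns the Spearman correlation between weighted degree
#' and participation with a p-value (seeded exact-style permutation for
#' N <= 30, asymptotic t otherwise).  On real consensus connectomes this
#' correlation is strongly negative (hubs drive the low-frequency global
#' mode); simple hub toys such as a star graph give the opposite sign.
#'
#' @param conn a [connectome].
#' @param binary correlate against binary degree instead of weighted.
#' @param n_perm permutations for the small-N p-value.
#' @param seed permutation seed.
#' @return list with `rho`, `p`, `participation`, `dominant_eigenvalue`.
#' @export
hub_mode_anticorrelation <- function(conn, binary = FALSE, n_perm = 10000,
                                     seed = 42) {
  stopifnot(inherits(conn, "connectome"))
  n <- nrow(conn$weights)
  if (n < 5) ws_stop("need at least 5 nodes", "walksum_error_dimension")
  if (conn$directed)
    ws_stop("dominant mode undefined for directed weights; symmetrise first",
            "walksum_error_asymmetric")
  e <- eigen(conn$weights, symmetric = TRUE)
  i <- which.max(abs(e$values))
  part <- abs(e$vectors[, i])
  deg <- weighted_degree(conn, binary = binary)
  rho <- spearman(deg, part)
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_,
                              participation = part,
                              dominant_eigenvalue = e$values[i]))
  if (n <= 30) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    rp <- replicate(n_perm, spearman(deg, sample(part)))
    p <- (sum(abs(rp) >= abs(rho)) + 1) / (n_perm + 1)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, participation = part,
       dominant_eigenvalue = e$values[i])
}

#' Full eigenmodel analysis of a resolvent field
#'
#' Convenience wrapper: Laplacian spectrum, mode projections, per-mode peak
#' frequencies, the eigenvalue-frequency correlation, cumulative mode
#' variance for the top `k_top` modes across the grid, and the hub-mode
#' correlation.
#'
#' @param conn a [connectome].
#' @param field a `resolvent_field` on `conn` (computed if `NULL`).
#' @param kind Laplacian kind.
#' @param k_top number of modes for the cumulative-variance curve.
#' @param method projection method (see [project_modes()]).
#' @return object of class `eigenmodel` with fields `eigen`, `projections`,
#'   `peak_f`, `rho_lambda_f`, `cum_var` (per grid frequency), `hub_mode`.
#' @export
eigenmodel <- function(conn, field = NULL, kind = "normalized", k_top = 5,
                       method = "quadratic") {
  if (is.null(field)) field <- bare_resolvent(conn)
  eig <- laplacian(conn, kind)
  proj <- project_modes(field, eig, method)
  peak_f <- peak_frequency_per_mode(proj)
  rho <- eigenmodel_correlation(eig, peak_f)
  cv <- vapply(field$f, function(fr)
    cumulative_mode_variance(field, eig, k_top, fr), numeric(1))
  hub <- hub_mode_anticorrelation(conn)
  structure(list(eigen = eig, projections = proj, peak_f = peak_f,
                 rho_lambda_f = rho, cum_var = cv, k_top = k_top,
                 f = field$f, hub_mode = hub[c("rho", "p")]),
            class = "eigenmodel")
}

#' @export
print.eigenmodel <- function(x, ...) {
  cat("<eigenmodel>\n")
  cat(sprintf("  %d modes (%s Laplacian), eigenvalues %.3f-%.3f\n",
              length(x$eigen$values), x$eigen$kind,
              min(x$eigen$values), max(x$eigen$values)))
  cat(sprintf("  eigenvalue-peak-frequency Spearman rho = %.3f\n",
              x$rho_lambda_f))
  cat(sprintf("  top-%d modes explain %.1f%% of I variance at %g Hz, %.1f%% at %g Hz\n",
              x$k_top, 100 * x$cum_var[1], x$f[1],
              100 * x$cum_var[length(x$f)], x$f[length(x$f)]))
  cat(sprintf("  hub-mode Spearman rho = %.3f (p = %.3g)\n",
              x$hub_mode$rho, x$hub_mode$p))
  invisible(x)
}
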