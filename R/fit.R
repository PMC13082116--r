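#' @keywords internal
profile_vector <- function(prof, variant = "both", bands = NULL) {
  sel <- if (is.null(bands)) rep(TRUE, length(prof$f))
  else Reduce(`|`, lapply(seq_len(nrow(bands)), function(b)
    prof$f >= bands$f_lo[b] & prof$f <= bands$f_hi[b]))
  vI <- as.vector(prof$mean_I[, sel, drop = FALSE])
  if (variant == "I_only") return(vI)
  c(vI, as.vector(prof$mean_absQ[, sel, drop = FALSE]))
}

#' Fit objective: model-data profile rank agreement
#'
#' Spearman correlation between the model's and the data's concatenated
#' distance-binned I and `|Q|` profiles across bins x grid frequencies.
#' The objective variant is always recorded with any reported value
#' (`"both"` = I and `|Q|` concatenated, `"I_only"` = I profile alone; a
#' band restriction drops grid frequencies outside the bands).
#'
#' @param model_profile,empirical_profile [distance_profile()] objects with
#'   matching binning and grid.
#' @param variant `"both"` (default) or `"I_only"`.
#' @param bands optional [band_scheme()] restriction.
#' @return Spearman rho.
#' @export
fit_objective <- function(model_profile, empirical_profile,
                          variant = c("both", "I_only"), bands = NULL) {
  variant <- match.arg(variant)
  if (!isTRUE(all.equal(model_profile$f, empirical_profile$f)) ||
      length(model_profile$mid) != length(empirical_profile$mid))
    ws_stop("model and empirical profiles have incompatible binning or grid",
            "walksum_error_grid")
  a <- profile_vector(model_profile, variant, bands)
  b <- profile_vector(empirical_profile, variant, bands)
  ok <- is.finite(a) & is.finite(b)
  spearman(a[ok], b[ok])
}

#' Precompute dressed-model profiles over the search grid
#'
#' One distance-binned profile per (omega0, zeta) cell; reusable across
#' [grid_search()] calls on the same connectome.
#'
#' @inheritParams grid_search
#' @return list of class `model_profile_grid`.
#' @export
dressing_profile_grid <- function(conn, grid = frequency_grid(),
                                  omega0_grid = seq(5, 16, by = 0.5),
                                  zeta_grid = seq(0.05, 1.0, by = 0.05),
                                  reading = "literal", n_bins = 20) {
  profs <- vector("list", length(omega0_grid) * length(zeta_grid))
  k <- 0L
  for (i in seq_along(omega0_grid)) for (j in seq_along(zeta_grid)) {
    k <- k + 1L
    Hd <- dressed_resolvent(conn, grid, omega0_grid[i], zeta_grid[j],
                            reading = reading, warn_series = FALSE)
    profs[[k]] <- distance_profile(Hd, conn$distances, n_bins)
  }
  structure(list(profiles = profs, omega0_grid = omega0_grid,
                 zeta_grid = zeta_grid, reading = reading, n_bins = n_bins,
                 f = grid$f),
            class = "model_profile_grid")
}

#' Exhaustive grid search for homogeneous dressing parameters
#'
#' Evaluates [fit_objective()] at every cell of the declared search grid
#' (natural frequency 5-16 Hz in 0.5 Hz steps, damping 0.05-1.0 in 0.05
#' steps: 460 cells by default) and returns the argmax; ties resolve to the
#' lowest omega0, then the lowest zeta.  A flat objective therefore returns
#' the grid origin and is flagged low-confidence.
#'
#' @param conn a [connectome].
#' @param empirical a [distance_profile()] of the empirical coherency (or
#'   of any target field) with the same binning as the model profiles.
#' @param grid a [frequency_grid()].
#' @param omega0_grid,zeta_grid search grids.
#' @param reading dressed-operator reading (see [dressed_resolvent()]).
#' @param variant objective variant (see [fit_objective()]).
#' @param bands optional band restriction for the objective.
#' @param n_bins distance bins.
#' @param model_profiles optional precomputed [dressing_profile_grid()].
#' @return object of class `dressing_fit` with the objective `surface`
#'   (omega0 x zeta), best parameters, and provenance.
#' @export
grid_search <- function(conn, empirical, grid = frequency_grid(),
                        omega0_grid = seq(5, 16, by = 0.5),
                        zeta_grid = seq(0.05, 1.0, by = 0.05),
                        reading = "literal",
                        variant = "both", bands = NULL, n_bins = 20,
                        model_profiles = NULL) {
  stopifnot(inherits(empirical, "distance_profile"))
  if (is.null(model_profiles))
    model_profiles <- dressing_profile_grid(conn, grid, omega0_grid,
                                            zeta_grid, reading, n_bins)
  no <- length(model_profiles$omega0_grid)
  nz <- length(model_profiles$zeta_grid)
  surface <- matrix(NA_real_, no, nz,
                    dimnames = list(model_profiles$omega0_grid,
                                    model_profiles$zeta_grid))
  k <- 0L
  for (i in seq_len(no)) for (j in seq_len(nz)) {
    k <- k + 1L
    surface[i, j] <- fit_objective(model_profiles$profiles[[k]], empirical,
                                   variant, bands)
  }
  if (all(is.na(surface))) {
    # degenerate target (constant profile): objective carries no signal
    warning("fit objective undefined everywhere (degenerate target); ",
            "returning the tie-rule grid origin", call. = FALSE)
    best <- c(1L, 1L)
    flat <- TRUE
  } else {
    best <- which(surface == max(surface, na.rm = TRUE), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    flat <- diff(range(surface, na.rm = TRUE)) < 1e-12
  }
  structure(list(surface = surface,
                 omega0 = model_profiles$omega0_grid[best[1]],
                 zeta = model_profiles$zeta_grid[best[2]],
                 rho = surface[best[1], best[2]],
                 flat_objective = flat,
                 reading = model_profiles$reading, variant = variant,
                 n_bins = model_profiles$n_bins),
            class = "dressing_fit")
}

#' @export
coef.dressing_fit <- function(object, ...) {
  if (!is.null(object$group_params)) return(object$group_params)
  c(omega0 = object$omega0, zeta = object$zeta)
}

#' @export
print.dressing_fit <- function(x, ...) {
  cat("<dressing_fit>")
  if (!is.null(x$group_params)) {
    cat(" (heterogeneous)\n")
    print(x$group_params)
  } else cat(sprintf(" omega0 = %g Hz, zeta = %g\n", x$omega0, x$zeta))
  cat(sprintf("  objective rho = %.4f (variant %s, reading %s)\n",
              x$rho, x$variant, x$reading))
  if (isTRUE(x$flat_objective))
    cat("  WARNING: flat objective surface; parameters are the tie-rule default\n")
  invisible(x)
}

#' @export
summary.dressing_fit <- function(object, ...) {
  print(object)
  s <- object$surface
  if (!is.null(s)) {
    cat(sprintf("  surface: %d cells, rho range [%.4f, %.4f]\n",
                length(s), min(s, na.rm = TRUE), max(s, na.rm = TRUE)))
  }
  invisible(object)
}

#' Leave-one-dataset-out cross-validation of the dressing fit
#'
#' For each named dataset, parameters are fitted on the remaining
#' datasets (profiles averaged element-wise) and the test objective is
#' evaluated on the held-out profile.  With `heterogeneous = TRUE` the
#' three-group fit also runs and `delta` reports its test improvement over
#' the homogeneous fit.
#'
#' @param conn a [connectome].
#' @param dataset_profiles named list (>= 2) of [distance_profile()]s.
#' @param heterogeneous also run the per-group fit?
#' @param part [partition_by_degree()] result (required when
#'   `heterogeneous`).
#' @param iterations coordinate-descent cycles for the heterogeneous fit.
#' @param ... passed to [grid_search()].
#' @return list of class `loo_cv`, one entry per direction with `train`
#'   (fit), `test_rho`, and optionally `het`, `het_test_rho`, `delta`.
#' @export
loo_crossval <- function(conn, dataset_profiles, heterogeneous = FALSE,
                         part = NULL, iterations = 3, ...) {
  if (length(dataset_profiles) < 2)
    ws_stop("need at least 2 named datasets", "walksum_error_params")
  if (is.null(names(dataset_profiles)) ||
      any(!nzchar(names(dataset_profiles))))
    ws_stop("dataset profiles must be named", "walksum_error_params")
  dots <- list(...)
  out <- list()
  for (held in names(dataset_profiles)) {
    train_profs <- dataset_profiles[setdiff(names(dataset_profiles), held)]
    train <- average_profiles(train_profs)
    fit <- grid_search(conn, train, ...)
    grid <- if (!is.null(dots$grid)) dots$grid else frequency_grid()
    Ht <- dressed_resolvent(conn, grid, fit$omega0, fit$zeta,
                            reading = fit$reading, warn_series = FALSE)
    mp <- distance_profile(Ht, conn$distances, fit$n_bins)
    test_rho <- fit_objective(mp, dataset_profiles[[held]], fit$variant,
                              dots$bands)
    entry <- list(held_out = held, train = fit, test_rho = test_rho)
    if (heterogeneous) {
      if (is.null(part)) ws_stop("heterogeneous fit needs a partition",
                                 "walksum_error_params")
      het <- heterogeneous_fit(conn, part, train, iterations = iterations,
                               init = fit, ...)
      Hh <- heterogeneous_dressed_resolvent(conn, grid, part,
                                            het$group_params,
                                            reading = het$reading)
      hp <- distance_profile(Hh, conn$distances, fit$n_bins)
      entry$het <- het
      entry$het_test_rho <- fit_objective(hp, dataset_profiles[[held]],
                                          fit$variant, dots$bands)
      entry$delta <- entry$het_test_rho - test_rho
    }
    out[[paste0("rest->", held)]] <- entry
  }
  structure(out, class = "loo_cv")
}

#' @keywords internal
average_profiles <- function(profs) {
  out <- profs[[1]]
  if (length(profs) > 1) {
    for (fld in c("mean_I", "mean_Q", "mean_absQ")) {
      acc <- Reduce(`+`, lapply(profs, `[[`, fld))
      out[[fld]] <- acc / length(profs)
    }
  }
  out
}

#' Heterogeneous (three-group) dressing fit by coordinate descent
#'
#' Starting from the homogeneous optimum, cycles over degree groups in
#' descending mean-degree order (hubs first) and exhaustively optimises one
#' group's (omega0, zeta) on the grid while the others stay fixed; by
#' construction the objective never decreases across steps, and the
#' homogeneous solution is in the feasible set, so the in-sample objective
#' is at least the homogeneous one.
#'
#' @inheritParams grid_search
#' @param part a [partition_by_degree()] result.
#' @param iterations full cycles over the groups (default 3; 0 returns the
#'   initialisation).
#' @param init optional homogeneous `dressing_fit` to initialise from
#'   (computed if missing).
#' @return a `dressing_fit` with `group_params` (matrix, row g =
#'   group g - 1) and the objective `trace` across steps.
#' @export
heterogeneous_fit <- function(conn, part, empirical,
                              grid = frequency_grid(),
                              omega0_grid = seq(5, 16, by = 0.5),
                              zeta_grid = seq(0.05, 1.0, by = 0.05),
                              reading = "literal", variant = "both",
                              bands = NULL, n_bins = 20, iterations = 3,
                              init = NULL, model_profiles = NULL) {
  stopifnot(inherits(part, "node_partition"))
  if (is.null(init))
    init <- grid_search(conn, empirical, grid, omega0_grid, zeta_grid,
                        reading, variant, bands, n_bins,
                        model_profiles = model_profiles)
  G <- part$n_groups
  params <- matrix(rep(c(init$omega0, init$zeta), each = G), nrow = G,
                   dimnames = list(NULL, c("omega0", "zeta")))
  eval_params <- function(pm) {
    H <- heterogeneous_dressed_resolvent(conn, grid, part, pm,
                                         reading = reading)
    fit_objective(distance_profile(H, conn$distances, n_bins), empirical,
                  variant, bands)
  }
  cur <- eval_params(params)
  trace <- cur
  mean_deg <- vapply(seq_len(G) - 1L, function(g)
    mean(part$degree[part$group_of == g]), numeric(1))
  order_g <- order(mean_deg, decreasing = TRUE)
  if (iterations > 0) for (it in seq_len(iterations)) {
    for (g in order_g) {
      best <- list(rho = cur, par = params[g, ])
      for (o in omega0_grid) for (z in zeta_grid) {
        trial <- params
        trial[g, ] <- c(o, z)
        r <- eval_params(trial)
        if (isTRUE(r > best$rho)) best <- list(rho = r, par = c(o, z))
      }
      params[g, ] <- best$par
      cur <- best$rho
      trace <- c(trace, cur)
    }
  }
  structure(list(group_params = params, rho = cur, trace = trace,
                 homogeneous = init, surface = NULL,
                 flat_objective = FALSE,
                 reading = reading, variant = variant, n_bins = n_bins),
            class = "dressing_fit")
}
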