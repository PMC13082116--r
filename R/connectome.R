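#' @keywords internal
ws_stop <- function(msg, class) {
  stop(structure(class = c(class, "walksum_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Construct a connectome object
#'
#' Bundles a weighted structural connectivity matrix with a matching
#' fibre-tract distance matrix (mm).  Weights are normalised on construction
#' so that their spectral radius is strictly below one, which guarantees
#' convergence of the walk-sum series behind [bare_resolvent()].
#'
#' @param weights N x N nonnegative matrix of connection weights
#'   (arbitrary tractography units; normalised here).
#' @param distances N x N nonnegative matrix of fibre-tract distances in mm.
#' @param labels optional character vector of node identifiers.
#' @param coords optional N x 3 matrix of node positions (mm).
#' @param directed logical; consensus tractography is symmetric, so the
#'   default is `FALSE`.  An asymmetric weight matrix with
#'   `directed = FALSE` is an error, never silently symmetrised.
#' @param safety spectral-radius normalisation safety factor (default 1.01).
#' @return An object of class `connectome`: a list with elements `weights`,
#'   `distances`, `labels`, `coords`, `normalisation_factor`, `directed`.
#' @export
connectome <- function(weights, distances, labels = NULL, coords = NULL,
                       directed = FALSE, safety = 1.01) {
  weights <- as.matrix(weights)
  distances <- as.matrix(distances)
  dimnames(weights) <- NULL
  dimnames(distances) <- NULL
  if (!all(is.finite(weights)) || !all(is.finite(distances)))
    ws_stop("non-finite values in weights or distances",
            "walksum_error_nonfinite")
  if (nrow(weights) != ncol(weights) || nrow(distances) != ncol(distances) ||
      nrow(weights) != nrow(distances))
    ws_stop(sprintf("dimension mismatch: weights %dx%d vs distances %dx%d",
                    nrow(weights), ncol(weights),
                    nrow(distances), ncol(distances)),
            "walksum_error_dimension")
  n <- nrow(weights)
  if (n < 2) ws_stop("a connectome needs at least 2 nodes",
                     "walksum_error_dimension")
  if (any(weights < 0) || any(distances < 0))
    ws_stop("negative entries in weights or distances",
            "walksum_error_negative")
  if (!isTRUE(all.equal(distances, t(distances), tolerance = 1e-12,
                        check.attributes = FALSE)))
    ws_stop("distance matrix must be symmetric", "walksum_error_asymmetric")
  if (!directed &&
      !isTRUE(all.equal(weights, t(weights), tolerance = 1e-12,
                        check.attributes = FALSE)))
    ws_stop("asymmetric weights with directed = FALSE; pass directed = TRUE",
            "walksum_error_asymmetric")
  diag(weights) <- 0
  diag(distances) <- 0
  nz <- normalize_spectral_radius(weights, safety = safety)
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n, ncol(coords) == 3)
  }
  structure(list(weights = nz$matrix, distances = distances,
                 labels = as.character(labels), coords = coords,
                 normalisation_factor = nz$factor, directed = directed),
            class = "connectome")
}

#' Normalise a weight matrix to spectral radius below one
#'
#' When the spectral radius of `W` is already below one the matrix is
#' returned unchanged with factor 1; otherwise it is divided by
#' `safety` times the maximum eigenvalue magnitude.
#'
#' @param W square finite numeric matrix.
#' @param safety multiplicative safety margin (default 1.01).
#' @return list with `matrix` (normalised) and `factor` (the divisor used).
#' @export
normalize_spectral_radius <- function(W, safety = 1.01) {
  W <- as.matrix(W)
  if (!all(is.finite(W))) ws_stop("non-finite weight matrix",
                                  "walksum_error_nonfinite")
  if (nrow(W) != ncol(W)) ws_stop("matrix not square",
                                  "walksum_error_dimension")
  rho <- spectral_radius(W)
  if (rho < 1) return(list(matrix = W, factor = 1))
  f <- safety * rho
  list(matrix = W / f, factor = f)
}

#' @keywords internal
spectral_radius <- function(W) {
  if (all(W == 0)) return(0)
  max(Mod(eigen(W, only.values = TRUE)$values))
}

#' Weighted node degree
#'
#' Row sums of the (normalised) weight matrix.  With `binary = TRUE` the
#' count of nonzero connections is returned instead.
#'
#' @param conn a [connectome] object.
#' @param binary count edges instead of summing weights?
#' @return numeric vector of length N, named by node label.
#' @export
weighted_degree <- function(conn, binary = FALSE) {
  stopifnot(inherits(conn, "connectome"))
  d <- if (binary) rowSums(conn$weights > 0) else rowSums(conn$weights)
  names(d) <- conn$labels
  d
}

#' Partition nodes into degree groups
#'
#' Splits nodes into `n_groups` equal-count groups by weighted degree
#' (tertiles by default): group 0 = hubs (highest degree), the last group =
#' peripheral nodes.  Ties are broken by node index, so the assignment is a
#' deterministic function of the degree sequence.
#'
#' @param conn a [connectome] object.
#' @param n_groups number of groups (default 3: hub / mid / peripheral).
#' @param binary use binary degree instead of weighted degree.
#' @return list of class `node_partition` with `group_of` (integer in
#'   `0:(n_groups-1)`, 0 = hub), `thresholds` (degree cut values) and
#'   `degree`.
#' @export
partition_by_degree <- function(conn, n_groups = 3, binary = FALSE) {
  deg <- weighted_degree(conn, binary = binary)
  n <- length(deg)
  if (n_groups > n) ws_stop("more groups than nodes",
                            "walksum_error_dimension")
  ord <- order(deg, seq_len(n))            # ascending degree, index tie-break
  g_asc <- ceiling(seq_len(n) * n_groups / n)
  group_of <- integer(n)
  group_of[ord] <- n_groups - g_asc        # 0 = top-degree group (hubs)
  thr <- vapply(seq_len(n_groups - 1), function(k)
    max(deg[group_of == k]), numeric(1))
  structure(list(group_of = group_of, thresholds = thr, degree = deg,
                 n_groups = n_groups),
            class = "node_partition")
}

#' Read a connectome from delimited matrix files
#'
#' Weights and distances are read from delimited text (comma or tab,
#' auto-detected; optional header row/column ignored when non-numeric).
#'
#' @param weights_path,distances_path paths to square numeric matrix files.
#' @inheritParams connectome
#' @return a validated, normalised [connectome].
#' @export
load_connectome <- function(weights_path, distances_path, directed = FALSE,
                            safety = 1.01) {
  W <- read_matrix_file(weights_path)
  D <- read_matrix_file(distances_path)
  connectome(W, D, directed = directed, safety = safety)
}

#' @keywords internal
read_matrix_file <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          stringsAsFactors = FALSE)
  # drop a header row / label column if present (non-numeric)
  if (all(is.na(suppressWarnings(as.numeric(unlist(df[1, ]))))))
    df <- df[-1, , drop = FALSE]
  num1 <- suppressWarnings(as.numeric(df[[1]]))
  if (all(is.na(num1))) df <- df[, -1, drop = FALSE]
  m <- as.matrix(as.data.frame(lapply(df, function(x)
    suppressWarnings(as.numeric(x)))))
  dimnames(m) <- NULL
  m
}

#' Write a connectome to a directory of delimited files
#'
#' Writes `weights.tsv`, `distances.tsv`, `labels.txt`, optional
#' `coords.tsv`, and a `meta.json` sidecar holding the normalisation factor
#' and directedness.  Matrices are written at full precision so that
#' load -> save -> load round-trips bit-identically.
#'
#' @param conn a [connectome].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_connectome <- function(conn, dir) {
  stopifnot(inherits(conn, "connectome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_file(conn$weights, file.path(dir, "weights.tsv"))
  write_matrix_file(conn$distances, file.path(dir, "distances.tsv"))
  writeLines(conn$labels, file.path(dir, "labels.txt"))
  if (!is.null(conn$coords))
    write_matrix_file(conn$coords, file.path(dir, "coords.tsv"))
  jsonlite::write_json(
    list(normalisation_factor = conn$normalisation_factor,
         directed = conn$directed, n_nodes = nrow(conn$weights)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a connectome written by [write_connectome()]
#' @param dir directory produced by [write_connectome()].
#' @return a [connectome].
#' @export
read_connectome <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  W <- read_matrix_file(file.path(dir, "weights.tsv"))
  D <- read_matrix_file(file.path(dir, "distances.tsv"))
  labels <- readLines(file.path(dir, "labels.txt"))
  coords <- NULL
  cp <- file.path(dir, "coords.tsv")
  if (file.exists(cp)) coords <- read_matrix_file(cp)
  conn <- connectome(W, D, labels = labels, coords = coords,
                     directed = isTRUE(meta$directed))
  # weights on disk are already normalised; keep the recorded factor
  conn$normalisation_factor <- meta$normalisation_factor
  conn
}

#' @keywords internal
write_matrix_file <- function(m, path) {
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d nodes, %s", nrow(x$weights),
              if (x$directed) "directed" else "undirected"), "\n")
  cat(sprintf("  spectral radius %.4f (normalisation factor %.4g)\n",
              spectral_radius(x$weights), x$normalisation_factor))
  cat(sprintf("  distances %.1f-%.1f mm\n",
              min(x$distances[upper.tri(x$distances)]),
              max(x$distances)))
  invisible(x)
}

#' @export
print.node_partition <- function(x, ...) {
  cat(sprintf("<node_partition> %d groups (0 = hub): sizes %s\n",
              x$n_groups,
              paste(tabulate(x$group_of + 1L, x$n_groups), collapse = "/")))
  invisible(x)
}
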