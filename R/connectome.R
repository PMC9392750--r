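# ROI matrices are plain base matrices carrying ROI ids in dimnames; all
# joins downstream are by id, never by position alone.

roi_ids <- function(m) {
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  ids
}

check_connectivity <- function(z, tol = 1e-9) {
  if (!is.matrix(z) || nrow(z) != ncol(z))
    stop("connectivity must be a square ROI x ROI matrix", call. = FALSE)
  if (any(!is.finite(z)))
    stop("connectivity matrix contains non-finite entries", call. = FALSE)
  if (max(abs(z - t(z))) > tol)
    stop("connectivity matrix is not symmetric (tolerance ", tol, ")",
         call. = FALSE)
  invisible(z)
}

#' Fisher-z functional connectivity from ROI timeseries
#'
#' Cross-correlates ROI timeseries columns (Pearson) and applies the Fisher
#' z (atanh) transform. Correlations are clipped at |r| = 0.999999 before
#' the transform so that duplicated timeseries yield a large but finite
#' connectivity value. The diagonal is stored as 0 by convention.
#'
#' @param ts numeric matrix, rows = timepoints, columns = ROIs; column names
#'   are used as ROI ids.
#' @return symmetric ROI x ROI matrix of Fisher-z connectivity with zero
#'   diagonal.
#' @export
compute_connectivity <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 timepoints", call. = FALSE)
  if (ncol(ts) < 2) stop("need at least 2 ROIs", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance timeseries for ROI(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(ts)
  r <- pmin(pmax(r, -0.999999), 0.999999)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2  # kill rounding asymmetry
  dimnames(z) <- list(colnames(ts), colnames(ts))
  z
}

#' Average a set of subject-level connectivity matrices
#'
#' @param mats list of square connectivity matrices sharing ROI ids.
#' @return the element-wise mean matrix.
#' @export
average_connectomes <- function(mats) {
  if (!length(mats)) stop("empty list of connectomes", call. = FALSE)
  ids <- roi_ids(mats[[1]])
  for (m in mats) {
    check_connectivity(m)
    if (!identical(roi_ids(m), ids))
      stop("connectomes have mismatched ROI ids", call. = FALSE)
  }
  Reduce(`+`, mats) / length(mats)
}

#' Density-threshold a connectivity matrix
#'
#' Retains the strongest `density` fraction of possible undirected edges,
#' ranking upper-triangle entries by signed Fisher-z value. Ties at the
#' cutoff are broken deterministically by lexicographic (row, column) index.
#' Retained edges keep their original weight; all others are set to 0.
#'
#' @param z symmetric connectivity matrix.
#' @param density fraction of edges to retain, in (0, 1].
#' @return thresholded symmetric matrix with attributes `density` (the
#'   requested fraction) and `n_edges` (retained edge count).
#' @export
threshold_density <- function(z, density = 0.3) {
  check_connectivity(z)
  if (density <= 0 || density > 1)
    stop("density must be in (0, 1]", call. = FALSE)
  n <- nrow(z)
  ut <- which(upper.tri(z))
  k <- as.integer(round(density * length(ut)))
  if (k < 1) stop("density of ", density, " retains zero edges", call. = FALSE)
  # order() is stable, and upper.tri indices are already in column-major
  # (lexicographic) order, so ties resolve to the lowest (i, j) index.
  keep <- ut[order(-z[ut])[seq_len(k)]]
  w <- matrix(0, n, n, dimnames = dimnames(z))
  w[keep] <- z[keep]
  w <- w + t(w)
  attr(w, "density") <- density
  attr(w, "n_edges") <- k
  w
}

#' Shortest-path distance matrix of a thresholded connectome
#'
#' Converts retained edge weights to lengths as 1/weight (stronger
#' connectivity = shorter distance) and computes all-pairs shortest-path
#' lengths on the weighted graph.
#'
#' @param w thresholded connectivity matrix (output of
#'   [threshold_density()]); all retained weights must be positive.
#' @return symmetric distance matrix with zero diagonal; errors if the
#'   thresholded graph is disconnected.
#' @export
distance_matrix <- function(w) {
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop("expected a square matrix", call. = FALSE)
  if (any(w[w != 0] <= 0))
    stop("thresholded matrix has nonpositive retained weights; ",
         "cannot convert connectivity to distance", call. = FALSE)
  ee <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  g <- igraph::make_graph(t(ee), n = nrow(w), directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop("thresholded graph is disconnected (", comp$no,
         " components of sizes ", sizes, ")", call. = FALSE)
  }
  d <- igraph::distances(g, weights = 1 / w[ee], algorithm = "dijkstra")
  dimnames(d) <- dimnames(w)
  d
}

#' Mean connectivity-based distance per ROI
#'
#' For each ROI, the mean shortest-path distance to all remaining ROIs —
#' the per-node global-connectivity measure from which the hub map is
#' derived (low mean distance = strongly globally connected).
#'
#' @param d distance matrix from [distance_matrix()].
#' @return named numeric vector of per-ROI mean off-diagonal distances.
#' @export
weighted_degree <- function(d) {
  n <- nrow(d)
  if (is.null(n) || n < 2) stop("need at least 2 ROIs", call. = FALSE)
  md <- (rowSums(d) - diag(d)) / (n - 1)
  names(md) <- roi_ids(d)
  md
}

#' Scaled hub map
#'
#' Linearly rescales mean connectivity-based distance to \[-1, 1\] with the
#' sign flipped, so that the most globally connected ROI (lowest mean
#' distance) scores +1 and the least connected scores -1.
#'
#' @param mean_distance named numeric vector from [weighted_degree()].
#' @return named numeric vector in \[-1, 1\].
#' @export
scale_hub_map <- function(mean_distance) {
  rng <- range(mean_distance)
  if (!all(is.finite(rng))) stop("non-finite mean distances", call. = FALSE)
  if (rng[1] == rng[2])
    stop("constant mean distance: hub map undefined", call. = FALSE)
  1 - 2 * (mean_distance - rng[1]) / (rng[2] - rng[1])
}

#' Hub map from a connectivity matrix
#'
#' Convenience chain: density thresholding, shortest-path distance, per-ROI
#' mean distance, and rescaling to \[-1, 1\].
#'
#' @param z symmetric Fisher-z connectivity matrix.
#' @param density edge density retained by the threshold (default 0.3).
#' @return named numeric scaled hub map.
#' @export
build_hub_map <- function(z, density = 0.3) {
  scale_hub_map(weighted_degree(distance_matrix(threshold_density(z, density))))
}

#' Shuffle a connectome into a null model
#'
#' Randomly permutes the upper-triangle connectivity values (preserving
#' their multiset exactly) and re-symmetrizes, producing a degree-structure-
#' destroying null connectome for exact tests.
#'
#' @param z symmetric connectivity matrix.
#' @param seed integer seed; the same seed reproduces the same shuffle.
#' @return shuffled symmetric matrix with zero diagonal.
#' @export
shuffle_connectome <- function(z, seed) {
  check_connectivity(z)
  ut <- which(upper.tri(z))
  vals <- z[ut]
  perm <- with_local_seed(seed, sample.int(length(vals)))
  out <- matrix(0, nrow(z), ncol(z), dimnames = dimnames(z))
  out[ut] <- vals[perm]
  out <- out + t(out)
  out
}

# Run code under a temporary RNG state so package functions taking a seed
# do not disturb the caller's random stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
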