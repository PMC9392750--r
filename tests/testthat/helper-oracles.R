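# Independent brute-force oracles, deliberately written with different
# algorithms than the package (element loops, Floyd-Warshall, sort-and-take)
# so that agreement is informative.

# all-pairs shortest paths by Floyd-Warshall on an edge-length matrix
# (0 = no edge except on the diagonal)
fw_shortest_paths <- function(len) {
  n <- nrow(len)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && len[i, j] > 0) d[i, j] <- len[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  dimnames(d) <- dimnames(len)
  d
}

# sort-and-take density thresholding oracle
brute_threshold <- function(z, density) {
  n <- nrow(z)
  pairs <- which(upper.tri(z), arr.ind = TRUE)
  vals <- z[pairs]
  k <- round(density * nrow(pairs))
  ord <- order(-vals, pairs[, 1], pairs[, 2])
  keep <- ord[seq_len(k)]
  w <- matrix(0, n, n, dimnames = dimnames(z))
  for (e in keep) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    w[i, j] <- z[i, j]; w[j, i] <- z[i, j]
  }
  w
}

# element-loop row mean excluding the diagonal
brute_mean_distance <- function(d) {
  n <- nrow(d)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) if (j != i) s <- s + d[i, j]
    out[i] <- s / (n - 1)
  }
  names(out) <- rownames(d)
  out
}

# random symmetric positive-weight connectivity matrix (complete graph,
# so any density threshold >= 2/n keeps it connected in practice; callers
# verify connectivity)
rand_conn_matrix <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("r%02d", seq_len(n))
  z <- matrix(0, n, n, dimnames = list(ids, ids))
  ut <- which(upper.tri(z))
  z[ut] <- abs(rnorm(length(ut), 0.4, 0.2)) + 0.05
  z + t(z)
}

# 3-ROI path fixture: A-B and B-C with weight 0.5 (edge length 2 each)
path_threshold_fixture <- function() {
  ids <- c("A", "B", "C")
  w <- matrix(0, 3, 3, dimnames = list(ids, ids))
  w["A", "B"] <- w["B", "A"] <- 0.5
  w["B", "C"] <- w["C", "B"] <- 0.5
  w
}
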