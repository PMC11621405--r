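# Brute-force reference implementations and small data builders used across
# the suite. The oracles deliberately avoid the package's own code paths.

# O(n^2) mutual-KNN scan: returns a logical nq x nr matrix of MNN pairs
brute_mnn <- function(d_q, d_r, K) {
  nq <- nrow(d_q); nr <- nrow(d_r)
  dmat <- as.matrix(stats::dist(rbind(d_q, d_r)))[1:nq, nq + (1:nr)]
  sq <- t(apply(dmat, 1, function(row) rank(row, ties.method = "first") <= K))
  sr <- apply(dmat, 2, function(col) rank(col, ties.method = "first") <= K)
  sq & sr
}

# O(n^2) radius adjacency
brute_radius_adj <- function(xy, R) {
  n <- nrow(xy)
  dmat <- as.matrix(stats::dist(xy))
  lapply(seq_len(n), function(i) {
    setdiff(which(dmat[i, ] <= R), i)
  })
}

# pair-counting adjusted Rand index
brute_ari <- function(a, b) {
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  tab <- table(a, b)
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  exp_idx <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# per-cell count/normalize loop for the enrichment features
brute_enrichment <- function(adjacency, labels) {
  valid <- labels != "NM"
  types <- sort(unique(labels[valid]))
  f <- as.numeric(table(factor(labels[valid], levels = types)))
  f <- f / sum(f)
  rows <- list(); ys <- character(0)
  for (i in which(valid)) {
    nb <- adjacency[[i]]
    nb <- nb[valid[nb]]
    if (length(nb) == 0) next
    lam <- sapply(types, function(t) sum(labels[nb] == t))
    rows[[length(rows) + 1]] <- lam / (f * sum(lam))
    ys <- c(ys, labels[i])
  }
  list(X = do.call(rbind, rows), y = ys, types = types)
}

# two well-separated Gaussian blobs in n_dim dimensions
make_blobs <- function(n_per = 60, sep = 20, n_dim = 5) {
  m <- rbind(matrix(rnorm(n_per * n_dim), ncol = n_dim),
             matrix(rnorm(n_per * n_dim, mean = sep), ncol = n_dim))
  rownames(m) <- sprintf("c%03d", seq_len(2 * n_per))
  list(x = m, label = rep(c("A", "B"), each = n_per))
}

# a small NB count matrix with marker structure for two types
make_toy_counts <- function(n_per = 40, n_genes = 30, seed_labels = c("A", "B")) {
  labs <- rep(seed_labels, each = n_per)
  base <- matrix(1, 2, n_genes)
  base[1, 1:5] <- 25
  base[2, 6:10] <- 25
  rates <- base[as.integer(factor(labs)), ]
  rates <- rates / rowSums(rates)
  vals <- matrix(stats::rnbinom(length(labs) * n_genes, mu = 800 * rates,
                                size = 10),
                 length(labs), n_genes)
  cm <- count_matrix(vals, sprintf("cell%03d", seq_along(labs)),
                     sprintf("g%02d", seq_len(n_genes)))
  list(counts = cm, labels = labs)
}

# run the radius-0 interaction pipeline on a snapshot
interaction_rankings <- function(snap, seed) {
  g <- build_neighborhoods(snap$coords, "delaunay_R0", max_dist = 100)
  feat <- enrichment_features(g, snap$type_labels)
  fit_niche_classifier(feat, seed = seed)
}
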