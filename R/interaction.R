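#' Build a spatial neighborhood graph from cell centroids
#'
#' Two schemes: `"delaunay_R0"` links Delaunay-triangulation neighbors
#' (juxtacrine contacts), discarding edges whose centroid-to-centroid
#' distance exceeds `max_dist` (Delaunay can bridge wide intercellular
#' space); `"radius_R"` links all pairs within radius `R` (paracrine range).
#' Distances are in the units of the input coordinates.
#'
#' @param coords 2-column matrix or data frame with `x`, `y` (and optionally
#'   `cell_id`) per cell.
#' @param mode `"delaunay_R0"` (default) or `"radius_R"`.
#' @param R neighborhood radius for `radius_R` mode.
#' @param max_dist Delaunay edge length cutoff (default 100, i.e. 100 microns
#'   on micron-scaled platforms).
#' @return A `NeighborGraph`: list with `edges` (data frame `i`, `j`, `dist`
#'   with `i < j`), `adjacency` (per-cell neighbor index list), `n`, `mode`,
#'   `R`, `max_dist`.
#' @export
build_neighborhoods <- function(coords, mode = c("delaunay_R0", "radius_R"),
                                R = NULL, max_dist = 100) {
  mode <- match.arg(mode)
  xy <- extract_xy(coords)
  n <- nrow(xy)
  if (mode == "delaunay_R0") {
    if (n < 4) stop("Delaunay triangulation needs >= 4 cells, got ", n)
    tri <- tryCatch(
      deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE),
      error = function(e) stop("degenerate geometry for ", n, " cells: ",
                               conditionMessage(e)))
    e <- tri$delsgs
    i <- pmin(e$ind1, e$ind2); j <- pmax(e$ind1, e$ind2)
    d <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
    keep <- d <= max_dist
    edges <- data.frame(i = i[keep], j = j[keep], dist = d[keep])
  } else {
    if (is.null(R) || R <= 0) stop("radius_R mode needs a positive R")
    nn <- RANN::nn2(xy, k = n, searchtype = "radius", radius = R)
    idx <- nn$nn.idx; dst <- nn$nn.dists
    from <- rep(seq_len(n), ncol(idx))
    to <- as.vector(idx)
    d <- as.vector(dst)
    keep <- to > 0 & to != from & is.finite(d)
    from <- from[keep]; to <- to[keep]; d <- d[keep]
    keep2 <- from < to
    edges <- data.frame(i = from[keep2], j = to[keep2], dist = d[keep2])
    edges <- edges[!duplicated(edges[, 1:2]), ]
  }
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  adjacency <- rep(list(integer(0)), n)
  if (nrow(edges) > 0) {
    both_from <- c(edges$i, edges$j)
    both_to <- c(edges$j, edges$i)
    split_adj <- split(both_to, factor(both_from, levels = seq_len(n)))
    adjacency <- unname(lapply(split_adj, function(v) sort(as.integer(v))))
  }
  structure(list(edges = edges, adjacency = adjacency, n = n, mode = mode,
                 R = R, max_dist = max_dist, coords = xy),
            class = "NeighborGraph")
}

extract_xy <- function(coords) {
  if (inherits(coords, "SpatialDataset")) coords <- coords$coords
  if (is.data.frame(coords)) {
    stopifnot(all(c("x", "y") %in% names(coords)))
    as.matrix(coords[, c("x", "y")])
  } else as.matrix(coords[, 1:2, drop = FALSE])
}

#' @export
print.NeighborGraph <- function(x, ...) {
  cat(sprintf("NeighborGraph (%s): %d cells, %d edges\n",
              x$mode, x$n, nrow(x$edges)))
  invisible(x)
}

#' Niche composition enrichment features
#'
#' Counts, for every labeled cell, its neighbors of each cell type
#' (`Lambda`), and normalizes by the expectation under the global type
#' frequencies `f`: `X_ij = Lambda_ij / (f_j * sum_k Lambda_ik)`. An entry of
#' 1 therefore means the type is represented in the niche exactly at its
#' global frequency. Cells labeled `'NM'` are excluded from rows, neighbor
#' counts and frequencies; cells with no labeled neighbor are dropped (their
#' indices are recorded in `dropped_cells`).
#'
#' @param graph a [build_neighborhoods()] graph.
#' @param labels per-cell type labels aligned with the graph's cells.
#' @return A `NicheFeatures`: list with `X` (enrichment ratios), `Lambda`
#'   (integer neighbor counts), `y` (factor of central cell types), `f`
#'   (global type frequencies), `cells` (row indices into the input),
#'   `dropped_cells`.
#' @export
enrichment_features <- function(graph, labels) {
  labels <- as.character(labels)
  if (length(labels) != graph$n) stop("labels length != graph cells")
  valid <- !is.na(labels) & labels != "NM"
  types <- sort(unique(labels[valid]))
  f <- as.numeric(table(factor(labels[valid], levels = types)))
  f <- f / sum(f)
  names(f) <- types
  if (any(f == 0)) {
    warning("types with zero global frequency excluded: ",
            paste(types[f == 0], collapse = ", "))
    types <- types[f > 0]; f <- f[f > 0]
  }
  cells <- which(valid)
  Lambda <- matrix(0L, length(cells), length(types),
                   dimnames = list(NULL, types))
  for (r in seq_along(cells)) {
    nb <- graph$adjacency[[cells[r]]]
    nb <- nb[valid[nb]]
    if (length(nb) > 0) {
      tab <- table(factor(labels[nb], levels = types))
      Lambda[r, ] <- as.integer(tab)
    }
  }
  tot <- rowSums(Lambda)
  dropped <- cells[tot == 0]
  keep <- tot > 0
  Lambda <- Lambda[keep, , drop = FALSE]
  cells <- cells[keep]
  X <- Lambda / (rowSums(Lambda) %o% f)
  structure(list(X = X, Lambda = Lambda,
                 y = factor(labels[cells], levels = types),
                 f = f, cells = cells, dropped_cells = dropped),
            class = "NicheFeatures")
}

# stratified fold ids, deterministic given the RNG state
stratified_folds <- function(y, F) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(F), length(idx))
  }
  fold
}

#' Fit the niche composition classifier
#'
#' Trains an L2-penalized multinomial logistic regression predicting each
#' central cell's type from the z-scored niche enrichment features, with
#' balanced class weights (inverse class frequency). The inverse penalty `C`
#' is selected by grid search (log-spaced `1e-4 ... 1e4`) under stratified
#' `F`-fold cross-validated accuracy; the reported coefficients are the mean
#' over per-fold refits at the selected `C`, with their fold standard
#' deviation as uncertainty, and the confusion matrix is the row-normalized
#' mean of the held-out confusion across folds. Positive `beta[k, j]` means
#' niche type `j` is enriched around central type `k`.
#'
#' @param feat a [enrichment_features()] object.
#' @param seed RNG seed for fold assignment (set for reproducible fits).
#' @param F number of folds (default 5).
#' @param C_grid inverse-regularization grid (default `10^(-4:4)`).
#' @return An `InteractionModel`: list with `beta` (types x types mean
#'   coefficients, rows = central type), `beta_sd`, `intercepts`,
#'   `confusion` (rows = true type, row-normalized), `C`, `cv_accuracy`,
#'   `class_accuracy`, `folds`, `types`.
#' @export
fit_niche_classifier <- function(feat, seed = NULL, F = 5,
                                 C_grid = 10^seq(-4, 4, length.out = 9)) {
  if (!is.null(seed)) set.seed(seed)
  X <- feat$X; y <- feat$y
  types <- levels(y)
  K <- length(types)
  if (K < 2) stop("need at least 2 classes")
  small <- names(which(table(y) < F))
  if (length(small) > 0) {
    warning("classes with fewer than ", F, " members excluded from training: ",
            paste(small, collapse = ", "))
    keep <- !(y %in% small)
    X <- X[keep, , drop = FALSE]
    y <- droplevels(y[keep])
    types <- levels(y); K <- length(types)
  }
  n <- nrow(X)
  Xs <- standardize_cols(X)
  w <- n / (K * as.numeric(table(y)[y]))     # balanced class weights
  fold <- stratified_folds(y, F)

  fit_one <- function(rows, C, quiet = FALSE) {
    lam <- 1 / (C * length(rows))
    call_fit <- function() glmnet::glmnet(
      Xs[rows, , drop = FALSE], y[rows], family = "multinomial",
      alpha = 0, lambda = lam * c(16, 8, 4, 2, 1),
      weights = w[rows], standardize = FALSE,
      type.multinomial = "ungrouped", maxit = 1e5)
    # extreme C values can fail to converge on separable data; the grid
    # search treats such a C as unusable
    tryCatch(if (quiet) suppressWarnings(call_fit()) else call_fit(),
             error = function(e) NULL)
  }
  pred_one <- function(fit, rows) {
    p <- predict(fit, Xs[rows, , drop = FALSE], s = min(fit$lambda),
                 type = "class")
    factor(as.character(p), levels = types)
  }

  # grid search over C by CV accuracy
  cv_acc <- sapply(C_grid, function(C) {
    accs <- sapply(seq_len(F), function(f) {
      tr <- which(fold != f); te <- which(fold == f)
      fit <- fit_one(tr, C, quiet = TRUE)
      if (is.null(fit)) return(-Inf)
      mean(pred_one(fit, te) == y[te])
    })
    mean(accs)
  })
  if (all(!is.finite(cv_acc))) stop("classifier failed at every C")
  C_best <- C_grid[which.max(cv_acc)]

  # per-fold refits at the selected C
  beta_f <- array(NA_real_, c(K, ncol(X), F),
                  dimnames = list(types, colnames(X), NULL))
  int_f <- matrix(NA_real_, K, F, dimnames = list(types, NULL))
  conf <- matrix(0, K, K, dimnames = list(types, types))
  for (f in seq_len(F)) {
    tr <- which(fold != f); te <- which(fold == f)
    fit <- fit_one(tr, C_best)
    if (is.null(fit)) stop("classifier refit failed at selected C = ", C_best)
    cf <- stats::coef(fit, s = min(fit$lambda))
    for (k in seq_len(K)) {
      ck <- as.matrix(cf[[types[k]]])
      int_f[k, f] <- ck[1, 1]
      beta_f[k, , f] <- ck[-1, 1]
    }
    pred <- pred_one(fit, te)
    conf <- conf + table(y[te], pred) / F
  }
  beta <- apply(beta_f, c(1, 2), mean)
  beta_sd <- apply(beta_f, c(1, 2), sd)
  conf_norm <- conf / pmax(rowSums(conf), .Machine$double.eps)
  structure(list(beta = beta, beta_sd = beta_sd,
                 intercepts = rowMeans(int_f),
                 confusion = conf_norm, C = C_best,
                 cv_accuracy = max(cv_acc),
                 cv_path = data.frame(C = C_grid, accuracy = cv_acc),
                 class_accuracy = diag(conf_norm),
                 folds = F, types = types),
            class = "InteractionModel")
}

#' @export
print.InteractionModel <- function(x, ...) {
  cat(sprintf(
    "InteractionModel: %d cell types, C = %g, CV accuracy = %.3f\n",
    length(x$types), x$C, x$cv_accuracy))
  invisible(x)
}

#' Rank niche predictors of a central cell type
#'
#' @param model an [fit_niche_classifier()] model.
#' @param central central cell type name.
#' @param positive_only keep only positive coefficients (default TRUE).
#' @param exclude_self drop the central type itself (default TRUE).
#' @return data frame `niche`, `beta`, `beta_sd` sorted by decreasing
#'   coefficient.
#' @export
rank_niche_predictors <- function(model, central, positive_only = TRUE,
                                  exclude_self = TRUE) {
  b <- model$beta[central, ]
  s <- model$beta_sd[central, ]
  df <- data.frame(niche = names(b), beta = unname(b), beta_sd = unname(s))
  if (exclude_self) df <- df[df$niche != central, ]
  if (positive_only) df <- df[df$beta > 0, ]
  df[order(-df$beta), ]
}

#' Build the directed cell-type interaction graph
#'
#' Each central type's coefficient vector is normalized by its maximum
#' absolute component, and a directed edge niche -> central is drawn
#' wherever the normalized coefficient exceeds the cutoff `c`.
#'
#' @param model an [fit_niche_classifier()] model.
#' @param c edge cutoff on the normalized coefficient (default 0.01).
#' @return An `InteractionGraph`: list with `edges` (data frame `niche`,
#'   `central`, `weight`), `cutoff`, `norm_beta`, and an `igraph` object
#'   `graph`.
#' @export
build_interaction_graph <- function(model, c = 0.01) {
  beta <- model$beta
  norm_beta <- beta
  for (k in seq_len(nrow(beta))) {
    mx <- max(abs(beta[k, ]))
    norm_beta[k, ] <- if (mx > 0) beta[k, ] / mx else 0
  }
  idx <- which(norm_beta > c, arr.ind = TRUE)
  edges <- data.frame(
    niche = colnames(beta)[idx[, 2]],
    central = rownames(beta)[idx[, 1]],
    weight = norm_beta[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$central, -edges$weight), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("niche", "central", "weight")], directed = TRUE,
    vertices = data.frame(name = model$types))
  structure(list(edges = edges, cutoff = c, norm_beta = norm_beta, graph = g),
            class = "InteractionGraph")
}

#' @export
print.InteractionGraph <- function(x, ...) {
  cat(sprintf("InteractionGraph: %d edges at cutoff %g\n",
              nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Domain-level cell type enrichment z-scores
#'
#' For each tissue domain `d` and cell type `j`, computes the type's
#' frequency `f_dj` inside the domain, its mean and (population) standard
#' deviation across domains, and the enrichment z-score
#' `Z_dj = (f_dj - mu_j) / sigma_j`, alongside the observed/expected ratio
#' `f_dj / f_j` against the global type frequency.
#'
#' @param domain_labels per-cell domain assignment.
#' @param type_labels per-cell type assignment (same cells).
#' @return A `DomainScore`: list with `Z`, `ratio` (domains x types), `f_dj`,
#'   `mu`, `sigma`, `global_f`.
#' @export
domain_consistency <- function(domain_labels, type_labels) {
  if (length(domain_labels) != length(type_labels))
    stop("domain and type labels must cover the same cells")
  d <- factor(domain_labels); t <- factor(type_labels)
  tab <- table(d, t)
  f_dj <- tab / pmax(rowSums(tab), 1)
  f_dj <- matrix(f_dj, nrow(tab), ncol(tab),
                 dimnames = list(levels(d), levels(t)))
  mu <- colMeans(f_dj)
  sigma <- sqrt(colMeans(sweep(f_dj, 2, mu)^2))  # population sd over domains
  Z <- sweep(sweep(f_dj, 2, mu), 2, sigma, "/")
  if (any(sigma == 0)) {
    warning("types with zero across-domain sd get Z = 0: ",
            paste(colnames(f_dj)[sigma == 0], collapse = ", "))
    Z[, sigma == 0] <- 0
  }
  global_f <- as.numeric(table(t)) / length(t)
  ratio <- sweep(f_dj, 2, global_f, "/")
  structure(list(Z = Z, ratio = ratio, f_dj = f_dj, mu = mu, sigma = sigma,
                 global_f = setNames(global_f, levels(t))),
            class = "DomainScore")
}

#' Best-match correlation between two domain partitions
#'
#' Correlates each ground-truth domain's cell-type profile (z-score or
#' observed/expected ratio) against every predicted domain's profile and
#' reports the maximum Pearson correlation per ground-truth domain — the
#' standard summary for comparing niche/domain detection outputs.
#'
#' @param truth,pred [domain_consistency()] scores over the same cell types.
#' @param use `"z"` (default) or `"ratio"`.
#' @return named numeric vector: per truth domain, the best correlation.
#' @export
best_match_correlation <- function(truth, pred, use = c("z", "ratio")) {
  use <- match.arg(use)
  A <- if (use == "z") truth$Z else truth$ratio
  B <- if (use == "z") pred$Z else pred$ratio
  common <- intersect(colnames(A), colnames(B))
  if (length(common) < 2) stop("need >= 2 shared cell types")
  A <- A[, common, drop = FALSE]; B <- B[, common, drop = FALSE]
  sapply(rownames(A), function(d)
    max(apply(B, 1, function(p) suppressWarnings(cor(A[d, ], p)))))
}

#' Compare a predicted labeling against ground truth
#'
#' Reports the adjusted Rand index (partition agreement, label-name
#' invariant), the mean per-type Jaccard index (intersection-over-union over
#' type names shared by both labelings), and class-frequency-weighted
#' precision.
#'
#' @param pred,truth character label vectors over the same cells.
#' @return list with `ARI`, `Jaccard`, `weighted_precision`.
#' @export
evaluate_annotation <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  ari <- mclust::adjustedRandIndex(pred, truth)
  shared <- intersect(unique(pred), unique(truth))
  shared <- setdiff(shared, "NM")
  if (length(shared) == 0) stop("no shared type names for Jaccard")
  jac <- mean(sapply(shared, function(t) {
    inter <- sum(pred == t & truth == t)
    uni <- sum(pred == t | truth == t)
    if (uni == 0) 0 else inter / uni
  }))
  tt <- table(truth)
  wprec <- sum(sapply(names(tt), function(t) {
    denom <- sum(pred == t)
    prec <- if (denom == 0) 0 else sum(pred == t & truth == t) / denom
    tt[[t]] / length(truth) * prec
  }))
  list(ARI = ari, Jaccard = jac, weighted_precision = wprec)
}
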