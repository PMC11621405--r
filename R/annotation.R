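#' Variance-stabilizing normalization via analytic Pearson residuals
#'
#' Computes negative-binomial Pearson residuals under the null model
#' `mu_gc = depth_c * p_g` with a fixed overdispersion `theta`:
#' `r_gc = (x_gc - mu_gc) / sqrt(mu_gc + mu_gc^2 / theta)`, clipped to
#' `+/- sqrt(n_cells)`. `theta = Inf` gives plain Poisson Pearson residuals.
#' Genes with zero total count carry no information and are dropped (their
#' ids are recorded in the `dropped_genes` attribute).
#'
#' @param counts a [count_matrix()].
#' @param theta negative-binomial overdispersion of the null model
#'   (default 100).
#' @return A `ResidualMatrix`: dense cells x genes matrix of residuals with
#'   attributes `clip_bound`, `theta` and `dropped_genes`.
#' @export
normalize_residuals <- function(counts, theta = 100) {
  m <- as.matrix(strip_cm(counts))
  gene_tot <- colSums(m)
  dropped <- colnames(m)[gene_tot == 0]
  if (all(gene_tot == 0)) stop("all-zero count matrix")
  m <- m[, gene_tot > 0, drop = FALSE]
  gene_tot <- gene_tot[gene_tot > 0]
  depth <- rowSums(m)
  p <- gene_tot / sum(gene_tot)
  mu <- outer(depth, p)
  denom <- sqrt(mu + mu^2 / theta)
  res <- (m - mu) / denom
  res[denom == 0] <- 0
  clip <- sqrt(nrow(m))
  res[res > clip] <- clip
  res[res < -clip] <- -clip
  structure(res, clip_bound = clip, theta = theta, dropped_genes = dropped,
            class = c("ResidualMatrix", "matrix", "array"))
}

#' Principal-component embedding of a residual matrix
#'
#' Centers genes, extracts the top principal components ordered by decreasing
#' explained variance, and standardizes each component to zero mean and unit
#' variance.
#'
#' @param res a [normalize_residuals()] matrix (any numeric matrix accepted).
#' @param n_pcs number of components (default 50); reduced with a warning if
#'   it exceeds the matrix rank.
#' @param standardize standardize columns after projection (default TRUE).
#' @return An `Embedding`: cells x n_pcs matrix with attribute `sdev`
#'   (component standard deviations before standardization).
#' @export
embed_top_pcs <- function(res, n_pcs = 50, standardize = TRUE) {
  res <- unclass(res)
  max_rank <- min(nrow(res) - 1, ncol(res))
  if (n_pcs > max_rank) {
    warning("n_pcs reduced from ", n_pcs, " to rank limit ", max_rank)
    n_pcs <- max_rank
  }
  pc <- prcomp(res, center = TRUE, scale. = FALSE, rank. = n_pcs)
  emb <- pc$x
  if (standardize) emb <- standardize_cols(emb)
  structure(emb, sdev = pc$sdev, standardized = standardize,
            class = c("Embedding", "matrix", "array"))
}

standardize_cols <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, s, "/")
}

#' Joint principal-component embedding of both modalities
#'
#' Fits one PCA on the row-stacked query and reference residual matrices over
#' the shared gene set and splits the projection back, so that query and
#' reference cells live in a single comparable latent basis (a prerequisite
#' for cross-modality nearest-neighbor search). Each block is then
#' standardized per component.
#'
#' @param res_q,res_r residual matrices over the same genes in the same
#'   order.
#' @param n_pcs number of components (default 50).
#' @return List with `Embedding`s `d_q` and `d_r`.
#' @export
joint_embedding <- function(res_q, res_r, n_pcs = 50) {
  if (ncol(res_q) != ncol(res_r) ||
      !identical(colnames(res_q), colnames(res_r)))
    stop("query and reference residuals must share the same gene order")
  stacked <- rbind(unclass(res_q), unclass(res_r))
  emb <- embed_top_pcs(stacked, n_pcs = n_pcs, standardize = FALSE)
  nq <- nrow(res_q)
  d_q <- standardize_cols(emb[seq_len(nq), , drop = FALSE])
  d_r <- standardize_cols(emb[-seq_len(nq), , drop = FALSE])
  list(d_q = structure(d_q, standardized = TRUE,
                       class = c("Embedding", "matrix", "array")),
       d_r = structure(d_r, standardized = TRUE,
                       class = c("Embedding", "matrix", "array")))
}

knn_ids <- function(query, data, k) {
  RANN::nn2(data = data, query = query, k = k, treetype = "kd")
}

#' Leiden guide clustering of the spatial embedding
#'
#' Builds a K-nearest-neighbor graph (Euclidean, 15 neighbors by default) on
#' the embedding and partitions it with the Leiden algorithm under the
#' modularity objective. Guide clusters prune dispersed anchors and gate the
#' iterative annotation. Seeded from R's RNG: call `set.seed()` for
#' reproducible partitions.
#'
#' @param emb an [embed_top_pcs()] embedding of the spatial cells.
#' @param resolution Leiden resolution (default 0.4, the setting used for
#'   embryo/intestine/cortex-scale panels).
#' @param k_graph neighbors for the KNN graph (default 15).
#' @return integer vector of cluster ids (1-based), named by cell.
#' @export
guide_cluster <- function(emb, resolution = 0.4, k_graph = 15) {
  n <- nrow(emb)
  if (n <= k_graph) stop("fewer cells (", n, ") than k_graph + 1")
  nn <- knn_ids(emb, emb, k_graph + 1)
  from <- rep(seq_len(n), each = k_graph)
  to <- as.vector(t(nn$nn.idx[, -1, drop = FALSE]))
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g)
  part <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  setNames(as.integer(igraph::membership(part)), rownames(emb))
}

#' Find soft mutual-nearest-neighbor anchors between modalities
#'
#' For every query cell the K nearest reference cells are located (KD-tree,
#' Euclidean) and vice versa; query `q` and reference `r` are mutual nearest
#' neighbors iff each lies in the other's neighbor set. Query cells whose
#' MNN partners carry exactly one reference label become anchors with that
#' label. Cells whose partners carry several labels ("confused") are resolved
#' by majority vote over non-confused anchors among their K query-side
#' nearest neighbors, restricted to anchors in the cell's guide cluster;
#' unresolved ties (or no eligible voters) yield `'NM'`. With
#' `weighted = TRUE` votes are weighted by inverse distance, which breaks
#' most ties.
#'
#' @param d_q,d_r standardized embeddings of query and spatial cells sharing
#'   the component space (see [joint_embedding()]).
#' @param ref_labels per-reference-cell type labels (row order of `d_r`).
#' @param guide per-query-cell guide cluster ids from [guide_cluster()];
#'   optional — without it confused anchors are resolved without guide
#'   pruning.
#' @param K neighborhood size of the soft MNN criterion (default 50).
#' @param weighted use inverse-distance-weighted voting for confused anchors.
#' @return An `AnchorSet`: list with `entries` (data frame `cell_id`,
#'   `label`, `status` in `anchor|confused_resolved|NM|unassigned`),
#'   `guide_labels`, and `params`.
#' @export
find_anchors <- function(d_q, d_r, ref_labels, guide = NULL, K = 50,
                         weighted = FALSE) {
  nq <- nrow(d_q); nr <- nrow(d_r)
  if (K >= nq || K >= nr)
    stop("K (", K, ") must be smaller than both modality sizes")
  if (ncol(d_q) != ncol(d_r)) stop("embeddings must share n_pcs")
  ref_labels <- as.character(ref_labels)
  if (length(ref_labels) != nr) stop("ref_labels length != reference cells")
  # s_q: K nearest reference cells of each query cell; s_r: K nearest query
  # cells of each reference cell.
  s_q <- knn_ids(d_q, d_r, K)$nn.idx
  s_r <- knn_ids(d_r, d_q, K)$nn.idx
  in_sr <- Matrix::sparseMatrix(i = rep(seq_len(nr), each = K),
                                j = as.vector(t(s_r)), x = TRUE,
                                dims = c(nr, nq))
  status <- rep("unassigned", nq)
  label <- rep(NA_character_, nq)
  mnn_labels <- vector("list", nq)
  for (q in seq_len(nq)) {
    partners <- s_q[q, ][in_sr[cbind(s_q[q, ], q)]]
    if (length(partners) == 0) next
    labs <- unique(ref_labels[partners])
    mnn_labels[[q]] <- labs
    if (length(labs) == 1) {
      status[q] <- "anchor"; label[q] <- labs
    } else {
      status[q] <- "confused"
    }
  }
  # resolve confused anchors from non-confused anchors among query-side KNN
  kq <- min(K + 1, nq)
  nn_q <- knn_ids(d_q, d_q, kq)
  anchor_mask <- status == "anchor"
  for (q in which(status == "confused")) {
    idx <- nn_q$nn.idx[q, -1]
    dst <- nn_q$nn.dists[q, -1]
    keep <- anchor_mask[idx]
    if (!is.null(guide)) keep <- keep & guide[idx] == guide[q]
    idx <- idx[keep]; dst <- dst[keep]
    if (length(idx) == 0) { status[q] <- "NM"; label[q] <- "NM"; next }
    v <- vote(label[idx], if (weighted) 1 / pmax(dst, 1e-12) else NULL)
    if (is.na(v)) { status[q] <- "NM"; label[q] <- "NM" }
    else { status[q] <- "confused_resolved"; label[q] <- v }
  }
  structure(list(
    entries = data.frame(cell_id = rownames(d_q), label = label,
                         status = status, stringsAsFactors = FALSE),
    guide_labels = guide,
    params = list(K = K, weighted = weighted)),
    class = "AnchorSet")
}

# majority vote; optional weights; NA on a tie
vote <- function(labels, weights = NULL) {
  if (length(labels) == 0) return(NA_character_)
  if (is.null(weights)) weights <- rep(1, length(labels))
  tot <- tapply(weights, labels, sum)
  top <- tot[tot == max(tot)]
  if (length(top) > 1) NA_character_ else names(top)
}

#' @export
print.AnchorSet <- function(x, ...) {
  cat(sprintf("AnchorSet: %d query cells (%s)\n", nrow(x$entries),
              paste(sprintf("%s=%d", names(table(x$entries$status)),
                            table(x$entries$status)), collapse = ", ")))
  invisible(x)
}

#' Remove dispersed anchors using guide clusters
#'
#' For each cell-type label, anchors falling in a guide cluster that holds
#' less than a fraction `r` of that label's anchors are considered dispersed
#' (noise from imperfect matching) and demoted to unassigned.
#'
#' @param anchors an [find_anchors()] result.
#' @param guide per-query-cell guide cluster ids; defaults to the ones stored
#'   in `anchors`.
#' @param r dispersion threshold in `[0, 1]` (default 0.15).
#' @return The filtered `AnchorSet` (never larger than the input).
#' @export
filter_anchors <- function(anchors, guide = anchors$guide_labels, r = 0.15) {
  if (r < 0 || r > 1) stop("dispersion r must lie in [0, 1]")
  if (is.null(guide)) stop("guide cluster ids are required")
  e <- anchors$entries
  is_anchor <- e$status %in% c("anchor", "confused_resolved")
  for (lab in unique(e$label[is_anchor])) {
    sel <- is_anchor & e$label == lab
    tab <- table(guide[sel]) / sum(sel)
    bad_clusters <- names(tab)[tab < r]
    drop <- sel & as.character(guide) %in% bad_clusters
    e$status[drop] <- "unassigned"
    e$label[drop] <- NA_character_
  }
  anchors$entries <- e
  anchors$guide_labels <- guide
  anchors$params$r <- r
  anchors
}

#' Iteratively annotate non-anchor cells
#'
#' Each unassigned cell receives the majority label of current anchors among
#' its K nearest query-side neighbors. The vote is accepted only when the
#' winning label's modal guide cluster (over current anchors of that label)
#' equals the cell's guide cluster; ties give `'NM'`. Newly labeled cells
#' join the anchor set and the procedure repeats `max_iter` times (3 by
#' default — more iterations propagate low-confidence labels).
#'
#' @param anchors filtered [filter_anchors()] anchor set.
#' @param d_q standardized query embedding.
#' @param guide guide cluster ids; defaults to the ones stored in `anchors`.
#' @param K neighbors consulted per vote (defaults to the anchor K).
#' @param max_iter annotation rounds (default 3).
#' @param weighted weight votes by inverse distance (breaks ties; off by
#'   default).
#' @return Named character vector of labels over all query cells; cells that
#'   remain unassigned or tied are `'NM'`.
#' @export
iterative_annotate <- function(anchors, d_q, guide = anchors$guide_labels,
                               K = anchors$params$K, max_iter = 3,
                               weighted = FALSE) {
  e <- anchors$entries
  lab <- e$label
  assigned <- e$status %in% c("anchor", "confused_resolved", "iterative")
  if (!any(assigned)) stop("no anchors to annotate from")
  n <- nrow(d_q)
  kq <- min(K + 1, n)
  nn <- knn_ids(d_q, d_q, kq)
  for (iter in seq_len(max_iter)) {
    top_guide <- label_top_guide(lab[assigned], guide[assigned])
    new_lab <- lab
    new_assigned <- assigned
    for (q in which(!assigned)) {
      idx <- nn$nn.idx[q, -1]
      dst <- nn$nn.dists[q, -1]
      keep <- assigned[idx]
      idx <- idx[keep]; dst <- dst[keep]
      if (length(idx) == 0) next
      v <- vote(lab[idx], if (weighted) 1 / pmax(dst, 1e-12) else NULL)
      if (is.na(v)) { new_lab[q] <- "NM"; next }
      if (!is.null(guide) && !is.na(top_guide[v]) &&
          top_guide[v] != guide[q]) next
      new_lab[q] <- v
      new_assigned[q] <- TRUE
    }
    changed <- !identical(new_lab, lab) || !identical(new_assigned, assigned)
    lab <- new_lab; assigned <- new_assigned
    if (!changed) break
  }
  lab[is.na(lab)] <- "NM"
  setNames(lab, e$cell_id)
}

label_top_guide <- function(labels, guide) {
  out <- tapply(guide, labels, function(g) {
    tab <- table(g)
    as.character(names(tab)[which.max(tab)])
  })
  setNames(as.character(out), names(out))
}

#' Full annotation pipeline: label transfer from reference to spatial cells
#'
#' Runs shared-gene alignment, per-modality Pearson-residual normalization, a
#' joint 50-component PCA, Leiden guide clustering, soft-MNN anchor finding,
#' dispersion filtering and iterative annotation, returning the spatial
#' dataset with labels attached.
#'
#' @param sp a [spatial_dataset()].
#' @param ref a [reference_dataset()].
#' @param K MNN/vote neighborhood size (default 50).
#' @param dispersion anchor dispersion threshold r (default 0.15).
#' @param guide_resolution Leiden resolution of the guide clustering
#'   (default 0.4).
#' @param n_pcs number of principal components (default 50).
#' @param max_iter annotation iterations (default 3).
#' @param min_count minimum transcript total per cell (default 5).
#' @param weighted_if_nm_above switch to inverse-distance-weighted voting and
#'   redo annotation if the fraction of `'NM'` cells exceeds this value
#'   (default 0.1).
#' @param theta residual overdispersion (default 100).
#' @return List: `sp` (labeled `SpatialDataset`), `annotations` (data frame
#'   `cell_id`, `label`, `status`, `guide_cluster`), `anchors`, `embedding`.
#' @export
annotate_spatial <- function(sp, ref, K = 50, dispersion = 0.15,
                             guide_resolution = 0.4, n_pcs = 50, max_iter = 3,
                             min_count = 5, weighted_if_nm_above = 0.1,
                             theta = 100) {
  al <- align_shared_genes(sp, ref, min_count = min_count)
  res_q <- normalize_residuals(al$sp$counts, theta = theta)
  res_r <- normalize_residuals(al$ref$counts, theta = theta)
  shared <- intersect(colnames(res_q), colnames(res_r))
  emb <- joint_embedding(res_q[, shared, drop = FALSE],
                         res_r[, shared, drop = FALSE], n_pcs = n_pcs)
  guide <- guide_cluster(emb$d_q, resolution = guide_resolution)
  run <- function(weighted) {
    a <- find_anchors(emb$d_q, emb$d_r,
                      al$ref$cluster_labels[rownames(emb$d_r)],
                      guide = guide, K = K, weighted = weighted)
    a <- filter_anchors(a, guide, r = dispersion)
    labels <- iterative_annotate(a, emb$d_q, guide, K = K,
                                 max_iter = max_iter, weighted = weighted)
    list(anchors = a, labels = labels)
  }
  fit <- run(weighted = FALSE)
  if (mean(fit$labels == "NM") > weighted_if_nm_above) {
    fit <- run(weighted = TRUE)
  }
  status <- fit$anchors$entries$status
  status[status == "unassigned"] <-
    ifelse(fit$labels[status == "unassigned"] == "NM", "NM", "iterative")
  ann <- data.frame(cell_id = names(fit$labels), label = unname(fit$labels),
                    status = status, guide_cluster = unname(guide),
                    stringsAsFactors = FALSE)
  sp_out <- al$sp
  sp_out$labels <- fit$labels
  list(sp = sp_out, annotations = ann, anchors = fit$anchors, embedding = emb)
}
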