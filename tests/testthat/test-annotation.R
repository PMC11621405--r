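test_that("Pearson residuals vanish for a uniform gene in equal-depth cells", {
  vals <- cbind(rep(4, 5), rep(6, 5))  # equal depth, constant genes
  cm <- count_matrix(vals, paste0("c", 1:5), c("g1", "g2"))
  res <- normalize_residuals(cm)
  expect_true(all(abs(res) < 1e-12))
})

test_that("theta = Inf reproduces hand-computed Poisson Pearson residuals", {
  vals <- rbind(c(2, 0), c(1, 1), c(0, 4), c(3, 1))
  cm <- count_matrix(vals, paste0("c", 1:4), c("g1", "g2"))
  res <- normalize_residuals(cm, theta = Inf)
  depth <- rowSums(vals); p <- colSums(vals) / sum(vals)
  mu <- outer(depth, p)
  hand <- (vals - mu) / sqrt(mu)
  clip <- sqrt(4)
  hand <- pmin(pmax(hand, -clip), clip)
  expect_equal(unclass(res), hand, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("residual magnitudes never exceed sqrt(n_cells) and all-zero input errors", {
  set.seed(2)
  vals <- matrix(rnbinom(200, mu = 2, size = 0.5), 20, 10)
  vals[1, ] <- c(500, rep(0, 9))  # force an extreme residual
  cm <- count_matrix(vals, paste0("c", 1:20), paste0("g", 1:10))
  res <- normalize_residuals(cm)
  expect_true(all(abs(res) <= sqrt(20) + 1e-12))
  expect_error(normalize_residuals(
    count_matrix(matrix(0, 3, 3), paste0("c", 1:3), paste0("g", 1:3))),
    "all-zero")
})

test_that("PCA embedding respects rank, variance ordering, and an eigen oracle", {
  set.seed(3)
  # rank-2 matrix
  low <- matrix(rnorm(30 * 2), 30, 2) %*% matrix(rnorm(2 * 10), 2, 10)
  emb <- suppressWarnings(embed_top_pcs(low, n_pcs = 8, standardize = FALSE))
  sdev <- attr(emb, "sdev")
  expect_true(all(diff(sdev) <= 1e-12))              # non-increasing variance
  expect_lt(sum(sdev[-(1:2)]^2), 1e-8 * sum(sdev^2)) # rank limit
  # eigen oracle on a 20 x 10 matrix
  m <- matrix(rnorm(200), 20, 10)
  emb2 <- embed_top_pcs(m, n_pcs = 5, standardize = FALSE)
  cen <- scale(m, scale = FALSE)
  eig <- eigen(crossprod(cen) / (nrow(m) - 1), symmetric = TRUE)
  proj <- cen %*% eig$vectors[, 1:5]
  for (k in 1:5)  # PCs defined up to sign
    expect_equal(abs(unclass(emb2)[, k]), abs(proj[, k]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  # standardization contract
  emb3 <- embed_top_pcs(m, n_pcs = 5)
  expect_true(all(abs(colMeans(emb3)) < 1e-8))
  expect_true(all(abs(apply(emb3, 2, sd) - 1) < 1e-8))
})

test_that("guide clustering separates two distant blobs and is seed-stable", {
  set.seed(4)
  blobs <- make_blobs(n_per = 60, sep = 20)
  emb <- structure(scale(blobs$x)[, , drop = FALSE],
                   class = c("Embedding", "matrix", "array"))
  set.seed(10); g1 <- guide_cluster(emb, resolution = 0.4)
  set.seed(10); g2 <- guide_cluster(emb, resolution = 0.4)
  expect_identical(g1, g2)
  expect_equal(length(unique(g1)), 2L)
  expect_equal(length(unique(g1[blobs$label == "A"])), 1L)
  expect_equal(length(unique(g1[blobs$label == "B"])), 1L)
  expect_error(guide_cluster(emb[1:10, ], k_graph = 15), "fewer cells")
})

test_that("identical modalities make every cell an anchor of its own label", {
  set.seed(5)
  blobs <- make_blobs(n_per = 40, sep = 15)
  emb <- blobs$x
  rownames(emb) <- sprintf("q%03d", seq_len(nrow(emb)))
  a <- find_anchors(emb, blobs$x, blobs$label, K = 10)
  expect_true(all(a$entries$status == "anchor"))
  expect_equal(a$entries$label, blobs$label)
})

test_that("MNN pairs agree with an O(n^2) brute-force mutual-KNN scan", {
  set.seed(6)
  d_q <- matrix(rnorm(60 * 4), 60, 4)
  d_r <- matrix(rnorm(55 * 4), 55, 4)
  rownames(d_q) <- sprintf("q%02d", 1:60)
  K <- 7
  brute <- brute_mnn(d_q, d_r, K)
  # recompute MNN partner labels exactly as find_anchors sees them
  labs <- sprintf("L%02d", 1:55)  # unique label per reference cell
  a <- find_anchors(d_q, d_r, labs, K = K)
  for (q in 1:60) {
    partners <- which(brute[q, ])
    row <- a$entries[q, ]
    if (length(partners) == 1) {
      expect_equal(row$status, "anchor")
      expect_equal(row$label, labs[partners])
    } else if (length(partners) == 0) {
      expect_equal(row$status, "unassigned")
    } else {
      expect_true(row$status %in% c("confused_resolved", "NM"))
    }
  }
  expect_error(find_anchors(d_q, d_r, labs, K = 60), "smaller")
})

test_that("dispersion filtering drops minority-cluster anchors only", {
  entries <- data.frame(
    cell_id = sprintf("c%02d", 1:11),
    label = rep("A", 11),
    status = rep("anchor", 11), stringsAsFactors = FALSE)
  anchors <- structure(list(entries = entries, guide_labels = NULL,
                            params = list(K = 5)), class = "AnchorSet")
  guide <- c(rep(1L, 10), 2L)          # 1/11 < 0.15 in cluster 2
  filt <- filter_anchors(anchors, guide, r = 0.15)
  expect_equal(filt$entries$status[11], "unassigned")
  expect_true(all(filt$entries$status[1:10] == "anchor"))
  # all in one cluster: nothing removed
  filt2 <- filter_anchors(anchors, rep(1L, 11), r = 0.15)
  expect_true(all(filt2$entries$status == "anchor"))
  expect_error(filter_anchors(anchors, guide, r = 1.5), "\\[0, 1\\]")
  # anchor set can only shrink
  n_anchor <- function(a) sum(a$entries$status == "anchor")
  expect_lte(n_anchor(filt), n_anchor(anchors))
})

test_that("iterative annotation takes unanimous votes and NMs exact ties", {
  # 1 unassigned cell at the origin surrounded by anchors
  emb <- rbind(c(0, 0), cbind(cos(1:8), sin(1:8)))
  rownames(emb) <- sprintf("c%d", 1:9)
  mk <- function(labels) {
    structure(list(entries = data.frame(
      cell_id = rownames(emb),
      label = c(NA, labels),
      status = c("unassigned", rep("anchor", 8))),
      guide_labels = rep(1L, 9), params = list(K = 8)),
      class = "AnchorSet")
  }
  lab <- iterative_annotate(mk(rep("B", 8)), emb, K = 8)
  expect_equal(unname(lab[1]), "B")
  lab_tie <- iterative_annotate(mk(rep(c("B", "C"), 4)), emb, K = 8)
  expect_equal(unname(lab_tie[1]), "NM")
  expect_error(iterative_annotate(
    structure(list(entries = data.frame(cell_id = "c1", label = NA,
                                        status = "unassigned"),
                   guide_labels = 1L, params = list(K = 1)),
              class = "AnchorSet"), emb[1, , drop = FALSE]), "no anchors")
})

test_that("label transfer recovers generating labels on synthetic tissue", {
  set.seed(7)
  snap <- list(coords = cbind(runif(600, -50, 50), runif(600, -50, 50)),
               type_labels = rep(paste0("T", 0:5), each = 100))
  dat <- synth_expression(snap, synthetic_expression_config(),
                          n_ref_per_type = 150)
  ann <- annotate_spatial(dat$sp, dat$ref)
  acc <- mean(ann$sp$labels == dat$truth$labels)
  expect_gte(acc, 0.95)
  # output labels come from the reference label set plus the sentinel
  expect_true(all(ann$sp$labels %in% c(unique(dat$ref$cluster_labels), "NM")))
  ev <- evaluate_annotation(ann$sp$labels, dat$truth$labels)
  expect_gte(ev$ARI, 0.9)
})

test_that("the annotation pipeline is bit-identical under a fixed seed", {
  set.seed(8)
  snap <- list(coords = cbind(runif(300, -50, 50), runif(300, -50, 50)),
               type_labels = rep(paste0("T", 0:2), each = 100))
  dat <- synth_expression(snap, synthetic_expression_config(n_genes = 40),
                          n_ref_per_type = 80)
  set.seed(99); a1 <- annotate_spatial(dat$sp, dat$ref, K = 30, n_pcs = 30)
  set.seed(99); a2 <- annotate_spatial(dat$sp, dat$ref, K = 30, n_pcs = 30)
  expect_identical(a1$annotations, a2$annotations)
})

test_that("end-to-end annotation reproduces reference labels on identical modalities", {
  set.seed(9)
  toy <- make_toy_counts(n_per = 80, n_genes = 30)
  n <- nrow(toy$counts)
  sp <- spatial_dataset(toy$counts, cbind(runif(n, 0, 100), runif(n, 0, 100)))
  ref <- reference_dataset(toy$counts, toy$labels)
  ann <- annotate_spatial(sp, ref, K = 30, n_pcs = 20)
  expect_equal(unname(ann$sp$labels), toy$labels)
})
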