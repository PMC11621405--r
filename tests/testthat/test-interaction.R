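test_that("radius neighborhoods follow the distance rule on collinear points", {
  xy <- cbind(c(0, 3, 6), 0)
  g <- build_neighborhoods(xy, "radius_R", R = 5)
  expect_equal(g$adjacency[[2]], c(1L, 3L))   # inner point: both ends
  expect_equal(g$adjacency[[1]], 2L)
  expect_equal(g$adjacency[[3]], 2L)
})

test_that("Delaunay edges beyond the distance cutoff are discarded", {
  xy <- rbind(c(0, 0), c(10, 0), c(5, 8), c(155, 4))  # last cell is remote
  g <- build_neighborhoods(xy, "delaunay_R0", max_dist = 100)
  expect_false(4L %in% unlist(g$adjacency[1:3]))
  expect_equal(length(g$adjacency[[4]]), 0L)
  g_all <- build_neighborhoods(xy, "delaunay_R0", max_dist = Inf)
  expect_gt(length(g_all$adjacency[[4]]), 0L)
  expect_error(build_neighborhoods(xy[1:3, ], "delaunay_R0"), ">= 4")
})

test_that("radius adjacency equals O(n^2) brute-force thresholding", {
  set.seed(21)
  xy <- cbind(runif(200, 0, 40), runif(200, 0, 40))
  g <- build_neighborhoods(xy, "radius_R", R = 4)
  brute <- brute_radius_adj(xy, 4)
  for (i in seq_len(200)) expect_identical(g$adjacency[[i]], as.integer(brute[[i]]))
})

test_that("enrichment ratios match hand evaluation and the expectation limit", {
  # cell 1: neighbors 2,2,3 -> Lambda (2,1) with f = (0.5, 0.5)
  adj <- list(c(2L, 3L, 4L), integer(0), integer(0), integer(0))
  g <- structure(list(adjacency = adj, n = 4), class = "NeighborGraph")
  labels <- c("A", "A", "B", "B")  # f = (0.5, 0.5); cell 1 sees A,B,B
  feat <- enrichment_features(g, labels)
  # Lambda row for cell 1 is (1, 2): X = (1/(0.5*3), 2/(0.5*3))
  expect_equal(unname(feat$Lambda[1, ]), c(1L, 2L))
  expect_equal(unname(feat$X[1, ]), c(2 / 3, 4 / 3), tolerance = 1e-12)
  # a neighborhood composed exactly at the global frequencies -> all ones
  adj3 <- list(c(2L, 4L), integer(0), integer(0), integer(0))
  g3 <- structure(list(adjacency = adj3, n = 4), class = "NeighborGraph")
  feat3 <- enrichment_features(g3, c("A", "A", "B", "B"))
  expect_equal(unname(feat3$X[1, ]), c(1, 1), tolerance = 1e-12)
})

test_that("the enrichment identity sum_j f_j X_ij sum_k Lambda_ik = sum_j Lambda_ij holds", {
  set.seed(22)
  xy <- cbind(runif(150, 0, 30), runif(150, 0, 30))
  labels <- sample(c("A", "B", "C", "NM"), 150, replace = TRUE,
                   prob = c(.4, .3, .2, .1))
  g <- build_neighborhoods(xy, "radius_R", R = 5)
  feat <- enrichment_features(g, labels)
  lhs <- (feat$X %*% feat$f) * rowSums(feat$Lambda)
  expect_equal(as.numeric(lhs), rowSums(feat$Lambda), tolerance = 1e-9)
})

test_that("enrichment features equal a brute-force count-and-normalize loop", {
  set.seed(23)
  xy <- cbind(runif(180, 0, 30), runif(180, 0, 30))
  labels <- sample(c("A", "B", "C", "NM"), 180, replace = TRUE)
  g <- build_neighborhoods(xy, "radius_R", R = 4)
  feat <- enrichment_features(g, labels)
  brute <- brute_enrichment(g$adjacency, labels)
  expect_equal(unname(feat$X), unname(brute$X), tolerance = 1e-12)
  expect_equal(as.character(feat$y), brute$y)
})

test_that("no-signal features give chance-level confusion", {
  set.seed(24)
  diag_vals <- replicate(10, {
    n <- 240
    y <- factor(rep(c("A", "B", "C"), each = n / 3))
    feat <- structure(list(
      X = matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("A", "B", "C"))),
      Lambda = NULL, y = y, f = rep(1 / 3, 3)), class = "NicheFeatures")
    m <- fit_niche_classifier(feat, seed = sample.int(1e6, 1))
    mean(diag(m$confusion))
  })
  se <- sd(diag_vals) / sqrt(length(diag_vals))
  expect_lt(abs(mean(diag_vals) - 1 / 3), 3 * se + 0.05)
})

test_that("a planted niche association dominates the classifier coefficients", {
  set.seed(25)
  n <- 300
  y <- factor(rep(c("A", "B", "C"), each = n / 3))
  X <- matrix(abs(rnorm(n * 3, 1, 0.3)), n, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  X[y == "A", "B"] <- X[y == "A", "B"] + 3   # A cells enriched in B neighbors
  feat <- structure(list(X = X, Lambda = NULL, y = y, f = rep(1 / 3, 3)),
                    class = "NicheFeatures")
  m <- fit_niche_classifier(feat, seed = 1)
  expect_equal(names(which.max(m$beta["A", ])), "B")
  expect_true(all(abs(rowSums(m$confusion) - 1) < 1e-9))
})

test_that("classifier refits are bit-identical under a fixed seed", {
  set.seed(26)
  xy <- cbind(runif(200, 0, 20), runif(200, 0, 20))
  labels <- sample(c("A", "B"), 200, replace = TRUE)
  g <- build_neighborhoods(xy, "radius_R", R = 3)
  feat <- enrichment_features(g, labels)
  m1 <- fit_niche_classifier(feat, seed = 5)
  m2 <- fit_niche_classifier(feat, seed = 5)
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$C, m2$C)
  expect_identical(m1$confusion, m2$confusion)
})

test_that("interaction graph normalization and cutoff behave as specified", {
  beta <- rbind(A = c(A = 0.4, B = -0.2, C = 0.8),
                B = c(0, 0, 0),
                C = c(0.1, 0.2, 0.3))
  colnames(beta) <- c("A", "B", "C")
  model <- structure(list(beta = beta, types = c("A", "B", "C")),
                     class = "InteractionModel")
  g <- build_interaction_graph(model, c = 0.01)
  a_edges <- g$edges[g$edges$central == "A", ]
  expect_equal(sort(a_edges$weight), c(0.5, 1.0))   # hand normalization
  expect_false("B" %in% a_edges$niche)              # negative excluded
  expect_equal(nrow(g$edges[g$edges$central == "B", ]), 0L)  # all-zero row
  g_top <- build_interaction_graph(model, c = 1.0)
  expect_equal(nrow(g_top$edges), 0L)               # weights never exceed 1
  expect_true(all(abs(g$norm_beta) <= 1 + 1e-12))
})

test_that("domain z-scores match hand evaluation with population sd", {
  dom <- rep(c("d1", "d2"), each = 10)
  typ <- c(rep("A", 8), rep("B", 2), rep("A", 2), rep("B", 8))
  ds <- domain_consistency(dom, typ)
  expect_equal(unname(ds$Z), rbind(c(1, -1), c(-1, 1)), tolerance = 1e-12)
  # identical compositions: sigma = 0 rule gives Z = 0
  typ_same <- rep(c("A", "B"), 10)
  expect_warning(ds0 <- domain_consistency(dom, typ_same), "zero")
  expect_true(all(ds0$Z == 0))
  # composition equal to global frequencies: ratio 1 everywhere
  expect_equal(unname(ds0$ratio), matrix(1, 2, 2), tolerance = 1e-12)
})

test_that("best-match correlation identifies matching domain profiles", {
  dom <- rep(c("d1", "d2", "d3"), each = 30)
  set.seed(27)
  typ <- unlist(lapply(list(c(.7, .2, .1), c(.1, .7, .2), c(.2, .1, .7)),
                       function(p) sample(c("A", "B", "C"), 30, TRUE, p)))
  ds <- domain_consistency(dom, typ)
  bm <- best_match_correlation(ds, ds)
  expect_equal(unname(bm), rep(1, 3), tolerance = 1e-12)
})

test_that("annotation metrics satisfy identity, relabeling and a pair-count oracle", {
  labs <- c("A", "A", "B", "B", "C", "C")
  ev <- evaluate_annotation(labs, labs)
  expect_equal(ev$ARI, 1); expect_equal(ev$Jaccard, 1)
  expect_equal(ev$weighted_precision, 1)
  renamed <- c("X", "X", "Y", "Y", "Z", "Z")
  expect_equal(mclust::adjustedRandIndex(renamed, labs), 1)  # partition-invariant
  set.seed(28)
  for (rep in 1:5) {
    a <- sample(c("A", "B"), 6, replace = TRUE)
    b <- sample(c("A", "B", "C"), 6, replace = TRUE)
    expect_equal(mclust::adjustedRandIndex(a, b), brute_ari(a, b),
                 tolerance = 1e-12)
  }
  expect_error(evaluate_annotation(rep("X", 3), rep("Y", 3)), "shared")
})
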