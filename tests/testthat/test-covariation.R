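test_that("iNMF drives the objective to zero on exactly factorizable data", {
  set.seed(31)
  Ht <- matrix(runif(40 * 3), 40, 3)
  Wt <- matrix(runif(3 * 25), 3, 25)
  E <- Ht %*% Wt
  fit <- fit_inmf(E, E, LF = 3, lambda = 0, max_iter = 2000, tol = 1e-14)
  # residual negligible against the data scale (and against any generic
  # starting objective, which is of order sum(E^2))
  expect_lt(tail(fit$objective, 1), 1e-6 * sum(E^2))
})

test_that("iNMF at lambda = 0 with V frozen coincides with plain two-block NMF", {
  set.seed(32)
  E <- matrix(rexp(30 * 20), 30, 20)
  LF <- 3
  H0 <- matrix(runif(30 * LF), 30, LF)
  W0 <- matrix(runif(LF * 20), LF, 20)
  fit <- fit_inmf(E, E, LF = LF, lambda = 0, max_iter = 200, tol = 1e-12,
                  init = list(H_sc = H0, H_sp = H0, W = W0), fix_V = TRUE)
  expect_true(all(fit$V_sc == 0) && all(fit$V_sp == 0))
  # independent two-block NMF oracle: alternating exact NNLS via quadratic
  # programming on each small subproblem, same init and update order
  nnls1 <- function(M, b) {
    p <- length(b)
    best <- NULL
    for (code in 0:(2^p - 1)) {
      S <- which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
      x <- numeric(p)
      if (length(S) > 0) {
        xs <- tryCatch(solve(M[S, S, drop = FALSE], b[S]),
                       error = function(e) NULL)
        if (is.null(xs) || any(xs < -1e-9)) next
        x[S] <- xs
      }
      if (any(M %*% x - b < -1e-8 * (1 + max(abs(b))) &
                x <= 0)) next
      best <- x
      break
    }
    best
  }
  H <- H0; W <- W0
  for (it in 1:200) {
    M <- tcrossprod(W)
    B <- W %*% t(E)
    H <- t(sapply(seq_len(nrow(E)), function(j) nnls1(M, B[, j])))
    M2 <- 2 * crossprod(H)
    B2 <- 2 * crossprod(H, E)
    W <- sapply(seq_len(ncol(E)), function(g) nnls1(M2, B2[, g]))
    obj_now <- 2 * sum((E - H %*% W)^2)
    if (it > 1 && prev - obj_now < 1e-12 * prev) break
    prev <- obj_now
  }
  obj_nmf <- 2 * sum((E - H %*% W)^2)
  expect_equal(tail(fit$objective, 1), obj_nmf,
               tolerance = 1e-8)
})

test_that("iNMF objective is non-increasing and factors stay non-negative", {
  set.seed(33)
  for (s in 1:5) {
    E1 <- matrix(rexp(50 * 30), 50, 30)
    E2 <- matrix(rexp(45 * 30), 45, 30)
    fit <- fit_inmf(E1, E2, LF = 3, lambda = 2, seed = s, max_iter = 40)
    expect_true(all(diff(fit$objective) <= 1e-8 * fit$objective[1]))
    expect_true(min(fit$W, fit$H_sc, fit$H_sp, fit$V_sc, fit$V_sp) >= 0)
  }
  expect_error(fit_inmf(matrix(-1, 2, 2), matrix(1, 2, 2), LF = 1),
               "non-negative")
})

test_that("alignment score hits its closed-form limits", {
  expect_equal(alignment_score_value(10, 10, 100), 0)        # x = K
  expect_equal(alignment_score_value(10 / 100, 10, 100), 1)  # x = K/n
  expect_equal(alignment_score_value(5, 10, 100), 1 - 4.9 / 9.9,
               tolerance = 1e-10)
  expect_equal(alignment_score_value(5, 10, 100), 0.50505, tolerance = 1e-5)
  # fully separated clouds score ~0
  H1 <- matrix(rnorm(200 * 2), 200, 2)
  H2 <- matrix(rnorm(200 * 2, mean = 100), 200, 2)
  expect_equal(alignment_score(H1, H2, seed = 1), 0, tolerance = 1e-9)
  expect_error(alignment_score(H1[1, , drop = FALSE], H2[1, , drop = FALSE]),
               "at least 2")
})

test_that("lambda selection stabilizes immediately on identical modalities", {
  set.seed(34)
  E <- matrix(rexp(60 * 20), 60, 20)
  sel <- select_lambda(E, E, LF = 2, seed = 3, max_iter = 30)
  expect_lte(sel$lambda, 2)
  expect_true(all(is.finite(sel$path$score)))
  expect_true(all(sel$path$score <= 1 + 1e-9))
})

test_that("oNMF transfer recovers planted loadings and leaves W untouched", {
  set.seed(35)
  E1 <- matrix(rexp(60 * 30), 60, 30)
  fit <- fit_onmf_transfer(E1, E1, LF = 3, seed = 1)
  expect_true(all(diff(fit$kl_objective) <= 1e-8 * abs(fit$kl_objective[1])))
  H_true <- matrix(runif(20 * 3, 0.2, 2), 20, 3)
  E2 <- H_true %*% fit$W
  fit2 <- fit_onmf_transfer(E1, E2, LF = 3, seed = 1)
  expect_identical(fit$W, fit2$W)   # bit-identical W after transfer
  rel <- max(abs(fit2$H_sp - H_true)) / max(H_true)
  expect_lt(rel, 1e-3)
  # reference side identical too (transfer only touches H_sp)
  expect_identical(fit$H_sc, fit2$H_sc)
})

test_that("factor entropy hits closed forms and ordering is a pure permutation", {
  mk <- function(H) {
    structure(list(W = matrix(runif(ncol(H) * 4), ncol(H), 4),
                   H_sc = H, H_sp = H, V_sc = NULL, V_sp = NULL,
                   LF = ncol(H), method = "onmf"), class = "FactorModel")
  }
  H <- cbind(rep(1, 4), c(1, 0, 0, 0), c(0.75, 0.25, 0, 0))
  m <- entropy_order(mk(H))
  expect_equal(unname(m$entropy),
               sort(c(1, 0, -sum(c(.75, .25) * log2(c(.75, .25))) / log2(4))),
               tolerance = 1e-10)
  expect_equal(min(m$entropy), 0)   # one-hot factor
  expect_equal(max(m$entropy), 1)   # uniform factor
  # two-cell column (0.75, 0.25) evaluates to the hand value 0.8113
  H2 <- cbind(c(0.75, 0.25), c(1, 1))
  m2 <- entropy_order(mk(H2))
  expect_equal(m2$entropy[[1]], 0.8113, tolerance = 1e-4)
  # reconstruction is unchanged by the permutation
  set.seed(36)
  E1 <- matrix(rexp(30 * 15), 30, 15)
  fit <- fit_onmf_transfer(E1, E1, LF = 3, seed = 2)
  rec_before <- fit$H_sc %*% fit$W
  ord <- entropy_order(fit)
  expect_equal(ord$H_sc %*% ord$W, rec_before, tolerance = 1e-12)
  expect_true(all(diff(ord$entropy) >= 0))
})

test_that("ridge covariation recovers a planted coupling of 2.0 and ranks it first", {
  set.seed(37)
  n <- 1000
  coordsA <- cbind(runif(n, -50, 50), runif(n, -50, 50))
  labels <- c(rep("A", n), rep("B", 3 * n))
  coords <- rbind(coordsA,
                  coordsA[rep(1:n, each = 3), ] +
                    matrix(rnorm(6 * n, 0, 0.4), ncol = 2))
  g <- build_neighborhoods(coords, "radius_R", R = 1.5)
  actB <- rnorm(3 * n)
  HB <- cbind(actB, rnorm(3 * n))          # factor 2 is pure noise
  mB <- vapply(1:n, function(i) {
    nb <- g$adjacency[[i]]
    mean(actB[nb[nb > n] - n])
  }, 0)
  HA <- cbind(2 * mB + rnorm(n, 0, 0.1))
  tab <- regress_covariation("A", list(A = HA, B = HB), g, labels,
                             niche_types = "B")
  b1 <- tab[tab$niche_factor == 1, ]
  expect_lt(abs(b1$alpha_raw - 2), 0.2)          # within 10 %
  expect_equal(which.max(abs(tab$alpha)), 1L)    # coupling ranked first
  expect_equal(b1$S, 1)
  expect_lt(b1$p, 1e-10)
  expect_true(all(tab$p > 0 & tab$p <= 1))
})

test_that("large ridge penalties shrink coefficients strictly", {
  set.seed(38)
  n <- 120
  coordsA <- cbind(runif(n, -50, 50), runif(n, -50, 50))
  labels <- c(rep("A", n), rep("B", n))
  coords <- rbind(coordsA, coordsA + matrix(rnorm(2 * n, 0, 0.3), ncol = 2))
  g <- build_neighborhoods(coords, "radius_R", R = 1.5)
  HB <- matrix(rnorm(n), ncol = 1)
  HA <- matrix(rnorm(n) + 0.5 * HB[, 1], ncol = 1)
  t_small <- regress_covariation("A", list(A = HA, B = HB), g, labels,
                                 niche_types = "B", eta_grid = 2^-10)
  t_big <- regress_covariation("A", list(A = HA, B = HB), g, labels,
                               niche_types = "B", eta_grid = 2^10)
  expect_lt(sum(abs(t_big$alpha)), sum(abs(t_small$alpha)))
})

test_that("interaction-graph gating selects the niche types for regression", {
  set.seed(39)
  beta <- rbind(A = c(A = 0, B = 1, C = 0.001), B = c(0, 0, 0), C = c(0, 0, 0))
  colnames(beta) <- c("A", "B", "C")
  model <- structure(list(beta = beta, types = c("A", "B", "C")),
                     class = "InteractionModel")
  ig <- build_interaction_graph(model, c = 0.01)
  n <- 60
  coords <- cbind(runif(3 * n, 0, 10), runif(3 * n, 0, 10))
  labels <- rep(c("A", "B", "C"), each = n)
  g <- build_neighborhoods(coords, "radius_R", R = 3)
  H <- function() matrix(rnorm(n), ncol = 1)
  tab <- regress_covariation("A", list(A = H(), B = H(), C = H()), g, labels,
                             interaction = ig, cutoff = 0.1)
  expect_true(all(tab$niche_type == "B"))   # C fell below the cutoff
  tab2 <- suppressMessages(regress_covariation(
    "B", list(A = H(), B = H(), C = H()), g, labels,
    interaction = ig, cutoff = 0.1))
  expect_equal(nrow(tab2), 0L)              # no niche type passes for B
})

test_that("self-transfer reproduces the reference loadings on factorizable data", {
  # when both modalities coincide and the data are exactly rank-LF, the
  # KL-fitted reference loadings and the Frobenius-transferred spatial
  # loadings share the same minimizer
  set.seed(70)
  Ht <- matrix(runif(50 * 3, 0.2, 2), 50, 3)
  Wt <- matrix(runif(3 * 30, 0.1, 1), 3, 30)
  E <- Ht %*% Wt
  fit <- fit_onmf_transfer(E, E, LF = 3, tol = 1e-6, max_iter = 5000)
  expect_lt(max(abs(fit$H_sp - fit$H_sc)) / max(fit$H_sc), 1e-3)
})
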