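EPS <- 1e-10

#' Scale a non-negative expression matrix for factorization
#'
#' Divides each gene (column) by its standard deviation without centering,
#' preserving non-negativity — the required preprocessing before the
#' factorization routines. Constant genes are left unscaled.
#'
#' @param E non-negative cells x genes matrix.
#' @return scaled matrix.
#' @export
scale_nonneg <- function(E) {
  E <- as.matrix(E)
  s <- apply(E, 2, sd)
  s[s == 0] <- 1
  sweep(E, 2, s, "/")
}

inmf_objective <- function(E1, H1, V1, E2, H2, V2, W, lambda) {
  sum((E1 - H1 %*% (W + V1))^2) + lambda * sum((H1 %*% V1)^2) +
    sum((E2 - H2 %*% (W + V2))^2) + lambda * sum((H2 %*% V2)^2)
}

# Solve m independent non-negative least-squares problems
#   min_x 0.5 x' M x - b' x,  x >= 0
# sharing one positive-definite LF x LF Gram matrix M; B holds the b vectors
# as columns. Exact solution by exhaustive active-set enumeration (KKT check
# per subset), which is cheap and vectorizes across problems for the small
# factor counts used here.
nnls_shared <- function(M, B, tol = 1e-10) {
  p <- nrow(M)
  m <- ncol(B)
  X <- matrix(0, p, m)
  # x = 0 is optimal iff b <= 0
  unsolved <- colSums(B > tol) > 0
  if (!any(unsolved)) return(X)
  scale_ref <- max(abs(B)) + 1
  subsets <- lapply(seq_len(2^p - 1), function(code)
    which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0))
  subsets <- subsets[order(vapply(subsets, length, 1L))]
  for (S in subsets) {
    idx <- which(unsolved)
    if (length(idx) == 0) break
    xs <- tryCatch(solve(M[S, S, drop = FALSE], B[S, idx, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(xs)) next
    xs <- matrix(xs, length(S), length(idx))
    feas <- colSums(xs < -tol * scale_ref) == 0
    comp <- setdiff(seq_len(p), S)
    if (length(comp) > 0) {
      grad <- M[comp, S, drop = FALSE] %*% xs - B[comp, idx, drop = FALSE]
      feas <- feas & colSums(grad < -tol * scale_ref) == 0
    }
    ok <- idx[feas]
    if (length(ok) > 0) {
      X[S, ok] <- pmax(xs[, feas, drop = FALSE], 0)
      unsolved[ok] <- FALSE
    }
  }
  if (any(unsolved)) {
    # numerically marginal problems: fall back to a ridge-stabilized solve
    idx <- which(unsolved)
    Mr <- M + diag(1e-10 * max(diag(M)), p)
    X[, idx] <- pmax(solve(Mr, B[, idx, drop = FALSE]), 0)
  }
  X
}

#' Integrative NMF across the reference and spatial modality
#'
#' Factorizes both cell-type-specific expression matrices over the shared
#' gene set into shared gene factors `W`, per-modality cell loadings
#' `H_sc`/`H_sp`, and per-modality heterogeneity terms `V_sc`/`V_sp`, by
#' minimizing
#' `||E_sc - H_sc (W + V_sc)||_F^2 + lambda ||H_sc V_sc||_F^2 +
#'  ||E_sp - H_sp (W + V_sp)||_F^2 + lambda ||H_sp V_sp||_F^2`
#' over non-negative matrices. Solved by alternating non-negative least
#' squares (each block is minimized exactly, so the objective is
#' non-increasing per iteration); converged when the relative objective
#' decrease falls below `tol` or after `max_iter` iterations.
#'
#' @param E_sc,E_sp non-negative cells x genes matrices over identical
#'   genes, scaled but not centered (see [scale_nonneg()]).
#' @param LF number of latent factors (default 3; 3-5 is the practical range
#'   for within-cell-type variability).
#' @param lambda heterogeneity penalty; larger values force more of the
#'   modality-specific signal into `V` (default 0).
#' @param seed RNG seed; the default NNDSVDa initialization is deterministic,
#'   so this only matters for user-supplied random `init` matrices.
#' @param max_iter,tol convergence controls (defaults 100, 1e-6).
#' @param init optional list with entries `W`, `H_sc`, `H_sp`, `V_sc`,
#'   `V_sp` overriding the random initialization (e.g. `V = 0` matrices).
#' @param fix_V freeze the heterogeneity terms at their initial value
#'   (zero matrices unless given in `init`); with `lambda = 0` and
#'   `fix_V = TRUE` the model reduces exactly to two-block NMF with a
#'   shared basis.
#' @return A `FactorModel`: list with `W` (LF x genes), `H_sc`, `H_sp`
#'   (cells x LF), `V_sc`, `V_sp`, `lambda`, `LF`, `objective` (per
#'   iteration), `method = "inmf"`.
#' @export
fit_inmf <- function(E_sc, E_sp, LF = 3, lambda = 0, seed = NULL,
                     max_iter = 100, tol = 1e-6, init = NULL,
                     fix_V = FALSE) {
  E1 <- as.matrix(E_sc); E2 <- as.matrix(E_sp)
  if (min(E1) < 0 || min(E2) < 0) stop("inputs must be non-negative")
  if (ncol(E1) != ncol(E2)) stop("modalities must share the gene set")
  G <- ncol(E1)
  if (LF > min(nrow(E1), nrow(E2), G))
    stop("LF exceeds the smallest input dimension")
  if (!is.null(seed)) set.seed(seed)
  # deterministic NNDSVDa initialization (per modality for the loadings,
  # reference side for the shared basis); V starts at zero — the first ANLS
  # sweep moves it off zero wherever the data demand it
  ini1 <- nndsvda_init(E1, LF)
  H1 <- init$H_sc %||% ini1$H
  H2 <- init$H_sp %||% nndsvda_init(E2, LF)$H
  W  <- init$W    %||% ini1$W
  V1 <- init$V_sc %||% matrix(0, LF, G)
  V2 <- init$V_sp %||% matrix(0, LF, G)
  obj <- inmf_objective(E1, H1, V1, E2, H2, V2, W, lambda)
  trace <- obj
  # alternating non-negative least squares: each block (H1, H2, V1, V2, W)
  # is minimized exactly, so the objective is non-increasing
  for (it in seq_len(max_iter)) {
    P1 <- W + V1
    H1 <- t(nnls_shared(tcrossprod(P1) + lambda * tcrossprod(V1),
                        P1 %*% t(E1)))
    P2 <- W + V2
    H2 <- t(nnls_shared(tcrossprod(P2) + lambda * tcrossprod(V2),
                        P2 %*% t(E2)))
    HtH1 <- crossprod(H1); HtE1 <- crossprod(H1, E1)
    HtH2 <- crossprod(H2); HtE2 <- crossprod(H2, E2)
    if (!fix_V) {
      V1 <- nnls_shared((1 + lambda) * HtH1, HtE1 - HtH1 %*% W)
      V2 <- nnls_shared((1 + lambda) * HtH2, HtE2 - HtH2 %*% W)
    }
    W <- nnls_shared(HtH1 + HtH2,
                     HtE1 - HtH1 %*% V1 + HtE2 - HtH2 %*% V2)
    new_obj <- inmf_objective(E1, H1, V1, E2, H2, V2, W, lambda)
    trace <- c(trace, new_obj)
    if (obj - new_obj < tol * abs(obj)) { obj <- new_obj; break }
    obj <- new_obj
  }
  rownames(H1) <- rownames(E1); rownames(H2) <- rownames(E2)
  colnames(W) <- colnames(V1) <- colnames(V2) <- colnames(E1)
  structure(list(W = W, H_sc = H1, H_sp = H2, V_sc = V1, V_sp = V2,
                 lambda = lambda, LF = LF, objective = trace,
                 method = "inmf"),
            class = "FactorModel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.FactorModel <- function(x, ...) {
  cat(sprintf("FactorModel (%s): %d factors, %d genes, %d + %d cells\n",
              x$method, x$LF, ncol(x$W), nrow(x$H_sc), nrow(x$H_sp)))
  invisible(x)
}

#' Modality alignment score in factor space
#'
#' Measures how well the two modalities mix in the shared factor space: the
#' larger loading matrix is downsampled to the smaller one's cell count `n`,
#' the two are merged, and for each cell the number of same-dataset cells
#' among its `K = max(1, round(0.01 n))` nearest neighbors is averaged into
#' `xbar`. The score is `1 - (xbar - K/n) / (K - K/n)`: 1 for ideal mixing,
#' 0 when the datasets are fully separated.
#'
#' @param H_sc,H_sp cell loading matrices with the same number of factors.
#' @param seed RNG seed for the downsampling.
#' @return scalar score.
#' @export
alignment_score <- function(H_sc, H_sp, seed = NULL) {
  if (ncol(H_sc) != ncol(H_sp)) stop("factor counts differ")
  if (!is.null(seed)) set.seed(seed)
  n <- min(nrow(H_sc), nrow(H_sp))
  if (n < 2) stop("need at least 2 cells per modality")
  sub <- function(H) {
    if (nrow(H) > n) H[sample.int(nrow(H), n), , drop = FALSE] else H
  }
  A <- sub(as.matrix(H_sc)); B <- sub(as.matrix(H_sp))
  merged <- rbind(A, B)
  origin <- rep(c(1L, 2L), each = n)
  K <- max(1L, round(0.01 * n))
  nn <- RANN::nn2(merged, k = min(K + 1, 2 * n))$nn.idx[, -1, drop = FALSE]
  same <- rowMeans(matrix(origin[nn], nrow(merged)) == origin) * ncol(nn)
  xbar <- mean(same)
  # mixing beyond the chance expectation (xbar < K/n, possible when paired
  # cells coincide in factor space) is clipped to the ideal score
  min(alignment_score_value(xbar, K, n), 1)
}

#' Alignment score from its sufficient statistics
#'
#' The closed form `1 - (xbar - K/n) / (K - K/n)` underlying
#' [alignment_score()]: `xbar` is the mean same-dataset neighbor count among
#' `K` nearest neighbors, `n` the per-dataset cell count after
#' downsampling.
#'
#' @param xbar mean same-dataset neighbor count.
#' @param K neighborhood size.
#' @param n per-dataset cell count.
#' @return scalar score (1 = ideal mixing, 0 = full separation).
#' @export
alignment_score_value <- function(xbar, K, n) {
  1 - (xbar - K / n) / (K - K / n)
}

#' Select the iNMF heterogeneity penalty by alignment-score stabilization
#'
#' Fits [fit_inmf()] for `lambda = 0, 2, 4, ...` and stops as soon as the
#' alignment score changes by less than `tol` between consecutive values,
#' returning that `lambda` and the full path. If no stabilization occurs by
#' `lambda_max`, the last value is returned with a warning.
#'
#' @param E_sc,E_sp as in [fit_inmf()].
#' @param LF number of factors.
#' @param seed RNG seed (controls initialization and downsampling).
#' @param tol stabilization threshold on the score difference
#'   (default 0.001).
#' @param lambda_max largest penalty tried (default 40).
#' @param ... passed to [fit_inmf()].
#' @return list with `lambda`, `path` (data frame `lambda`, `score`), and
#'   `model` (the fit at the selected `lambda`).
#' @export
select_lambda <- function(E_sc, E_sp, LF = 3, seed = NULL, tol = 0.001,
                          lambda_max = 40, ...) {
  lambdas <- seq(0, lambda_max, by = 2)
  scores <- numeric(0)
  models <- list()
  chosen <- NA
  for (i in seq_along(lambdas)) {
    fit <- fit_inmf(E_sc, E_sp, LF = LF, lambda = lambdas[i], seed = seed, ...)
    scores[i] <- alignment_score(fit$H_sc, fit$H_sp, seed = seed)
    models[[i]] <- fit
    if (i > 1 && abs(scores[i] - scores[i - 1]) < tol) { chosen <- i; break }
  }
  if (is.na(chosen)) {
    warning("alignment score did not stabilize by lambda = ", lambda_max)
    chosen <- length(lambdas[seq_along(scores)])
  }
  list(lambda = lambdas[chosen],
       path = data.frame(lambda = lambdas[seq_along(scores)], score = scores),
       model = models[[chosen]])
}

# NNDSVD initialization, "a" variant (zeros replaced by the data mean)
nndsvda_init <- function(E, LF) {
  sv <- svd(E, nu = LF, nv = LF)
  H <- matrix(0, nrow(E), LF)
  W <- matrix(0, LF, ncol(E))
  H[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  W[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  for (k in seq_len(LF)[-1]) {
    u <- sv$u[, k]; v <- sv$v[, k]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg && npos > 0) {
      H[, k] <- sqrt(sv$d[k] * npos) * up / sqrt(sum(up^2))
      W[k, ] <- sqrt(sv$d[k] * npos) * vp / sqrt(sum(vp^2))
    } else if (nneg > 0) {
      H[, k] <- sqrt(sv$d[k] * nneg) * un / sqrt(sum(un^2))
      W[k, ] <- sqrt(sv$d[k] * nneg) * vn / sqrt(sum(vn^2))
    }
  }
  avg <- mean(E)
  H[H <= 0] <- avg
  W[W <= 0] <- avg
  list(H = H, W = W)
}

kl_divergence <- function(X, Y) {
  pos <- X > 0
  sum(X[pos] * log(X[pos] / Y[pos])) - sum(X) + sum(Y)
}

#' Ordinary NMF on the reference with fixed-basis transfer to spatial cells
#'
#' Learns `W` and `H_sc` from the reference matrix alone by
#' Kullback-Leibler NMF with multiplicative updates and NNDSVDa
#' initialization (at most `max_iter` iterations). The spatial loadings
#' `H_sp` are then obtained under the frozen `W` by the Frobenius
#' multiplicative update iterated until the relative change of `H_sp` falls
#' below `transfer_tol`; `W` is bit-identical before and after the
#' transfer. Preferable over [fit_inmf()] when the spatial modality suffers
#' from segmentation spill-over or background that would contaminate
#' jointly learned factors.
#'
#' @param E_sc,E_sp non-negative cells x genes matrices over identical
#'   genes.
#' @param LF number of factors (default 3).
#' @param seed RNG seed (transfer initialization).
#' @param max_iter KL-NMF iteration cap (default 1000).
#' @param tol relative KL-objective tolerance (default 1e-4).
#' @param transfer_tol relative-change tolerance of the fixed-W update
#'   (default 1e-6).
#' @return A `FactorModel` with `method = "onmf"`; `kl_objective` holds the
#'   per-iteration KL divergence. Zero rows of `E_sp` get zero loadings
#'   (with a warning).
#' @export
fit_onmf_transfer <- function(E_sc, E_sp, LF = 3, seed = NULL,
                              max_iter = 1000, tol = 1e-4,
                              transfer_tol = 1e-6) {
  E1 <- as.matrix(E_sc); E2 <- as.matrix(E_sp)
  if (min(E1) < 0 || min(E2) < 0) stop("inputs must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  ini <- nndsvda_init(E1, LF)
  H <- ini$H; W <- ini$W
  Y <- H %*% W
  obj <- kl_divergence(E1, Y)
  trace <- obj
  for (it in seq_len(max_iter)) {
    R <- E1 / (Y + EPS)
    H <- H * (R %*% t(W)) / (matrix(rowSums(W), nrow(H), ncol(H),
                                    byrow = TRUE) + EPS)
    Y <- H %*% W
    R <- E1 / (Y + EPS)
    W <- W * (t(H) %*% R) / (matrix(colSums(H), nrow(W), ncol(W)) + EPS)
    Y <- H %*% W
    new_obj <- kl_divergence(E1, Y)
    trace <- c(trace, new_obj)
    if (obj - new_obj < tol * abs(obj)) { obj <- new_obj; break }
    obj <- new_obj
  }
  # fixed-W Frobenius transfer of the spatial loadings
  zero_rows <- rowSums(E2) == 0
  if (any(zero_rows))
    warning(sum(zero_rows), " zero spatial rows get zero loadings")
  H2 <- matrix(runif(nrow(E2) * LF, 0, sqrt(mean(E2[!zero_rows, ]) / LF)),
               nrow(E2), LF)
  WWt <- W %*% t(W)
  EWt <- E2 %*% t(W)
  for (it in seq_len(5000)) {
    H2_new <- H2 * EWt / (H2 %*% WWt + EPS)
    delta <- max(abs(H2_new - H2)) / max(max(abs(H2)), EPS)
    H2 <- H2_new
    if (delta < transfer_tol) break
  }
  H2[zero_rows, ] <- 0
  rownames(H) <- rownames(E1); rownames(H2) <- rownames(E2)
  colnames(W) <- colnames(E1)
  structure(list(W = W, H_sc = H, H_sp = H2, V_sc = NULL, V_sp = NULL,
                 lambda = NA_real_, LF = LF, kl_objective = trace,
                 method = "onmf"),
            class = "FactorModel")
}

#' Normalized factor entropy and entropy ordering
#'
#' Each reference loading column is normalized to a probability vector `p`
#' and scored by `E = -sum(p log2 p) / log2(n_cells)`, which lies in
#' `[0, 1]`: 0 for a one-hot factor (maximally specific), 1 for a uniform
#' factor (no structure). Factors of `H_sc`, `H_sp`, `W` (and `V` when
#' present) are then jointly permuted by increasing entropy, so factor 1 is
#' always the most structured one. A pure permutation: reconstructions are
#' unchanged.
#'
#' @param model a [fit_inmf()] or [fit_onmf_transfer()] model.
#' @return the model with reordered factors and an `entropy` field (sorted
#'   increasing). An all-zero column is assigned entropy 1 with a warning.
#' @export
entropy_order <- function(model) {
  H <- model$H_sc
  ent <- apply(H, 2, function(col) {
    s <- sum(col)
    if (s == 0) return(NA_real_)
    p <- col / s
    p <- p[p > 0]
    -sum(p * log2(p)) / log2(length(col))
  })
  if (anyNA(ent)) {
    warning("all-zero factor column(s); entropy set to 1")
    ent[is.na(ent)] <- 1
  }
  ord <- order(ent)
  model$H_sc <- model$H_sc[, ord, drop = FALSE]
  model$H_sp <- model$H_sp[, ord, drop = FALSE]
  model$W <- model$W[ord, , drop = FALSE]
  if (!is.null(model$V_sc)) model$V_sc <- model$V_sc[ord, , drop = FALSE]
  if (!is.null(model$V_sp)) model$V_sp <- model$V_sp[ord, , drop = FALSE]
  model$entropy <- ent[ord]
  model
}

# closed-form leave-one-out mean squared error for ridge (no intercept,
# standardized inputs); leverages h_ii = rowSums((X A) * X) to stay O(n p^2)
ridge_loocv_mse <- function(X, y, eta) {
  A <- solve(crossprod(X) + diag(eta, ncol(X)))
  XA <- X %*% A
  h <- pmin(rowSums(XA * X), 1 - 1e-12)
  fitted <- XA %*% crossprod(X, y)
  mean(((y - fitted) / (1 - h))^2)
}

ridge_fit <- function(X, y, eta) {
  p <- ncol(X)
  XtX <- crossprod(X)
  A <- solve(XtX + diag(eta, p))
  alpha <- A %*% crossprod(X, y)
  fitted <- X %*% alpha
  tr_hat <- sum(rowSums((X %*% A) * X))
  df <- nrow(X) - tr_hat
  sigma2 <- sum((y - fitted)^2) / max(df, 1)
  covm <- sigma2 * A %*% XtX %*% A   # sandwich covariance
  se <- sqrt(pmax(diag(covm), 0))
  tstat <- as.vector(alpha) / pmax(se, .Machine$double.eps)
  p_val <- pmax(2 * pt(-abs(tstat), df = max(df, 1)), .Machine$double.xmin)
  list(alpha = as.vector(alpha), se = se, t = tstat, p = p_val, df = df)
}

#' Covariation of central-cell factors with niche-averaged factors
#'
#' For every instance of the central cell type, each retained niche type's
#' loadings are averaged over its members in the instance's neighborhood,
#' and every central factor is ridge-regressed on these niche-averaged
#' factors. The penalty
#' `eta` is selected per regression from `2^-10 ... 2^10` by closed-form
#' leave-one-out mean squared error; response and predictors are z-scored
#' before fitting; p-values come from two-tailed t-statistics under the
#' ridge sandwich covariance with effective degrees of freedom
#' `n - trace(hat)`.
#'
#' @param central central cell type name.
#' @param factors named list (by cell type) of spatial loading matrices
#'   (cells x LF, rownames = cell ids) or `FactorModel`s (their `H_sp` is
#'   used). Must contain `central` and every retained niche type.
#' @param graph [build_neighborhoods()] graph over all spatial cells.
#' @param labels per-cell type labels aligned with the graph.
#' @param interaction optional [build_interaction_graph()]; niche types `m`
#'   are retained when their normalized coefficient for predicting the
#'   central type exceeds `cutoff`. Without it, every type in `factors` is
#'   used.
#' @param cutoff interaction-graph cutoff `c` (default 0.1).
#' @param niche_types explicit niche type selection, overriding both the
#'   interaction graph and the default (all types in `factors`).
#' @param eta_grid ridge penalty grid (default `2^(-10:10)`).
#' @param min_instances minimum usable central instances (default 10).
#' @return A `CovariationTable` data frame: `central_type`,
#'   `central_factor`, `niche_type`, `niche_factor`, `alpha` (standardized
#'   ridge coefficient), `alpha_raw` (original response scale), `p`, `S`
#'   (`alpha / max |alpha|` within the regression), `n_pairs` (central
#'   cells with >= 1 `m`-neighbor), `eta`, `n_instances`. Empty (with the
#'   documented columns) when no niche type passes the cutoff.
#' @export
regress_covariation <- function(central, factors, graph, labels,
                                interaction = NULL, cutoff = 0.1,
                                niche_types = NULL,
                                eta_grid = 2^(-10:10), min_instances = 10) {
  labels <- as.character(labels)
  if (length(labels) != graph$n) stop("labels length != graph cells")
  get_H <- function(x) if (inherits(x, "FactorModel")) x$H_sp else as.matrix(x)
  empty <- data.frame(central_type = character(), central_factor = integer(),
                      niche_type = character(), niche_factor = integer(),
                      alpha = numeric(), alpha_raw = numeric(), p = numeric(),
                      S = numeric(), n_pairs = integer(), eta = numeric(),
                      n_instances = integer())
  if (!central %in% names(factors)) stop("no factors for central type")
  if (is.null(niche_types)) {
    if (!is.null(interaction)) {
      nb <- interaction$norm_beta[central, ]
      niche_types <- names(nb)[nb > cutoff]
    } else {
      niche_types <- names(factors)
    }
  }
  niche_types <- intersect(niche_types, names(factors))
  if (length(niche_types) == 0) {
    message("no niche type passes cutoff ", cutoff, " for ", central)
    return(structure(empty, class = c("CovariationTable", "data.frame")))
  }
  Hc <- get_H(factors[[central]])
  inst <- which(labels == central)
  if (nrow(Hc) != length(inst))
    stop("central loadings rows must match central cells in graph order")
  # niche-averaged design blocks; NA when an instance has no m-neighbor
  blocks <- list(); n_pairs <- integer(0)
  for (m in niche_types) {
    Hm <- get_H(factors[[m]])
    m_cells <- which(labels == m)
    if (nrow(Hm) != length(m_cells))
      stop("loadings rows must match type cells in graph order for ", m)
    pos <- setNames(seq_along(m_cells), m_cells)
    B <- matrix(NA_real_, length(inst), ncol(Hm))
    for (r in seq_along(inst)) {
      nbr <- graph$adjacency[[inst[r]]]
      nbr_m <- nbr[labels[nbr] == m]
      if (length(nbr_m) > 0)
        B[r, ] <- colMeans(Hm[pos[as.character(nbr_m)], , drop = FALSE])
    }
    n_pairs[m] <- sum(!is.na(B[, 1]))
    colnames(B) <- paste0(m, ".F", seq_len(ncol(Hm)))
    blocks[[m]] <- B
  }
  design <- do.call(cbind, blocks)
  ok <- complete.cases(design)
  if (sum(ok) < min_instances) {
    message("only ", sum(ok), " usable instances of ", central,
            "; returning empty table")
    return(structure(empty, class = c("CovariationTable", "data.frame")))
  }
  design <- design[ok, , drop = FALSE]
  Hc_use <- Hc[ok, , drop = FALSE]
  n <- nrow(design); p <- ncol(design)
  grid <- eta_grid
  if (n < p) {
    warning("fewer instances (", n, ") than predictors (", p,
            "); eta floor raised to 1")
    grid <- grid[grid >= 1]
  }
  x_sd <- apply(design, 2, sd)
  Xs <- standardize_cols(design)
  out <- list()
  meta <- data.frame(niche_type = rep(niche_types,
                                      vapply(blocks, ncol, 1L)),
                     niche_factor = unlist(lapply(blocks, function(b)
                       seq_len(ncol(b)))), row.names = NULL)
  for (i in seq_len(ncol(Hc_use))) {
    y <- Hc_use[, i]
    y_sd <- sd(y)
    ys <- if (y_sd > 0) (y - mean(y)) / y_sd else y - mean(y)
    mses <- vapply(grid, function(e) ridge_loocv_mse(Xs, ys, e), 0)
    eta <- grid[which.min(mses)]
    fit <- ridge_fit(Xs, ys, eta)
    S <- if (max(abs(fit$alpha)) > 0) fit$alpha / max(abs(fit$alpha)) else
      fit$alpha
    out[[i]] <- data.frame(
      central_type = central, central_factor = i,
      niche_type = meta$niche_type, niche_factor = meta$niche_factor,
      alpha = fit$alpha,
      alpha_raw = fit$alpha * y_sd / ifelse(x_sd > 0, x_sd, 1),
      p = fit$p, S = S,
      n_pairs = as.integer(n_pairs[meta$niche_type]),
      eta = eta, n_instances = n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("CovariationTable", "data.frame"))
}
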