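#' Configuration for the particle-based tissue simulator
#'
#' Cells are modeled as 2D particles whose pairwise attraction is encoded in
#' a symmetric Lennard-Jones well-depth matrix `eps`: larger `eps[a, b]`
#' makes types `a` and `b` co-localize. All quantities are in reduced LJ
#' units.
#'
#' @param n_types number of cell types (default 6).
#' @param cells_per_type particles per type (default 200).
#' @param box simulation box `c(lo, hi)` per axis, periodic (default
#'   `c(-50, 50)`).
#' @param eps symmetric `n_types x n_types` well-depth matrix (default all
#'   1).
#' @param sigma particle size — the repulsive core diameter (default 2).
#' @param rc interaction cutoff range (default 5).
#' @param temperature reduced thermostat temperature (default 1).
#' @param mass particle mass (default 1).
#' @param dt integration timestep (default 0.005).
#' @param damping Langevin friction time (default 1).
#' @param n_steps integration steps (default 4e4, i.e. 200 LJ time units —
#'   past the kinetic-temperature and neighborhood-composition plateau at
#'   this density).
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_types = 6, cells_per_type = 200,
                              box = c(-50, 50), eps = NULL, sigma = 2,
                              rc = 5, temperature = 1, mass = 1, dt = 0.005,
                              damping = 1, n_steps = 4e4) {
  if (is.null(eps)) eps <- matrix(1, n_types, n_types)
  eps <- as.matrix(eps)
  if (!isSymmetric(unname(eps)) || any(eps <= 0))
    stop("eps must be symmetric positive")
  if (nrow(eps) != n_types) stop("eps dimension != n_types")
  if (rc <= sigma) stop("rc must exceed sigma")
  if (n_steps <= 0) stop("n_steps must be positive")
  structure(list(n_types = n_types, cells_per_type = cells_per_type,
                 box = box, eps = eps, sigma = sigma, rc = rc,
                 temperature = temperature, mass = mass, dt = dt,
                 damping = damping, n_steps = as.integer(n_steps)),
            class = "SimulationConfig")
}

#' Benchmark scenario configurations
#'
#' Two ground-truth affinity layouts over six types `T0 ... T5` of 200
#' cells each (`sigma = 2`, `rc = 5`, box `[-50, 50]^2`, `T = 1`, `m = 1`;
#' all other pairs at `eps = 1`):
#' * `scenario1`: `eps(T0,T2) = 3`, `eps(T3,T5) = 5`.
#' * `scenario2`: additionally `eps(T2,T3) = 10`, `eps(T1,T3) = 8`,
#'   creating a strict affinity ordering around T3.
#'
#' @param name `"scenario1"` or `"scenario2"`.
#' @return A [simulation_config()].
#' @export
scenario_config <- function(name = c("scenario1", "scenario2")) {
  name <- match.arg(name)
  eps <- matrix(1, 6, 6, dimnames = list(paste0("T", 0:5), paste0("T", 0:5)))
  set_pair <- function(a, b, v) {
    eps[a, b] <<- v; eps[b, a] <<- v
  }
  set_pair("T0", "T2", 3)
  set_pair("T3", "T5", 5)
  if (name == "scenario2") {
    set_pair("T2", "T3", 10)
    set_pair("T1", "T3", 8)
  }
  simulation_config(n_types = 6, cells_per_type = 200, eps = eps)
}

#' Simulate a tissue snapshot by Langevin dynamics
#'
#' Places one particle per cell uniformly at random without core overlap,
#' assigns Maxwell-Boltzmann velocities at the target temperature, and
#' integrates 2D Langevin dynamics (velocity-Verlet with friction and
#' thermal noise, BAOAB splitting) under truncated Lennard-Jones pair
#' potentials with per-type-pair well depths, periodic boundary conditions,
#' and motion confined to the plane. The final configuration is the
#' simulated tissue: types with elevated mutual `eps` end up spatially
#' co-localized. Deterministic given `set.seed()`.
#'
#' @param config a [simulation_config()].
#' @return A `TissueSnapshot`: list with `coords` (n x 2, wrapped into the
#'   box), `type_labels` (`"T0"`, ...), `config`, `final_temperature`
#'   (mean kinetic temperature over the last quarter of the run) and
#'   `temperature_trace`.
#' @export
simulate_tissue <- function(config = simulation_config()) {
  n <- config$n_types * config$cells_per_type
  L <- diff(config$box)
  min_sep <- 0.85 * config$sigma
  if (n * pi * (min_sep / 2)^2 > 0.45 * L^2)
    stop("density too high to place ", n, " particles without overlap")
  xy <- place_nonoverlapping(n, config$box, min_sep)
  types <- rep(seq_len(config$n_types) - 1L, each = config$cells_per_type)
  seed_draw <- runif(1)
  out <- lj_simulate_cpp(xy, types, unname(config$eps), config$sigma,
                         config$rc, config$box[1], config$box[2],
                         config$temperature, config$mass, config$dt,
                         config$damping, config$n_steps, seed_draw,
                         limit_steps = 2000L, vmax = 5)
  labels <- paste0("T", types)
  structure(list(coords = out$coords, type_labels = labels, config = config,
                 final_temperature = out$final_temperature,
                 temperature_trace = out$temperature_trace),
            class = "TissueSnapshot")
}

place_nonoverlapping <- function(n, box, min_sep) {
  xy <- matrix(NA_real_, n, 2)
  L <- diff(box)
  cellw <- max(min_sep, 1e-6)
  ncell <- max(1, floor(L / cellw))
  cellw <- L / ncell
  occ <- vector("list", ncell * ncell)
  placed <- 0
  attempts <- 0
  while (placed < n) {
    attempts <- attempts + 1
    if (attempts > 200 * n) stop("could not place particles without overlap")
    p <- runif(2, box[1], box[2])
    cx <- min(ncell - 1, floor((p[1] - box[1]) / cellw))
    cy <- min(ncell - 1, floor((p[2] - box[1]) / cellw))
    clash <- FALSE
    for (dx in -1:1) for (dy in -1:1) {
      cc <- ((cy + dy) %% ncell) * ncell + ((cx + dx) %% ncell) + 1
      for (q in occ[[cc]]) {
        d <- p - xy[q, ]
        d <- d - L * round(d / L)
        if (sum(d^2) < min_sep^2) { clash <- TRUE; break }
      }
      if (clash) break
    }
    if (clash) next
    placed <- placed + 1
    xy[placed, ] <- p
    occ[[cy * ncell + cx + 1]] <- c(occ[[cy * ncell + cx + 1]], placed)
  }
  xy
}

#' @export
print.TissueSnapshot <- function(x, ...) {
  cat(sprintf(
    "TissueSnapshot: %d particles, %d types, final T = %.3f\n",
    nrow(x$coords), x$config$n_types, x$final_temperature))
  invisible(x)
}

#' Lennard-Jones pair potential
#'
#' `V(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6)`: zero at distance `sigma`,
#' minimum `-eps` at `2^(1/6) sigma`.
#'
#' @param r distances.
#' @param eps well depth.
#' @param sigma particle size.
#' @return potential values.
#' @export
lj_potential <- function(r, eps = 1, sigma = 2) {
  lj_potential_cpp(as.numeric(r), eps, sigma)
}

#' Configuration for synthetic expression with planted factor covariation
#'
#' @param n_genes total gene count (default 60).
#' @param markers_per_type marker genes per type (default 5).
#' @param factor_genes genes loaded by each type's latent factor
#'   (default 10).
#' @param marker_strength multiplicative marker elevation (default 20).
#' @param loading latent factor loading magnitude on factor genes
#'   (default 0.5).
#' @param gamma cross-type coupling: a central cell's factor activity gains
#'   `gamma` times the mean activity of its designated neighbor type
#'   (default 0 — no coupling).
#' @param coupling named list mapping a central type to the neighbor type
#'   whose activity drives it, e.g. `list(T3 = "T5")`.
#' @param noise_sd activity noise (default 0.1).
#' @param nb_size negative-binomial size (inverse dispersion) of counts
#'   (default 10).
#' @param depth mean transcripts per cell (default 1000).
#' @return A `SyntheticExpressionConfig` list.
#' @export
synthetic_expression_config <- function(n_genes = 60, markers_per_type = 5,
                                        factor_genes = 10,
                                        marker_strength = 20, loading = 0.5,
                                        gamma = 0, coupling = list(),
                                        noise_sd = 0.1, nb_size = 10,
                                        depth = 1000) {
  structure(list(n_genes = n_genes, markers_per_type = markers_per_type,
                 factor_genes = factor_genes,
                 marker_strength = marker_strength, loading = loading,
                 gamma = gamma, coupling = coupling, noise_sd = noise_sd,
                 nb_size = nb_size, depth = depth),
            class = "SyntheticExpressionConfig")
}

#' Generate synthetic spatial and reference expression from a snapshot
#'
#' Every cell type has marker genes and one latent gene program. Spatial
#' cells get a factor activity `a = base + gamma * mean(neighbor activity) +
#' noise`, where the neighbor mean runs over Delaunay neighbors of the
#' coupled type; counts are negative-binomial with gene rates
#' `base_profile * exp(a * loading)` scaled to the cell's depth. Reference
#' cells are drawn from the same per-type programs without any spatial
#' coupling. True labels, activities and the coupling are returned as
#' ground truth, making label transfer and the covariation analysis fully
#' checkable.
#'
#' @param snapshot a [simulate_tissue()] snapshot (or any list with
#'   `coords` and `type_labels`).
#' @param cfg a [synthetic_expression_config()].
#' @param n_ref_per_type reference cells per type (default 200).
#' @return list with `sp` ([spatial_dataset()] — labels NOT attached),
#'   `ref` ([reference_dataset()]), `truth` (list with `labels`,
#'   `activity_sp`, `activity_ref`, `gamma`, `coupling`, `factor_genes`
#'   per type).
#' @export
synth_expression <- function(snapshot, cfg = synthetic_expression_config(),
                             n_ref_per_type = 200) {
  labels <- snapshot$type_labels
  types <- sort(unique(labels))
  n_types <- length(types)
  need <- n_types * cfg$markers_per_type
  if (cfg$n_genes < need)
    stop("n_genes (", cfg$n_genes, ") < markers needed (", need, ")")
  genes <- sprintf("g%03d", seq_len(cfg$n_genes))
  # per-type base profile: flat background + elevated markers
  base <- matrix(1, n_types, cfg$n_genes, dimnames = list(types, genes))
  marker_idx <- split(seq_len(need),
                      rep(seq_len(n_types), each = cfg$markers_per_type))
  for (t in seq_len(n_types))
    base[t, marker_idx[[t]]] <- cfg$marker_strength
  # per-type factor loading vectors (non-negative, on a gene block)
  load_mat <- matrix(0, n_types, cfg$n_genes, dimnames = list(types, genes))
  fg <- list()
  for (t in seq_len(n_types)) {
    start <- ((t - 1) * cfg$factor_genes) %% cfg$n_genes
    idx <- (start + seq_len(cfg$factor_genes) - 1) %% cfg$n_genes + 1
    load_mat[t, idx] <- cfg$loading
    fg[[types[t]]] <- genes[idx]
  }
  # spatial activities with neighbor coupling over Delaunay contacts
  n_sp <- length(labels)
  act_sp <- rnorm(n_sp, 0, 1)
  if (cfg$gamma != 0 && length(cfg$coupling) > 0) {
    graph <- build_neighborhoods(snapshot$coords, mode = "delaunay_R0",
                                 max_dist = 100)
    base_act <- act_sp
    for (central in names(cfg$coupling)) {
      donor <- cfg$coupling[[central]]
      for (i in which(labels == central)) {
        nbr <- graph$adjacency[[i]]
        nbr <- nbr[labels[nbr] == donor]
        if (length(nbr) > 0)
          act_sp[i] <- cfg$gamma * mean(base_act[nbr]) +
            rnorm(1, 0, cfg$noise_sd)
      }
    }
  }
  draw_counts <- function(labs, act, prefix) {
    n <- length(labs)
    rates <- base[labs, , drop = FALSE] *
      exp(act * load_mat[labs, , drop = FALSE])
    rates <- rates / rowSums(rates)
    depth <- cfg$depth
    counts <- matrix(rnbinom(n * ncol(rates), mu = depth * rates,
                             size = cfg$nb_size),
                     n, ncol(rates))
    count_matrix(counts, sprintf("%s%05d", prefix, seq_len(n)), genes)
  }
  sp_counts <- draw_counts(labels, act_sp, "sp")
  ref_labels <- rep(types, each = n_ref_per_type)
  act_ref <- rnorm(length(ref_labels), 0, 1)
  ref_counts <- draw_counts(ref_labels, act_ref, "sc")
  sp <- spatial_dataset(sp_counts, snapshot$coords)
  ref <- reference_dataset(ref_counts, ref_labels)
  list(sp = sp, ref = ref,
       truth = list(labels = setNames(labels, rownames(sp_counts)),
                    activity_sp = setNames(act_sp, rownames(sp_counts)),
                    activity_ref = setNames(act_ref, rownames(ref_counts)),
                    gamma = cfg$gamma, coupling = cfg$coupling,
                    factor_genes = fg))
}

#' Rank a central type's foreign-neighbor counts in a snapshot
#'
#' Mean count of Delaunay neighbors of each other type around cells of the
#' central type — the direct geometric readout of the simulated affinities,
#' used as ground truth ordering.
#'
#' @param snapshot a [simulate_tissue()] snapshot.
#' @param central central type label.
#' @param max_dist Delaunay distance cutoff (default 100).
#' @return named numeric vector (decreasing) of mean neighbor counts per
#'   foreign type.
#' @export
neighbor_count_ranking <- function(snapshot, central, max_dist = 100) {
  graph <- build_neighborhoods(snapshot$coords, mode = "delaunay_R0",
                               max_dist = max_dist)
  labels <- snapshot$type_labels
  types <- setdiff(sort(unique(labels)), central)
  cells <- which(labels == central)
  counts <- sapply(types, function(t)
    mean(vapply(cells, function(i)
      sum(labels[graph$adjacency[[i]]] == t), 0)))
  sort(counts, decreasing = TRUE)
}
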