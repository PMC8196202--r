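#' Principal-component reduction of a normalized matrix
#'
#' Eigendecomposition of the sample covariance of the z-scored matrix.
#' Components are ordered by decreasing variance and each loading column is
#' oriented so that its largest-magnitude entry is positive, giving a
#' deterministic sign convention.
#'
#' @param matrix a `normalized_matrix`.
#' @param n_dims number of leading components to keep (at most the rank of
#'   the centered matrix).
#' @return A `pca_projection`: list with `scores` (n x m, rownames kept),
#'   `loadings` (d x m, orthonormal columns), `explained_variance_fraction`
#'   and `center` (d vector).
#' @export
pca_reduce <- function(matrix, n_dims) {
  stopifnot(inherits(matrix, "normalized_matrix") || is.matrix(matrix))
  X <- if (is.matrix(matrix)) matrix else matrix$values
  n <- nrow(X); d <- ncol(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center, "-")
  S <- crossprod(Xc) / (n - 1)
  e <- eigen(S, symmetric = TRUE)
  tol <- max(e$values) * 1e-9
  rank <- sum(e$values > tol)
  if (n_dims < 1 || n_dims > rank)
    stop("n_dims exceeds the rank (", rank, ") of the centered matrix")
  L <- e$vectors[, seq_len(n_dims), drop = FALSE]
  for (j in seq_len(n_dims)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  scores <- Xc %*% L
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(n_dims))
  colnames(L) <- colnames(scores)
  rownames(L) <- colnames(X)
  structure(list(scores = scores, loadings = L,
                 explained_variance_fraction =
                   e$values[seq_len(n_dims)] / sum(e$values),
                 eigenvalues = e$values[seq_len(n_dims)],
                 center = setNames(center, colnames(X))),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat("<pca_projection> ", nrow(x$scores), " points, ", ncol(x$scores),
      " PCs (", round(100 * sum(x$explained_variance_fraction), 2),
      "% variance)\n", sep = "")
  invisible(x)
}

#' Volume of a simplex from its vertex matrix
#'
#' `|det(A_2 - A_1, ..., A_k - A_1)| / (k-1)!` for a k x (k-1) vertex matrix.
#'
#' @param vertices k x m matrix of vertex coordinates with k = m + 1.
#' @return The m-dimensional volume.
#' @export
simplex_volume <- function(vertices) {
  k <- nrow(vertices); m <- ncol(vertices)
  if (k != m + 1) stop("a simplex in ", m, " dims needs ", m + 1, " vertices")
  M <- sweep(vertices[-1, , drop = FALSE], 2, vertices[1, ], "-")
  abs(det(M)) / factorial(m)
}

#' Volume of the convex hull of a point set
#'
#' Exact hull volume via an incremental beneath-beyond construction (1-D is
#' the range).  Returns 0 for affinely degenerate point sets.
#'
#' @param points n x m coordinate matrix.
#' @return The m-dimensional hull volume.
#' @export
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) == 1) return(diff(range(points)))
  cpp_hull_volume(points)
}

#' Configuration for the simplex fit
#'
#' @param algorithm `"soft_mves"` (soft minimal-volume enclosing simplex,
#'   the default) or `"interior"` (maximum-volume simplex with vertices
#'   restricted to observed points, a pure convex-combination variant kept
#'   for robustness comparisons).
#' @param lambda weight of the enclosure penalty (negative barycentric slack
#'   of points outside the candidate simplex, averaged over points and scaled
#'   by k), relative to log simplex volume.  Large values force full
#'   enclosure; the default balances enclosure against the outward bias that
#'   extreme noise points impose on a fully enclosing simplex.
#' @param tol convergence tolerance on the objective between restarts.
#' @param maxit maximum Nelder-Mead iterations per restart.
#' @param restarts maximum number of Nelder-Mead restarts.
#' @param seed integer recorded with the fit (the default initialization is
#'   deterministic, so the seed only matters if callers randomize starts).
#' @return A list of class `simplex_fit_config`.
#' @export
simplex_fit_config <- function(algorithm = c("soft_mves", "interior"),
                               lambda = 10, tol = 1e-6, maxit = 500,
                               restarts = 6, seed = 0L) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, lambda = lambda, tol = tol,
                 maxit = maxit, restarts = restarts, seed = as.integer(seed)),
            class = "simplex_fit_config")
}

# Maximum-volume simplex with vertices restricted to data points: vertex-wise
# coordinate ascent.  The simplex volume is an affine function of any single
# vertex with the others fixed, V(x) = |w . x + b|, so each sweep scores every
# candidate point with one matrix-vector product.
max_volume_vertex_search <- function(scores, k, max_sweeps = 20) {
  n <- nrow(scores); m <- ncol(scores)
  idx <- init_archetype_indices(scores, k)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (j in seq_len(k)) {
      others <- scores[idx[-j], , drop = FALSE]
      base <- others[1, ]
      E <- sweep(others[-1, , drop = FALSE], 2, base, "-") # (m-1) x m
      w <- vapply(seq_len(m), function(i) det(rbind(diag(m)[i, ], E)),
                  numeric(1))
      vals <- abs(sweep(scores, 2, base, "-") %*% w)
      best <- which.max(vals)
      if (best != idx[j] && vals[best] > vals[idx[j]] * (1 + 1e-12)) {
        idx[j] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  scores[idx, , drop = FALSE]
}

# Linear scale factor of the minimal facet-wise enclosing expansion of the
# simplex with vertex matrix A: each facet is pushed outward just past the
# furthest point beyond it, which equals an affine dilation by 1 + S where
# S is the summed per-facet barycentric violation (1 when A already
# encloses).  Volumes scale by this factor to the m-th power.
enclosing_dilation <- function(scores, A) {
  W <- cpp_barycentric(scores, A)
  slack <- pmax(0, -apply(W, 2, min))
  1 + sum(slack)
}

init_archetype_indices <- function(scores, k) {
  n <- nrow(scores)
  ctr <- colMeans(scores)
  d2 <- rowSums(sweep(scores, 2, ctr, "-")^2)
  chosen <- which.max(d2)
  while (length(chosen) < k) {
    sumd <- rowSums(vapply(chosen, function(i)
      sqrt(rowSums(sweep(scores, 2, scores[i, ], "-")^2)), numeric(n)))
    sumd[chosen] <- -Inf
    chosen <- c(chosen, which.max(sumd))
  }
  chosen
}

# Initialization: furthest-sum seed (greedy data points maximizing summed
# distance to the chosen set, started from the point farthest from the
# centroid), refined by the max-volume vertex ascent, then expanded about its
# centroid until every point is enclosed.
init_archetypes <- function(scores, k) {
  A <- max_volume_vertex_search(scores, k)
  s <- enclosing_dilation(scores, A)
  c0 <- colMeans(A)
  sweep(sweep(A, 2, c0, "-") * s, 2, c0, "+")
}

#' Fit a minimal-volume enclosing simplex to PC scores
#'
#' Minimizes `log(volume) + lambda * sum(hinge)` over the k x (k-1) archetype
#' coordinates, where the hinge term is the total negative barycentric slack
#' of points falling outside the candidate simplex (a soft enclosure
#' constraint in the SISAL tradition).  Initialization is a furthest-sum
#' vertex seed expanded to enclose the data; optimization is Nelder-Mead with
#' restarts, so the fit is deterministic for a given configuration.
#'
#' @param projection a `pca_projection` whose dimension is `k - 1` (or any m
#'   with `k = m + 1`).
#' @param k number of archetypes (>= 2).
#' @param config a [simplex_fit_config()].
#' @return An `archetype_model`: list with `k`, `m`, `archetypes_pc` (k x m),
#'   `archetypes_feature_space` (k x d, z-units), `t_ratio`, `volume`,
#'   `fit_config`, and the `projection` it was fitted in.
#' @export
fit_simplex <- function(projection, k, config = simplex_fit_config()) {
  stopifnot(inherits(projection, "pca_projection"))
  scores <- projection$scores
  m <- ncol(scores)
  if (k != m + 1)
    stop("k (", k, ") must equal projection dimension + 1 (", m + 1, ")")
  if (nrow(scores) < k) stop("need at least k = ", k, " points")
  hull_vol <- convex_hull_volume(scores)
  if (hull_vol <= .Machine$double.eps)
    stop("rank-deficient point cloud: hull volume is zero")

  if (config$algorithm == "interior") {
    A <- max_volume_vertex_search(scores, k, config$maxit)
    val <- -log(simplex_volume(A))
  } else {
    # Penalty is normalized per point (and scaled by k) so the
    # volume-vs-enclosure balance does not grow with cohort size: with the
    # raw summed hinge, any n in the hundreds forces full enclosure and the
    # vertices inherit the outward bias of the most extreme noise points.
    lambda_eff <- config$lambda * k / nrow(scores)
    Xt1 <- rbind(t(scores), 1)
    obj <- function(par) cpp_simplex_objective(par, Xt1, as.integer(k),
                                               as.integer(m), lambda_eff)
    best_par <- as.vector(init_archetypes(scores, k))
    best_val <- obj(best_par)
    stagnant <- 0L
    for (r in seq_len(config$restarts)) {
      # restart from the incumbent; on even rounds nudge it with a tiny
      # deterministic jitter to escape Nelder-Mead stagnation at hinge kinks
      start <- if (r %% 2 == 0)
        best_par * (1 + with_seed(sub_seed(config$seed, r),
                                  rnorm(length(best_par), sd = 1e-3)))
      else best_par
      fit <- stats::optim(start, obj, method = "Nelder-Mead",
                          control = list(maxit = config$maxit,
                                         reltol = 1e-12))
      if (fit$value < best_val - config$tol) {
        stagnant <- 0L
      } else stagnant <- stagnant + 1L
      if (fit$value < best_val) { best_val <- fit$value; best_par <- fit$par }
      if (stagnant >= 2L) break
    }
    A <- matrix(best_par, k, m)
    val <- best_val
  }
  colnames(A) <- colnames(scores)
  Af <- sweep(A %*% t(projection$loadings), 2, projection$center, "+")
  colnames(Af) <- rownames(projection$loadings)
  vol <- simplex_volume(A)
  # the t-ratio compares ENCLOSING volumes: dilate the fitted simplex about
  # its centroid just enough to cover every point, so soft-enclosure slack
  # does not leak into the shuffle-null statistic
  s <- enclosing_dilation(scores, A)
  structure(list(k = k, m = m, archetypes_pc = A,
                 archetypes_feature_space = Af,
                 volume = vol, enclosing_scale = s,
                 t_ratio = vol * s^m / hull_vol,
                 hull_volume = hull_vol,
                 objective = val,
                 fit_config = config,
                 projection = projection),
            class = "archetype_model")
}

#' @export
print.archetype_model <- function(x, ...) {
  cat("<archetype_model> k = ", x$k, " archetypes in ", x$m,
      " PCs; t-ratio = ", signif(x$t_ratio, 5), "\n", sep = "")
  invisible(x)
}

#' Simplex-to-hull volume ratio (t-ratio)
#'
#' `V(enclosing simplex) / V(convex hull of the scores)`, where the
#' enclosing simplex is the fitted simplex dilated about its centroid by the
#' smallest factor that covers every point (1 when the fit already
#' encloses).  The ratio is therefore always >= 1, and values near 1 mean
#' the cloud itself is nearly a simplex; it is invariant under rotation and
#' uniform scaling of the space.
#'
#' @param model an `archetype_model`.
#' @param projection a `pca_projection` in the same space (defaults to the
#'   projection the model was fitted in).
#' @return The scalar ratio.
#' @export
t_ratio <- function(model, projection = model$projection) {
  stopifnot(inherits(model, "archetype_model"))
  if (ncol(projection$scores) != model$m)
    stop("projection dimension does not match the model")
  hull_vol <- convex_hull_volume(projection$scores)
  if (hull_vol <= .Machine$double.eps) stop("zero hull volume")
  s <- enclosing_dilation(projection$scores, model$archetypes_pc)
  simplex_volume(model$archetypes_pc) * s^model$m / hull_vol
}

#' Independently permute each column of a matrix
#'
#' The column-shuffle null: every feature column is permuted with its own
#' draw, preserving each marginal exactly while destroying all inter-feature
#' correlation.
#'
#' @param matrix a `normalized_matrix` or plain matrix.
#' @param seed integer seed (deterministic output for a given seed).
#' @return Same type as the input with shuffled columns.
#' @export
shuffle_columns <- function(matrix, seed) {
  X <- if (inherits(matrix, "normalized_matrix")) matrix$values else matrix
  Xs <- with_seed(seed, {
    apply(X, 2, function(col) col[sample.int(length(col))])
  })
  dimnames(Xs) <- dimnames(X)
  if (inherits(matrix, "normalized_matrix")) {
    out <- matrix
    out$values <- Xs
    out
  } else Xs
}

#' Shuffle-null significance test of the fitted simplex
#'
#' Computes the observed t-ratio from the full pipeline (PCA to k-1 dims,
#' simplex fit, volume ratio), then repeats the identical pipeline on
#' `n_shuffles` column-shuffled copies of the matrix.  The empirical p-value
#' is the fraction of shuffled t-ratios at or below the observed one: a tight
#' simplex around genuinely low-dimensional structure beats its shuffled
#' counterparts, which need larger simplices relative to their hulls.
#'
#' @param matrix a `normalized_matrix` (column shuffling preserves z-scores,
#'   so shuffled copies are not re-standardized).
#' @param k number of archetypes.
#' @param n_shuffles number of shuffled null datasets (>= 1).
#' @param seed root seed; shuffle i uses a deterministic sub-seed.
#' @param config fit configuration shared by real and null fits.
#' @return A `significance_result`: list with `t_real`, `t_null`, `p_value`,
#'   `n_shuffles`, `p_label` and the fitted `model`.
#' @export
significance_test <- function(matrix, k, n_shuffles, seed,
                              config = simplex_fit_config()) {
  if (!is.numeric(n_shuffles) || n_shuffles < 1)
    stop("`n_shuffles` must be >= 1")
  n_shuffles <- as.integer(n_shuffles)
  proj <- pca_reduce(matrix, k - 1)
  model <- fit_simplex(proj, k, config)
  t_real <- model$t_ratio

  t_null <- rep(NA_real_, n_shuffles)
  for (i in seq_len(n_shuffles)) {
    null_i <- shuffle_columns(matrix, sub_seed(seed, i))
    t_null[i] <- tryCatch({
      proj_i <- pca_reduce(null_i, k - 1)
      fit_simplex(proj_i, k, config)$t_ratio
    }, error = function(e) NA_real_)
  }
  failed <- sum(is.na(t_null))
  if (failed > 0) {
    warning(failed, " shuffle fit(s) failed and were excluded")
    t_null <- t_null[!is.na(t_null)]
    n_shuffles <- length(t_null)
    if (n_shuffles == 0) stop("all shuffle fits failed")
  }
  p <- sum(t_null <= t_real) / n_shuffles
  structure(list(t_real = t_real, t_null = t_null, p_value = p,
                 n_shuffles = n_shuffles,
                 p_label = if (p == 0) paste0("< ", format(1 / n_shuffles))
                           else format(p),
                 model = model),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat("<significance_result> t = ", signif(x$t_real, 5), "; p ",
      if (x$p_value == 0) x$p_label else paste0("= ", x$p_label),
      " (", x$n_shuffles, " shuffles)\n", sep = "")
  invisible(x)
}

# All permutations of 1..k (Heap's algorithm); k <= 8 by design.
all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1)
  out <- vector("list", k * length(sub))
  idx <- 1
  for (p in sub) for (pos in seq_len(k)) {
    out[[idx]] <- append(p + (p >= k) * 0L, k, after = pos - 1)
    idx <- idx + 1
  }
  out
}

# Optimal vertex matching between a reference and a refit archetype set:
# permutation minimizing the total Euclidean distance (exhaustive; k <= 8).
match_archetypes <- function(reference, candidate) {
  k <- nrow(reference)
  if (k > 8) stop("archetype matching supported for k <= 8")
  cost <- as.matrix(stats::dist(rbind(reference, candidate)))[seq_len(k),
            k + seq_len(k), drop = FALSE]
  best <- NULL; best_cost <- Inf
  for (p in all_permutations(k)) {
    cc <- sum(cost[cbind(seq_len(k), p)])
    if (cc < best_cost) { best_cost <- cc; best <- p }
  }
  best
}

#' Bootstrap uncertainty of the archetype positions
#'
#' Resamples rows with replacement, refits the simplex, and matches each
#' refit's archetypes to the reference fit by the minimum-total-distance
#' vertex assignment (exhaustive over permutations).  The matched positions
#' summarize positional uncertainty as per-archetype means and covariances
#' (the bootstrap "ellipses").
#'
#' @param matrix a `normalized_matrix`.
#' @param k number of archetypes.
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed root seed; resample i uses a deterministic sub-seed.
#' @param config fit configuration.
#' @return A `bootstrap_summary`: list with `positions` (n_boot x k x m
#'   array), per-archetype `mean` (k x m) and `covariance` (list of m x m),
#'   `reference` model and `n_failed`.
#' @export
bootstrap_archetypes <- function(matrix, k, n_boot, seed,
                                 config = simplex_fit_config()) {
  if (n_boot < 1) stop("`n_boot` must be >= 1")
  X <- matrix$values
  n <- nrow(X)
  proj <- pca_reduce(matrix, k - 1)
  ref <- fit_simplex(proj, k, config)
  m <- ref$m

  positions <- array(NA_real_, c(n_boot, k, m))
  failed <- 0
  for (b in seq_len(n_boot)) {
    idx <- with_seed(sub_seed(seed, b), sample.int(n, n, replace = TRUE))
    nm_b <- matrix; nm_b$values <- X[idx, , drop = FALSE]
    fit_b <- tryCatch({
      proj_b <- pca_reduce(nm_b, k - 1)
      fit_simplex(proj_b, k, config)
    }, error = function(e) NULL)
    if (is.null(fit_b)) { failed <- failed + 1; next }
    # refit lives in its own PC basis; compare in feature z-space mapped back
    # through the reference projection so coordinates are commensurable
    A_ref_space <- sweep(fit_b$archetypes_feature_space, 2,
                         ref$projection$center, "-") %*% ref$projection$loadings
    p <- match_archetypes(ref$archetypes_pc, A_ref_space)
    positions[b, , ] <- A_ref_space[p, , drop = FALSE]
  }
  if (failed > 0) warning(failed, " bootstrap fit(s) failed and were skipped")
  ok <- apply(positions, 1, function(s) all(is.finite(s)))
  mean_pos <- apply(positions[ok, , , drop = FALSE], c(2, 3), mean)
  covs <- lapply(seq_len(k), function(j)
    stats::cov(matrix(positions[ok, j, ], nrow = sum(ok))))
  structure(list(positions = positions, mean = mean_pos, covariance = covs,
                 reference = ref, n_failed = failed),
            class = "bootstrap_summary")
}

#' Scan candidate archetype numbers with corrected significance
#'
#' Runs [significance_test()] for each candidate k and selects the smallest k
#' whose p-value clears the Bonferroni-corrected level
#' `alpha / length(k_candidates)`; reports raw and corrected p-values for
#' every candidate.
#'
#' @param matrix a `normalized_matrix`.
#' @param k_candidates integer vector of candidate archetype numbers (>= 2).
#' @param n_shuffles shuffles per candidate.
#' @param seed root seed (each candidate uses a distinct sub-seed).
#' @param alpha family-wise level (default 0.05).
#' @param config fit configuration.
#' @return A `k_scan_result`: list with `table` (k, t_real, p_raw,
#'   p_corrected, significant), `selected_k` (or `NA`), `alpha`,
#'   `correction = "bonferroni"` and the per-k `results`.
#' @export
scan_k <- function(matrix, k_candidates, n_shuffles, seed, alpha = 0.05,
                   config = simplex_fit_config()) {
  if (length(k_candidates) == 0) stop("empty candidate list")
  if (any(k_candidates < 2)) stop("candidate k must be >= 2")
  n_k <- length(k_candidates)
  results <- lapply(seq_along(k_candidates), function(i)
    significance_test(matrix, k_candidates[i], n_shuffles,
                      sub_seed(seed, 1000 + i), config))
  p_raw <- vapply(results, `[[`, numeric(1), "p_value")
  sig <- p_raw < alpha / n_k
  tab <- data.frame(k = k_candidates,
                    t_real = vapply(results, `[[`, numeric(1), "t_real"),
                    p_raw = p_raw,
                    p_corrected = pmin(1, p_raw * n_k),
                    significant = sig)
  selected <- if (any(sig)) min(k_candidates[sig]) else NA_integer_
  structure(list(table = tab, selected_k = selected, alpha = alpha,
                 correction = "bonferroni", results = results),
            class = "k_scan_result")
}

#' @export
print.k_scan_result <- function(x, ...) {
  print(x$table)
  cat("selected k:", if (is.na(x$selected_k)) "none" else x$selected_k, "\n")
  invisible(x)
}
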