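# Shared fixtures and independent oracles used across the suite.

# Wrap a raw score matrix as a projection so geometry functions can be
# exercised on hand-made point sets.
as_projection <- function(scores) {
  scores <- as.matrix(scores)
  structure(list(scores = scores, loadings = diag(ncol(scores)),
                 center = rep(0, ncol(scores)),
                 explained_variance_fraction =
                   rep(1 / ncol(scores), ncol(scores))),
            class = "pca_projection")
}

# Small wide cohort table with optional missing cells.
toy_table <- function(values, participants = NULL, visits = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(participants)) participants <- sprintf("P%02d", seq_len(n))
  if (is.null(visits)) visits <- rep(1L, n)
  df <- data.frame(participant_id = participants, visit_index = visits,
                   stringsAsFactors = FALSE)
  if (is.null(colnames(values))) colnames(values) <- paste0("f", seq_len(ncol(values)))
  df <- cbind(df, as.data.frame(values))
  meta <- data.frame(feature = colnames(values), kind = "continuous",
                     group = "lab", stringsAsFactors = FALSE)
  feature_table(df, meta)
}

# Population-sd z-score, written independently of the package.
zscore_pop <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  (x - m) / s
}

# Map the generator's true archetype profiles into a fitted model's PC space.
truth_in_model_space <- function(truth, model) {
  z <- sweep(sweep(truth$archetype_profiles, 2,
                   model$normalization$feature_means, "-"),
             2, model$normalization$feature_sds, "/")
  sweep(z, 2, model$projection$center, "-") %*% model$projection$loadings
}

# Matched maximum archetype error relative to the minimum true edge length.
matched_recovery_error <- function(truth, model) {
  At <- truth_in_model_space(truth, model)
  perm <- best_assignment(At, model$archetypes_pc)
  max(sqrt(rowSums((model$archetypes_pc[perm, , drop = FALSE] - At)^2))) /
    min(dist(At))
}

# Independent brute-force assignment: enumerate permutations recursively.
best_assignment <- function(reference, candidate) {
  k <- nrow(reference)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(k))) {
    cost <- sum(sqrt(rowSums((candidate[p, , drop = FALSE] - reference)^2)))
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  best
}

# LP-feasibility membership test for a point in the convex hull of the
# simplex vertices, via the phase-1 simplex method in boot::simplex.
lp_member <- function(point, vertices) {
  k <- nrow(vertices)
  A3 <- rbind(t(vertices), rep(1, k))
  b3 <- c(point, 1)
  flip <- b3 < 0
  A3[flip, ] <- -A3[flip, ]
  b3[flip] <- -b3[flip]
  res <- suppressWarnings(boot::simplex(a = rep(0, k), A3 = A3, b3 = b3,
                                        maxi = FALSE))
  res$solved == 1
}

# Hypergeometric upper/lower tails by direct enumeration of the pmf through
# log-binomial coefficients (independent of phyper).
hyper_tails_enum <- function(N, K, n1, x) {
  support <- max(0, n1 - (N - K)):min(K, n1)
  pmf <- exp(lchoose(K, support) + lchoose(N - K, n1 - support) -
               lchoose(N, n1))
  c(upper = sum(pmf[support >= x]), lower = sum(pmf[support <= x]))
}

# Closed-form Welch t-test (statistic, Welch-Satterthwaite df, two-sided p).
welch_closed_form <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}
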