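test_that("PCA reduction matches a direct eigendecomposition", {
  # rank-1 cloud along (1,1,1)
  line <- outer(seq(-2, 2, length.out = 30), c(1, 1, 1))
  p1 <- pca_reduce(line + 0, 1)
  expect_equal(p1$explained_variance_fraction[1], 1)
  expect_equal(abs(drop(p1$loadings)), rep(1 / sqrt(3), 3), tolerance = 1e-9)
  expect_true(all(p1$loadings > 0)) # sign convention
  expect_error(pca_reduce(line + 0, 2), "rank")

  # known 2-D covariance diag(4, 1) rotated by 30 degrees
  set.seed(5)
  th <- pi / 6
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  X <- matrix(rnorm(10000), 5000, 2) %*% diag(c(2, 1)) %*% t(R)
  p2 <- pca_reduce(X, 2)
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(p2$eigenvalues, ev, tolerance = 1e-9)
  expect_true(all(diff(p2$explained_variance_fraction) <= 0))
  # orthonormal loadings and exact score reconstruction
  expect_lt(max(abs(crossprod(p2$loadings) - diag(2))), 1e-9)
  expect_lt(max(abs(sweep(X, 2, p2$center, "-") %*% p2$loadings - p2$scores)),
            1e-9)

  # more dimensions than affinely independent points
  four <- rbind(diag(3), 0)
  expect_error(pca_reduce(four + 0, 4), "rank")
})

test_that("hull volume matches known polytopes and simplex volume the determinant", {
  expect_equal(convex_hull_volume(matrix(c(0, 3, 7), 3, 1)), 7)
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(convex_hull_volume(sq), 1, tolerance = 1e-12)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(cube), 1, tolerance = 1e-12)
  # interior points change nothing
  set.seed(1)
  inside <- matrix(runif(300), 100, 3)
  expect_equal(convex_hull_volume(rbind(cube, inside)), 1, tolerance = 1e-12)
  # 4-D cross-polytope: volume 2^d / d! = 2/3
  cross4 <- rbind(diag(4), -diag(4))
  expect_equal(convex_hull_volume(cross4), 2 / 3, tolerance = 1e-12)
  # degenerate (coplanar) cloud
  flat <- cbind(matrix(rnorm(40), 20, 2), 1)
  expect_equal(convex_hull_volume(flat), 0)

  expect_equal(simplex_volume(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(simplex_volume(rbind(rep(0, 3), diag(3))), 1 / 6)
})

test_that("fitting exact simplex vertices returns them with t-ratio 1", {
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  m <- fit_simplex(as_projection(tri), 3)
  perm <- best_assignment(tri, m$archetypes_pc)
  expect_lt(max(abs(m$archetypes_pc[perm, ] - tri)), 1e-6)
  expect_equal(m$t_ratio, 1, tolerance = 1e-6)

  # feature-space back-mapping is consistent with loadings and center
  expect_lt(max(abs(m$archetypes_feature_space -
                    (m$archetypes_pc %*% t(as_projection(tri)$loadings)))),
            1e-9)

  expect_error(fit_simplex(as_projection(matrix(rnorm(9), 3, 3)), 4),
               "at least k")
  flat <- cbind(rnorm(20), 1)
  expect_error(fit_simplex(as_projection(flat), 3), "rank-deficient")
})

test_that("noise-free mixtures of four archetypes are recovered to < 1% of edge", {
  truth <- synthetic_truth(k = 4, d = 3, separation = 10, noise_sd = 0,
                           dirichlet_alpha = 1, seed = 2)
  cohort <- sample_cross_section(truth, 500, seed = 3)
  proj <- as_projection(cohort$data)
  # noise-free data warrants hard enclosure: there is no noise band for the
  # soft penalty to absorb, and every facet is densely supported
  m <- fit_simplex(proj, 4, simplex_fit_config(lambda = 1000))
  A_true <- truth$archetype_profiles
  perm <- best_assignment(A_true, m$archetypes_pc)
  err <- max(sqrt(rowSums((m$archetypes_pc[perm, ] - A_true)^2)))
  expect_lt(err / min(dist(A_true)), 0.01)
})

test_that("t-ratio is 2 for the unit square and invariant to similarity maps", {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  cfg <- simplex_fit_config(restarts = 100, tol = 1e-12, maxit = 1000)
  m <- fit_simplex(as_projection(sq), 3, cfg)
  expect_equal(m$t_ratio, 2, tolerance = 1e-3)

  # rotation + uniform scaling leave the ratio unchanged
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  model_rot <- m
  model_rot$archetypes_pc <- 3.7 * m$archetypes_pc %*% t(R)
  proj_rot <- as_projection(3.7 * sq %*% t(R))
  expect_equal(t_ratio(model_rot, proj_rot), m$t_ratio, tolerance = 1e-9)

  expect_error(t_ratio(m, as_projection(cbind(rnorm(10), 1))), "zero hull")
})

test_that("column shuffling preserves marginals, kills correlation, is seeded", {
  set.seed(8)
  one <- matrix(rnorm(100), 100, 1)
  s1 <- shuffle_columns(one, seed = 4)
  expect_equal(sort(s1[, 1]), sort(one[, 1]))

  x <- rnorm(1000)
  two <- cbind(x, x)
  hits <- vapply(1:50, function(s) {
    abs(cor(shuffle_columns(two, seed = s))[1, 2]) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.98)

  expect_equal(shuffle_columns(two, seed = 9), shuffle_columns(two, seed = 9))
  expect_false(identical(shuffle_columns(two, seed = 9),
                         shuffle_columns(two, seed = 10)))
})

test_that("a large enclosure penalty keeps at least 99% of points inside", {
  truth <- synthetic_truth(k = 4, d = 8, noise_sd = 0.05, seed = 13)
  cohort <- sample_cross_section(truth, 400, seed = 14)
  nm <- impute_and_standardize(as_cohort_table(cohort$data))
  proj <- pca_reduce(nm, 3)
  m <- fit_simplex(proj, 4, simplex_fit_config(lambda = 1000))
  W <- barycentric_coordinates(proj$scores, m)
  expect_lt(max(abs(rowSums(W) - 1)), 1e-9)
  expect_gte(mean(apply(W, 1, min) >= -1e-6), 0.99)
})

test_that("significance pipeline is deterministic given data and seed", {
  truth <- synthetic_truth(k = 3, d = 6, noise_sd = 0.05, seed = 15)
  cohort <- sample_cross_section(truth, 200, seed = 16)
  nm <- impute_and_standardize(as_cohort_table(cohort$data))
  a <- significance_test(nm, 3, 10, seed = 21)
  b <- significance_test(nm, 3, 10, seed = 21)
  expect_identical(a$t_real, b$t_real)
  expect_identical(a$t_null, b$t_null)
  expect_equal(a$p_value, sum(a$t_null <= a$t_real) / 10)
  expect_error(significance_test(nm, 3, 0, seed = 1), "n_shuffles")
})

test_that("bootstrap matches vertices across resamples and tracks noise", {
  # degenerate bootstrap: four replicated vertices give zero-spread positions
  A <- make_archetype_profiles(4, 3, separation = 6, seed = 4)
  stacked <- A[rep(1:4, each = 60), ]
  nm <- impute_and_standardize(as_cohort_table(stacked))
  bs <- bootstrap_archetypes(nm, 4, 10, seed = 5)
  ref_pos <- bs$reference$archetypes_pc
  spread <- apply(bs$positions, 1, function(s)
    max(abs(s - ref_pos)))
  expect_lt(max(spread), 1e-6)
  expect_lt(max(vapply(bs$covariance, function(C) max(abs(C)), numeric(1))),
            1e-10)

  # matching recovers a planted permutation, agreeing with brute force
  set.seed(6)
  ref <- matrix(rnorm(12), 4, 3)
  perm <- c(3, 1, 4, 2)
  cand <- ref[perm, ] + matrix(rnorm(12, sd = 1e-3), 4, 3)
  got <- cohortsimplex:::match_archetypes(ref, cand)
  expect_equal(got, order(perm))
  expect_equal(got, best_assignment(ref, cand))

  # bootstrap position spread grows with the noise level
  radius <- vapply(c(0.02, 0.10), function(ns) {
    truth <- synthetic_truth(k = 4, d = 8, noise_sd = ns, seed = 31)
    cohort <- sample_cross_section(truth, 300, seed = 32)
    nmb <- impute_and_standardize(as_cohort_table(cohort$data))
    bsb <- bootstrap_archetypes(nmb, 4, 15, seed = 33)
    mean(vapply(bsb$covariance, function(C) sqrt(mean(diag(C))), numeric(1)))
  }, numeric(1))
  expect_lt(radius[1], radius[2])
})

test_that("k scan reports raw and corrected p-values with a consistent rule", {
  truth <- synthetic_truth(k = 4, d = 10, noise_sd = 0.05, seed = 41)
  cohort <- sample_cross_section(truth, 500, seed = 42)
  nm <- impute_and_standardize(as_cohort_table(cohort$data))
  ks <- scan_k(nm, c(2, 4), n_shuffles = 40, seed = 43)
  expect_equal(ks$table$p_corrected, pmin(1, ks$table$p_raw * 2))
  expect_equal(ks$table$significant, ks$table$p_raw < 0.05 / 2)
  # the planted k is significant and the selection obeys the stated rule
  expect_true(ks$table$significant[ks$table$k == 4])
  sig_k <- ks$table$k[ks$table$significant]
  expect_equal(ks$selected_k,
               if (length(sig_k)) min(sig_k) else NA_integer_)
  expect_error(scan_k(nm, integer(0), 10, 1), "empty")
})
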