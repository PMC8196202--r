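test_that("distances and equal-count binning follow the stated conventions", {
  expect_equal(distances_to_archetype(matrix(c(3, 4, 0), 1, 3), c(0, 0, 0)), 5)
  expect_equal(distances_to_archetype(matrix(1:3, 1, 3), 1:3), 0)
  set.seed(2)
  pts <- matrix(rnorm(300), 100, 3)
  a <- rnorm(3)
  brute <- apply(pts, 1, function(p) sqrt(sum((p - a)^2)))
  expect_lt(max(abs(distances_to_archetype(pts, a) - brute)), 1e-12)
  expect_error(distances_to_archetype(pts, 1:4), "dimension")

  b <- assign_bins(40:1, 20) # distances 40..1 in reverse order
  expect_equal(unname(table(b$bin_of)), rep(2L, 20), ignore_attr = TRUE)
  expect_equal(b$bin_of[39:40], c(1L, 1L)) # the two smallest distances

  sizes <- table(assign_bins(runif(30), 20)$bin_of)
  expect_true(all(sizes %in% 1:2))
  expect_equal(sum(sizes), 30)

  # ties across a bin boundary resolve by original row index (stable sort)
  d <- c(0.5, 0.2, 0.2, 0.2, 0.2, 0.2, 0.9, 0.1)
  got <- assign_bins(d, 4)$bin_of
  ord <- order(d, seq_along(d))
  oracle <- integer(8)
  oracle[ord] <- rep(1:4, each = 2)
  expect_equal(got, oracle)

  expect_error(assign_bins(runif(10), 20), "fewer points")
  expect_error(assign_bins(runif(10), 1), "n_bins")
})

test_that("continuous first-bin test equals the closed-form Welch formula", {
  bins <- structure(list(bin_of = c(1, 1, 1, 2, 2, 2, 3, 3, 3), n_bins = 3,
                         distances = 1:9, archetype_index = 1L),
                    class = "bin_assignment")
  feat <- c(5, 6, 7, 1, 2, 3, 1, 2, 3)
  rec <- test_continuous(feat, bins)
  oracle <- welch_closed_form(c(5, 6, 7), c(1, 2, 3, 1, 2, 3))
  expect_equal(rec$p_value, oracle$p, tolerance = 1e-9)
  expect_equal(rec$mean_first, 6)
  expect_equal(rec$mean_rest, 2)
  expect_equal(rec$direction, "high")

  # random splits agree with the closed form too
  set.seed(9)
  for (i in 1:20) {
    n <- 60
    bins2 <- assign_bins(runif(n), 10)
    x <- rnorm(n)
    rec2 <- test_continuous(x, bins2)
    o2 <- welch_closed_form(x[bins2$bin_of == 1], x[bins2$bin_of != 1])
    expect_equal(rec2$p_value, o2$p, tolerance = 1e-9)
  }

  # degenerate inputs: constant feature, tiny first bin
  recc <- test_continuous(rep(4, 9), bins)
  expect_equal(recc$p_value, 1)
  expect_equal(recc$direction, "none")
  rec1 <- test_continuous(c(5, NA, NA, 1, 2, 3, 1, 2, 3), bins)
  expect_true(rec1$untestable)
  expect_equal(rec1$p_value, 1)
})

test_that("hypergeometric tails equal pmf enumeration on a margin sweep", {
  # spec'd worked margin: N=200, K=20, n1=10, x=5
  bins <- structure(list(bin_of = rep(c(1, 2), c(10, 190)), n_bins = 2,
                         distances = 1:200, archetype_index = 1L),
                    class = "bin_assignment")
  ind <- rep(FALSE, 200)
  ind[c(1:5, 11:25)] <- TRUE # 5 carriers in bin 1, 20 total
  rec <- test_discrete(ind, bins)
  en <- hyper_tails_enum(200, 20, 10, 5)
  expect_equal(rec$p_value, min(en), tolerance = 1e-12)
  expect_equal(rec$direction, "high")
  expect_equal(rec$count_first, 5)

  # dense sweep of small margins plus a seeded spread of larger N up to 500
  worst <- 0
  for (N in c(2, 3, 7, 17, 40)) {
    for (K in 0:N) for (n1 in 1:N) {
      lo <- max(0, n1 - (N - K)); hi <- min(K, n1)
      for (x in lo:hi) {
        en <- hyper_tails_enum(N, K, n1, x)
        worst <- max(worst,
                     abs(phyper(x - 1, K, N - K, n1, lower.tail = FALSE) -
                           en["upper"]),
                     abs(phyper(x, K, N - K, n1) - en["lower"]))
      }
    }
  }
  expect_lt(worst, 1e-12)
  set.seed(4)
  worst_big <- 0
  for (i in 1:500) {
    N <- sample(41:500, 1); K <- sample(0:N, 1); n1 <- sample(1:N, 1)
    lo <- max(0, n1 - (N - K)); hi <- min(K, n1)
    x <- sample(lo:hi, 1)
    en <- hyper_tails_enum(N, K, n1, x)
    worst_big <- max(worst_big,
                     abs(phyper(x - 1, K, N - K, n1, lower.tail = FALSE) -
                           en["upper"]),
                     abs(phyper(x, K, N - K, n1) - en["lower"]))
  }
  expect_lt(worst_big, 1e-12)

  # empty first-bin overlap has upper tail exactly 1
  ind0 <- rep(FALSE, 200); ind0[150:169] <- TRUE
  rec0 <- test_discrete(ind0, bins)
  expect_equal(phyper(-1, 20, 180, 10, lower.tail = FALSE), 1)
  expect_equal(rec0$count_first, 0)
  expect_equal(rec0$direction, "low")

  # everyone a carrier: forced margin, untestable direction
  recN <- test_discrete(rep(TRUE, 200), bins)
  expect_equal(recN$p_value, 1)
  expect_equal(recN$direction, "none")

  # no carriers at all
  recK0 <- test_discrete(rep(FALSE, 200), bins)
  expect_true(recK0$untestable)
})

test_that("enrichment table applies exact Bonferroni accounting", {
  truth <- synthetic_truth(k = 4, d = 8, noise_sd = 0.05, seed = 51)
  cohort <- sample_cross_section(truth, 300, seed = 52)
  planted <- plant_trait(cohort, trait_spec("sig", "continuous", 1,
                                            effect = 5), seed = 53)
  disc <- plant_trait(cohort, trait_spec("grp", "discrete", 2,
                                         base_rate = 0.1, boost_rate = 0.5),
                      seed = 54)
  set.seed(55)
  nulls <- matrix(rnorm(300 * 3), 300, 3,
                  dimnames = list(NULL, paste0("null", 1:3)))
  model <- fit_cohort_model(as_cohort_table(cohort$data), 4)
  traits <- as_cohort_table(nulls, traits = list(sig = planted, grp = disc))
  tab <- run_enrichment(traits, model, n_bins = 20, alpha = 0.05)

  # family accounting: 4 continuous x 4 archetypes + 2 categories x 2 tails
  # x 4 archetypes
  expect_equal(tab$n_tests, 4L * 4L + 2L * 2L * 4L)
  expect_equal(tab$bonferroni_threshold, 0.05 / tab$n_tests)
  expect_equal(sum(tab$records$significant),
               sum(tab$records$p_value < tab$bonferroni_threshold &
                     !tab$records$untestable))
  expect_true(all(tab$records$p_value >= 0 & tab$records$p_value <= 1))

  # the planted continuous trait is enriched (high) somewhere, nulls nowhere
  sig <- tab$records[tab$records$significant, ]
  expect_true(any(sig$feature == "sig" & sig$direction == "high"))
  # permuting a planted trait across rows destroys its enrichment
  traits_perm <- traits
  set.seed(56)
  traits_perm$data$sig <- sample(traits_perm$data$sig)
  tab_perm <- run_enrichment(traits_perm, model, n_bins = 20, alpha = 0.05)
  rp <- tab_perm$records
  expect_false(any(rp$significant[rp$feature == "sig"]))

  # missing discrete responses become an explicit category
  traits_na <- traits
  traits_na$data$grp[1:40] <- NA
  tab_na <- run_enrichment(traits_na, model, n_bins = 20, alpha = 0.05)
  expect_true("no response" %in% tab_na$records$category)

  empty <- feature_table(traits$data[, 1:2], traits$meta[0, ])
  expect_error(run_enrichment(empty, model), "no testable|no aligned")

  # TSV export round-trips the record table
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_tsv(tab, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(tab$records))
  expect_equal(back$p_value, tab$records$p_value, tolerance = 1e-12)
})

test_that("bin-count sensitivity is deterministic and summarized against the middle", {
  truth <- synthetic_truth(k = 3, d = 6, noise_sd = 0.05, seed = 61)
  cohort <- sample_cross_section(truth, 200, seed = 62)
  planted <- plant_trait(cohort, trait_spec("sig", "continuous", 1,
                                            effect = 5), seed = 63)
  model <- fit_cohort_model(as_cohort_table(cohort$data), 3)
  traits <- as_cohort_table(matrix(rnorm(200), 200, 1,
                                   dimnames = list(NULL, "nullf")),
                            traits = list(sig = planted))
  same <- bin_sensitivity(traits, model, bin_counts = c(20, 20))
  expect_identical(same$tables[[1]]$records, same$tables[[2]]$records)

  bs <- bin_sensitivity(traits, model, bin_counts = c(15, 20, 25))
  expect_equal(bs$reference_bins, 20)
  expect_equal(bs$summary$gained[bs$summary$n_bins == 20], 0)
  expect_equal(bs$summary$lost[bs$summary$n_bins == 20], 0)
  expect_error(bin_sensitivity(traits, model, bin_counts = c(1)), ">= 2")
})

test_that("low-abundance pre-filter keeps prevalent, abundant features", {
  set.seed(71)
  counts <- cbind(good = rpois(100, 50),
                  sparse = rbinom(100, 1, 0.5) * rpois(100, 60),
                  rare = rpois(100, 2))
  tab <- toy_table(counts)
  kept <- filter_low_abundance(tab, max_zero_fraction = 0.05, min_mean = 5)
  expect_equal(feature_names(kept), "good")
})
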