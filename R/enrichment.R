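#' Euclidean distances from score rows to an archetype
#'
#' @param points n x m matrix of coordinates (model space).
#' @param archetype length-m coordinate vector.
#' @return n vector of non-negative distances.
#' @export
distances_to_archetype <- function(points, archetype) {
  points <- as.matrix(points)
  if (ncol(points) != length(archetype))
    stop("dimension mismatch: points have ", ncol(points),
         " columns, archetype has length ", length(archetype))
  sqrt(rowSums(sweep(points, 2, archetype, "-")^2))
}

#' Equal-count bins by distance to an archetype
#'
#' Orders the cohort by distance (ties broken by original row index, a stable
#' sort) and splits it into `n_bins` bins whose sizes differ by at most one;
#' bin 1 holds the points nearest the archetype.  Equal-count rather than
#' equal-width binning guarantees a fixed first-bin sample size for the
#' enrichment tests.
#'
#' @param distances n vector of distances.
#' @param n_bins number of bins (2 <= n_bins <= n).
#' @param archetype_index optional label recorded in the result.
#' @return A `bin_assignment`: list with `bin_of` (n vector of bin indices),
#'   `n_bins`, `distances` and `archetype_index`.
#' @export
assign_bins <- function(distances, n_bins = 20, archetype_index = NA_integer_) {
  n <- length(distances)
  if (n_bins < 2) stop("`n_bins` must be >= 2")
  if (n < n_bins) stop("fewer points (", n, ") than bins (", n_bins, ")")
  ord <- order(distances, seq_len(n)) # stable: ties by row index
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  bin_of <- integer(n)
  bin_of[ord] <- rep(seq_len(n_bins), times = sizes)
  structure(list(bin_of = bin_of, n_bins = n_bins, distances = distances,
                 archetype_index = archetype_index),
            class = "bin_assignment")
}

empty_record <- function(feature, category, archetype, test) {
  data.frame(feature = feature, category = category, archetype = archetype,
             test = test, mean_first = NA_real_, mean_rest = NA_real_,
             median_first = NA_real_, median_rest = NA_real_,
             count_first = NA_integer_, p_value = 1, direction = "none",
             significant = FALSE, decay_monotonicity = NA_real_,
             untestable = TRUE, stringsAsFactors = FALSE)
}

#' First-bin enrichment test for a continuous trait
#'
#' Welch's two-sample two-sided t-test of the trait in the first bin (closest
#' to the archetype) against the rest of the cohort.  Means and medians of
#' both groups are recorded; the direction is the sign of the mean
#' difference.  A descriptive decay-monotonicity score (Spearman correlation
#' of per-bin means with bin index) is attached but never gates
#' significance.
#'
#' @param feature n vector of trait values (missing allowed, excluded
#'   pairwise).
#' @param bins a [assign_bins()] result aligned with `feature`.
#' @return One-row data frame (an enrichment record).
#' @export
test_continuous <- function(feature, bins) {
  stopifnot(inherits(bins, "bin_assignment"))
  if (length(feature) != length(bins$bin_of))
    stop("feature length does not match the bin assignment")
  first <- feature[bins$bin_of == 1]
  rest <- feature[bins$bin_of != 1]
  first <- first[!is.na(first)]; rest <- rest[!is.na(rest)]
  rec <- empty_record(NA_character_, NA_character_, bins$archetype_index,
                      "welch_t")
  if (length(first) < 2 || length(rest) < 2) return(rec)
  rec$mean_first <- mean(first); rec$mean_rest <- mean(rest)
  rec$median_first <- median(first); rec$median_rest <- median(rest)
  tt <- tryCatch(t.test(first, rest), error = function(e) NULL)
  if (is.null(tt) || !is.finite(tt$p.value)) return(rec) # zero-variance etc.
  rec$p_value <- tt$p.value
  rec$direction <- if (rec$mean_first > rec$mean_rest) "high"
                   else if (rec$mean_first < rec$mean_rest) "low" else "none"
  rec$untestable <- FALSE
  bin_means <- tapply(feature, bins$bin_of, mean, na.rm = TRUE)
  if (sum(is.finite(bin_means)) >= 3 && sd(bin_means, na.rm = TRUE) > 0)
    rec$decay_monotonicity <- suppressWarnings(
      cor(as.numeric(names(bin_means)), bin_means, method = "spearman",
          use = "complete.obs"))
  rec
}

#' First-bin enrichment test for a discrete category
#'
#' Hypergeometric tail probabilities for the category count in the first bin:
#' with N the cohort size, K the carriers, n1 the first-bin size and x the
#' first-bin carriers, the upper tail P(X >= x) tests over-representation and
#' the lower tail P(X <= x) depletion.  The reported p-value is the smaller
#' tail and the direction names it; both tails count as performed tests in
#' the Bonferroni family.
#'
#' @param category_indicator n logical vector (TRUE = carrier; `NA` treated
#'   as non-carrier of this category).
#' @param bins a [assign_bins()] result aligned with the indicator.
#' @return One-row data frame (an enrichment record) with attribute
#'   `"n_tests"` = 2.
#' @export
test_discrete <- function(category_indicator, bins) {
  stopifnot(inherits(bins, "bin_assignment"))
  ind <- as.logical(category_indicator)
  ind[is.na(ind)] <- FALSE
  if (length(ind) != length(bins$bin_of))
    stop("indicator length does not match the bin assignment")
  N <- length(ind); K <- sum(ind)
  first <- bins$bin_of == 1
  n1 <- sum(first); x <- sum(ind & first)
  rec <- empty_record(NA_character_, NA_character_, bins$archetype_index,
                      "hypergeometric")
  rec$count_first <- x
  if (K == 0) return(rec)
  upper <- phyper(x - 1, K, N - K, n1, lower.tail = FALSE) # P(X >= x)
  lower <- phyper(x, K, N - K, n1)                         # P(X <= x)
  rec$p_value <- min(upper, lower)
  rec$mean_first <- x / n1
  rec$mean_rest <- (K - x) / (N - n1)
  rec$direction <- if (K == N) "none"
                   else if (upper < lower) "high"
                   else if (lower < upper) "low" else "none"
  if (K == N) rec$p_value <- 1
  rec$untestable <- FALSE
  attr(rec, "n_tests") <- 2L
  rec
}

align_features_to_scores <- function(features, scores) {
  keys <- row_key(features$data$participant_id, features$data$visit_index)
  score_keys <- rownames(scores)
  if (is.null(score_keys))
    stop("scores must carry participant::visit rownames for alignment")
  common <- intersect(score_keys, keys)
  if (length(common) == 0) stop("no aligned rows between features and scores")
  list(features = features$data[match(common, keys), , drop = FALSE],
       scores = scores[match(common, score_keys), , drop = FALSE])
}

#' Enrichment of every trait at every archetype
#'
#' Expands each discrete feature into per-category indicators (missing
#' responses become an explicit `"no response"` category), tests every
#' (feature-or-category, archetype) pair with the appropriate first-bin test,
#' and applies Bonferroni control at `alpha / n_tests`, where `n_tests`
#' counts every test actually performed (two tails per discrete category).
#'
#' @param features a `feature_table` of traits, aligned to `scores` rows by
#'   (participant, visit) key.
#' @param model an `archetype_model` providing the archetype positions.
#' @param scores n x m model-space coordinates with participant::visit
#'   rownames (defaults to the model's fitting scores).
#' @param n_bins number of distance bins (default 20).
#' @param alpha family-wise error level (default 0.05).
#' @return An `enrichment_table`: list with `records` (data frame sorted by
#'   p-value), `n_tests`, `alpha` and `bonferroni_threshold`.
#' @export
run_enrichment <- function(features, model, scores = model$projection$scores,
                           n_bins = 20, alpha = 0.05) {
  stopifnot(inherits(features, "feature_table"),
            inherits(model, "archetype_model"))
  al <- align_features_to_scores(features, scores)
  fdat <- al$features; sc <- al$scores
  meta <- features$meta
  records <- list(); n_tests <- 0L

  for (a in seq_len(model$k)) {
    d <- distances_to_archetype(sc, model$archetypes_pc[a, ])
    bins <- assign_bins(d, n_bins, archetype_index = a)
    for (f in meta$feature) {
      kind <- meta$kind[meta$feature == f]
      if (kind == "continuous") {
        rec <- test_continuous(fdat[[f]], bins)
        rec$feature <- f
        if (!rec$untestable) n_tests <- n_tests + 1L
        records[[length(records) + 1]] <- rec
      } else {
        v <- fdat[[f]]
        v[is.na(v)] <- "no response"
        for (cat in sort(unique(v))) {
          rec <- test_discrete(v == cat, bins)
          rec$feature <- f; rec$category <- cat
          if (!rec$untestable)
            n_tests <- n_tests + attr(rec, "n_tests")
          records[[length(records) + 1]] <- rec
        }
      }
    }
  }
  if (n_tests == 0L) stop("no testable features: Bonferroni family is empty")
  records <- do.call(rbind, records)
  threshold <- alpha / n_tests
  records$significant <- !records$untestable & records$p_value < threshold
  records <- records[order(records$p_value), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, n_tests = n_tests, alpha = alpha,
                 bonferroni_threshold = threshold, n_bins = n_bins),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("<enrichment_table> ", x$n_tests, " tests; Bonferroni threshold ",
      signif(x$bonferroni_threshold, 5), "; ",
      sum(x$records$significant), " significant\n", sep = "")
  print(head(x$records, 10))
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error level.
#' @param n_tests number of tests in the family.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("`n_tests` must be >= 1")
  alpha / n_tests
}

#' Sensitivity of the enrichment table to the number of bins
#'
#' Re-runs [run_enrichment()] for each bin count and summarizes, per count,
#' how many significant (feature/category, archetype) hits are gained or
#' lost relative to the middle (median) bin count.
#'
#' @inheritParams run_enrichment
#' @param bin_counts integer vector of bin counts to compare (each >= 2).
#' @return A `bin_sensitivity` result: list with `tables` (one
#'   `enrichment_table` per count) and `summary` (data frame: n_bins,
#'   n_significant, gained, lost).
#' @export
bin_sensitivity <- function(features, model, scores = model$projection$scores,
                            bin_counts = c(15, 20, 25), alpha = 0.05) {
  if (any(bin_counts < 2)) stop("each bin count must be >= 2")
  tables <- lapply(bin_counts, function(b)
    run_enrichment(features, model, scores, n_bins = b, alpha = alpha))
  names(tables) <- as.character(bin_counts)
  hit_key <- function(tab) {
    r <- tab$records[tab$records$significant, , drop = FALSE]
    paste(r$feature, r$category, r$archetype, r$direction)
  }
  mid <- order(bin_counts)[ceiling(length(bin_counts) / 2)]
  ref_hits <- hit_key(tables[[mid]])
  summary <- data.frame(
    n_bins = bin_counts,
    n_significant = vapply(tables, function(t) sum(t$records$significant),
                           integer(1)),
    gained = vapply(tables, function(t)
      length(setdiff(hit_key(t), ref_hits)), integer(1)),
    lost = vapply(tables, function(t)
      length(setdiff(ref_hits, hit_key(t))), integer(1)))
  rownames(summary) <- NULL
  structure(list(tables = tables, summary = summary,
                 reference_bins = bin_counts[mid]),
            class = "bin_sensitivity")
}

#' @export
print.bin_sensitivity <- function(x, ...) {
  cat("<bin_sensitivity> reference:", x$reference_bins, "bins\n")
  print(x$summary)
  invisible(x)
}

#' Prevalence/abundance pre-filter for compositional count features
#'
#' Keeps features (e.g. microbial genera) whose fraction of zero values is
#' below `max_zero_fraction` and whose mean exceeds `min_mean`.
#'
#' @param table a `feature_table` of count-like continuous features.
#' @param max_zero_fraction maximum tolerated fraction of zeros (default
#'   0.05).
#' @param min_mean minimum mean value (default 5).
#' @return The filtered `feature_table`.
#' @export
filter_low_abundance <- function(table, max_zero_fraction = 0.05,
                                 min_mean = 5) {
  stopifnot(inherits(table, "feature_table"))
  cont <- feature_names(table, "continuous")
  keep <- vapply(cont, function(f) {
    v <- table$data[[f]]
    mean(v == 0, na.rm = TRUE) < max_zero_fraction &&
      mean(v, na.rm = TRUE) > min_mean
  }, logical(1))
  drop <- cont[!keep]
  out <- table
  out$data <- table$data[, setdiff(names(table$data), drop), drop = FALSE]
  out$meta <- table$meta[!(table$meta$feature %in% drop), , drop = FALSE]
  out
}
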