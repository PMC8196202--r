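#' Fit the full cohort model: standardize, reduce, fit, test
#'
#' Convenience wrapper running the cross-sectional pipeline on a feature
#' table: impute and z-score the continuous features, reduce to k - 1
#' principal components, fit the minimal-volume enclosing simplex, and
#' (optionally) run the shuffle-null significance test.  The returned model
#' carries the normalization parameters and projection needed to place later
#' visits in the same space.
#'
#' @param table a `feature_table` (one row per selected participant visit).
#' @param k number of archetypes.
#' @param n_shuffles shuffles for the significance test (0 to skip).
#' @param seed root seed for the shuffle null.
#' @param config a [simplex_fit_config()].
#' @return An `archetype_model` with added elements `normalization` (the
#'   `normalized_matrix`, including means/sds) and, if requested,
#'   `significance`.
#' @export
fit_cohort_model <- function(table, k, n_shuffles = 0, seed = 1,
                             config = simplex_fit_config()) {
  nm <- impute_and_standardize(table)
  proj <- pca_reduce(nm, k - 1)
  model <- fit_simplex(proj, k, config)
  model$normalization <- nm
  if (n_shuffles > 0)
    model$significance <- significance_test(nm, k, n_shuffles, seed, config)
  model
}

#' Serialize a fitted model to JSON
#'
#' Writes the archetype coordinates (PC and feature space), projection
#' (center, loadings, explained variance), normalization parameters, fit
#' configuration, t-ratio and any significance summary, so a model can be
#' reloaded and later visits projected without refitting.
#'
#' @param model an `archetype_model` (ideally from [fit_cohort_model()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "archetype_model"))
  obj <- list(
    k = model$k, m = model$m,
    archetypes_pc = model$archetypes_pc,
    archetypes_feature_space = model$archetypes_feature_space,
    t_ratio = model$t_ratio,
    volume = model$volume,
    hull_volume = model$hull_volume,
    fit_config = unclass(model$fit_config),
    projection = list(center = model$projection$center,
                      loadings = model$projection$loadings,
                      explained_variance_fraction =
                        model$projection$explained_variance_fraction),
    normalization = if (!is.null(model$normalization))
      list(feature_means = model$normalization$feature_means,
           feature_sds = model$normalization$feature_sds,
           features = model$normalization$features),
    significance = if (!is.null(model$significance))
      list(t_real = model$significance$t_real,
           p_value = model$significance$p_value,
           p_label = model$significance$p_label,
           n_shuffles = model$significance$n_shuffles))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model serialized with [write_model_json()]
#'
#' Rebuilds an `archetype_model` sufficient for projection, enrichment and
#' trajectory analysis (the original scores are not stored; supply scores
#' explicitly where needed).
#'
#' @param path JSON file path.
#' @return An `archetype_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(x) {
    m <- as.matrix(x)
    dimnames(m) <- NULL
    m
  }
  proj <- structure(list(
    scores = NULL,
    loadings = to_mat(obj$projection$loadings),
    explained_variance_fraction = obj$projection$explained_variance_fraction,
    center = unlist(obj$projection$center)), class = "pca_projection")
  norm <- NULL
  if (!is.null(obj$normalization)) {
    feats <- unlist(obj$normalization$features)
    norm <- structure(list(
      values = NULL,
      feature_means = setNames(unlist(obj$normalization$feature_means), feats),
      feature_sds = setNames(unlist(obj$normalization$feature_sds), feats),
      imputation_mask = NULL, row_keys = NULL, features = feats),
      class = "normalized_matrix")
    rownames(proj$loadings) <- feats
    names(proj$center) <- feats
  }
  structure(list(k = obj$k, m = obj$m,
                 archetypes_pc = to_mat(obj$archetypes_pc),
                 archetypes_feature_space = to_mat(obj$archetypes_feature_space),
                 t_ratio = obj$t_ratio, volume = obj$volume,
                 hull_volume = obj$hull_volume,
                 fit_config = do.call(simplex_fit_config, obj$fit_config),
                 projection = proj,
                 normalization = norm,
                 significance = obj$significance),
            class = "archetype_model")
}

#' Write an enrichment table to TSV
#'
#' Columns: feature, category, archetype, test, mean_first, mean_rest,
#' median_first, median_rest, count_first, p_value, direction, significant.
#'
#' @param table an `enrichment_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(table, path) {
  stopifnot(inherits(table, "enrichment_table"))
  cols <- c("feature", "category", "archetype", "test", "mean_first",
            "mean_rest", "median_first", "median_rest", "count_first",
            "p_value", "direction", "significant")
  utils::write.table(table$records[cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scatter of the score cloud and fitted archetypes on two PCs
#'
#' @param x an `archetype_model` fitted with scores available.
#' @param dims which two PCs to draw (default 1:2).
#' @param ... passed to [graphics::plot()].
#' @export
plot.archetype_model <- function(x, dims = c(1, 2), ...) {
  sc <- x$projection$scores
  if (is.null(sc)) stop("model carries no scores (loaded from JSON?)")
  graphics::plot(sc[, dims], pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.4), ...)
  A <- x$archetypes_pc
  ord <- c(seq_len(nrow(A)), 1)
  graphics::lines(A[ord, dims], col = "firebrick", lwd = 2)
  graphics::points(A[, dims], col = "firebrick", pch = 17, cex = 1.4)
  invisible(x)
}
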