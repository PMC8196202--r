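#' Correlations between distance-to-archetype and trait levels
#'
#' Pearson correlation between each continuous trait and the Euclidean
#' distance of every sample to each archetype (pairwise-complete).  The sign
#' convention follows the distance axis: r > 0 means low trait levels close
#' to the archetype (the trait rises with distance), r < 0 means high levels
#' close to the archetype.
#'
#' @param scores n x m model-space coordinates with participant::visit
#'   rownames.
#' @param model an `archetype_model`.
#' @param features a `feature_table`; only continuous features are used.
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @return A named list (one element per archetype) of data frames
#'   (`feature`, `r`, `n_used`, `untestable`) sorted by `r` descending.
#' @export
archetype_distance_correlations <- function(scores, model, features,
                                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "archetype_model"),
            inherits(features, "feature_table"))
  al <- align_features_to_scores(features, scores)
  cont <- feature_names(features, "continuous")
  out <- vector("list", model$k)
  for (a in seq_len(model$k)) {
    d <- distances_to_archetype(al$scores, model$archetypes_pc[a, ])
    rows <- lapply(cont, function(f) {
      v <- al$features[[f]]
      ok <- !is.na(v)
      n_used <- sum(ok)
      if (n_used < 3 || sd(v[ok]) == 0)
        return(data.frame(feature = f, r = NA_real_, n_used = n_used,
                          untestable = TRUE))
      data.frame(feature = f, r = cor(d[ok], v[ok], method = method),
                 n_used = n_used, untestable = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$r, tab$feature, na.last = TRUE), , drop = FALSE]
    rownames(tab) <- NULL
    out[[a]] <- tab
  }
  names(out) <- paste0("archetype_", seq_len(model$k))
  out
}

#' Correlations between principal components and trait levels
#'
#' Pearson correlation between each of the first `n_pcs` score vectors and
#' each continuous trait, ranking the traits that shape each axis of
#' variation.  Constant traits are flagged and reported with r = 0.
#'
#' @param projection a `pca_projection`.
#' @param features a `feature_table` aligned to the scores by
#'   (participant, visit) key.
#' @param n_pcs number of leading components to profile.
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @return A named list (one element per PC) of data frames (`feature`, `r`,
#'   `n_used`, `zero_variance`) sorted by `r` descending.
#' @export
pc_feature_correlations <- function(projection, features, n_pcs,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(projection, "pca_projection"),
            inherits(features, "feature_table"))
  if (n_pcs > ncol(projection$scores))
    stop("n_pcs exceeds the projection dimension")
  al <- align_features_to_scores(features, projection$scores)
  cont <- feature_names(features, "continuous")
  out <- vector("list", n_pcs)
  for (p in seq_len(n_pcs)) {
    pc <- al$scores[, p]
    rows <- lapply(cont, function(f) {
      v <- al$features[[f]]
      ok <- !is.na(v)
      if (sum(ok) < 3 || sd(v[ok]) == 0)
        return(data.frame(feature = f, r = 0, n_used = sum(ok),
                          zero_variance = TRUE))
      data.frame(feature = f, r = cor(pc[ok], v[ok], method = method),
                 n_used = sum(ok), zero_variance = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$r, tab$feature), , drop = FALSE]
    rownames(tab) <- NULL
    out[[p]] <- tab
  }
  names(out) <- colnames(projection$scores)[seq_len(n_pcs)]
  out
}

#' Top positively and negatively correlated traits for one axis
#'
#' @param correlation_table one element of [pc_feature_correlations()] or
#'   [archetype_distance_correlations()].
#' @param n number of traits to keep from each end (default 10).
#' @return Data frame with the `n` most positive and `n` most negative rows.
#' @export
top_correlations <- function(correlation_table, n = 10) {
  tab <- correlation_table[!is.na(correlation_table$r), , drop = FALSE]
  tab <- tab[order(-tab$r), , drop = FALSE]
  n_pos <- min(n, sum(tab$r > 0))
  n_neg <- min(n, sum(tab$r < 0))
  out <- rbind(head(tab, n_pos), utils::tail(tab, n_neg))
  rownames(out) <- NULL
  out
}

#' Cumulative explained-variance fraction of the leading components
#'
#' @param projection a `pca_projection`.
#' @param n_pcs number of leading components (defaults to all kept).
#' @return Fraction of total variance explained by the first `n_pcs`
#'   components.
#' @export
explained_variance <- function(projection, n_pcs = NULL) {
  stopifnot(inherits(projection, "pca_projection"))
  f <- projection$explained_variance_fraction
  if (is.null(n_pcs)) n_pcs <- length(f)
  if (n_pcs > length(f)) stop("n_pcs exceeds the stored components")
  sum(f[seq_len(n_pcs)])
}
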