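#' Construct a cohort feature table
#'
#' A `feature_table` couples a wide per-visit data frame (one row per
#' participant/visit, one column per measured feature) with feature metadata
#' declaring each feature `continuous` or `discrete` and its group (e.g.
#' clinical_lab, metabolite, questionnaire).  All downstream preprocessing,
#' enrichment and trajectory functions consume this container.
#'
#' @param data data frame with columns `participant_id`, `visit_index` and one
#'   column per feature. Missing cells are `NA`.
#' @param meta data frame with columns `feature`, `kind`
#'   (`"continuous"`/`"discrete"`) and `group`.
#' @return An object of class `feature_table` with elements `data` and `meta`.
#' @export
feature_table <- function(data, meta) {
  stopifnot(is.data.frame(data), is.data.frame(meta))
  need <- c("participant_id", "visit_index")
  if (!all(need %in% names(data)))
    stop("`data` must have participant_id and visit_index columns")
  if (!all(c("feature", "kind", "group") %in% names(meta)))
    stop("`meta` must have feature, kind and group columns")
  if (!all(meta$kind %in% c("continuous", "discrete")))
    stop("feature kind must be 'continuous' or 'discrete'")

  feats <- setdiff(names(data), need)
  missing_meta <- setdiff(feats, meta$feature)
  if (length(missing_meta))
    stop("features in data absent from meta: ", paste(missing_meta, collapse = ", "))
  if (anyDuplicated(meta$feature))
    stop("duplicated feature names in meta")

  key <- row_key(data$participant_id, data$visit_index)
  if (anyDuplicated(key))
    stop("duplicate (participant, visit) pair: ", key[duplicated(key)][1])

  data$participant_id <- as.character(data$participant_id)
  data$visit_index <- as.integer(data$visit_index)
  for (f in feats) {
    kind <- meta$kind[match(f, meta$feature)]
    if (kind == "continuous" && !is.numeric(data[[f]]))
      stop("continuous feature '", f, "' is not numeric")
    if (kind == "discrete") data[[f]] <- as.character(data[[f]])
  }
  meta <- meta[meta$feature %in% feats, , drop = FALSE]
  rownames(meta) <- NULL

  structure(list(data = data, meta = meta), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$data), " rows (",
      length(unique(x$data$participant_id)), " participants), ",
      nrow(x$meta), " features (",
      sum(x$meta$kind == "continuous"), " continuous / ",
      sum(x$meta$kind == "discrete"), " discrete)\n", sep = "")
  invisible(x)
}

feature_names <- function(table, kind = NULL) {
  m <- table$meta
  if (!is.null(kind)) m <- m[m$kind %in% kind, , drop = FALSE]
  m$feature
}

#' Load a cohort table and its feature metadata from delimited files
#'
#' Reads CSV or TSV (chosen by file extension), records empty cells and
#' `NA`/`NaN` tokens as missing, and validates the result as a
#' [feature_table()].  Non-numeric tokens in a continuous column and features
#' missing from the metadata are errors.
#'
#' @param data_path path to the wide cohort table (`participant_id`,
#'   `visit_index`, feature columns).
#' @param meta_path path to the metadata table (`feature`, `kind`, `group`).
#' @return A `feature_table`.
#' @export
load_cohort <- function(data_path, meta_path) {
  read_any <- function(path, colClasses = NA) {
    if (!file.exists(path)) stop("file not found: ", path)
    fun <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) read.delim else read.csv
    fun(path, na.strings = c("", "NA", "NaN"), check.names = FALSE,
        stringsAsFactors = FALSE, colClasses = colClasses)
  }
  meta <- read_any(meta_path)
  raw <- read_any(data_path, colClasses = "character")
  if (!all(c("participant_id", "visit_index") %in% names(raw)))
    stop("data file must have participant_id and visit_index columns")

  out <- raw
  out$visit_index <- as.integer(raw$visit_index)
  for (f in setdiff(names(raw), c("participant_id", "visit_index"))) {
    kind <- meta$kind[match(f, meta$feature)]
    if (length(kind) == 1 && !is.na(kind) && kind == "continuous") {
      v <- raw[[f]]
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop("non-numeric value '", v[bad[1]], "' in continuous column '", f,
             "' at data row ", bad[1])
      out[[f]] <- num
    }
  }
  absent <- setdiff(meta$feature, names(out))
  if (length(absent))
    stop("features in meta absent from data: ", paste(absent, collapse = ", "))
  feature_table(out, meta)
}

#' Iteratively filter participants and features by missingness
#'
#' Removes participants whose missing fraction across continuous features
#' exceeds `max_fraction` (all of their visits), then features whose missing
#' fraction across the remaining rows exceeds it, repeating both passes until
#' no further removal occurs, so the surviving table satisfies both
#' constraints simultaneously and the result does not depend on pass order.
#'
#' @param table a `feature_table`.
#' @param max_fraction maximum tolerated missing fraction in `[0, 1)`
#'   (default `0.10`).
#' @return The filtered `feature_table` with an attribute `"removal_log"`
#'   listing removed participants and features per iteration.
#' @export
filter_by_missingness <- function(table, max_fraction = 0.10) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(max_fraction) || max_fraction < 0 || max_fraction >= 1)
    stop("`max_fraction` must satisfy 0 <= max_fraction < 1")

  data <- table$data
  cont <- feature_names(table, "continuous")
  log <- list()
  repeat {
    changed <- FALSE
    if (length(cont) == 0 || nrow(data) == 0)
      stop("empty cohort after missingness filter")
    miss <- is.na(as.matrix(data[cont]))
    pfrac <- tapply(rowMeans(miss), data$participant_id, mean)
    bad_p <- names(pfrac)[pfrac > max_fraction]
    if (length(bad_p)) {
      data <- data[!(data$participant_id %in% bad_p), , drop = FALSE]
      log[[length(log) + 1]] <- list(participants_removed = bad_p)
      changed <- TRUE
    }
    if (nrow(data) == 0) stop("empty cohort after missingness filter")
    miss <- is.na(as.matrix(data[cont]))
    ffrac <- colMeans(miss)
    bad_f <- cont[ffrac > max_fraction]
    if (length(bad_f)) {
      data <- data[, setdiff(names(data), bad_f), drop = FALSE]
      cont <- setdiff(cont, bad_f)
      log[[length(log) + 1]] <- list(features_removed = bad_f)
      changed <- TRUE
    }
    if (!changed) break
  }
  if (length(cont) == 0) stop("empty cohort after missingness filter")
  meta <- table$meta[table$meta$feature %in% setdiff(names(data),
            c("participant_id", "visit_index")), , drop = FALSE]
  out <- feature_table(data, meta)
  attr(out, "removal_log") <- log
  out
}

#' Randomly select one visit per participant
#'
#' Draws one visit uniformly at random per participant (avoiding the
#' pseudo-replication of repeated visits), deterministically for a given
#' seed.  The retained (participant, visit) keys are the join keys used to
#' align every other data type with the cross-sectional model.
#'
#' @param table a `feature_table`.
#' @param seed integer seed for the selection.
#' @return A `feature_table` with exactly one row per participant, carrying
#'   the selected keys in attribute `"selected_keys"`.
#' @export
select_one_visit <- function(table, seed) {
  stopifnot(inherits(table, "feature_table"))
  data <- table$data
  if (nrow(data) == 0) stop("empty table")
  ids <- unique(data$participant_id)
  keep <- with_seed(seed, {
    vapply(ids, function(p) {
      rows <- which(data$participant_id == p)
      if (length(rows) == 1) rows else rows[sample.int(length(rows), 1)]
    }, integer(1))
  })
  keep <- sort(keep)
  out <- table
  out$data <- data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  attr(out, "selected_keys") <-
    out$data[, c("participant_id", "visit_index"), drop = FALSE]
  out
}

#' Impute missing values and z-score the continuous features
#'
#' Each continuous feature has its missing cells replaced by the observed
#' mean, then is standardized to mean 0 / sd 1 using the population standard
#' deviation (divide by n).  Because imputation precedes standardization,
#' imputed cells land exactly at z = 0.  The learned means and sds are stored
#' so later visits can be projected with [apply_standardization()].
#'
#' @param table a `feature_table`; only its continuous features are used.
#' @return A `normalized_matrix`: list with `values` (n x d z-score matrix,
#'   rownames are participant::visit keys), `feature_means`, `feature_sds`,
#'   `imputation_mask`, `row_keys` and `features`.
#' @export
impute_and_standardize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  cont <- feature_names(table, "continuous")
  if (length(cont) == 0) stop("no continuous features to standardize")
  X <- as.matrix(table$data[cont])
  mask <- is.na(X)
  n <- nrow(X)

  means <- numeric(length(cont)); sds <- numeric(length(cont))
  for (j in seq_along(cont)) {
    obs <- X[!mask[, j], j]
    if (length(unique(obs)) < 2)
      stop("zero-variance feature: ", cont[j])
    X[mask[, j], j] <- mean(obs)
    means[j] <- mean(X[, j])
    sds[j] <- sqrt(mean((X[, j] - means[j])^2)) # population convention
    if (sds[j] <= 0) stop("zero-variance feature: ", cont[j])
    X[, j] <- (X[, j] - means[j]) / sds[j]
  }
  keys <- table$data[, c("participant_id", "visit_index"), drop = FALSE]
  rownames(X) <- row_key(keys$participant_id, keys$visit_index)
  structure(list(values = X,
                 feature_means = setNames(means, cont),
                 feature_sds = setNames(sds, cont),
                 imputation_mask = mask,
                 row_keys = keys,
                 features = cont),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("<normalized_matrix> ", nrow(x$values), " x ", ncol(x$values),
      " (z-units; ", sum(x$imputation_mask), " imputed cells)\n", sep = "")
  invisible(x)
}

#' Standardize new rows with reference normalization parameters
#'
#' Transforms rows (e.g. later visits of the same participants) using the
#' means and sds stored in a reference [impute_and_standardize()] fit, never
#' refitting, so the new coordinates live in the reference z-space.  Missing
#' cells take the reference mean (z = 0).
#'
#' @param table a `feature_table` whose continuous features are all present in
#'   the reference.
#' @param ref a `normalized_matrix` supplying the reference means/sds.
#' @return A `normalized_matrix` in the reference scale (its
#'   `feature_means`/`feature_sds` are the reference parameters).
#' @export
apply_standardization <- function(table, ref) {
  stopifnot(inherits(table, "feature_table"), inherits(ref, "normalized_matrix"))
  feats <- ref$features
  absent <- setdiff(feats, names(table$data))
  if (length(absent))
    stop("features absent from table: ", paste(absent, collapse = ", "))
  X <- as.matrix(table$data[feats])
  mask <- is.na(X)
  X <- sweep(X, 2, ref$feature_means[feats], "-")
  X <- sweep(X, 2, ref$feature_sds[feats], "/")
  X[mask] <- 0
  keys <- table$data[, c("participant_id", "visit_index"), drop = FALSE]
  rownames(X) <- row_key(keys$participant_id, keys$visit_index)
  structure(list(values = X,
                 feature_means = ref$feature_means,
                 feature_sds = ref$feature_sds,
                 imputation_mask = mask,
                 row_keys = keys,
                 features = feats),
            class = "normalized_matrix")
}
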