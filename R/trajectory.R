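#' Barycentric coordinates of a point with respect to the model simplex
#'
#' Solves the affine system `rbind(t(archetypes), 1) %*% w = c(point, 1)`:
#' the unique weights expressing the point relative to the k = m + 1
#' vertices.  The weights always sum to 1; the point lies inside the simplex
#' exactly when all weights are non-negative (up to a small tolerance).
#'
#' @param point length-m coordinate vector, or an n x m matrix of points.
#' @param model an `archetype_model` (or a k x m vertex matrix).
#' @return A k vector (or n x k matrix) of barycentric weights.
#' @export
barycentric_coordinates <- function(point, model) {
  A <- if (inherits(model, "archetype_model")) model$archetypes_pc else model
  pts <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  if (ncol(pts) != ncol(A))
    stop("point dimension does not match the simplex")
  W <- cpp_barycentric(pts, A)
  if (is.matrix(point)) W else drop(W)
}

#' Project longitudinal visits and assemble per-participant trajectories
#'
#' Every visit is standardized with the baseline normalization parameters
#' stored in the model (never refit), projected with the stored PCA loadings
#' and center, grouped per participant and ordered by visit.  Each time point
#' carries its barycentric weights and an outside-the-simplex flag, so
#' movement reflects the individual against a fixed frame.
#'
#' @param all_visits a `feature_table` holding every visit (the model's
#'   continuous features must all be present).
#' @param model a model from [fit_cohort_model()] (must carry
#'   `normalization`).
#' @param outside_tol tolerance on negative barycentric weights before a
#'   point counts as outside (default 1e-9; raise to absorb fit slack).
#' @return A list of `trajectory` objects: each has `participant_id`,
#'   `visit_index`, `coords` (t x m), `bary` (t x k) and `outside` (t
#'   logicals).
#' @export
build_trajectories <- function(all_visits, model, outside_tol = 1e-9) {
  stopifnot(inherits(all_visits, "feature_table"),
            inherits(model, "archetype_model"))
  if (is.null(model$normalization))
    stop("model carries no normalization parameters; use fit_cohort_model()")
  ref <- model$normalization
  nm <- apply_standardization(all_visits, ref)
  Z <- nm$values
  coords <- sweep(Z, 2, model$projection$center, "-") %*% model$projection$loadings
  W <- cpp_barycentric(coords, model$archetypes_pc)
  outside <- apply(W, 1, min) < -outside_tol

  ids <- nm$row_keys$participant_id
  visits <- nm$row_keys$visit_index
  out <- lapply(unique(ids), function(p) {
    rows <- which(ids == p)
    rows <- rows[order(visits[rows])]
    structure(list(participant_id = p,
                   visit_index = visits[rows],
                   coords = coords[rows, , drop = FALSE],
                   bary = W[rows, , drop = FALSE],
                   outside = outside[rows]),
              class = "trajectory")
  })
  names(out) <- unique(ids)
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$participant_id, ": ", length(x$visit_index),
      " visits, ", sum(x$outside), " outside the simplex\n", sep = "")
  invisible(x)
}

#' Displacement statistics of one trajectory
#'
#' @param trajectory a `trajectory` (>= 2 time points for non-trivial
#'   output).
#' @param model optional `archetype_model`; when supplied, per-archetype
#'   distance changes (last minus first visit) are included.
#' @return List with `n_timepoints`, `first_to_last_distance`, `max_step`,
#'   `path_length`, `n_outside` and `per_archetype_delta` (distance at last
#'   visit minus distance at first visit, negative = moved toward), plus
#'   `untestable` when fewer than two time points exist.
#' @export
displacement_stats <- function(trajectory, model = NULL) {
  stopifnot(inherits(trajectory, "trajectory"))
  X <- trajectory$coords
  t <- nrow(X)
  if (t < 2)
    return(list(n_timepoints = t, first_to_last_distance = NA_real_,
                max_step = NA_real_, path_length = NA_real_,
                n_outside = sum(trajectory$outside),
                per_archetype_delta = NULL, untestable = TRUE))
  steps <- sqrt(rowSums((X[-1, , drop = FALSE] - X[-t, , drop = FALSE])^2))
  delta <- NULL
  if (!is.null(model)) {
    A <- model$archetypes_pc
    d_first <- distances_to_archetype(A, X[1, ])
    d_last <- distances_to_archetype(A, X[t, ])
    delta <- d_last - d_first
  }
  list(n_timepoints = t,
       first_to_last_distance = sqrt(sum((X[t, ] - X[1, ])^2)),
       max_step = max(steps),
       path_length = sum(steps),
       n_outside = sum(trajectory$outside),
       per_archetype_delta = delta,
       untestable = FALSE)
}

#' Rank trajectories and flag atypical movement
#'
#' Restricts to trajectories with at least `min_timepoints` visits (a single
#' aberrant visit can be a measurement error or a transient), ranks them by
#' first-to-last displacement, and flags (a) the top `top_fraction` movers,
#' labelled toward/away per archetype by the sign of the distance change, and
#' (b) trajectories with at least `min_outside` out-of-simplex time points.
#'
#' @param trajectories list of `trajectory` objects from
#'   [build_trajectories()].
#' @param model the `archetype_model` the trajectories live in.
#' @param min_timepoints minimum visits for eligibility (default 3).
#' @param top_fraction fraction of eligible trajectories flagged as top
#'   movers (default 0.02).
#' @param min_outside minimum out-of-simplex time points for the escape flag
#'   (default 2).
#' @return A `trajectory_report`: list with `per_trajectory` (data frame:
#'   participant, n_timepoints, first_to_last, max_step, path_length,
#'   n_outside, rank, percentile, per-archetype deltas, top_mover,
#'   outside_flag, direction labels) and `summary` (min/mean/median/max/sd of
#'   first-to-last distance over eligible trajectories).
#' @export
flag_trajectories <- function(trajectories, model, min_timepoints = 3,
                              top_fraction = 0.02, min_outside = 2) {
  stats_list <- lapply(trajectories, displacement_stats, model = model)
  eligible <- vapply(stats_list, function(s)
    s$n_timepoints >= min_timepoints, logical(1))
  if (!any(eligible)) stop("no trajectories with >= ", min_timepoints,
                           " time points")
  el <- stats_list[eligible]
  k <- model$k
  df <- data.frame(
    participant_id = vapply(trajectories[eligible], `[[`, character(1),
                            "participant_id"),
    n_timepoints = vapply(el, `[[`, numeric(1), "n_timepoints"),
    first_to_last = vapply(el, `[[`, numeric(1), "first_to_last_distance"),
    max_step = vapply(el, `[[`, numeric(1), "max_step"),
    path_length = vapply(el, `[[`, numeric(1), "path_length"),
    n_outside = vapply(el, `[[`, numeric(1), "n_outside"),
    stringsAsFactors = FALSE)
  deltas <- t(vapply(el, `[[`, numeric(k), "per_archetype_delta"))
  colnames(deltas) <- paste0("delta_archetype_", seq_len(k))
  df <- cbind(df, as.data.frame(deltas))

  n_el <- nrow(df)
  df$rank <- rank(-df$first_to_last, ties.method = "first")
  df$percentile <- 100 * (1 - (df$rank - 1) / n_el)
  n_top <- max(1L, floor(top_fraction * n_el))
  df$top_mover <- df$rank <= n_top & df$first_to_last > 0
  df$outside_flag <- df$n_outside >= min_outside
  dir_lab <- apply(deltas, 1, function(dl)
    paste(ifelse(dl < 0, "toward", "away"), collapse = "/"))
  df$direction <- ifelse(df$top_mover, dir_lab, "")
  df <- df[order(df$rank), , drop = FALSE]
  rownames(df) <- NULL

  structure(list(
    per_trajectory = df,
    summary = list(n_eligible = n_el,
                   min = min(df$first_to_last),
                   mean = mean(df$first_to_last),
                   median = median(df$first_to_last),
                   max = max(df$first_to_last),
                   sd = sd(df$first_to_last)),
    min_timepoints = min_timepoints,
    top_fraction = top_fraction,
    min_outside = min_outside),
    class = "trajectory_report")
}

#' @export
print.trajectory_report <- function(x, ...) {
  s <- x$summary
  cat("<trajectory_report> ", s$n_eligible, " eligible trajectories; ",
      "first-to-last distance mean ", signif(s$mean, 3), " (median ",
      signif(s$median, 3), ", max ", signif(s$max, 3), ")\n",
      sum(x$per_trajectory$top_mover), " top movers, ",
      sum(x$per_trajectory$outside_flag), " outside-flagged\n", sep = "")
  invisible(x)
}
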