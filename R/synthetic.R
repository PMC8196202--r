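# Orthonormal basis (d x m) drawn deterministically from a seed, via QR of a
# standard normal matrix.
random_orthonormal <- function(d, m, seed) {
  with_seed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(d * m), d, m)))
    # fix signs so the basis is unique given the seed
    for (j in seq_len(m)) if (Q[which.max(abs(Q[, j])), j] < 0)
      Q[, j] <- -Q[, j]
    Q
  })
}

# Vertices of a regular (k-1)-simplex with unit edge, centered at the origin.
regular_simplex <- function(k) {
  m <- k - 1
  V <- diag(k)[, seq_len(m), drop = FALSE] # k standard-basis corners in k dims
  V <- sweep(diag(k), 2, 1 / k, "-")       # center the k corners
  # orthonormal basis of the simplex plane
  B <- qr.Q(qr(t(V[-1, , drop = FALSE])))[, seq_len(m), drop = FALSE]
  P <- V %*% B
  P / sqrt(2) # standard-simplex edges have length sqrt(2)
}

#' Archetype profiles: a regular simplex embedded in feature space
#'
#' Vertices of a regular (k-1)-simplex of edge length `separation`, embedded
#' in `d` dimensions by a seeded random orthonormal map.
#'
#' @param k number of archetypes.
#' @param d ambient feature dimension (>= k - 1).
#' @param separation pairwise distance between archetypes.
#' @param seed integer seed.
#' @return k x d matrix of archetype profiles.
#' @export
make_archetype_profiles <- function(k, d, separation = 10, seed = 1) {
  if (d < k - 1) stop("d must be at least k - 1")
  P <- regular_simplex(k) * separation
  Q <- random_orthonormal(d, k - 1, seed)
  A <- P %*% t(Q)
  colnames(A) <- paste0("f", seq_len(d))
  A
}

#' Ground-truth description of a synthetic cohort
#'
#' Bundles the latent simplex (archetype profiles), the Dirichlet
#' concentration of the mixture weights, and the noise level (as a fraction
#' of the minimum inter-archetype distance).  The defaults produce a
#' visibly vertex-concentrated cloud: symmetric Dirichlet alpha 0.6 and 5%
#' noise.
#'
#' @param k number of archetypes (default 4).
#' @param d feature dimension (default 20).
#' @param separation inter-archetype distance (default 10).
#' @param dirichlet_alpha symmetric Dirichlet concentration (default 0.6).
#' @param noise_sd Gaussian noise sd as a fraction of the minimum
#'   inter-archetype distance (default 0.05).
#' @param seed integer seed for the embedding.
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(k = 4, d = 20, separation = 10,
                            dirichlet_alpha = 0.6, noise_sd = 0.05,
                            seed = 1) {
  A <- make_archetype_profiles(k, d, separation, seed)
  min_edge <- min(stats::dist(A))
  structure(list(k = k, d = d, separation = separation,
                 archetype_profiles = A, min_edge = min_edge,
                 dirichlet_alpha = dirichlet_alpha, noise_sd = noise_sd,
                 seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> k = ", x$k, ", d = ", x$d, ", edge = ",
      signif(x$min_edge, 4), ", alpha = ", x$dirichlet_alpha,
      ", noise = ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

rdirichlet <- function(n, alpha, k) {
  g <- matrix(rgamma(n * k, shape = alpha), n, k)
  g / rowSums(g)
}

#' Sample a cross-sectional cohort from the latent simplex
#'
#' Rows are symmetric-Dirichlet convex combinations of the archetype
#' profiles plus isotropic Gaussian noise with sd `noise_sd * min_edge`.
#'
#' @param truth a [synthetic_truth()].
#' @param n number of samples.
#' @param seed integer seed (defaults to the truth's seed).
#' @return List with `data` (n x d matrix), `weights` (n x k mixture rows)
#'   and `truth`.
#' @export
sample_cross_section <- function(truth, n, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  k <- truth$k; d <- truth$d
  if (n == 0)
    return(list(data = matrix(numeric(0), 0, d,
                              dimnames = list(NULL, colnames(truth$archetype_profiles))),
                weights = matrix(numeric(0), 0, k), truth = truth))
  with_seed(seed, {
    W <- rdirichlet(n, truth$dirichlet_alpha, k)
    X <- W %*% truth$archetype_profiles
    X <- X + matrix(rnorm(n * d, sd = truth$noise_sd * truth$min_edge), n, d)
    colnames(X) <- colnames(truth$archetype_profiles)
    list(data = X, weights = W, truth = truth)
  })
}

#' Specification of a planted enrichable trait
#'
#' @param name trait name.
#' @param kind `"continuous"` or `"discrete"`.
#' @param target_archetype index of the archetype the trait concentrates at.
#' @param effect continuous: amplitude of the exponential decay signal (in sd
#'   units of the unit-variance noise).
#' @param decay_length continuous: length scale of the decay, in the same
#'   units as the feature-space distances.
#' @param base_rate,boost_rate discrete: carrier probability away from /
#'   additional probability within the nearest decile of distance to the
#'   target.
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, kind = c("continuous", "discrete"),
                       target_archetype, effect = 5, decay_length = NULL,
                       base_rate = 0.05, boost_rate = 0.5) {
  kind <- match.arg(kind)
  stopifnot(is.finite(effect), base_rate >= 0, base_rate <= 1,
            boost_rate >= 0, base_rate + boost_rate <= 1)
  structure(list(name = name, kind = kind,
                 target_archetype = as.integer(target_archetype),
                 effect = effect, decay_length = decay_length,
                 base_rate = base_rate, boost_rate = boost_rate),
            class = "trait_spec")
}

#' Plant an enrichable trait on a synthetic cohort
#'
#' Continuous traits decay exponentially with the (feature-space) distance to
#' the target archetype, `effect * exp(-dist / decay_length)`, plus unit
#' Gaussian noise.  Discrete traits are Bernoulli carriers with probability
#' `base_rate`, boosted by `boost_rate` within the nearest decile of distance
#' to the target archetype.
#'
#' @param cohort a [sample_cross_section()] result.
#' @param spec a [trait_spec()].
#' @param seed integer seed.
#' @return For continuous traits a numeric vector, for discrete a character
#'   vector (`"carrier"`/`"non-carrier"`), with attribute `"spec"`.
#' @export
plant_trait <- function(cohort, spec, seed = 1) {
  stopifnot(inherits(spec, "trait_spec"))
  truth <- cohort$truth
  if (spec$target_archetype < 1 || spec$target_archetype > truth$k)
    stop("unknown target archetype: ", spec$target_archetype)
  a <- truth$archetype_profiles[spec$target_archetype, ]
  d <- distances_to_archetype(cohort$data, a)
  n <- length(d)
  v <- with_seed(seed, {
    if (spec$kind == "continuous") {
      lam <- if (is.null(spec$decay_length)) truth$min_edge / 2
             else spec$decay_length
      spec$effect * exp(-d / lam) + rnorm(n)
    } else {
      p <- rep(spec$base_rate, n)
      p[d <= quantile(d, 0.1)] <- spec$base_rate + spec$boost_rate
      ifelse(runif(n) < p, "carrier", "non-carrier")
    }
  })
  attr(v, "spec") <- spec
  v
}

#' Wrap a sample matrix (plus optional traits) as a feature table
#'
#' Gives synthetic samples the participant/visit bookkeeping the pipeline
#' expects: participants `P0001, ...`, all at visit 1.
#'
#' @param data n x d matrix of feature values.
#' @param traits optional named list of planted trait vectors.
#' @param group group label recorded in the metadata (default "synthetic").
#' @return A `feature_table`.
#' @export
as_cohort_table <- function(data, traits = NULL, group = "synthetic") {
  n <- nrow(data)
  df <- data.frame(participant_id = sprintf("P%04d", seq_len(n)),
                   visit_index = 1L, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(data))
  meta <- data.frame(feature = colnames(data), kind = "continuous",
                     group = group, stringsAsFactors = FALSE)
  for (nm in names(traits)) {
    v <- traits[[nm]]
    kind <- if (is.numeric(v)) "continuous" else "discrete"
    df[[nm]] <- v
    meta <- rbind(meta, data.frame(feature = nm, kind = kind,
                                   group = "trait"))
  }
  feature_table(df, meta)
}

#' Specification of one participant's longitudinal pattern
#'
#' @param pattern `"tumble"` (stationary jitter about a base point),
#'   `"drift"` (sustained motion toward an archetype plus jitter) or
#'   `"escape"` (successive steps along a fixed direction crossing the
#'   simplex boundary).
#' @param n_visits number of visits (1-8; drift/escape need >= 3).
#' @param step_sd per-visit jitter sd, in feature-space distance units.
#' @param drift_target archetype index (drift only).
#' @param drift_fraction fraction of the remaining distance to the target
#'   covered per visit (drift only, default 0.2).
#' @param escape_step step length per visit along the escape direction.
#' @param escape_direction unit vector in the simplex plane (optional; a
#'   seeded direction through the nearest face is used when omitted).
#' @return A `trajectory_spec` list.
#' @export
trajectory_spec <- function(pattern = c("tumble", "drift", "escape"),
                            n_visits = 4, step_sd = 0.3,
                            drift_target = NULL, drift_fraction = 0.2,
                            escape_step = NULL, escape_direction = NULL) {
  pattern <- match.arg(pattern)
  if (n_visits < 1 || n_visits > 8) stop("n_visits must be in 1..8")
  if (pattern %in% c("drift", "escape") && n_visits < 3)
    stop("drift/escape patterns need at least 3 visits")
  if (pattern == "drift" && is.null(drift_target))
    stop("drift pattern needs a drift_target archetype")
  structure(list(pattern = pattern, n_visits = as.integer(n_visits),
                 step_sd = step_sd, drift_target = drift_target,
                 drift_fraction = drift_fraction, escape_step = escape_step,
                 escape_direction = escape_direction),
            class = "trajectory_spec")
}

#' Sample longitudinal visit series on the latent simplex
#'
#' Each participant gets a base point drawn from the same Dirichlet mixture
#' as the cross-section; visits then follow the participant's pattern with
#' all motion confined to the simplex plane (so trajectory geometry is
#' controlled exactly) and mapped back to feature space.
#'
#' @param truth a [synthetic_truth()].
#' @param specs list of [trajectory_spec()], one per participant.
#' @param seed integer seed.
#' @return A `feature_table` of visits with attribute `"patterns"` (the
#'   pattern per participant).
#' @export
sample_longitudinal <- function(truth, specs, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  k <- truth$k; d <- truth$d
  A <- truth$archetype_profiles
  ctr <- colMeans(A)
  # orthonormal basis of the simplex plane in feature space
  B <- qr.Q(qr(t(sweep(A[-1, , drop = FALSE], 2, A[1, ], "-"))))[, seq_len(k - 1),
                                                                 drop = FALSE]
  A_plane <- sweep(A, 2, ctr, "-") %*% B

  rows <- with_seed(seed, {
    lapply(seq_along(specs), function(i) {
      sp <- specs[[i]]
      stopifnot(inherits(sp, "trajectory_spec"))
      w <- rdirichlet(1, truth$dirichlet_alpha, k)
      base <- drop(w %*% A_plane)
      t <- sp$n_visits
      pos <- matrix(NA_real_, t, k - 1)
      if (sp$pattern == "tumble") {
        for (v in seq_len(t))
          pos[v, ] <- base + rnorm(k - 1, sd = sp$step_sd)
      } else if (sp$pattern == "drift") {
        target <- A_plane[sp$drift_target, ]
        cur <- base
        for (v in seq_len(t)) {
          pos[v, ] <- cur + rnorm(k - 1, sd = sp$step_sd)
          cur <- cur + sp$drift_fraction * (target - cur)
        }
      } else { # escape
        dir <- sp$escape_direction
        if (is.null(dir)) {
          dir <- rnorm(k - 1)
          dir <- dir / sqrt(sum(dir^2))
        }
        step <- if (is.null(sp$escape_step)) 0.4 * truth$min_edge
                else sp$escape_step
        for (v in seq_len(t))
          pos[v, ] <- base + (v - 1) * step * dir +
            rnorm(k - 1, sd = sp$step_sd)
      }
      X <- sweep(pos %*% t(B), 2, ctr, "+")
      data.frame(participant_id = sprintf("L%04d", i),
                 visit_index = seq_len(t),
                 as.data.frame(X, col.names = colnames(A)))
    })
  })
  df <- do.call(rbind, rows)
  names(df)[-(1:2)] <- colnames(A)
  meta <- data.frame(feature = colnames(A), kind = "continuous",
                     group = "synthetic", stringsAsFactors = FALSE)
  out <- feature_table(df, meta)
  attr(out, "patterns") <- vapply(specs, `[[`, character(1), "pattern")
  out
}

#' Standard-normal null cohort
#'
#' Independent N(0, 1) entries: the no-structure reference for calibrating
#' the shuffle-null significance test.
#'
#' @param n rows. @param d columns. @param seed integer seed.
#' @return n x d matrix with columns `f1..fd`.
#' @export
gaussian_null <- function(n, d, seed = 1) {
  stopifnot(n >= 1, d >= 1)
  X <- with_seed(seed, matrix(rnorm(n * d), n, d))
  colnames(X) <- paste0("f", seq_len(d))
  X
}
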