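## Best-/worst-case beta elicitation: generate a full CPT for an ordinal
## child from two elicited beta distributions, per-parent weights and
## per-state scores; plus method-of-moments fitting of empirical best-case
## distributions.

#' Beta distribution parameters
#' @param alpha,beta Strictly positive, finite shape parameters.
#' @return An object of class `beta_spec`.
#' @export
beta_spec <- function(alpha, beta) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
    stop("beta parameters must be strictly positive and finite", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "beta_spec")
}

beta_mean <- function(bs) bs$alpha / (bs$alpha + bs$beta)

#' Discretisation bins on the decrease-in-abundance fraction
#'
#' Edges must run strictly increasing from exactly 0 to exactly 1. The
#' default is five 20-percent-wide bins, matching the reported outcome
#' classes (0-20, 21-40, 41-60, 61-80, 81-100 % decrease).
#'
#' @param edges Numeric vector of bin edges.
#' @return An object of class `bin_scheme` with elements `edges`, `labels`
#'   and `midpoints`.
#' @export
bin_scheme <- function(edges = c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
  edges <- as.numeric(edges)
  if (length(edges) < 2 || any(diff(edges) <= 0) ||
      edges[1] != 0 || edges[length(edges)] != 1)
    stop("bin edges must be strictly increasing from exactly 0 to exactly 1",
         call. = FALSE)
  k <- length(edges) - 1L
  labels <- if (identical(edges, c(0, 0.2, 0.4, 0.6, 0.8, 1))) {
    c("0-20%", "21-40%", "41-60%", "61-80%", "81-100%")
  } else {
    paste0(format(100 * edges[-length(edges)], trim = TRUE), "-",
           format(100 * edges[-1], trim = TRUE), "%")
  }
  structure(list(edges = edges, labels = labels,
                 midpoints = (edges[-1] + edges[-length(edges)]) / 2),
            class = "bin_scheme")
}

#' Default decrease-in-abundance bins
#' @return The default five-bin [bin_scheme()].
#' @export
decrease_bins <- function() bin_scheme()

# assign fractions to bins: (e_k, e_{k+1}], edge values go to the
# lower-impact bin, 0 goes to the first bin
assign_bin <- function(x, edges) {
  idx <- findInterval(x, edges, left.open = TRUE, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(edges) - 1L] <- length(edges) - 1L
  idx
}

#' Influence of one parent on an elicited child
#'
#' @param parent Parent variable name.
#' @param weight Nonnegative relative importance of this parent.
#' @param scores Named numeric vector of state scores in `[0, 1]`, one per
#'   parent state in ordinal order; must be nondecreasing with minimum 0 and
#'   maximum 1 (score 0 = the parent's best-case state, 1 = worst-case).
#' @return An object of class `parent_influence`.
#' @export
parent_influence <- function(parent, weight, scores) {
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be named by the parent's states", call. = FALSE)
  scores <- vapply(scores, as.numeric, numeric(1))
  if (weight < 0) stop("weight must be >= 0", call. = FALSE)
  if (abs(min(scores)) > 0 || abs(max(scores) - 1) > 0)
    stop("parent '", parent, "': state scores must attain exactly 0 and 1",
         call. = FALSE)
  if (any(diff(scores) < 0))
    stop("parent '", parent, "': state scores must be nondecreasing over ",
         "the ordinal state order", call. = FALSE)
  structure(list(parent = parent, weight = as.numeric(weight),
                 scores = scores), class = "parent_influence")
}

#' Elicitation specification for one child node
#'
#' Captures the minimal expert input of the reduced-burden elicitation:
#' the child's distribution when every parent is at its most favourable
#' state (`best`) and at its least favourable state (`worst`), plus one
#' [parent_influence()] per parent. Worst case refers to the larger
#' decrease in abundance, so `mean(worst) >= mean(best)` is required.
#'
#' @param child Child variable name.
#' @param best,worst [beta_spec()] distributions for the best- and
#'   worst-case parent configurations.
#' @param influences List of [parent_influence()], exactly one per parent.
#' @param bins A [bin_scheme()] used to discretise the child.
#' @return An object of class `elicitation_spec`.
#' @export
elicitation_spec <- function(child, best, worst, influences,
                             bins = decrease_bins()) {
  stopifnot(inherits(best, "beta_spec"), inherits(worst, "beta_spec"),
            inherits(bins, "bin_scheme"))
  pnames <- vapply(influences, function(x) x$parent, character(1))
  if (anyDuplicated(pnames))
    stop("duplicate parent influences", call. = FALSE)
  if (!any(vapply(influences, function(x) x$weight > 0, logical(1))))
    stop("at least one parent must have weight > 0", call. = FALSE)
  if (beta_mean(worst) < beta_mean(best))
    stop("mean(worst) must be >= mean(best): the worst case is the larger ",
         "decrease", call. = FALSE)
  structure(list(child = child, best = best, worst = worst,
                 influences = stats::setNames(influences, pnames),
                 bins = bins),
            class = "elicitation_spec")
}

#' Relevance index of a parent-state configuration
#'
#' The weight-averaged parent-state score
#' `lambda = sum_i w_i s_i(config) / sum_i w_i`, positioning the
#' configuration between the elicited best case (`lambda = 0`) and worst
#' case (`lambda = 1`).
#'
#' @param spec An [elicitation_spec()].
#' @param config Named character vector assigning a state to every parent in
#'   `spec`.
#' @return `lambda` in `[0, 1]`.
#' @export
relevance_index <- function(spec, config) {
  w <- vapply(spec$influences, `[[`, numeric(1), "weight")
  if (sum(w) <= 0) stop("all parent weights are zero", call. = FALSE)
  cfg <- as.list(config)
  s <- vapply(spec$influences, function(inf) {
    st <- cfg[[inf$parent]]
    if (is.null(st) || is.na(st))
      stop("configuration does not assign a state to parent '",
           inf$parent, "'", call. = FALSE)
    if (!st %in% names(inf$scores))
      stop("'", st, "' is not a scored state of parent '", inf$parent, "'",
           call. = FALSE)
    inf$scores[[st]]
  }, numeric(1))
  sum(w * s) / sum(w)
}

#' Interpolate between two beta distributions
#'
#' Linear interpolation in `(alpha, beta)` parameter space:
#' `alpha(lambda) = (1 - lambda) alpha_best + lambda alpha_worst` and
#' likewise for beta. The interpolated mean is then a ratio of linear
#' functions of `lambda` and moves monotonically from `mean(best)` to
#' `mean(worst)`.
#'
#' @param best,worst [beta_spec()] endpoints.
#' @param lambda Relevance index in `[0, 1]`.
#' @return A [beta_spec()].
#' @export
interpolate_beta <- function(best, worst, lambda) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]", call. = FALSE)
  beta_spec((1 - lambda) * best$alpha + lambda * worst$alpha,
            (1 - lambda) * best$beta + lambda * worst$beta)
}

#' Bin probabilities of a beta distribution
#'
#' Component `k` is `I(e_{k+1}; a, b) - I(e_k; a, b)` with `I` the
#' regularised incomplete beta function (the beta CDF).
#'
#' @param bs A [beta_spec()].
#' @param bins A [bin_scheme()].
#' @return Probability vector over the bins (sums to 1).
#' @export
beta_bin_probs <- function(bs, bins = decrease_bins()) {
  p <- diff(stats::pbeta(bins$edges, bs$alpha, bs$beta))
  p / sum(p)
}

#' Generate a full CPT from an elicitation specification
#'
#' For every combination of parent states, the child column is the binned
#' interpolated beta
#' `beta_bin_probs(interpolate_beta(best, worst, relevance_index(...)))`.
#' Configurations in which every parent sits at a score-0 (resp. score-1)
#' state reproduce the elicited best (resp. worst) distribution exactly.
#'
#' @param spec An [elicitation_spec()]; parent states are taken from the
#'   score names of each influence.
#' @return A [bn_cpt()] for the child over the bin labels.
#' @export
build_cpt_from_elicitation <- function(spec) {
  parents <- names(spec$influences)
  pstates <- lapply(spec$influences, function(inf) names(inf$scores))
  grid <- expand.grid(pstates, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  k <- length(spec$bins$labels)
  cols <- vapply(seq_len(nrow(grid)), function(i) {
    lam <- relevance_index(spec, as.list(grid[i, , drop = FALSE]))
    beta_bin_probs(interpolate_beta(spec$best, spec$worst, lam), spec$bins)
  }, numeric(k))
  bn_cpt(spec$child, parents, cols,
         child_states = spec$bins$labels, parent_states = pstates)
}

#' Fit a beta distribution by the method of moments
#'
#' Estimates `alpha = m (m (1 - m) / v - 1)` and
#' `beta = (1 - m) (m (1 - m) / v - 1)` from the sample mean `m` and sample
#' variance `v` (denominator `n - 1`). Values are clipped to
#' `[0.001, 0.999]` before fitting; clipping is reported via a message.
#'
#' @param samples Numeric vector (>= 3 values) of fractions in `[0, 1]`.
#' @return A [beta_spec()]. Degenerate samples (variance 0 or
#'   `v >= m (1 - m)`) cannot be fitted; the error suggests using a
#'   point-mass column instead.
#' @export
fit_beta_moments <- function(samples) {
  x <- as.numeric(samples)
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (any(x < 0 | x > 1)) stop("samples must lie in [0, 1]", call. = FALSE)
  clipped <- x < 0.001 | x > 0.999
  if (any(clipped)) {
    message("fit_beta_moments: clipped ", sum(clipped),
            " value(s) to [0.001, 0.999]")
    x <- pmin(pmax(x, 0.001), 0.999)
  }
  m <- mean(x)
  v <- stats::var(x)
  if (!(v > 0) || v >= m * (1 - m))
    stop("sample moments are incompatible with a beta distribution ",
         "(variance 0 or >= m(1-m)); use a point-mass column instead",
         call. = FALSE)
  common <- m * (1 - m) / v - 1
  beta_spec(m * common, (1 - m) * common)
}
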