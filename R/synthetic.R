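## Synthetic inputs: random small networks for oracle testing, and
## before/after benthic core surveys (overdispersed counts) from which
## empirical best-case decrease distributions are fitted.

#' Random directed acyclic graph
#'
#' Nodes are shuffled into a random order and each node draws parents only
#' from nodes earlier in that order, so the result is acyclic by
#' construction.
#'
#' @param n_nodes Number of nodes (>= 1), named `X01`, `X02`, ...
#' @param max_parents Maximum parents per node.
#' @param seed Integer seed; deterministic per seed.
#' @return List with `nodes` (character vector) and `edges` (two-column
#'   from/to character matrix).
#' @export
random_dag <- function(n_nodes, max_parents, seed) {
  if (n_nodes < 1) stop("n_nodes must be >= 1", call. = FALSE)
  nodes <- sprintf("X%02d", seq_len(n_nodes))
  edges <- matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  with_seed(seed, {
    ord <- sample(nodes)
    for (k in seq_along(ord)) {
      avail <- min(max_parents, k - 1L)
      if (avail < 1L) next
      np <- sample.int(avail + 1L, 1L) - 1L
      if (np > 0L) {
        pars <- ord[sample.int(k - 1L, np)]
        edges <- rbind(edges, cbind(pars, ord[k]))
      }
    }
  })
  colnames(edges) <- c("from", "to")
  list(nodes = nodes, edges = edges)
}

#' Random network with Dirichlet CPT columns
#'
#' Dresses a DAG from [random_dag()] with CPTs whose columns are drawn from
#' a symmetric Dirichlet distribution (normalised by construction; large
#' concentration gives near-uniform columns).
#'
#' @param dag A list with `nodes` and `edges` (see [random_dag()]).
#' @param n_states States per node (labels `s1`, `s2`, ...).
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param seed Integer seed.
#' @return A `bn_network` of random variables.
#' @export
random_cpts <- function(dag, n_states, concentration, seed) {
  if (concentration <= 0) stop("concentration must be > 0", call. = FALSE)
  states <- paste0("s", seq_len(n_states))
  variables <- lapply(dag$nodes, bn_variable, states = states,
                      role = "random", tier = "pressure")
  cpts <- with_seed(seed, {
    lapply(dag$nodes, function(v) {
      pars <- dag$edges[dag$edges[, "to"] == v, "from"]
      ncomb <- n_states ^ length(pars)
      g <- matrix(stats::rgamma(n_states * ncomb, shape = concentration),
                  nrow = n_states)
      vals <- sweep(g, 2L, colSums(g), "/")
      bn_cpt(v, pars, vals, child_states = states,
             parent_states = stats::setNames(
               rep(list(states), length(pars)), pars))
    })
  })
  bn_network(variables, cpts)
}

#' Specification of a before/after core survey
#'
#' @param n_cores_control,n_cores_impact Replicate cores per arm (>= 3).
#' @param mean_density Named positive vector: mean individuals per core per
#'   functional group in the control (pre-disturbance) condition.
#' @param dispersion Negative-binomial size parameter (> 0); smaller values
#'   mean patchier counts.
#' @param true_decrease Named vector of relative decreases in `[0, 1]` per
#'   group in the impacted arm.
#' @param seed Integer seed.
#' @return An object of class `survey_spec`.
#' @export
survey_spec <- function(n_cores_control, n_cores_impact, mean_density,
                        dispersion, true_decrease, seed) {
  if (n_cores_control < 3 || n_cores_impact < 3)
    stop("need at least 3 cores per arm", call. = FALSE)
  if (any(true_decrease < 0 | true_decrease > 1))
    stop("true_decrease must lie in [0, 1]", call. = FALSE)
  if (any(mean_density <= 0) || dispersion <= 0)
    stop("densities and dispersion must be positive", call. = FALSE)
  if (is.null(names(mean_density)))
    names(mean_density) <- paste0("group", seq_along(mean_density))
  if (is.null(names(true_decrease))) names(true_decrease) <- names(mean_density)
  structure(list(n_cores_control = as.integer(n_cores_control),
                 n_cores_impact = as.integer(n_cores_impact),
                 mean_density = mean_density, dispersion = dispersion,
                 true_decrease = true_decrease[names(mean_density)],
                 seed = as.integer(seed)),
            class = "survey_spec")
}

#' Simulate a before/after core survey
#'
#' Control counts are negative binomial with the group's mean density;
#' impact counts use the density scaled by `1 - true_decrease`. Counts are
#' overdispersed (negative binomial rather than Poisson) to reflect patchy
#' benthic core samples.
#'
#' @param spec A [survey_spec()].
#' @return Data frame with columns `group`, `arm` (`control`/`impact`),
#'   `core`, `count`.
#' @export
simulate_survey <- function(spec) {
  stopifnot(inherits(spec, "survey_spec"))
  with_seed(spec$seed, {
    out <- NULL
    for (g in names(spec$mean_density)) {
      mu_c <- spec$mean_density[[g]]
      mu_i <- mu_c * (1 - spec$true_decrease[[g]])
      ctrl <- stats::rnbinom(spec$n_cores_control, size = spec$dispersion,
                             mu = mu_c)
      imp <- if (mu_i > 0)
        stats::rnbinom(spec$n_cores_impact, size = spec$dispersion, mu = mu_i)
      else rep.int(0L, spec$n_cores_impact)
      out <- rbind(out,
                   data.frame(group = g, arm = "control",
                              core = seq_len(spec$n_cores_control),
                              count = ctrl, stringsAsFactors = FALSE),
                   data.frame(group = g, arm = "impact",
                              core = seq_len(spec$n_cores_impact),
                              count = imp, stringsAsFactors = FALSE))
    }
    out
  })
}

#' Bootstrap relative-decrease samples from a survey table
#'
#' Resamples cores with replacement within each arm; each replicate's
#' decrease is `clip(1 - mean(impact) / mean(control), 0, 1)`. Replicates
#' whose control mean is zero are dropped (reported via a message). The
#' returned fractions feed [fit_beta_moments()] to produce an empirical
#' best-case beta distribution.
#'
#' @param survey Data frame from [simulate_survey()] (columns `group`,
#'   `arm`, `core`, `count`).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return Named list of numeric vectors of decreases, one per group.
#' @export
decrease_samples <- function(survey, n_boot = 1000, seed) {
  groups <- unique(survey$group)
  out <- stats::setNames(vector("list", length(groups)), groups)
  with_seed(seed, {
    for (g in groups) {
      ctrl <- survey$count[survey$group == g & survey$arm == "control"]
      imp <- survey$count[survey$group == g & survey$arm == "impact"]
      if (length(ctrl) < 3 || length(imp) < 3)
        stop("need at least 3 cores per arm for group '", g, "'",
             call. = FALSE)
      mc <- colMeans(matrix(ctrl[sample.int(length(ctrl),
                                            length(ctrl) * n_boot,
                                            replace = TRUE)],
                            nrow = length(ctrl)))
      mi <- colMeans(matrix(imp[sample.int(length(imp),
                                           length(imp) * n_boot,
                                           replace = TRUE)],
                            nrow = length(imp)))
      ok <- mc > 0
      if (any(!ok))
        message("decrease_samples: dropped ", sum(!ok),
                " replicate(s) with zero control mean for group '", g, "'")
      out[[g]] <- pmin(pmax(1 - mi[ok] / mc[ok], 0), 1)
    }
  })
  out
}
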