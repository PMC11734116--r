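## Discrete Bayesian-network core: variables, CPTs, networks, validation,
## exact inference by variable elimination, ancestral sampling, and a
## full-joint enumeration oracle.

#' Declare a network variable
#'
#' A variable has a unique name, an ordered set of at least two discrete
#' states, a role, a model tier and an expert-confidence tag. State order is
#' meaningful: ordinal scales run from the least to the most adverse state
#' unless the variable is flagged nominal (e.g. sediment particle size).
#'
#' @param name Variable name (unique within a network).
#' @param states Character vector of >= 2 unique state labels, in ordinal
#'   order unless `nominal = TRUE`.
#' @param role `"random"` (carries a CPT) or `"decision"` (controlled by the
#'   operator; never carries a CPT and is set as evidence or given an
#'   explicit prior).
#' @param tier One of `"operational"`, `"pressure"`, `"environment"`,
#'   `"biota"`.
#' @param confidence Expert confidence in the parameterisation: `"low"`,
#'   `"moderate"`, `"high"` or `"unrated"`. Metadata only; never alters
#'   probabilities.
#' @param nominal Logical; `TRUE` if the states have no ordinal
#'   interpretation.
#' @return An object of class `bn_variable`.
#' @export
bn_variable <- function(name, states,
                        role = c("random", "decision"),
                        tier = c("pressure", "operational", "environment", "biota"),
                        confidence = c("unrated", "low", "moderate", "high"),
                        nominal = FALSE) {
  role <- match.arg(role)
  tier <- match.arg(tier)
  confidence <- match.arg(confidence)
  states <- as.character(states)
  if (length(name) != 1L || !nzchar(name))
    stop("variable name must be a single non-empty string", call. = FALSE)
  if (length(states) < 2L || anyDuplicated(states))
    stop("variable '", name, "' needs >= 2 unique states", call. = FALSE)
  structure(list(name = name, states = states, role = role, tier = tier,
                 confidence = confidence, nominal = isTRUE(nominal)),
            class = "bn_variable")
}

#' Build a conditional probability table
#'
#' The table is stored as an array whose first dimension indexes the child
#' states and whose remaining dimensions index the parent states, so each
#' "column" (a child-probability vector for one full parent-state
#' combination) is a slice along dimension 1.
#'
#' @param child Child variable name.
#' @param parents Character vector of parent names (possibly empty), in the
#'   order of the array dimensions.
#' @param values Numeric array (or vector) of probabilities with
#'   `length(child_states) * prod(parent cardinalities)` entries; child
#'   dimension first, parents in `parents` order.
#' @param child_states,parent_states State labels for the child and (as a
#'   named list) each parent.
#' @return An object of class `bn_cpt`.
#' @export
bn_cpt <- function(child, parents, values, child_states, parent_states = list()) {
  parents <- as.character(parents)
  if (length(parents) != length(parent_states) ||
      (length(parents) && !identical(sort(names(parent_states)), sort(parents))))
    stop("parent_states must be a named list covering exactly the parents",
         call. = FALSE)
  parent_states <- parent_states[parents]
  card <- c(length(child_states),
            vapply(parent_states, length, integer(1), USE.NAMES = FALSE))
  if (length(values) != prod(card))
    stop("CPT for '", child, "': expected ", prod(card), " values, got ",
         length(values), call. = FALSE)
  dn <- c(list(child_states), unname(parent_states))
  names(dn) <- c(child, parents)
  arr <- array(as.numeric(values), dim = card, dimnames = dn)
  structure(list(child = child, parents = parents, values = arr),
            class = "bn_cpt")
}

#' Assemble a discrete Bayesian network
#'
#' Performs only the structural assembly needed to hold the pieces together;
#' probabilistic and graph invariants are checked by [validate_network()],
#' which reports violations rather than raising, so that deliberately broken
#' networks can be inspected.
#'
#' @param variables List of [bn_variable()] objects.
#' @param cpts List of [bn_cpt()] objects, one per random variable.
#' @param decision_priors Optional named list of probability vectors giving
#'   explicit priors for decision variables (needed only when a decision
#'   variable is queried or sampled without being fixed as evidence).
#' @param edges Optional two-column character matrix (from, to). When
#'   omitted, edges are derived from the CPT parent lists; when supplied they
#'   are stored as-is and checked against the parent lists by
#'   [validate_network()].
#' @return An object of class `bn_network`.
#' @export
bn_network <- function(variables, cpts, decision_priors = NULL, edges = NULL) {
  vnames <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(vnames))
    stop("duplicate variable names: ",
         paste(unique(vnames[duplicated(vnames)]), collapse = ", "),
         call. = FALSE)
  names(variables) <- vnames
  cnames <- vapply(cpts, function(x) x$child, character(1))
  names(cpts) <- cnames
  if (is.null(edges)) {
    edges <- do.call(rbind, c(list(matrix(character(0), ncol = 2)),
                              lapply(cpts, function(x) {
                                if (length(x$parents))
                                  cbind(x$parents, x$child)
                                else
                                  matrix(character(0), ncol = 2)
                              })))
  }
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  structure(list(variables = variables, cpts = cpts, edges = edges,
                 decision_priors = decision_priors),
            class = "bn_network")
}

node_names <- function(net) names(net$variables)

node_states <- function(net, var) net$variables[[var]]$states

parents_of <- function(net, var) {
  cpt <- net$cpts[[var]]
  if (is.null(cpt)) character(0) else cpt$parents
}

#' Topological order of a network (internal)
#' @noRd
topological_order <- function(net) {
  vn <- node_names(net)
  indeg <- stats::setNames(integer(length(vn)), vn)
  kids <- stats::setNames(vector("list", length(vn)), vn)
  if (nrow(net$edges)) {
    for (i in seq_len(nrow(net$edges))) {
      e <- net$edges[i, ]
      indeg[[e[2]]] <- indeg[[e[2]]] + 1L
      kids[[e[1]]] <- c(kids[[e[1]]], e[2])
    }
  }
  order <- character(0)
  frontier <- sort(vn[indeg == 0L])
  while (length(frontier)) {
    v <- frontier[1]; frontier <- frontier[-1]
    order <- c(order, v)
    for (ch in kids[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) frontier <- sort(c(frontier, ch))
    }
  }
  if (length(order) < length(vn)) return(NULL)  # cycle
  order
}

ancestors_of <- function(net, vars) {
  par_list <- lapply(node_names(net), function(v) {
    p <- parents_of(net, v)
    if (!length(p) && !is.null(net$edges) && nrow(net$edges))
      p <- net$edges[net$edges[, "to"] == v, "from"]
    p
  })
  names(par_list) <- node_names(net)
  seen <- character(0)
  frontier <- intersect(vars, node_names(net))
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(par_list[frontier])), seen)
  }
  seen
}

#' Validate a Bayesian network
#'
#' Checks every structural and probabilistic invariant: unique states,
#' acyclicity, agreement between the edge set and the CPT parent lists,
#' exactly one CPT per random variable and none for decision variables,
#' declared parents, full parent-state coverage, and nonnegative CPT columns
#' summing to one within `1e-6` (columns further off are reported; columns
#' within `1e-6` are accepted, as constructors renormalise them).
#'
#' @param net A `bn_network`.
#' @return Character vector of human-readable violation descriptions; empty
#'   when the network is valid. Violations are returned, never raised.
#' @export
validate_network <- function(net) {
  bad <- character(0)
  vn <- node_names(net)
  for (v in net$variables) {
    if (length(v$states) < 2L || anyDuplicated(v$states))
      bad <- c(bad, sprintf("variable '%s': states must be >= 2 and unique", v$name))
  }
  roles <- vapply(net$variables, function(v) v$role, character(1))
  for (v in vn) {
    if (roles[[v]] == "random" && is.null(net$cpts[[v]]))
      bad <- c(bad, sprintf("random variable '%s' has no CPT", v))
    if (roles[[v]] == "decision" && !is.null(net$cpts[[v]]))
      bad <- c(bad, sprintf("decision variable '%s' carries a CPT", v))
  }
  for (cpt in net$cpts) {
    if (!cpt$child %in% vn) {
      bad <- c(bad, sprintf("CPT child '%s' is not a declared variable", cpt$child))
      next
    }
    unknown <- setdiff(cpt$parents, vn)
    if (length(unknown))
      bad <- c(bad, sprintf("CPT '%s': undeclared parent(s) %s", cpt$child,
                            paste(unknown, collapse = ", ")))
    if (!identical(dimnames(cpt$values)[[1]], node_states(net, cpt$child)))
      bad <- c(bad, sprintf("CPT '%s': child states do not match declaration", cpt$child))
    for (p in intersect(cpt$parents, vn)) {
      if (!identical(dimnames(cpt$values)[[p]], node_states(net, p)))
        bad <- c(bad, sprintf("CPT '%s': parent '%s' states do not match declaration",
                              cpt$child, p))
    }
    m <- matrix(cpt$values, nrow = dim(cpt$values)[1])
    if (any(m < 0))
      bad <- c(bad, sprintf("CPT '%s': negative probabilities", cpt$child))
    sums <- colSums(m)
    off <- abs(sums - 1) > 1e-6
    if (any(off))
      bad <- c(bad, sprintf("CPT '%s': %d column(s) do not sum to 1 (max |error| %.3g)",
                            cpt$child, sum(off), max(abs(sums - 1))))
  }
  # edge set equals the union of parent lists
  derived <- do.call(rbind, c(list(matrix(character(0), ncol = 2)),
                              lapply(net$cpts, function(x)
                                if (length(x$parents)) cbind(x$parents, x$child)
                                else matrix(character(0), ncol = 2))))
  key <- function(m) sort(paste(m[, 1], m[, 2], sep = "->"))
  if (!identical(key(derived), key(net$edges)))
    bad <- c(bad, "edge set does not equal the union of CPT parent lists")
  if (is.null(topological_order(net)))
    bad <- c(bad, "graph is not acyclic (directed cycle present)")
  bad
}

## ---------------------------------------------------------------------------
## Factors

new_factor <- function(vars, states, values) {
  if (length(vars) == 0L)
    return(structure(list(vars = character(0), states = list(),
                          values = as.numeric(values)[1]),
                     class = "bn_factor"))
  card <- vapply(states, length, integer(1), USE.NAMES = FALSE)
  dn <- unname(states)
  names(dn) <- vars
  arr <- array(as.numeric(values), dim = card, dimnames = dn)
  structure(list(vars = vars, states = stats::setNames(states, vars),
                 values = arr), class = "bn_factor")
}

cpt_factor <- function(cpt) {
  vars <- c(cpt$child, cpt$parents)
  new_factor(vars, stats::setNames(dimnames(cpt$values), vars), cpt$values)
}

factor_card <- function(f) vapply(f$states, length, integer(1))

# expand a factor's value array over a superset scope `allvars`
factor_embed <- function(f, allvars, allstates) {
  if (length(f$vars) == 0L) {
    card <- vapply(allstates, length, integer(1))
    return(array(f$values, dim = card))
  }
  own <- allvars[allvars %in% f$vars]
  a <- aperm(f$values, match(own, f$vars))
  missing <- setdiff(allvars, f$vars)
  card_all <- vapply(allstates, length, integer(1))
  names(card_all) <- allvars
  vals <- array(rep(as.vector(a), times = prod(card_all[missing])),
                dim = c(card_all[own], card_all[missing]))
  aperm(vals, match(allvars, c(own, missing)))
}

factor_product <- function(f, g) {
  if (length(f$vars) == 0L) {
    if (length(g$vars) == 0L)
      return(new_factor(character(0), list(), f$values * g$values))
    return(new_factor(g$vars, g$states, g$values * f$values))
  }
  if (length(g$vars) == 0L)
    return(new_factor(f$vars, f$states, f$values * g$values))
  allvars <- union(f$vars, g$vars)
  allstates <- c(f$states, g$states[setdiff(g$vars, f$vars)])[allvars]
  new_factor(allvars, allstates,
             factor_embed(f, allvars, allstates) *
               factor_embed(g, allvars, allstates))
}

factor_marginalize <- function(f, var) {
  if (!var %in% f$vars) return(f)
  keep <- setdiff(f$vars, var)
  if (!length(keep))
    return(new_factor(character(0), list(), sum(f$values)))
  card <- factor_card(f)
  a <- aperm(f$values, c(match(keep, f$vars), match(var, f$vars)))
  dim(a) <- c(prod(card[keep]), card[[var]])
  new_factor(keep, f$states[keep], array(rowSums(a), dim = card[keep]))
}

factor_reduce <- function(f, var, state) {
  if (!var %in% f$vars) return(f)
  i <- match(state, f$states[[var]])
  if (is.na(i))
    stop("state '", state, "' is not a state of '", var, "'", call. = FALSE)
  idx <- lapply(f$vars, function(v) if (v == var) i else TRUE)
  vals <- do.call(`[`, c(list(f$values), idx, list(drop = FALSE)))
  keep <- setdiff(f$vars, var)
  if (!length(keep))
    return(new_factor(character(0), list(), as.numeric(vals)))
  card <- factor_card(f)[keep]
  dim(vals) <- card
  new_factor(keep, f$states[keep], vals)
}

## ---------------------------------------------------------------------------
## Inference

check_evidence <- function(net, evidence) {
  if (is.null(evidence) || !length(evidence)) return(character(0))
  evidence <- unlist(evidence)
  if (is.null(names(evidence)) || any(!nzchar(names(evidence))))
    stop("evidence must be a named vector (variable = state)", call. = FALSE)
  for (v in names(evidence)) {
    if (!v %in% node_names(net))
      stop("evidence names unknown variable '", v, "'", call. = FALSE)
    if (!evidence[[v]] %in% node_states(net, v))
      stop("'", evidence[[v]], "' is not a state of '", v, "'", call. = FALSE)
  }
  evidence
}

# factors for a set of variables, substituting explicit priors for decision
# variables that are not fixed by evidence
gather_factors <- function(net, vars, evidence) {
  out <- list()
  for (v in vars) {
    if (v %in% names(evidence) && is.null(net$cpts[[v]])) next
    cpt <- net$cpts[[v]]
    if (!is.null(cpt)) {
      out[[length(out) + 1L]] <- cpt_factor(cpt)
    } else {
      pr <- net$decision_priors[[v]]
      if (is.null(pr))
        stop("decision variable '", v, "' must be fixed as evidence or given ",
             "an explicit prior in the configuration", call. = FALSE)
      out[[length(out) + 1L]] <-
        new_factor(v, stats::setNames(list(node_states(net, v)), v), pr)
    }
  }
  out
}

# min-fill elimination ordering with lexicographic tie-break
min_fill_order <- function(scopes, elim) {
  adj <- stats::setNames(lapply(elim, function(v) character(0)), elim)
  allv <- unique(unlist(scopes))
  adj <- stats::setNames(lapply(allv, function(v) character(0)), allv)
  for (sc in scopes) {
    for (v in sc) adj[[v]] <- union(adj[[v]], setdiff(sc, v))
  }
  order <- character(0)
  remaining <- sort(elim)
  while (length(remaining)) {
    fills <- vapply(remaining, function(v) {
      nb <- intersect(adj[[v]], names(adj))
      nb <- setdiff(nb, order)
      n <- length(nb)
      if (n < 2L) return(0L)
      cnt <- 0L
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        if (!nb[j] %in% adj[[nb[i]]]) cnt <- cnt + 1L
      cnt
    }, integer(1))
    v <- remaining[which.min(fills)]  # remaining is sorted: lexicographic ties
    nb <- setdiff(intersect(adj[[v]], names(adj)), order)
    for (i in seq_along(nb)) for (j in seq_along(nb)) {
      if (i != j) adj[[nb[i]]] <- union(adj[[nb[i]]], nb[j])
    }
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
  }
  order
}

run_elimination <- function(factors, elim) {
  if (length(elim)) {
    ord <- min_fill_order(lapply(factors, `[[`, "vars"), elim)
    for (v in ord) {
      hit <- vapply(factors, function(f) v %in% f$vars, logical(1))
      if (!any(hit)) next
      prod <- Reduce(factor_product, factors[hit])
      factors <- c(factors[!hit], list(factor_marginalize(prod, v)))
    }
  }
  Reduce(factor_product, factors,
         new_factor(character(0), list(), 1))
}

#' Exact conditional marginals by variable elimination
#'
#' Computes `P(target | evidence)` for each target by sum-product variable
#' elimination over the ancestral subgraph of the targets and evidence
#' (barren descendants integrate to one and are pruned). The elimination
#' order is the min-fill heuristic with a lexicographic tie-break;
#' normalisation is applied once at the end.
#'
#' @param net A valid `bn_network`.
#' @param targets Character vector of query variables (disjoint from the
#'   evidence).
#' @param evidence Named character vector of observed states (possibly
#'   empty).
#' @return Named list of probability vectors, one per target, each summing
#'   to one. Evidence that has probability zero under the model raises an
#'   error.
#' @export
bn_query <- function(net, targets, evidence = character(0)) {
  evidence <- check_evidence(net, evidence)
  targets <- as.character(targets)
  if (!length(targets)) stop("no query targets given", call. = FALSE)
  if (length(bad <- setdiff(targets, node_names(net))))
    stop("unknown target variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(int <- intersect(targets, names(evidence))))
    stop("targets must be disjoint from evidence: ",
         paste(int, collapse = ", "), call. = FALSE)
  relevant <- ancestors_of(net, union(targets, names(evidence)))
  factors <- gather_factors(net, relevant, evidence)
  for (v in names(evidence)) {
    if (!v %in% relevant) next
    factors <- lapply(factors, factor_reduce, var = v, state = evidence[[v]])
  }
  elim <- setdiff(relevant, union(targets, names(evidence)))
  joint <- run_elimination(factors, elim)
  total <- if (length(joint$vars)) sum(joint$values) else joint$values
  if (!is.finite(total) || total <= 0)
    stop("evidence has probability zero under the model", call. = FALSE)
  out <- stats::setNames(vector("list", length(targets)), targets)
  for (v in targets) {
    f <- joint
    for (o in setdiff(joint$vars, v)) f <- factor_marginalize(f, o)
    p <- as.numeric(f$values)
    p <- p / sum(p)
    out[[v]] <- stats::setNames(p, node_states(net, v))
  }
  out
}

#' Posteriors for every non-evidence variable
#'
#' Applies [bn_query()] per variable under the same evidence.
#'
#' @inheritParams bn_query
#' @return Named list of probability vectors over the states of each
#'   non-evidence variable.
#' @export
posterior_all <- function(net, evidence = character(0)) {
  evidence <- check_evidence(net, evidence)
  targets <- setdiff(node_names(net), names(evidence))
  out <- stats::setNames(vector("list", length(targets)), targets)
  for (v in targets) out[[v]] <- bn_query(net, v, evidence)[[v]]
  out
}

#' Joint probability of a full assignment
#'
#' The chain-rule product over the random variables of the CPT entries
#' consistent with the assignment; decision variables are treated as
#' conditioned constants and contribute no factor.
#'
#' @param net A `bn_network`.
#' @param assignment Named character vector assigning a state to every
#'   variable (decision variables included).
#' @return A single probability.
#' @export
joint_probability <- function(net, assignment) {
  assignment <- unlist(assignment)
  missing <- setdiff(node_names(net), names(assignment))
  if (length(missing))
    stop("incomplete assignment; missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- 1
  for (cpt in net$cpts) {
    idx <- c(match(assignment[[cpt$child]], node_states(net, cpt$child)),
             vapply(cpt$parents, function(pa)
               match(assignment[[pa]], node_states(net, pa)), integer(1)))
    if (anyNA(idx))
      stop("assignment uses unknown state for CPT '", cpt$child, "'",
           call. = FALSE)
    p <- p * as.numeric(do.call(`[`, c(list(cpt$values), as.list(idx))))
  }
  p
}

#' Enumerate the full joint distribution
#'
#' Test oracle: multiplies every CPT (and decision prior) into one factor
#' over all variables. Guarded against joint state spaces above `1e6`
#' entries.
#'
#' @param net A `bn_network`; decision variables (if any) must have explicit
#'   priors.
#' @return A `bn_factor` over all variables whose values sum to one.
#' @export
enumerate_joint <- function(net) {
  card <- vapply(net$variables, function(v) length(v$states), integer(1))
  size <- prod(card)
  if (size > 1e6)
    stop("joint state space has ", format(size, big.mark = ","),
         " entries (> 1e6); refusing to enumerate", call. = FALSE)
  factors <- gather_factors(net, node_names(net), character(0))
  joint <- Reduce(factor_product, factors,
                  new_factor(character(0), list(), 1))
  # present with variables in declaration order
  ord <- match(node_names(net), joint$vars)
  if (length(joint$vars)) {
    joint$values <- aperm(joint$values, ord)
    joint$vars <- joint$vars[ord]
    joint$states <- joint$states[ord]
  }
  joint
}

# marginal of one variable from an enumerated joint factor
factor_marginal <- function(joint, var) {
  f <- joint
  for (o in setdiff(joint$vars, var)) f <- factor_marginalize(f, o)
  p <- as.numeric(f$values)
  stats::setNames(p / sum(p), joint$states[[var]])
}

## ---------------------------------------------------------------------------
## Sampling

# evaluate `code` under a private RNG stream seeded with `seed`
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Forward (ancestral) sampling
#'
#' Draws `n` full assignments in topological order. Decision variables must
#' either be fixed by the supplied evidence or carry a degenerate
#' (point-mass) prior; anything else is a missing-decision error. Evidence
#' may name decision variables only (conditioning on random variables would
#' require rejection or weighting, which this utility does not do).
#'
#' @param net A valid `bn_network`.
#' @param n Number of samples (>= 0).
#' @param seed Integer seed; sampling is deterministic per seed.
#' @param evidence Named character vector fixing decision variables.
#' @return A data frame with `n` rows and one character column per variable.
#' @export
forward_sample <- function(net, n, seed, evidence = character(0)) {
  evidence <- check_evidence(net, evidence)
  roles <- vapply(net$variables, function(v) v$role, character(1))
  if (length(bad <- intersect(names(evidence), names(roles)[roles == "random"])))
    stop("forward_sample evidence may fix decision variables only: ",
         paste(bad, collapse = ", "), call. = FALSE)
  ord <- topological_order(net)
  if (is.null(ord)) stop("network is cyclic; cannot sample", call. = FALSE)
  n <- as.integer(n)
  samples <- stats::setNames(
    replicate(length(ord), integer(n), simplify = FALSE), ord)
  with_seed(seed, {
    for (v in ord) {
      var <- net$variables[[v]]
      k <- length(var$states)
      if (var$role == "decision") {
        if (v %in% names(evidence)) {
          samples[[v]] <- rep.int(match(evidence[[v]], var$states), n)
        } else {
          pr <- net$decision_priors[[v]]
          if (is.null(pr) || max(pr) < 1)
            stop("decision variable '", v, "' is not fixed by evidence and ",
                 "has no degenerate prior", call. = FALSE)
          samples[[v]] <- rep.int(which.max(pr), n)
        }
        next
      }
      cpt <- net$cpts[[v]]
      m <- matrix(cpt$values, nrow = k)
      if (length(cpt$parents)) {
        pcard <- vapply(cpt$parents, function(p) length(node_states(net, p)),
                        integer(1))
        col <- rep.int(1L, n)
        mult <- 1L
        for (j in seq_along(cpt$parents)) {
          col <- col + (samples[[cpt$parents[j]]] - 1L) * mult
          mult <- mult * pcard[j]
        }
      } else {
        col <- rep.int(1L, n)
      }
      if (n > 0L) {
        pm <- m[, col, drop = FALSE]
        cum <- apply(pm, 2L, cumsum)
        u <- stats::runif(n) * cum[k, ]
        samples[[v]] <- 1L + colSums(cum[-k, , drop = FALSE] <
                                       rep(u, each = k - 1L))
      }
    }
  })
  out <- lapply(node_names(net), function(v)
    node_states(net, v)[samples[[v]]])
  names(out) <- node_names(net)
  as.data.frame(out, optional = TRUE, stringsAsFactors = FALSE)
}
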