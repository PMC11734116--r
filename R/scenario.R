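## Scenario analysis: posterior pressures and impacts per disturbance
## scenario, spatial domain and time step, plus summaries and comparisons.

pressure_nodes <- function() c("SuspendedSediment", "SedimentDeposition",
                               "ContaminantRelease", "SedimentChanges")

#' Evidence for a scenario in a spatial domain
#'
#' The union of the scenario's decision-variable assignments and
#' `Distance = domain`.
#'
#' @param scenario A scenario definition (element of
#'   `default_config()$scenarios`): a list with `name` and a named
#'   `assignments` vector over decision variables.
#' @param domain A `Distance` state (`"inside"`, `"near-field"`,
#'   `"far-field"`).
#' @param net Optionally, the network, used to verify that the scenario
#'   assigns decision variables only.
#' @return Named character vector of evidence.
#' @export
scenario_evidence <- function(scenario, domain, net = NULL) {
  if (!domain %in% c("inside", "near-field", "far-field"))
    stop("unknown spatial domain '", domain, "'", call. = FALSE)
  ev <- c(scenario$assignments, Distance = domain)
  if (!is.null(net)) {
    for (v in names(ev)) {
      if (!v %in% node_names(net))
        stop("scenario assigns unknown variable '", v, "'", call. = FALSE)
      if (net$variables[[v]]$role != "decision")
        stop("scenario assigns non-decision variable '", v, "'",
             call. = FALSE)
      if (!ev[[v]] %in% node_states(net, v))
        stop("'", ev[[v]], "' is not a state of '", v, "'", call. = FALSE)
    }
  }
  ev
}

#' Most likely outcome of a posterior
#'
#' Argmax over states; ties are broken toward the lower-impact (earlier
#' ordinal) state.
#'
#' @param probs Normalised probability vector.
#' @param states State labels (defaults to `names(probs)`).
#' @return List with `state` and `probability`.
#' @export
most_likely_outcome <- function(probs, states = names(probs)) {
  i <- which.max(probs)  # which.max returns the first maximum: the tie rule
  list(state = states[i], probability = as.numeric(probs[i]))
}

#' Midpoint-weighted expected decrease
#'
#' `sum_k probs_k * midpoint_k` over the decrease bins (midpoints 0.1, 0.3,
#' 0.5, 0.7, 0.9 for the default scheme).
#'
#' @param probs Normalised probability vector over the bins.
#' @param bins A [bin_scheme()].
#' @return Expected decrease fraction in `[0, 1]`.
#' @export
expected_decrease <- function(probs, bins = decrease_bins()) {
  sum(as.numeric(probs) * bins$midpoints)
}

#' Run a disturbance scenario
#'
#' Queries the network under the scenario evidence in each spatial domain
#' and collects posterior pressure levels and per-group impact records for
#' the immediate and one-year time steps (3 domains x 15 groups x 2 time
#' steps = 90 impact records; 3 domains x 4 pressure variables = 12
#' pressure records). Inference is exact, so repeated runs are identical.
#'
#' @param net A `bn_network` from [assemble_network()].
#' @param scenario A scenario definition (see [scenario_evidence()]), or the
#'   name of a scenario in the network's configuration.
#' @param config The model configuration; defaults to the one attached to
#'   `net`.
#' @return An object of class `era_scenario`: list with data frames
#'   `impacts` (scenario, domain, group, time_step, one probability column
#'   per bin, `most_likely`, `p_most_likely`, `expected_decrease`,
#'   `confidence`) and `pressures` (scenario, domain, variable, state,
#'   probability in long form).
#' @export
run_scenario <- function(net, scenario, config = attr(net, "config")) {
  if (is.character(scenario)) {
    if (is.null(config$scenarios[[scenario]]))
      stop("unknown scenario '", scenario, "'", call. = FALSE)
    scenario <- config$scenarios[[scenario]]
  }
  bins <- bin_scheme(config$bins)
  groups <- config$groups
  domains <- c("inside", "near-field", "far-field")
  k <- length(bins$labels)
  pcol <- paste0("p_", gsub("%", "", gsub("-", "_", bins$labels)))
  impacts <- NULL
  pressures <- NULL
  for (domain in domains) {
    ev <- scenario_evidence(scenario, domain, net)
    post <- posterior_all(net, ev)
    for (pv in pressure_nodes()) {
      p <- post[[pv]]
      pressures <- rbind(pressures, data.frame(
        scenario = scenario$name, domain = domain, variable = pv,
        state = names(p), probability = as.numeric(p),
        stringsAsFactors = FALSE))
    }
    for (i in seq_len(nrow(groups))) {
      for (step in c("immediate", "year1")) {
        node <- biota_node(if (step == "immediate") "Immediate" else "Year1",
                           groups$id[i])
        p <- post[[node]]
        ml <- most_likely_outcome(p)
        rec <- data.frame(scenario = scenario$name, domain = domain,
                          group = groups$id[i], time_step = step,
                          stringsAsFactors = FALSE)
        rec[pcol] <- as.list(as.numeric(p))
        rec$most_likely <- ml$state
        rec$p_most_likely <- ml$probability
        rec$expected_decrease <- expected_decrease(p, bins)
        rec$confidence <- groups$confidence[i]
        impacts <- rbind(impacts, rec)
      }
    }
  }
  rownames(impacts) <- NULL
  rownames(pressures) <- NULL
  structure(list(scenario = scenario$name, impacts = impacts,
                 pressures = pressures, bins = bins),
            class = "era_scenario")
}

#' Compare two scenario runs
#'
#' Per (domain, group, time step): the signed difference in expected
#' decrease (A minus B) and the total-variation distance
#' `TV = 0.5 * sum_k |pA_k - pB_k|` between the posterior bin
#' distributions.
#'
#' @param a,b `era_scenario` objects over the same model.
#' @return Data frame with columns `domain`, `group`, `time_step`,
#'   `delta_expected_decrease`, `tv_distance`.
#' @export
compare_scenarios <- function(a, b) {
  ia <- a$impacts
  ib <- b$impacts
  keys <- c("domain", "group", "time_step")
  ka <- do.call(paste, c(ia[keys], sep = "\r"))
  kb <- do.call(paste, c(ib[keys], sep = "\r"))
  if (!setequal(ka, kb) || anyDuplicated(ka))
    stop("scenario record sets do not match", call. = FALSE)
  ib <- ib[match(ka, kb), ]
  pcols <- grep("^p_", names(ia), value = TRUE)
  pcols <- setdiff(pcols, "p_most_likely")
  out <- ia[keys]
  out$delta_expected_decrease <- ia$expected_decrease - ib$expected_decrease
  out$tv_distance <- 0.5 * rowSums(abs(as.matrix(ia[pcols]) -
                                         as.matrix(ib[pcols])))
  rownames(out) <- NULL
  out
}
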