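## Print, summary and plot methods.

#' @export
print.bn_variable <- function(x, ...) {
  cat(sprintf("<%s %s> states: %s\n", x$role, x$name,
              paste(x$states, collapse = " | ")))
  invisible(x)
}

#' @export
print.bn_cpt <- function(x, ...) {
  cat(sprintf("CPT %s | %s\n", x$child,
              if (length(x$parents)) paste(x$parents, collapse = ", ")
              else "(no parents)"))
  print(x$values, ...)
  invisible(x)
}

#' @export
print.bn_network <- function(x, ...) {
  s <- structure_summary(x)
  cat(sprintf("Discrete Bayesian network: %d nodes, %d edges, %d roots\n",
              s$n_nodes, s$n_edges, s$n_roots))
  tiers <- s$tiers[s$tiers > 0]
  if (length(tiers))
    cat("  tiers:", paste(names(tiers), as.integer(tiers), sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.bn_network <- function(object, ...) {
  s <- structure_summary(object)
  roles <- vapply(object$variables, `[[`, character(1), "role")
  s$n_decision <- sum(roles == "decision")
  s$violations <- validate_network(object)
  class(s) <- "summary.bn_network"
  s
}

#' @export
print.summary.bn_network <- function(x, ...) {
  cat(sprintf("nodes: %d (decision: %d)  edges: %d  roots: %d\n",
              x$n_nodes, x$n_decision, x$n_edges, x$n_roots))
  cat("tiers:", paste(names(x$tiers), as.integer(x$tiers), sep = "=",
                      collapse = ", "), "\n")
  if (length(x$violations))
    cat("INVALID:\n ", paste(x$violations, collapse = "\n  "), "\n")
  else cat("network is valid\n")
  invisible(x)
}

#' @export
print.era_config <- function(x, ...) {
  cat(sprintf("Model configuration '%s': %d variables, %d edges, %d groups\n",
              x$name, length(x$variables), nrow(x$edges), nrow(x$groups)))
  cat("scenarios:", paste(names(x$scenarios), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.era_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d impact records, %d pressure posteriors\n",
              x$scenario, nrow(x$impacts),
              nrow(unique(x$pressures[c("variable", "domain")]))))
  agg <- stats::aggregate(expected_decrease ~ domain + time_step, x$impacts,
                          mean)
  agg$expected_decrease <- round(agg$expected_decrease, 3)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' @export
summary.era_scenario <- function(object, ...) {
  imp <- object$impacts
  out <- imp[, c("scenario", "domain", "group", "time_step", "most_likely",
                 "p_most_likely", "expected_decrease", "confidence")]
  class(out) <- c("summary.era_scenario", "data.frame")
  out
}

#' @export
print.summary.era_scenario <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$p_most_likely <- round(y$p_most_likely, 3)
  y$expected_decrease <- round(y$expected_decrease, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Plot a scenario run
#'
#' `which = "pressures"` draws stacked bars of the posterior pressure
#' levels per domain; `which = "impacts"` draws the most-likely outcome of
#' each group against its probability, by domain, for the chosen time
#' step.
#'
#' @param x An `era_scenario`.
#' @param which `"pressures"` or `"impacts"`.
#' @param time_step `"immediate"` or `"year1"` (impacts only).
#' @param ... Passed to the underlying base-graphics calls.
#' @return `x`, invisibly.
#' @export
plot.era_scenario <- function(x, which = c("pressures", "impacts"),
                              time_step = "year1", ...) {
  which <- match.arg(which)
  domains <- c("inside", "near-field", "far-field")
  if (which == "pressures") {
    old <- graphics::par(mfrow = c(2, 2), mar = c(3, 3, 2, 1))
    on.exit(graphics::par(old))
    for (pv in unique(x$pressures$variable)) {
      sub <- x$pressures[x$pressures$variable == pv, ]
      m <- vapply(domains, function(d)
        sub$probability[sub$domain == d], numeric(sum(sub$domain == "inside")))
      rownames(m) <- sub$state[sub$domain == "inside"]
      graphics::barplot(m, main = pv, col = grDevices::gray.colors(nrow(m)),
                        legend.text = nrow(m) <= 3, ...)
    }
  } else {
    imp <- x$impacts[x$impacts$time_step == time_step, ]
    lev <- x$bins$labels
    pch <- c(inside = 19, `near-field` = 17, `far-field` = 1)
    graphics::plot(match(imp$most_likely, lev), imp$p_most_likely,
                   xaxt = "n", xlab = "most likely decrease in abundance",
                   ylab = "probability of most likely outcome",
                   ylim = c(0, 1), pch = pch[imp$domain],
                   main = paste0("scenario '", x$scenario, "', ", time_step),
                   ...)
    graphics::axis(1, at = seq_along(lev), labels = lev)
    graphics::legend("topleft", legend = names(pch), pch = pch, bty = "n")
  }
  invisible(x)
}
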