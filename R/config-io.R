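## Configuration loading/validation, patch merging, deterministic CSV/JSON
## serialization and the command-line dispatcher.

config_keys <- c("name", "bins", "groups", "variables", "edges", "priors",
                 "pressure_cpts", "elicitation", "direct", "immediate",
                 "scenarios", "expected_counts", "decision_priors")

# canonical JSON-ready representation (named lists / unnamed arrays only)
config_to_list <- function(config) {
  list(
    name = config$name,
    bins = as.numeric(config$bins),
    groups = lapply(as.list(config$groups), function(col)
      if (is.factor(col)) as.character(col) else col),
    variables = lapply(config$variables, function(v)
      list(name = v$name, states = as.character(v$states), role = v$role,
           tier = v$tier, confidence = v$confidence,
           nominal = isTRUE(v$nominal))),
    edges = list(from = as.character(config$edges[, "from"]),
                 to = as.character(config$edges[, "to"])),
    priors = lapply(config$priors, as.numeric),
    pressure_cpts = lapply(config$pressure_cpts, function(x)
      list(parents = as.character(x$parents), values = as.numeric(x$values))),
    elicitation = lapply(config$elicitation, function(block)
      lapply(block, function(e)
        list(best = as.numeric(e$best), worst = as.numeric(e$worst),
             influences = lapply(e$influences, function(i)
               list(parent = i$parent, weight = as.numeric(i$weight),
                    scores = lapply(i$scores, as.numeric)))))),
    direct = list(depth_multipliers = as.list(config$direct$depth_multipliers)),
    immediate = list(grid_m = as.numeric(config$immediate$grid_m)),
    scenarios = lapply(config$scenarios, function(s)
      list(name = s$name, description = s$description,
           assignments = as.list(s$assignments))),
    expected_counts = as.list(config$expected_counts),
    decision_priors = if (is.null(config$decision_priors)) NULL
    else lapply(config$decision_priors, as.numeric))
}

config_from_list <- function(x, path = "config") {
  required <- setdiff(config_keys, "decision_priors")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(path, ": missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(x), config_keys)
  if (length(unknown))
    stop(path, ": unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- list(
    name = x$name,
    bins = as.numeric(x$bins),
    groups = as.data.frame(x$groups, stringsAsFactors = FALSE),
    variables = lapply(x$variables, function(v)
      list(name = v$name, states = as.character(unlist(v$states)),
           role = v$role, tier = v$tier, confidence = v$confidence,
           nominal = isTRUE(v$nominal))),
    edges = cbind(from = as.character(unlist(x$edges$from)),
                  to = as.character(unlist(x$edges$to))),
    priors = lapply(x$priors, function(p) as.numeric(unlist(p))),
    pressure_cpts = lapply(x$pressure_cpts, function(e)
      list(parents = as.character(unlist(e$parents)),
           values = as.numeric(unlist(e$values)))),
    elicitation = lapply(x$elicitation, function(block)
      lapply(block, function(e)
        list(best = as.numeric(unlist(e$best)),
             worst = as.numeric(unlist(e$worst)),
             influences = lapply(e$influences, function(i)
               list(parent = i$parent, weight = as.numeric(i$weight),
                    scores = lapply(as.list(i$scores), as.numeric)))))),
    direct = list(depth_multipliers =
                    vapply(as.list(x$direct$depth_multipliers), as.numeric,
                           numeric(1))),
    immediate = list(grid_m = as.numeric(x$immediate$grid_m)),
    scenarios = lapply(x$scenarios, function(s)
      list(name = s$name, description = s$description,
           assignments = vapply(as.list(s$assignments), as.character,
                                character(1)))),
    expected_counts = vapply(as.list(x$expected_counts), as.numeric,
                             numeric(1)),
    decision_priors = if (is.null(x$decision_priors)) NULL
    else lapply(x$decision_priors, function(p) as.numeric(unlist(p))))
  structure(cfg, class = "era_config")
}

#' Write a model configuration as JSON
#'
#' Serialisation is canonical (fixed key order, unboxed scalars, full
#' precision), so export -> load -> export is byte-identical.
#'
#' @param config An `era_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  json <- jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Load and schema-validate a model configuration
#'
#' @param path Path to a JSON document written by [write_model_config()]
#'   (or hand-authored to the same schema). Unknown keys are rejected with
#'   the offending path; missing sections are named.
#' @return An `era_config`.
#' @export
read_model_config <- function(path) {
  x <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  config_from_list(x, path = path)
}

#' Merge a patch over a configuration
#'
#' Recursively overrides existing keys only: every key in the patch must
#' already exist in the configuration (so typos surface as errors with
#' their full path), and untargeted keys are left untouched.
#'
#' @param config An `era_config`.
#' @param patch Named list mirroring a subset of the configuration
#'   structure.
#' @return The patched `era_config`.
#' @export
apply_config_patch <- function(config, patch) {
  merge_in <- function(base, patch, path) {
    if (!is.list(patch) || is.null(names(patch)) || !is.list(base))
      return(patch)
    for (k in names(patch)) {
      if (!k %in% names(base))
        stop("patch targets unknown key: ", path, "$", k, call. = FALSE)
      base[[k]] <- merge_in(base[[k]], patch[[k]], paste0(path, "$", k))
    }
    base
  }
  out <- merge_in(unclass(config), patch, "config")
  structure(out, class = "era_config")
}

# stable 31-adic string hash (exact in double arithmetic)
stable_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

evidence_hash <- function(evidence) {
  if (!length(evidence)) return(stable_hash(""))
  ord <- order(names(evidence))
  stable_hash(paste0(names(evidence)[ord], "=", unlist(evidence)[ord]))
}

#' Export posteriors as CSV
#'
#' One row per variable/state with the probability printed to six decimals
#' and a stable hash of the evidence that produced the posterior
#' (UTF-8, LF line endings, `.` decimal separator).
#'
#' @param posteriors Named list of probability vectors (e.g. from
#'   [posterior_all()]).
#' @param path Output file path.
#' @param evidence The evidence under which the posteriors were computed.
#' @return `path`, invisibly.
#' @export
write_posteriors_csv <- function(posteriors, path, evidence = character(0)) {
  h <- evidence_hash(evidence)
  rows <- do.call(rbind, lapply(names(posteriors), function(v)
    data.frame(variable = v, state = names(posteriors[[v]]),
               probability = sprintf("%.6f", posteriors[[v]]),
               evidence_hash = h, stringsAsFactors = FALSE)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Run manifest
#'
#' Provenance record emitted alongside command-line outputs: the command,
#' a stable hash of the configuration, the seeds, package version,
#' timestamp and output paths.
#'
#' @param command Character description of the invocation.
#' @param config The configuration used.
#' @param seed Seed(s) used, if any.
#' @param outputs Character vector of output paths.
#' @param path Where to write the manifest JSON (`NULL` to skip writing).
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(command, config = NULL, seed = NULL,
                         outputs = character(0), path = NULL) {
  m <- list(
    command = command,
    config_hash = if (is.null(config)) NA_character_ else
      stable_hash(jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE,
                                   digits = NA)),
    seed = seed,
    package_version = as.character(utils::packageVersion("chathamrisk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  if (!is.null(path))
    writeLines(jsonlite::toJSON(m, auto_unbox = TRUE, null = "null",
                                pretty = TRUE), path, useBytes = TRUE)
  invisible(m)
}

## ---------------------------------------------------------------------------
## Command-line dispatcher (used by inst/cli/era.R)

cli_flags <- function(argv) {
  flags <- list()
  positional <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
        flags[[key]] <- TRUE
        i <- i + 1L
      } else {
        flags[[key]] <- argv[i + 1L]
        i <- i + 2L
      }
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

cli_config <- function(flags) {
  if (!is.null(flags$config) && !identical(flags$config, "default"))
    read_model_config(flags$config)
  else default_config()
}

#' Command-line entry point
#'
#' Dispatches the subcommands `validate`, `show`, `scenario`, `compare` and
#' `synth` (see the shipped `inst/cli/era.R` wrapper). Returns an exit code
#' rather than quitting, so it can be driven programmatically.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code: 0 on success, 2 on usage errors, 1 on
#'   failures.
#' @export
era_main <- function(argv = character(0)) {
  usage <- paste(
    "usage: era <validate|show|scenario|compare|synth> [options]",
    "  era validate [--config FILE]",
    "  era show [--config FILE]",
    "  era scenario --scenario high|intermediate --out FILE",
    "      [--pressures FILE] [--config FILE]",
    "  era compare --a high --b intermediate --out FILE [--config FILE]",
    "  era synth survey --out FILE [--seed N]",
    "  era synth network --nodes N --out FILE [--seed N]",
    "  era oracle [--n-nets N] [--seed N]",
    sep = "\n")
  if (!length(argv)) { message(usage); return(2L) }
  cmd <- argv[1]
  parsed <- cli_flags(argv[-1])
  flags <- parsed$flags
  res <- tryCatch({
    switch(cmd,
      validate = {
        net <- assemble_network(cli_config(flags))
        bad <- validate_network(net)
        if (length(bad)) { message(paste(bad, collapse = "\n")); 1L }
        else { message("model OK"); 0L }
      },
      show = {
        s <- structure_summary(assemble_network(cli_config(flags)))
        message("nodes: ", s$n_nodes, "  edges: ", s$n_edges,
                "  roots: ", s$n_roots)
        message(paste(names(s$tiers), as.integer(s$tiers), sep = "=",
                      collapse = "  "))
        0L
      },
      scenario = {
        if (is.null(flags$scenario) || is.null(flags$out)) {
          message(usage); return(2L)
        }
        config <- cli_config(flags)
        net <- assemble_network(config)
        run <- run_scenario(net, flags$scenario, config)
        imp <- run$impacts
        num <- vapply(imp, is.numeric, logical(1))
        imp[num] <- lapply(imp[num], function(x) sprintf("%.6f", x))
        con <- file(flags$out, open = "wb")
        utils::write.csv(imp, con, row.names = FALSE, eol = "\n")
        close(con)
        outputs <- flags$out
        if (!is.null(flags$pressures)) {
          pr <- run$pressures
          pr$probability <- sprintf("%.6f", pr$probability)
          con <- file(flags$pressures, open = "wb")
          utils::write.csv(pr, con, row.names = FALSE, eol = "\n")
          close(con)
          outputs <- c(outputs, flags$pressures)
        }
        run_manifest(paste("era", paste(argv, collapse = " ")), config,
                     outputs = outputs,
                     path = paste0(flags$out, ".manifest.json"))
        0L
      },
      compare = {
        if (is.null(flags$a) || is.null(flags$b) || is.null(flags$out)) {
          message(usage); return(2L)
        }
        config <- cli_config(flags)
        net <- assemble_network(config)
        cmpd <- compare_scenarios(run_scenario(net, flags$a, config),
                                  run_scenario(net, flags$b, config))
        num <- vapply(cmpd, is.numeric, logical(1))
        cmpd[num] <- lapply(cmpd[num], function(x) sprintf("%.6f", x))
        con <- file(flags$out, open = "wb")
        utils::write.csv(cmpd, con, row.names = FALSE, eol = "\n")
        close(con)
        0L
      },
      synth = {
        what <- parsed$positional[1]
        seed <- as.integer(if (is.null(flags$seed)) 1 else flags$seed)
        if (identical(what, "survey")) {
          if (is.null(flags$out)) { message(usage); return(2L) }
          spec <- survey_spec(200, 200,
                              mean_density = c(benthos = 50),
                              dispersion = 5,
                              true_decrease = c(benthos = 0.4), seed = seed)
          con <- file(flags$out, open = "wb")
          utils::write.csv(simulate_survey(spec), con, row.names = FALSE,
                           eol = "\n")
          close(con)
          0L
        } else if (identical(what, "network")) {
          if (is.null(flags$out) || is.null(flags$nodes)) {
            message(usage); return(2L)
          }
          n <- as.integer(flags$nodes)
          net <- random_cpts(random_dag(n, 3, seed), 3, 1, seed + 1L)
          json <- jsonlite::toJSON(list(
            variables = lapply(net$variables, unclass),
            edges = list(from = net$edges[, "from"], to = net$edges[, "to"]),
            cpts = lapply(net$cpts, function(x)
              list(child = x$child, parents = x$parents,
                   values = as.numeric(x$values)))),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
          writeLines(json, flags$out, useBytes = TRUE)
          0L
        } else { message(usage); 2L }
      },
      oracle = {
        n_nets <- as.integer(if (is.null(flags[["n-nets"]])) 20
                             else flags[["n-nets"]])
        seed0 <- as.integer(if (is.null(flags$seed)) 0 else flags$seed)
        worst <- 0
        for (s in seed0 + seq_len(n_nets) - 1L) {
          rnet <- random_cpts(random_dag(3L + s %% 8L, 3L, s),
                              2L + s %% 2L, 1, s + 1000L)
          joint <- enumerate_joint(rnet)
          for (v in names(rnet$variables))
            worst <- max(worst, max(abs(bn_query(rnet, v)[[v]] -
                                          factor_marginal(joint, v))))
        }
        message(sprintf(
          "max |elimination - enumeration| over %d networks: %.3g",
          n_nets, worst))
        if (worst < 1e-9) 0L else 1L
      },
      { message("unknown subcommand '", cmd, "'\n", usage); 2L })
  }, error = function(e) { message("era: ", conditionMessage(e)); 1L })
  as.integer(res)
}
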