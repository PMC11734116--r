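# Shared fixtures, built in code.

# two-node chain: P(A = a1) = 0.3, P(B = b1 | a1) = 0.9, P(B = b1 | a2) = 0.5
chain_net <- function() {
  bn_network(
    list(bn_variable("A", c("a1", "a2")),
         bn_variable("B", c("b1", "b2"))),
    list(bn_cpt("A", character(0), c(0.3, 0.7), child_states = c("a1", "a2")),
         bn_cpt("B", "A", c(0.9, 0.1, 0.5, 0.5), child_states = c("b1", "b2"),
                parent_states = list(A = c("a1", "a2")))))
}

# chain whose CPTs are point masses along (a1, b1)
point_mass_net <- function() {
  bn_network(
    list(bn_variable("A", c("a1", "a2")),
         bn_variable("B", c("b1", "b2"))),
    list(bn_cpt("A", character(0), c(1, 0), child_states = c("a1", "a2")),
         bn_cpt("B", "A", c(1, 0, 0, 1), child_states = c("b1", "b2"),
                parent_states = list(A = c("a1", "a2")))))
}

# small random network (<= 10 nodes, <= 3 states, <= 3 parents),
# deterministic per seed
random_test_net <- function(seed) {
  n_nodes <- 3L + seed %% 8L
  n_states <- 2L + seed %% 2L
  random_cpts(random_dag(n_nodes, 3L, seed), n_states,
              concentration = 1, seed = seed + 1000L)
}

# random elicitation spec with monotone scores, deterministic given the
# ambient RNG state (callers wrap in with_seed/set.seed)
random_elicitation_spec <- function(n_parents = sample(1:3, 1)) {
  repeat {
    best <- beta_spec(runif(1, 0.3, 10), runif(1, 0.3, 10))
    worst <- beta_spec(runif(1, 0.3, 10), runif(1, 0.3, 10))
    if (worst$alpha / (worst$alpha + worst$beta) >=
        best$alpha / (best$alpha + best$beta)) break
  }
  infl <- lapply(seq_len(n_parents), function(i) {
    ns <- sample(2:4, 1)
    sc <- sort(runif(ns))
    sc <- (sc - min(sc)) / (max(sc) - min(sc))
    parent_influence(paste0("P", i), runif(1, 0.1, 2),
                     stats::setNames(sc, paste0("s", seq_len(ns))))
  })
  elicitation_spec("C", best, worst, infl)
}

# cache expensive shared objects across test files
.fixtures <- new.env(parent = emptyenv())

cached_default_net <- function() {
  if (is.null(.fixtures$net)) .fixtures$net <- chatham_network()
  .fixtures$net
}

cached_scenario_run <- function(which) {
  key <- paste0("run_", which)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- run_scenario(cached_default_net(), which)
  .fixtures[[key]]
}
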