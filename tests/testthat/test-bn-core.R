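test_that("the validator passes valid networks and names each violation", {
  expect_identical(validate_network(chain_net()), character(0))

  # CPT column summing to 0.9 -> one normalisation violation naming the child
  broken <- bn_network(
    list(bn_variable("A", c("a1", "a2"))),
    list(bn_cpt("A", character(0), c(0.4, 0.5), child_states = c("a1", "a2"))))
  v <- validate_network(broken)
  expect_length(grep("sum to 1", v), 1)
  expect_match(v[grep("sum to 1", v)], "'A'")

  # edge A -> B plus B -> A: acyclicity violation
  cyclic <- bn_network(
    list(bn_variable("A", c("a1", "a2")), bn_variable("B", c("b1", "b2"))),
    list(bn_cpt("A", "B", c(0.5, 0.5, 0.5, 0.5), child_states = c("a1", "a2"),
                parent_states = list(B = c("b1", "b2"))),
         bn_cpt("B", "A", c(0.5, 0.5, 0.5, 0.5), child_states = c("b1", "b2"),
                parent_states = list(A = c("a1", "a2")))))
  expect_length(grep("acyclic", validate_network(cyclic)), 1)

  # decision variables must not carry CPTs; random ones must
  mixed <- bn_network(
    list(bn_variable("D", c("d1", "d2"), role = "decision"),
         bn_variable("R", c("r1", "r2"))),
    list(bn_cpt("D", character(0), c(1, 0), child_states = c("d1", "d2"))))
  v <- validate_network(mixed)
  expect_true(any(grepl("decision variable 'D'", v)))
  expect_true(any(grepl("random variable 'R'", v)))
})

test_that("joint probability is the chain-rule product over random nodes", {
  net <- chain_net()
  expect_equal(joint_probability(net, c(A = "a1", B = "b1")), 0.27)
  expect_equal(joint_probability(net, c(A = "a2", B = "b2")), 0.35)
  # point-mass CPTs: the supported assignment has probability 1
  expect_equal(joint_probability(point_mass_net(), c(A = "a1", B = "b1")), 1)
  # assignment hitting a zero CPT entry
  expect_equal(joint_probability(point_mass_net(), c(A = "a2", B = "b1")), 0)
  expect_error(joint_probability(net, c(A = "a1")), "incomplete")

  # equals the corresponding enumeration entry exactly, on a random net
  rnet <- random_test_net(7)
  joint <- enumerate_joint(rnet)
  assign <- vapply(rnet$variables, function(v) v$states[1], character(1))
  expect_identical(joint_probability(rnet, assign),
                   as.numeric(joint$values[matrix(1L, 1,
                                                  length(rnet$variables))]))
})

test_that("queries reproduce total probability and Bayes' rule", {
  net <- chain_net()
  expect_equal(bn_query(net, "B")$B[["b1"]], 0.62)
  expect_equal(bn_query(net, "A", c(B = "b1"))$A[["a1"]], 0.27 / 0.62)
  expect_error(bn_query(net, "A", c(A = "a1")), "disjoint")
  expect_error(bn_query(point_mass_net(), "A", c(B = "b2")),
               "probability zero")
  # evidence consistency: P(X = x | X = x) = 1
  for (seed in c(3, 11)) {
    rnet <- random_test_net(seed)
    for (v in names(rnet$variables)) {
      st <- rnet$variables[[v]]$states[2]
      others <- setdiff(names(rnet$variables), v)
      post <- bn_query(rnet, others[1], stats::setNames(st, v))
      expect_equal(sum(post[[others[1]]]), 1, tolerance = 1e-12)
      # the conditioned variable itself is excluded from targets, so check
      # via joint on a two-node query through posterior_all
      pall <- posterior_all(rnet, stats::setNames(st, v))
      expect_false(v %in% names(pall))
    }
  }
})

test_that("variable-elimination marginals match the enumeration oracle", {
  for (seed in 0:9) {
    rnet <- random_test_net(seed)
    joint <- enumerate_joint(rnet)
    expect_equal(sum(joint$values), 1, tolerance = 1e-9)
    for (v in names(rnet$variables)) {
      expect_equal(bn_query(rnet, v)[[v]],
                   chathamrisk:::factor_marginal(joint, v),
                   tolerance = 1e-9)
    }
    # and under single-variable evidence
    ev_var <- names(rnet$variables)[1]
    ev <- stats::setNames(rnet$variables[[ev_var]]$states[1], ev_var)
    reduced <- chathamrisk:::factor_reduce(joint, ev_var, ev[[ev_var]])
    for (v in setdiff(names(rnet$variables), ev_var)) {
      f <- reduced
      for (o in setdiff(f$vars, v))
        f <- chathamrisk:::factor_marginalize(f, o)
      expect_equal(bn_query(rnet, v, ev)[[v]],
                   stats::setNames(as.numeric(f$values) / sum(f$values),
                                   rnet$variables[[v]]$states),
                   tolerance = 1e-9)
    }
  }
})

test_that("posterior_all agrees with per-variable queries and priors", {
  net <- chain_net()
  # no evidence: every root posterior equals its prior
  pall <- posterior_all(net)
  expect_equal(pall$A, c(a1 = 0.3, a2 = 0.7))
  # evidence on all variables but one: remaining posterior is its CPT row
  expect_equal(posterior_all(net, c(A = "a2"))$B, c(b1 = 0.5, b2 = 0.5))
  rnet <- random_test_net(5)
  pall <- posterior_all(rnet)
  for (v in names(pall))
    expect_identical(pall[[v]], bn_query(rnet, v)[[v]])
})

test_that("forward sampling is seed-stable and matches exact marginals", {
  # point-mass CPTs: every sample identical
  s <- forward_sample(point_mass_net(), 50, seed = 1)
  expect_identical(unique(s), data.frame(A = "a1", B = "b1"))
  # n = 0: empty table with the right columns
  s0 <- forward_sample(chain_net(), 0, seed = 1)
  expect_identical(dim(s0), c(0L, 2L))
  # deterministic per seed
  expect_identical(forward_sample(chain_net(), 100, seed = 9),
                   forward_sample(chain_net(), 100, seed = 9))
  # empirical P(b1) within binomial error of 0.62
  s <- forward_sample(chain_net(), 1e5, seed = 1)
  expect_lt(abs(mean(s$B == "b1") - 0.62), 0.01)
  # unfixed decision variable without a degenerate prior
  dnet <- bn_network(
    list(bn_variable("D", c("d1", "d2"), role = "decision"),
         bn_variable("R", c("r1", "r2"))),
    list(bn_cpt("R", "D", c(0.9, 0.1, 0.2, 0.8), child_states = c("r1", "r2"),
                parent_states = list(D = c("d1", "d2")))))
  expect_error(forward_sample(dnet, 5, seed = 1), "decision")
  s <- forward_sample(dnet, 2000, seed = 2, evidence = c(D = "d1"))
  expect_true(all(s$D == "d1"))
  expect_lt(abs(mean(s$R == "r1") - 0.9), 0.03)
  expect_error(forward_sample(dnet, 5, seed = 1,
                              evidence = c(R = "r1", D = "d1")),
               "decision variables only")
})

test_that("joint enumeration returns the exact product table, guarded", {
  net <- chain_net()
  joint <- enumerate_joint(net)
  expect_equal(joint$values["a1", "b1"], 0.27)
  expect_equal(joint$values["a1", "b2"], 0.03)
  expect_equal(joint$values["a2", "b1"], 0.35)
  expect_equal(joint$values["a2", "b2"], 0.35)
  # single three-state root: its prior
  root <- bn_network(list(bn_variable("R", c("r1", "r2", "r3"))),
                     list(bn_cpt("R", character(0), c(0.2, 0.3, 0.5),
                                 child_states = c("r1", "r2", "r3"))))
  expect_equal(as.numeric(enumerate_joint(root)$values), c(0.2, 0.3, 0.5))
  # guard: joint state space above 1e6
  big <- random_cpts(random_dag(21, 2, seed = 1), 2, 1, seed = 2)
  expect_error(enumerate_joint(big), "1e6|refusing")
})
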