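two_parent_spec <- function() {
  elicitation_spec(
    "C", beta_spec(1, 9), beta_spec(9, 1),
    list(parent_influence("P1", 2, c(p1a = 0, p1b = 0.5, p1c = 1)),
         parent_influence("P2", 1, c(p2a = 0, p2b = 1))))
}

test_that("the relevance index is the weight-averaged parent score", {
  spec <- two_parent_spec()
  expect_equal(relevance_index(spec, c(P1 = "p1a", P2 = "p2a")), 0)
  expect_equal(relevance_index(spec, c(P1 = "p1c", P2 = "p2b")), 1)
  expect_equal(relevance_index(spec, c(P1 = "p1b", P2 = "p2b")), 2 / 3)
  expect_error(relevance_index(spec, c(P1 = "p1a")), "P2")
  # degenerate weights are rejected at construction
  expect_error(
    elicitation_spec("C", beta_spec(1, 9), beta_spec(9, 1),
                     list(parent_influence("P", 0, c(a = 0, b = 1)))),
    "weight > 0")
  # invalid score vectors
  expect_error(parent_influence("P", 1, c(a = 0.2, b = 1)), "exactly 0 and 1")
  expect_error(parent_influence("P", 1, c(a = 0, b = 1, c = 0.5)),
               "nondecreasing")
})

test_that("beta interpolation is linear in parameter space with exact endpoints", {
  best <- beta_spec(1.7, 8.1)
  worst <- beta_spec(6.3, 2.2)
  expect_identical(interpolate_beta(best, worst, 0), best)
  expect_identical(interpolate_beta(best, worst, 1), worst)
  mid <- interpolate_beta(beta_spec(1, 9), beta_spec(9, 1), 0.5)
  expect_equal(c(mid$alpha, mid$beta), c(5, 5))
  expect_error(interpolate_beta(best, worst, 1.2), "\\[0, 1\\]")
  expect_error(interpolate_beta(best, worst, -0.1), "\\[0, 1\\]")
})

test_that("beta binning reproduces closed-form probabilities", {
  expect_equal(beta_bin_probs(beta_spec(1, 1), decrease_bins()),
               rep(0.2, 5), tolerance = 1e-12)
  expect_equal(beta_bin_probs(beta_spec(2, 1), bin_scheme(c(0, 0.5, 1))),
               c(0.25, 0.75), tolerance = 1e-12)  # CDF = x^2
  expect_equal(beta_bin_probs(beta_spec(2, 2), bin_scheme(c(0, 0.5, 1))),
               c(0.5, 0.5), tolerance = 1e-12)    # symmetry
})

test_that("elicited CPTs recover the endpoints and compose the sub-oracles", {
  # single binary parent with scores (0, 1): exactly the two endpoint columns
  spec <- elicitation_spec(
    "C", beta_spec(2, 5), beta_spec(6, 1.5),
    list(parent_influence("P", 1, c(lo = 0, hi = 1))))
  cpt <- build_cpt_from_elicitation(spec)
  expect_equal(as.numeric(cpt$values[, "lo"]),
               beta_bin_probs(spec$best, spec$bins), tolerance = 1e-12)
  expect_equal(as.numeric(cpt$values[, "hi"]),
               beta_bin_probs(spec$worst, spec$bins), tolerance = 1e-12)

  # three 3-state parents: 27 normalised columns
  spec3 <- elicitation_spec(
    "C", beta_spec(1, 4), beta_spec(4, 1),
    lapply(1:3, function(i)
      parent_influence(paste0("P", i), i, c(a = 0, b = 0.5, c = 1))))
  cpt3 <- build_cpt_from_elicitation(spec3)
  m <- matrix(cpt3$values, nrow = 5)
  expect_identical(ncol(m), 27L)
  expect_equal(colSums(m), rep(1, 27), tolerance = 1e-9)

  # the lambda = 1/2 column of a (1,9)/(9,1) pair equals binned Beta(5,5)
  spec2 <- elicitation_spec(
    "C", beta_spec(1, 9), beta_spec(9, 1),
    list(parent_influence("P", 1, c(a = 0, b = 0.5, c = 1))))
  cpt2 <- build_cpt_from_elicitation(spec2)
  expect_equal(as.numeric(cpt2$values[, "b"]),
               beta_bin_probs(beta_spec(5, 5), spec2$bins),
               tolerance = 1e-12)
})

test_that("the interpolated mean is monotone in lambda", {
  grid <- seq(0, 1, length.out = 101)
  set.seed(20)
  for (r in 1:100) {
    repeat {
      best <- beta_spec(runif(1, 0.2, 12), runif(1, 0.2, 12))
      worst <- beta_spec(runif(1, 0.2, 12), runif(1, 0.2, 12))
      if (worst$alpha / (worst$alpha + worst$beta) >=
          best$alpha / (best$alpha + best$beta)) break
    }
    means <- vapply(grid, function(l) {
      b <- interpolate_beta(best, worst, l)
      b$alpha / (b$alpha + b$beta)
    }, numeric(1))
    expect_true(all(diff(means) >= -1e-12))
  }
})

test_that("increasing one parent's state never lowers the expected decrease", {
  mids <- decrease_bins()$midpoints
  set.seed(77)
  for (r in 1:50) {
    cpt <- build_cpt_from_elicitation(random_elicitation_spec())
    d <- dim(cpt$values)
    ev <- apply(cpt$values, seq_along(d)[-1], function(p) sum(p * mids))
    ev <- array(ev, dim = d[-1])
    idx <- as.matrix(expand.grid(lapply(dim(ev), seq_len)))
    for (row in seq_len(nrow(idx))) {
      for (j in seq_along(dim(ev))) {
        up <- idx[row, ]
        if (up[j] < dim(ev)[j]) {
          up[j] <- up[j] + 1L
          expect_gte(ev[matrix(up, 1)], ev[matrix(idx[row, ], 1)] - 1e-12)
        }
      }
    }
  }
})

test_that("method-of-moments beta fitting matches closed forms and recovers", {
  # mean 0.5, sample variance 1/12 -> Beta(1, 1)
  a <- sqrt(1 / 12)
  fit <- fit_beta_moments(c(0.5 - a, 0.5, 0.5 + a))
  expect_equal(c(fit$alpha, fit$beta), c(1, 1), tolerance = 1e-9)
  # mean 0.5, sample variance 0.05 -> Beta(2, 2)
  a <- sqrt(0.05)
  fit <- fit_beta_moments(c(0.5 - a, 0.5, 0.5 + a))
  expect_equal(c(fit$alpha, fit$beta), c(2, 2), tolerance = 1e-9)
  # simulation recovery within +/- 15 %
  x <- chathamrisk:::with_seed(4, stats::rbeta(5000, 3, 7))
  fit <- fit_beta_moments(x)
  expect_lt(abs(fit$alpha - 3) / 3, 0.15)
  expect_lt(abs(fit$beta - 7) / 7, 0.15)
  # errors and clipping
  expect_error(fit_beta_moments(c(0.4, 0.6)), "at least 3")
  expect_error(fit_beta_moments(rep(0.5, 10)), "point-mass")
  expect_message(fit_beta_moments(c(0, 0.5, 0.9)), "clipped")
})
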