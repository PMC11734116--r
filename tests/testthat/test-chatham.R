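test_that("the default model reproduces the published structure", {
  net <- cached_default_net()
  expect_identical(validate_network(net), character(0))
  s <- structure_summary(net)
  expect_identical(s$n_nodes, 73L)
  expect_identical(s$n_edges, 154L)
  expect_identical(s$n_roots, 7L)
  expect_identical(as.integer(s$tiers[["biota"]]), 60L)
  expect_identical(as.integer(s$tiers[["operational"]]), 5L)
  # empty network degenerates cleanly
  empty <- bn_network(list(), list())
  s0 <- structure_summary(empty)
  expect_identical(c(s0$n_nodes, s0$n_edges, s0$n_roots), c(0L, 0L, 0L))
})

test_that("the default configuration encodes the scenario table and beta order", {
  cfg <- default_config()
  hi <- cfg$scenarios$high$assignments
  expect_identical(hi[["MiningIntensity"]], "100%")
  expect_identical(hi[["DepthExtraction"]], ">30 cm")
  expect_identical(hi[["ProcessingReturn"]], "at seafloor")
  lo <- cfg$scenarios$intermediate$assignments
  expect_identical(lo[["MiningIntensity"]], "50%")
  expect_identical(lo[["DepthExtraction"]], "<10 cm")
  # every elicitation spec satisfies mean(worst) >= mean(best)
  for (block in cfg$elicitation) for (e in block) {
    expect_gte(e$worst[1] / sum(e$worst), e$best[1] / sum(e$best))
  }
  # removing one biotic edge from the roster breaks assembly
  broken <- cfg
  drop <- which(broken$edges[, "to"] == "Year1_SoftBodied")[1]
  broken$edges <- broken$edges[-drop, , drop = FALSE]
  expect_error(assemble_network(broken), "edge roster")
})

test_that("direct removal follows intensity, escape and extraction depth", {
  # sessile group, full intensity, deep extraction, inside: everything goes
  expect_equal(direct_removal_fraction("SessErectSusp", "100%", ">30 cm",
                                       "inside"), 1.0)
  # no extraction outside the mined block
  expect_equal(direct_removal_fraction("DeepMeio", "100%", ">30 cm",
                                       "near-field"), 0)
  # mobile epifauna escape a fifth: 0.5 * 0.8
  expect_equal(direct_removal_fraction("MobGrazEpi", "50%", ">30 cm",
                                       "inside"), 0.4)
  # shallow extraction spares deep-dwelling infauna
  expect_equal(direct_removal_fraction("DeepMeio", "100%", "<10 cm",
                                       "inside"), 0.8)
  # monotone in intensity and, for infauna, in depth
  for (g in c("SessEncFilt", "DeepMeio", "PredScavHyper")) {
    fr <- vapply(c("50%", "75%", "100%"), function(i)
      direct_removal_fraction(g, i, ">30 cm", "inside"), numeric(1))
    expect_true(all(diff(fr) >= 0))
  }
  fr <- vapply(c("<10 cm", "10-30 cm", ">30 cm"), function(d)
    direct_removal_fraction("SmallSessMacro", "75%", d, "inside"), numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("direct CPTs are point masses with the lower-bin tie rule", {
  cpt <- direct_cpt("SessErectSusp")
  # fraction 1.0 -> (0,0,0,0,1); outside -> (1,0,0,0,0)
  expect_equal(as.numeric(cpt$values[, "100%", "inside"]), c(0, 0, 0, 0, 1))
  expect_equal(as.numeric(cpt$values[, "100%", "far-field"]),
               c(1, 0, 0, 0, 0))
  # mobile epifauna at 50 % inside: fraction 0.4 sits on the bin edge and
  # goes to the lower-impact bin 21-40
  cptm <- direct_cpt("MobGrazEpi")
  expect_equal(as.numeric(cptm$values[, "50%", "inside"]), c(0, 1, 0, 0, 0))
  # every column is a point mass
  m <- matrix(cpt$values, nrow = 5)
  expect_true(all(colSums(m) == 1) && all(m %in% c(0, 1)))
})

test_that("the immediate-combination CPT matches its analytic oracle", {
  cpt <- combined_immediate_cpt(grid_m = 200)
  col <- as.numeric(cpt$values[, "0-20%", "0-20%"])
  p1 <- 25 * (0.2 + 0.8 * log(0.8))  # P((1-D1)(1-D2) >= 0.8), D ~ U(0, 0.2)
  expect_lt(abs(col[1] - p1), 0.005)
  expect_lt(abs(col[2] - (1 - p1)), 0.005)
  expect_equal(col[3:5], c(0, 0, 0))
  # direct bin 81-100: all mass stays in 81-100 (T >= D1)
  expect_equal(as.numeric(cpt$values[, "81-100%", "0-20%"]),
               c(0, 0, 0, 0, 1))
  # symmetry of the combination in its two parents
  m <- matrix(cpt$values, nrow = 5)
  for (a in 1:5) for (b in 1:5)
    expect_equal(m[, (b - 1) * 5 + a], m[, (a - 1) * 5 + b])
  # stochastic dominance: T >= max(D1, D2), so no mass below either input bin
  for (a in 1:5) for (b in 1:5) {
    top <- max(a, b)
    if (top > 1)
      expect_equal(sum(m[seq_len(top - 1), (b - 1) * 5 + a]), 0)
  }
  expect_error(combined_immediate_cpt(grid_m = 10), ">= 50")
})

test_that("nodule removal never lowers the odds of significant sediment change", {
  net <- cached_default_net()
  cpt <- net$cpts$SedimentChanges
  for (dep in c("low", "moderate", "high"))
    expect_gte(cpt$values["significant", dep, "yes"],
               cpt$values["significant", dep, "no"])
})

test_that("configuration patches override targeted keys only", {
  cfg <- default_config()
  patched <- apply_config_patch(cfg, list(
    priors = list(SedimentContaminants = c(0.2, 0.4, 0.4)),
    immediate = list(grid_m = 120)))
  expect_equal(patched$priors$SedimentContaminants, c(0.2, 0.4, 0.4))
  expect_equal(patched$immediate$grid_m, 120)
  expect_identical(patched$priors$ParticleSize, cfg$priors$ParticleSize)
  expect_identical(patched$elicitation, cfg$elicitation)
  expect_error(apply_config_patch(cfg, list(prior = list())), "unknown key")
  # a patched model still assembles (counts unchanged)
  net <- assemble_network(patched)
  expect_identical(structure_summary(net)$n_nodes, 73L)
})
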