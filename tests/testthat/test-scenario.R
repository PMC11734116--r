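test_that("scenario evidence joins the operational states with the domain", {
  cfg <- default_config()
  net <- cached_default_net()
  ev <- scenario_evidence(cfg$scenarios$high, "inside", net)
  expect_length(ev, 5)
  expect_identical(ev[["MiningIntensity"]], "100%")
  expect_identical(ev[["Distance"]], "inside")
  ev <- scenario_evidence(cfg$scenarios$intermediate, "far-field", net)
  expect_identical(ev[["DepthExtraction"]], "<10 cm")
  expect_identical(ev[["Distance"]], "far-field")
  expect_error(scenario_evidence(cfg$scenarios$high, "offshore"), "domain")
  rogue <- list(name = "rogue",
                assignments = c(ParticleSize = "fine",
                                MiningIntensity = "50%"))
  expect_error(scenario_evidence(rogue, "inside", net), "non-decision")
})

test_that("a scenario run yields 90 normalised impact records per scenario", {
  run <- cached_scenario_run("high")
  expect_identical(nrow(run$impacts), 90L)
  expect_identical(nrow(unique(run$pressures[c("variable", "domain")])), 12L)
  pcols <- grep("^p_", names(run$impacts), value = TRUE)
  pcols <- setdiff(pcols, "p_most_likely")
  expect_equal(rowSums(run$impacts[pcols]), rep(1, 90), tolerance = 1e-9)
  expect_true(all(run$impacts$p_most_likely ==
                    do.call(pmax, run$impacts[pcols])))
  expect_true(all(run$impacts$expected_decrease >= 0 &
                    run$impacts$expected_decrease <= 1))
  agg <- stats::aggregate(probability ~ variable + domain, run$pressures, sum)
  expect_equal(agg$probability, rep(1, 12), tolerance = 1e-9)
  # exact inference: repeated runs are identical
  again <- run_scenario(cached_default_net(), "high")
  expect_identical(run$impacts, again$impacts)
  expect_error(run_scenario(cached_default_net(), "extreme"), "unknown")
})

test_that("posterior summaries follow the tie and midpoint rules", {
  ml <- most_likely_outcome(c(0.1, 0.2, 0.4, 0.2, 0.1),
                            decrease_bins()$labels)
  expect_identical(ml$state, "41-60%")
  expect_equal(ml$probability, 0.4)
  # ties break toward the lower-impact state
  ml <- most_likely_outcome(rep(0.2, 5), decrease_bins()$labels)
  expect_identical(ml$state, "0-20%")
  ml <- most_likely_outcome(c(0, 0, 0, 0, 1), decrease_bins()$labels)
  expect_identical(ml$state, "81-100%")
  expect_equal(ml$probability, 1)

  expect_equal(expected_decrease(c(0, 0, 0, 0, 1)), 0.9)
  expect_equal(expected_decrease(rep(0.2, 5)), 0.5)
  expect_equal(expected_decrease(c(0.5, 0.5, 0, 0, 0)), 0.2)
})

test_that("scenario comparison returns signed differences and TV distances", {
  hi <- cached_scenario_run("high")
  expect_true(all(compare_scenarios(hi, hi)$delta_expected_decrease == 0))
  expect_true(all(compare_scenarios(hi, hi)$tv_distance == 0))

  # adjacent point masses have TV distance 1
  fake <- function(p) {
    imp <- data.frame(scenario = "s", domain = "inside", group = "g",
                      time_step = "immediate", stringsAsFactors = FALSE)
    imp[paste0("p_", 1:5)] <- as.list(p)
    imp$p_most_likely <- max(p)
    imp$expected_decrease <- expected_decrease(p)
    list(impacts = imp)
  }
  cmp <- compare_scenarios(fake(c(1, 0, 0, 0, 0)), fake(c(0, 1, 0, 0, 0)))
  expect_equal(cmp$tv_distance, 1)
  expect_equal(cmp$delta_expected_decrease, -0.2)

  # high dominates intermediate after one year everywhere
  cmp <- compare_scenarios(hi, cached_scenario_run("intermediate"))
  yr <- cmp[cmp$time_step == "year1", ]
  expect_true(all(yr$delta_expected_decrease >= 0))
  expect_error(compare_scenarios(hi, fake(c(1, 0, 0, 0, 0))), "match")
})

test_that("scenario plots render on a null device", {
  run <- cached_scenario_run("high")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(run, which = "pressures"))
  expect_invisible(plot(run, which = "impacts", time_step = "immediate"))
})
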