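test_that("a hazard-free scenario retains and stains every seed", {
  sc <- smallScenario(p_expend1 = 0, p_die1 = 0, p_expend2 = 0,
                      p_die2 = 0, assay_fraction = 1)
  x <- simulateExperiment(sc)
  df <- packets(x)
  expect_true(all(df$n_retained == df$seeds_sown))
  expect_true(all(df$n_expended == 0))
  expect_true(all(df$n_stained == df$n_assayed))
  est <- estimateSurvival(x, by = "species")
  expect_equal(est$survival, 1)
})

test_that("simulation is deterministic and strata are independent", {
  sc <- calibratedScenario(rng_seed = 31)
  x1 <- simulateExperiment(sc)
  x2 <- simulateExperiment(sc)
  expect_identical(packets(x1), packets(x2))

  # dropping one design row leaves the other species' packets untouched
  d <- eriophyllumDesign()
  sc_full <- calibratedScenario(rng_seed = 8)
  sc_rare <- FateScenario(d[d$species == "E. mohavense", ],
                          hazardsOf(sc_full), assay_fraction = 0.5,
                          rng_seed = 8L)
  p_full <- packets(simulateExperiment(sc_full))
  p_rare <- packets(simulateExperiment(sc_rare))
  p_sub <- p_full[p_full$species == "E. mohavense", ]
  rownames(p_sub) <- NULL
  expect_identical(p_sub, p_rare)
})

test_that("model-implied pools follow the closed-form seasonal recursion", {
  sc <- smallScenario(p_expend1 = 0.3, p_die1 = 0.2, p_expend2 = 0.4,
                      p_die2 = 0.1)
  imp <- impliedPools(sc)
  one <- imp[imp$microhabitat == "control" & imp$burial_seasons == 1, ]
  two <- imp[imp$microhabitat == "control" & imp$burial_seasons == 2, ]
  # season 1: L = 0.5, D = 0.2, retained = 0.7
  expect_equal(one$p_retained, 0.7)
  expect_equal(one$p_retained_live, 0.5)
  expect_equal(one$staining_rate, 0.5 / 0.7)
  # season 2: L = 0.5 * 0.5, D = 0.2 * 0.6 + 0.5 * 0.1
  expect_equal(two$p_retained_live, 0.25)
  expect_equal(two$p_retained_dead, 0.17)
  expect_equal(two$survival, two$p_retained * two$staining_rate)
})

test_that("simulated pool frequencies converge to the closed form", {
  # the same hazards at two experiment sizes: error shrinks with n and
  # stays within 3 binomial standard errors at both
  for (n_packets in c(30L, 300L)) {
    sc <- smallScenario(n_packets = n_packets, seeds_per_packet = 12L,
                        rng_seed = 17)
    x <- simulateExperiment(sc)
    est <- estimateSurvival(x, by = "burial_seasons")
    imp <- impliedPools(sc)
    for (d in 1:2) {
      truth <- mean(imp$p_retained[imp$burial_seasons == d])
      n_seeds <- sum(packets(x)$seeds_sown[packets(x)$burial_seasons == d])
      se <- sqrt(truth * (1 - truth) / n_seeds)
      expect_lt(abs(est$pl[est$burial_seasons == d] - truth), 3 * se)
    }
  }
})

test_that("raising the expend hazard weakly lowers simulated retention", {
  retained <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(pe) {
    sc <- smallScenario(p_expend1 = pe, p_die1 = 0.05,
                        n_packets = 60L, seeds_per_packet = 15L,
                        rng_seed = 23)
    sum(packets(simulateExperiment(sc))$n_retained)
  }, numeric(1))
  expect_true(all(diff(retained) <= 0))
})

test_that("calibration inverts the closed-form pool equations", {
  # single-season worked example: expended 0.5, retained-live 0.25
  pools <- data.frame(species = "sp", cohort = "c1",
                      microhabitat = "control", retained_1 = 0.5,
                      staining_1 = 0.5, retained_2 = NA, staining_2 = NA)
  sc <- scenarioFromPools(pools, design = data.frame(
    species = "sp", cohort = "c1", n_packets = 6L, seeds_per_packet = 10L),
    microhabitats = "control")
  hz <- hazardsOf(sc)
  expect_equal(hz$p_expend[hz$season == 1], 0.5)
  expect_equal(hz$p_die[hz$season == 1], 0.25)  # live-given-retained 0.5

  # round-trip: targets taken from a known scenario recover its season-1
  # hazards and all of its implied pools
  sc0 <- smallScenario(p_expend1 = 0.35, p_die1 = 0.15, p_expend2 = 0.2,
                       p_die2 = 0.25)
  imp0 <- impliedPools(sc0)
  t1 <- imp0[imp0$burial_seasons == 1, ]
  t2 <- imp0[imp0$burial_seasons == 2, ]
  pools2 <- data.frame(species = t1$species, cohort = t1$cohort,
                       microhabitat = t1$microhabitat,
                       retained_1 = t1$p_retained,
                       staining_1 = t1$staining_rate,
                       retained_2 = t2$p_retained,
                       staining_2 = t2$staining_rate)
  sc1 <- scenarioFromPools(pools2, design = designOf(sc0))
  hz1 <- hazardsOf(sc1)
  expect_equal(hz1$p_expend[hz1$season == 1], rep(0.35, 3),
               tolerance = 1e-12)
  expect_equal(hz1$p_die[hz1$season == 1], rep(0.15, 3),
               tolerance = 1e-12)
  expect_equal(impliedPools(sc1)[, c("p_retained", "p_retained_live")],
               imp0[, c("p_retained", "p_retained_live")],
               tolerance = 1e-12)

  # a rising staining rate is representable via faster dead-seed decay
  pools3 <- data.frame(species = "sp", cohort = "c1",
                       microhabitat = "control", retained_1 = 0.327,
                       staining_1 = 0.49, retained_2 = 0.156,
                       staining_2 = 0.623)
  sc3 <- scenarioFromPools(pools3, design = data.frame(
    species = "sp", cohort = "c1", n_packets = 6L, seeds_per_packet = 10L),
    microhabitats = "control")
  hz3 <- hazardsOf(sc3)
  expect_gt(hz3$p_expend_dead[hz3$season == 2],
            hz3$p_expend[hz3$season == 2])

  # infeasible ordering: retention cannot grow between years
  pools4 <- pools3; pools4$retained_2 <- 0.5
  expect_error(scenarioFromPools(pools4, design = data.frame(
    species = "sp", cohort = "c1", n_packets = 6L,
    seeds_per_packet = 10L), microhabitats = "control"),
    "year-2 retained exceeds year-1 retained")
})

test_that("indivisible designs are rejected with the offending row named", {
  sc <- smallScenario()
  sc@design$n_packets <- 10L  # not divisible by 3 microhabitats x 2 years
  expect_error(simulateExperiment(sc), "design row 1")
})

test_that("the recovery study reports bias against closed-form truths", {
  sc <- smallScenario(n_packets = 24L, seeds_per_packet = 8L)
  expect_warning(rec <- parameterRecoveryStudy(sc, n_replicates = 2,
                                               seed = 2),
                 "suppressed")
  expect_true(all(is.na(rec$flagged)))
  expect_setequal(unique(rec$quantity), c("pl", "ps", "survival"))

  # sparser packets give noisier estimates at equal truth
  d <- data.frame(species = c("sp", "sp"), cohort = c("big", "tiny"),
                  n_packets = c(90L, 180L), seeds_per_packet = c(18L, 2L))
  hz <- expand.grid(microhabitat = c("control", "runoff", "shade"),
                    season = 1:2, cohort = c("big", "tiny"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hz$species <- "sp"; hz$p_expend <- 0.4; hz$p_die <- 0.1
  sc2 <- FateScenario(d, hz, assay_fraction = 1, rng_seed = 3L)
  rec2 <- parameterRecoveryStudy(sc2, n_replicates = 30, seed = 5)
  sd_big <- rec2$sd[rec2$cohort == "big" & rec2$quantity == "pl" &
                      rec2$burial_seasons == 1]
  sd_tiny <- rec2$sd[rec2$cohort == "tiny" & rec2$quantity == "pl" &
                       rec2$burial_seasons == 1]
  expect_true(all(sd_tiny > sd_big))
})
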