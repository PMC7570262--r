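test_that("pool summaries count and proportion the seed fate classes", {
  # single packet, everything intact, nothing assayed
  x <- SeedPacketExperiment(packetRow(n_expended = 0L, n_retained = 18L,
                                      n_assayed = 0L, n_stained = 0L))
  s <- summarizePools(x)
  expect_equal(s$prop_retained, 1)
  expect_equal(s$prop_expended, 0)
  expect_true(is.na(s$staining_rate))

  # two packets pooled by hand: 6 + 8 expended of 10 + 10 sown
  df <- rbind(packetRow("a", seeds_sown = 10L, n_expended = 6L,
                        n_retained = 4L, n_assayed = 0L, n_stained = 0L),
              packetRow("b", seeds_sown = 10L, n_expended = 8L,
                        n_retained = 2L, n_assayed = 0L, n_stained = 0L))
  s2 <- summarizePools(SeedPacketExperiment(df))
  expect_equal(s2$n_expended, 14L)
  expect_equal(s2$prop_expended, 0.70)

  # pool identity: F + C + unrecovered = total, proportions sum to 1
  x3 <- simulateExperiment(calibratedScenario(rng_seed = 13))
  s3 <- summarizePools(x3, by = c("species", "microhabitat"))
  expect_equal(s3$n_expended + s3$n_retained + s3$n_unrecovered, s3$n_total)
  expect_equal(s3$prop_expended + s3$prop_retained + s3$prop_unrecovered,
               rep(1, nrow(s3)))
})

test_that("pool counts aggregate associatively across grouping levels", {
  x <- simulateExperiment(calibratedScenario(rng_seed = 5))
  fine <- summarizePools(x, by = c("species", "cohort"))
  coarse <- summarizePools(x, by = "species")
  for (sp in unique(coarse$species)) {
    expect_equal(sum(fine$n_retained[fine$species == sp]),
                 coarse$n_retained[coarse$species == sp])
    expect_equal(sum(fine$n_expended[fine$species == sp]),
                 coarse$n_expended[coarse$species == sp])
  }
})

test_that("live/dead pools are intervals with the equal-split display rule", {
  # no expended seed: the live pool is known exactly
  x <- SeedPacketExperiment(packetRow(n_expended = 0L, n_retained = 18L,
                                      n_assayed = 18L, n_stained = 9L))
  ld <- liveDeadPools(summarizePools(x))
  expect_equal(ld$live_G_min, ld$live_G_max)
  expect_equal(ld$live_G_min, 0.5)

  # F = 40, pool-scale D = 10 and E = 5 of 100: G ranges over [10, 50]
  df <- packetRow(seeds_sown = 100L, n_expended = 40L, n_retained = 15L,
                  n_assayed = 15L, n_stained = 10L)
  ld2 <- liveDeadPools(summarizePools(SeedPacketExperiment(df)))
  expect_equal(ld2$pool_live_D * 100, 10)
  expect_equal(ld2$pool_dead_E * 100, 5)
  expect_equal(c(ld2$live_G_min, ld2$live_G_max) * 100, c(10, 50))
  expect_equal(c(ld2$dead_H_min, ld2$dead_H_max) * 100, c(5, 45))
  expect_equal(ld2$display_decayed_A * 100, 20)
  expect_equal(ld2$display_germinated_B * 100, 20)
  expect_match(attr(ld2, "display_rule"), "display convention")
})

test_that("sankey flows conserve mass and scale the assay subsample to C", {
  # everything retained, everything assayed and stained: one unit path
  x <- SeedPacketExperiment(packetRow(n_expended = 0L, n_retained = 18L,
                                      n_assayed = 18L, n_stained = 18L))
  fl <- sankeyFlows(summarizePools(x))
  expect_equal(fl$value[fl$target == "retained (C)"], 1)
  expect_equal(fl$value[fl$target == "retained live (D)"], 1)
  expect_equal(fl$value[fl$target == "retained dead (E)"], 0)

  # assayed subsample scaling: C's children reflect D/(D+E) applied to C
  y <- SeedPacketExperiment(packetRow(seeds_sown = 100L, n_expended = 40L,
                                      n_retained = 60L, n_assayed = 15L,
                                      n_stained = 10L))
  fl2 <- sankeyFlows(summarizePools(y))
  expect_equal(fl2$value[fl2$target == "retained live (D)"], 0.6 * 10 / 15)
  # root outflow equals the recovered fraction
  expect_equal(sum(fl2$value[fl2$source == "seed bank"]), 1)

  # no assay but retained seed: C terminates unsplit, flagged
  z <- SeedPacketExperiment(packetRow(n_expended = 6L, n_retained = 12L,
                                      n_assayed = 0L, n_stained = 0L))
  fl3 <- sankeyFlows(summarizePools(z))
  expect_false(any(fl3$source == "assay"))
  expect_match(fl3$note[fl3$target == "retained (C)"], "unsplit")
})

test_that("sankey export writes consumable JSON and CSV flow tables", {
  x <- simulateExperiment(calibratedScenario(rng_seed = 2))
  fl <- sankeyFlows(summarizePools(x, by = c("species", "burial_seasons")))
  fj <- tempfile(fileext = ".json"); fc <- tempfile(fileext = ".csv")
  writeSankey(fl, json = fj, csv = fc)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_setequal(names(back), unique(fl$group))
  expect_true(all(c("source", "target", "value") %in%
                    names(back[[1]])))
  csv <- read.csv(fc)
  expect_equal(nrow(csv), nrow(fl))
  unlink(c(fj, fc))
})
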