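test_that("seed bank survival is the product of retention and staining", {
  expect_equal(survivalEstimate(1, 1), 1)
  expect_equal(survivalEstimate(0.5, 0), 0)
  expect_equal(survivalEstimate(0.16, 0.623), 0.09968)
  expect_error(survivalEstimate(1.2, 0.5), "\\[0, 1\\]")
  expect_error(survivalEstimate(0.5, -0.1), "\\[0, 1\\]")
  # survival never exceeds either factor
  pl <- runif(50); ps <- runif(50)
  s <- survivalEstimate(pl, ps)
  expect_true(all(s <= pmin(pl, ps) + 1e-15))
})

test_that("pooled-count estimates handle empty retention and assay gracefully", {
  df <- rbind(
    packetRow("a", seeds_sown = 10L, n_expended = 10L, n_retained = 0L,
              n_assayed = 0L, n_stained = 0L),
    packetRow("b", species = "E. wallacei", seeds_sown = 10L,
              n_expended = 2L, n_retained = 8L, n_assayed = 4L,
              n_stained = 3L))
  est <- estimateSurvival(SeedPacketExperiment(df), by = "species")
  a <- est[est$species == "E. mohavense", ]
  expect_equal(a$pl, 0)
  expect_equal(a$survival, 0)  # zero retention forces zero survival
  b <- est[est$species == "E. wallacei", ]
  expect_equal(b$pl, 0.8)
  expect_equal(b$ps, 0.75)
  expect_equal(b$survival, 0.6)
})

test_that("stratum means reproduce the printed cross-species averages", {
  # year-2 survival by microhabitat, per species (percent scale)
  est <- data.frame(
    species = rep(c("rare", "common"), each = 3),
    microhabitat = rep(c("control", "runoff", "shade"), 2),
    pl = NA_real_, ps = NA_real_,
    survival = c(5.6, 9.6, 14.0, 1.0, 0.3, 5.3))
  attr(est, "by") <- c("species", "microhabitat")
  agg <- aggregateSurvival(est, over = "species")
  got <- setNames(roundHalfUp(agg$survival, 1), agg$microhabitat)
  expect_equal(got[["control"]], 3.3)
  expect_equal(got[["runoff"]], 5.0)
  expect_equal(got[["shade"]], 9.7)

  # order invariance and mean-of-identical
  agg_rev <- aggregateSurvival(est[6:1, ], over = "species")
  expect_equal(agg$survival[order(agg$microhabitat)],
               agg_rev$survival[order(agg_rev$microhabitat)])
  same <- est; same$survival <- 7
  expect_equal(aggregateSurvival(same, over = "species")$survival,
               rep(7, 3))
})

test_that("the average of survival products differs from the product of averages", {
  pl <- c(0.9, 0.2); ps <- c(0.1, 0.8)
  mean_of_products <- mean(pl * ps)      # 0.125
  product_of_means <- mean(pl) * mean(ps)  # 0.2475
  expect_false(isTRUE(all.equal(mean_of_products, product_of_means)))
  # the aggregation path reports the mean of stratum-level products
  est <- data.frame(species = c("a", "b"), pl = pl, ps = ps,
                    survival = pl * ps)
  attr(est, "by") <- "species"
  agg <- aggregateSurvival(est, over = "species")
  expect_equal(agg$survival, mean_of_products)
  expect_equal(agg$pl * agg$ps, product_of_means)
})

test_that("between-year decline is percent change with a guarded zero", {
  expect_equal(survivalDecline(0.2, 0.2), 0)
  expect_equal(survivalDecline(18.9, 3.3), (18.9 - 3.3) / 18.9 * 100)
  expect_error(survivalDecline(0, 0.1), "positive")
})

test_that("report rounding is half away from zero", {
  expect_equal(roundHalfUp(4.95, 1), 5.0)
  expect_equal(roundHalfUp(9.65, 1), 9.7)
  expect_equal(roundHalfUp(21.15, 0), 21)
  expect_equal(roundHalfUp(-4.95, 1), -5.0)
  # base round() ties to even, which is wrong for printed percentages
  expect_identical(round(0.25, 1), 0.2)
  expect_equal(roundHalfUp(0.25, 1), 0.3)
})

test_that("packet bootstrap intervals bracket the point estimate", {
  x <- simulateExperiment(calibratedScenario(rng_seed = 21))
  bs <- bootstrapSurvival(x, by = "species", n_boot = 200, seed = 4)
  expect_true(all(bs$survival_lo <= bs$survival + 1e-12))
  expect_true(all(bs$survival_hi >= bs$survival - 1e-12))
  expect_match(attr(bs, "interval"), "extension")
  # deterministic under a fixed seed
  bs2 <- bootstrapSurvival(x, by = "species", n_boot = 200, seed = 4)
  expect_equal(bs$survival_lo, bs2$survival_lo)
})
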