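test_that("Mann-Whitney U follows the rank-sum-minus-offset convention", {
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1 / 3)  # 2 of the 6 rank assignments are as extreme
  expect_true(r$exact)

  # identical multisets: W = n^2 / 2 by midrank symmetry, p = 1
  r2 <- mannWhitneyU(c(3, 1, 4, 1), c(1, 4, 3, 1))
  expect_equal(unname(r2$statistic), 8)
  expect_equal(r2$p.value, 1)

  # degenerate: all values identical across both samples
  r3 <- mannWhitneyU(rep(2, 5), rep(2, 4))
  expect_equal(r3$p.value, 1)
  expect_match(r3$method, "degenerate")
})

test_that("the exact path equals the brute-force permutation oracle", {
  # every split of {1..8} into two samples of 4: 70 instances
  for (idx in asplit(combn(8, 4), 2)) {
    a <- (1:8)[idx]; b <- (1:8)[-idx]
    got <- mannWhitneyU(a, b)
    oracle <- bruteForceMWU(a, b)
    expect_equal(unname(got$statistic), oracle$W)
    expect_equal(got$p.value, oracle$p)
  }
  # random tie-free instances across all shapes with n_a + n_b <= 10
  set.seed(7)
  for (na in 1:5) for (nb in na:(10 - na)) {
    for (rep in 1:3) {
      vals <- sample(1000, na + nb)
      a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
      got <- mannWhitneyU(a, b)
      oracle <- bruteForceMWU(a, b)
      expect_equal(got$p.value, oracle$p,
                   info = sprintf("na=%d nb=%d rep=%d", na, nb, rep))
    }
  }
})

test_that("ties route to the corrected normal approximation", {
  a <- c(1, 2, 2, 3, 5, 6, 9); b <- c(2, 3, 3, 4, 7, 8, 8)
  expect_warning(r <- mannWhitneyU(a, b, exact = TRUE), "ties")
  expect_true(r$tie_correction)
  # cross-check against the standard implementation of the same
  # approximation
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(unname(r$statistic), unname(ref$statistic))
  expect_equal(r$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("Kruskal-Wallis matches hand computation and the two-group identity", {
  r <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(unname(r$statistic), 7.2)
  expect_equal(unname(r$parameter), 2)

  expect_error(kruskalWallis(list(1:3)), "2 groups")

  # with two groups, H equals z^2 from the uncorrected normal MWU path
  set.seed(11)
  a <- rnorm(9); b <- rnorm(12) + 0.4
  kw <- kruskalWallis(list(a, b))
  mw <- mannWhitneyU(a, b, exact = FALSE, continuity = FALSE)
  expect_equal(kw$p.value, mw$p.value, tolerance = 1e-12)

  # tie-corrected H agrees with the standard implementation
  v <- c(1, 2, 2, 3, 3, 3, 4, 5, 5, 6, 7, 7)
  g <- rep(1:3, each = 4)
  expect_equal(unname(kruskalWallis(v, g)$statistic),
               unname(kruskal.test(v, g)$statistic), tolerance = 1e-12)
})

test_that("Dunn post-hoc z tests adjust and order sensibly", {
  # two groups: one comparison, adjustment cannot change the p-value
  d2 <- dunnPosthoc(list(a = c(1, 3, 5), b = c(2, 4, 6)))
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$p_raw, d2$p_adj)

  # three identical groups: all z = 0, all adjusted p = 1
  d3 <- dunnPosthoc(list(a = 1:3, b = 1:3, c = 1:3))
  expect_equal(d3$z, rep(0, 3))
  expect_equal(d3$p_adj, rep(1, 3))

  # adjusted p-values are monotone in raw p-values
  set.seed(3)
  for (method in c("bonferroni", "holm")) {
    d <- dunnPosthoc(split(rnorm(40), sample(1:4, 40, TRUE)),
                     method = method)
    o <- order(d$p_raw)
    expect_true(all(diff(d$p_adj[o]) >= -1e-12))
    expect_equal(attr(d, "adjustment"), method)
  }
})

test_that("the normality screen gates sample size and degeneracy", {
  expect_error(normalityScreen(c(1, 2)), "3 <= n")
  expect_error(normalityScreen(rep(1, 10)), "constant")
  # a 0/1-inflated survival mixture is flagged as non-normal
  set.seed(5)
  rejected <- mean(replicate(200, {
    v <- c(rep(0, 30), runif(20), rep(1, 10))
    normalityScreen(sample(v, 60, TRUE))$p.value < 0.05
  }))
  expect_gt(rejected, 0.9)
  # near-nominal rejection for genuinely normal data
  rate <- mean(replicate(400, normalityScreen(rnorm(60))$p.value < 0.05))
  expect_lt(rate, 0.12)
})

test_that("the quasibinomial GLM fits, flags and tabulates correctly", {
  # balanced two-level factor with identical group means: F ~ 0, p ~ 1
  d <- data.frame(f = rep(c("a", "b"), each = 4),
                  y = rep(c(0.3, 0.5, 0.4, 0.6), 2), w = 20)
  fit <- fitQuasibinomialGLM(y ~ f, d, weights = d$w)
  tab <- devianceTable(fit)
  expect_lt(tab$f_value[1], 1e-8)
  expect_gt(tab$p_value[1], 0.999)
  expect_equal(tab$term, c("f", "residuals"))
  expect_equal(tab$df, c(1, 6))

  # deviance decreases monotonically across IRLS iterations
  set.seed(9)
  d2 <- data.frame(f = sample(c("a", "b"), 40, TRUE),
                   g = sample(c("u", "v", "w"), 40, TRUE), w = 25)
  d2$y <- rbinom(40, 25, plogis(0.5 * (d2$f == "b"))) / 25
  fit2 <- fitQuasibinomialGLM(y ~ f * g, d2, weights = d2$w)
  expect_true(all(diff(fit2$deviance_trace) <= 1e-10))
  expect_true(all(fit2$fitted > 0 & fit2$fitted < 1))
  expect_equal(fit2$df_residual, fit2$n - fit2$rank)

  # perfectly separated data are flagged, not silently reported
  d3 <- data.frame(f = rep(c("a", "b"), each = 6),
                   y = rep(c(0, 1), each = 6))
  expect_warning(fit3 <- fitQuasibinomialGLM(y ~ f, d3), "separation")
  expect_true(fit3$separation)

  # domain errors
  expect_error(fitQuasibinomialGLM(y ~ f, data.frame(f = c("a", "b"),
                                                     y = c(0.5, 1.2))),
               "\\[0, 1\\]")
  expect_error(fitQuasibinomialGLM(y ~ f,
                                   data.frame(f = "a", y = 0.5),
                                   weights = 1), "2 levels")
})
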