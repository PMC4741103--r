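test_that("known/unknown pools partition the session 1:(stride-1)", {
  s <- generateSession(tiny_specs(1), 300, seed = 31, imageSize = 64)
  p <- splitKnownUnknown(s, 10)
  expect_equal(nFrames(p$known), 30)
  expect_equal(nFrames(p$unknown), 270)
  expect_length(intersect(frameIndices(p$known), frameIndices(p$unknown)), 0)
  expect_setequal(c(frameIndices(p$known), frameIndices(p$unknown)), 1:300)
  expect_equal(nFrames(p$unknown) / nFrames(s), 9 / 10)

  expect_error(splitKnownUnknown(s, 1), "at least 2")
  expect_error(splitKnownUnknown(s, 1000), "exceeds")
})

test_that("condition batteries respect order, seeding and pool size", {
  s <- generateSession(tiny_specs(1), 60, seed = 37, imageSize = 64)

  b <- buildConditionBattery(s, randomized = FALSE, nImages = 20, seed = 5)
  expect_false(is.unsorted(b$frameIndex))
  expect_false(b$replacement)

  b2 <- buildConditionBattery(s, randomized = FALSE, nImages = 20, seed = 5)
  expect_identical(b, b2)

  # the randomized battery is a permutation of the ordered one
  br <- buildConditionBattery(s, randomized = TRUE, nImages = 20, seed = 5)
  expect_identical(sort(br$frameIndex), sort(b$frameIndex))
  expect_false(identical(br$frameIndex, b$frameIndex))

  # small pools fall back to sampling with replacement, flagged
  small <- subsampleSession(s, 10)
  bs <- buildConditionBattery(small, randomized = TRUE, nImages = 20,
                              seed = 5)
  expect_true(bs$replacement)
  expect_length(bs$frames, 20)

  empty <- new("Session", frames = list(), posture = integer(),
               partner = integer(), frameIndex = integer(),
               schedule = data.frame(partner_id = integer(),
                                     start_frame = integer(),
                                     end_frame = integer()),
               seed = NA_integer_)
  expect_error(buildConditionBattery(empty, FALSE, 10, 1), "empty")
})

test_that("binomial p-values are exact upper tails", {
  expect_equal(binomialVsChance(10, 10, 0.5), 0.5^10)
  expect_equal(binomialVsChance(0, 15, 0.3), 1)

  # brute-force pmf summation oracle for all n <= 20
  for (n in c(5, 11, 20)) {
    for (hits in c(0, 1, n %/% 2, n)) {
      brute <- sum(choose(n, hits:n) * 0.2^(hits:n) * 0.8^(n - hits:n))
      expect_equal(binomialVsChance(hits, n, 0.2), brute,
                   tolerance = 1e-12)
    }
  }
  expect_error(binomialVsChance(3, 10, 1.2), "chance")
  expect_error(binomialVsChance(11, 10, 0.5), "hits")
})

test_that("bootstrap intervals behave like percentile bootstraps", {
  expect_equal(bootstrapCI(rep(80, 6), seed = 1), c(80, 80))

  set.seed(10)
  x <- rnorm(40, mean = 50, sd = 8)
  ci <- bootstrapCI(x, nBoot = 5000, seed = 2)
  expect_lte(ci[1], mean(x))
  expect_gte(ci[2], mean(x))
  expect_identical(ci, bootstrapCI(x, nBoot = 5000, seed = 2))

  # width close to the analytic normal interval for larger samples
  y <- rnorm(200, mean = 0, sd = 1)
  ci2 <- bootstrapCI(y, nBoot = 5000, seed = 3)
  analytic <- 2 * 1.96 * sd(y) / sqrt(200)
  expect_lt(abs((ci2[2] - ci2[1]) - analytic) / analytic, 0.15)

  expect_error(bootstrapCI(5), "two scores")
})

test_that("contrast signs summarize the four-condition table", {
  tab <- expand.grid(known = c(TRUE, FALSE), randomized = c(TRUE, FALSE),
                     partner = 1:3)
  tab$score <- ifelse(tab$known, 90, 70)
  cc <- contrastCheck(tab)
  expect_equal(cc$known_effect_sign, 1)
  expect_equal(cc$random_effect_sign, 0)

  tab$score <- 50
  cc2 <- contrastCheck(tab)
  expect_equal(cc2$known_effect_sign, 0)
  expect_equal(cc2$random_effect_sign, 0)

  expect_error(contrastCheck(tab[tab$known, ]), "all four")
})

test_that("a single-partner experiment scores 100% in all four conditions", {
  cfg <- peracConfig(seed = 11, framesPerPartner = 40, nImages = 10)
  ex <- runExperiment(tiny_specs(1), cfg)
  res <- results(ex)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$score == 100))
  expect_equal(unique(res$chance), 100)
})

test_that("the experiment table has 4 rows per partner and valid scores", {
  cfg <- peracConfig(seed = 12, framesPerPartner = 40, nImages = 10)
  ex <- runExperiment(tiny_specs(3), cfg)
  res <- results(ex)
  expect_equal(nrow(res), 12L)
  expect_equal(sort(unique(res$condition)),
               sort(c("random/known", "non-random/known",
                      "random/unknown", "non-random/unknown")))
  expect_true(all(res$score >= 0 & res$score <= 100))
  expect_equal(res$score, 100 * res$hits / res$n_images)
  expect_equal(unique(res$chance), 100 / 3)
  sm <- summarizeExperiment(ex, nBoot = 500, seed = 1)
  expect_equal(nrow(sm), 4L)
  expect_true(all(sm$p_binomial >= 0 & sm$p_binomial <= 1))
})
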