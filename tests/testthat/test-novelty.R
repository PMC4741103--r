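test_that("frame error is the normalized Euclidean prediction error", {
  expect_equal(frameError(motorState(2), motorState(2)), 0)

  # uniform 0.2 prediction against a one-hot: sqrt(0.8^2 + 4*0.2^2)/sqrt(2)
  e <- frameError(rep(0.2, 5), motorState(1))
  expect_equal(e, sqrt(0.8^2 + 4 * 0.2^2) / sqrt(2))
  expect_equal(round(e, 3), 0.632)

  # invariant under a common permutation of the classes
  set.seed(8)
  p <- runif(5); a <- motorState(3)
  for (i in 1:10) {
    perm <- sample(5)
    expect_equal(frameError(p[perm], a[perm]), frameError(p, a))
  }

  expect_error(frameError(1:3, 1:4), "same length")
})

test_that("the novelty detector fires once at baseline and once per step", {
  st <- newNoveltyState()
  events <- 0L
  for (t in 1:80) {
    r <- noveltyStep(st, 0.3)
    st <- r$state
    if (r$event) events <- events + 1L
  }
  expect_equal(events, 1L)             # only the t = 1 baseline
  expect_equal(st@events$time, 1L)

  # a step 0.1 -> 0.6 fires exactly one extra event, soon after the step
  st <- newNoveltyState()
  stream <- c(rep(0.1, 50), rep(0.6, 50))
  for (t in seq_along(stream)) st <- noveltyStep(st, stream[t])$state
  expect_equal(nrow(st@events), 2L)
  expect_gte(st@events$time[2], 51L)
  expect_lte(st@events$time[2], 51L + st@window)

  # two steps inside one refractory period are not double-counted
  st <- newNoveltyState()
  stream <- c(rep(0.1, 30), rep(0.5, 5), rep(0.9, 30))
  for (t in seq_along(stream)) st <- noveltyStep(st, stream[t])$state
  expect_lte(nrow(st@events), 3L)
  if (nrow(st@events) > 1)
    expect_true(all(diff(st@events$time) > st@refractory))

  expect_error(noveltyStep(newNoveltyState(), NaN), "finite")
})

test_that("person neurons are recruited by events and conditioned by views", {
  pm <- newPersonModel(nInputs = 4)
  expect_error(personLearnFrame(matrix(runif(4)), pm, event = FALSE),
               "event must precede")
  pm <- personLearnFrame(matrix(runif(8), 4), pm, event = TRUE)
  expect_equal(nPersons(pm), 1L)
  pm <- personLearnFrame(matrix(runif(8), 4), pm, event = TRUE)
  expect_equal(nPersons(pm), 2L)
  expect_equal(pm@currentPerson, 2L)
  expect_equal(nrow(pm@map@weights), 2L)

  # conditioning moves the current person's prediction toward 1
  x <- runif(4)
  before <- drop(pm@map@weights %*% x)[2]
  pm <- personLearnFrame(matrix(x), pm, event = FALSE)
  after <- drop(pm@map@weights %*% x)[2]
  expect_gt(after, before)
})

test_that("a single-partner model recognizes its own frames perfectly", {
  s <- generateSession(tiny_specs(1), 30, seed = 17)
  sub <- subsampleSession(s, 10)
  m <- trainModel(sub, peracConfig(seed = 1))
  expect_equal(nPersons(m), 1L)
  r <- recognizePerson(sub, m)
  expect_equal(r$score, 100)
  expect_equal(r$score, 100 * r$hits / r$n)
  expect_true(all(r$predicted == 1L))
})

test_that("frozen-model recognition is bit-reproducible", {
  s <- generateSession(tiny_specs(2), 20, seed = 19)
  sub <- subsampleSession(s, 5)
  m <- trainModel(sub, peracConfig(seed = 2))
  r1 <- recognizePerson(sub, m, useStm = TRUE)
  r2 <- recognizePerson(sub, m, useStm = TRUE)
  expect_identical(r1, r2)
})

test_that("a random winner-take-all readout hits a class at rate 1/N", {
  set.seed(9)
  N <- 12L
  hits <- mean(replicate(4000, wta(runif(N)) == 5L))
  expect_lt(abs(hits - 1 / N), 0.02)
})

test_that("posture imitation beats three times chance on held-out frames", {
  s <- generateSession(avatarGrid()[1], 300, seed = 23)
  pools <- splitKnownUnknown(s, 10)
  m <- trainModel(pools$known, peracConfig(seed = 3))
  held <- subsampleSession(pools$unknown, 5)   # thin out for speed
  acc <- mean(predictPosture(held, m) == postures(held))
  expect_gt(acc, 0.6)
})

test_that("model checkpoints round-trip through JSON exactly", {
  s <- generateSession(tiny_specs(2), 20, seed = 29, imageSize = 64)
  sub <- subsampleSession(s, 5)
  m <- trainModel(sub, peracConfig(seed = 4, imageSize = 64))
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_equal(prototypes(m2@vf), prototypes(m@vf))
  expect_equal(m2@misp@weights, m@misp@weights)
  expect_equal(m2@person@map@weights, m@person@map@weights)
  expect_equal(m2@novelty@events, m@novelty@events)
  r1 <- recognizePerson(sub, m)
  r2 <- recognizePerson(sub, m2)
  expect_identical(r1$predicted, r2$predicted)
})
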