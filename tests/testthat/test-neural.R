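test_that("prototype activities follow the normalized-L1 similarity", {
  p <- runif(32)
  net <- vfLearn(p, newVFNetwork(32))$net
  expect_equal(vfActivities(p, net), 1)

  # uniform offset of 0.1 on every entry: activity exactly 0.9
  p2 <- rep(0.45, 32)
  net2 <- vfLearn(p2, newVFNetwork(32))$net
  expect_equal(vfActivities(p2 + 0.1, net2), 0.9)

  # monotone non-increasing in the L1 distance to the prototype
  set.seed(5)
  dirs <- matrix(runif(32 * 6), 32)
  for (k in 1:6) {
    d <- dirs[, k] / sum(dirs[, k])
    acts <- sapply(seq(0, 2, by = 0.25),
                   function(s) vfActivities(pmin(p2 + s * d, 1), net2))
    expect_true(all(diff(acts) <= 1e-12))
    expect_true(all(acts >= 0 & acts <= 1))
  }
})

test_that("incremental learning recruits one-shot and averages the winner", {
  v <- runif(16)
  r1 <- vfLearn(v, newVFNetwork(16), t = 1)
  expect_true(r1$recruited)
  expect_equal(prototypes(r1$net)[, 1], v)
  expect_equal(r1$activities, 1)
  expect_equal(recruitLog(r1$net), data.frame(time = 1L, neuron = 1L))

  # re-presenting the same view: no recruit, winner at 1, zero update
  r2 <- vfLearn(v, r1$net, t = 2)
  expect_false(r2$recruited)
  expect_equal(r2$winner, 1)
  expect_identical(prototypes(r2$net), prototypes(r1$net))

  # plug-in check of the averaging rule at VF = 0.9, epsilon = 0.1
  p <- rep(0.45, 16)
  net <- vfLearn(p, newVFNetwork(16, gamma = 0.85, epsilon = 0.1))$net
  v2 <- p + 0.1
  r3 <- vfLearn(v2, net)
  expect_false(r3$recruited)
  expect_equal(prototypes(r3$net)[, 1], p + 0.1 * (v2 - p) * (1 - 0.9))

  expect_error(vfLearn(c(1, NA), newVFNetwork(2)), "non-finite")
})

test_that("the Widrow-Hoff step and its fixed points behave", {
  m <- newAssociativeMap(1, 1, learningRate = 0.5)
  expect_equal(lmsStep(1, 1, m)@weights[1, 1], 0.5)

  # target equal to the prediction leaves the weights untouched
  m2 <- newAssociativeMap(2, 3, learningRate = 0.1)
  m2@weights <- matrix(runif(6), 2, 3)
  x <- runif(3)
  y <- drop(m2@weights %*% x)
  expect_equal(lmsStep(x, y, m2)@weights, m2@weights)

  expect_error(lmsStep(c(1, 2), 1, m), "input length")
})

test_that("repeated LMS epochs converge to the least-squares solution", {
  set.seed(6)
  X <- qr.Q(qr(matrix(rnorm(15), 5, 3)))   # well-conditioned design
  y <- drop(X %*% c(0.5, -0.3, 0.8))       # linearly solvable
  m <- newAssociativeMap(1, 3, learningRate = 0.05)
  for (epoch in 1:2000)
    for (i in 1:5) m <- lmsStep(X[i, ], y[i], m)
  wstar <- solve(crossprod(X), crossprod(X, y))   # normal equations
  expect_lt(max(abs(drop(m@weights) - drop(wstar))), 1e-3)
})

test_that("short-term memory filters as a leaky integrator", {
  b0 <- newSTMBuffer(3, decay = 0)
  x <- c(0.2, 0.9, 0.1)
  expect_equal(stmUpdate(b0, x)@state, x)

  b <- newSTMBuffer(1, decay = 0.6)
  for (i in 1:200) b <- stmUpdate(b, 0.8)
  expect_equal(b@state, 0.8, tolerance = 1e-10)

  b2 <- newSTMBuffer(1, decay = 0.5)
  b2 <- stmUpdate(b2, 1)
  expect_equal(b2@state, 0.5)
  b2 <- stmUpdate(b2, 0)
  expect_equal(b2@state, 0.25)
})

test_that("winner-take-all picks the first maximum", {
  expect_equal(wta(c(0.1, 0.9, 0.3)), 2)
  expect_equal(wta(c(0.4, 0.4)), 1)
  expect_error(wta(numeric(0)), "empty")
  set.seed(7)
  for (i in 1:50) {
    v <- runif(sample(2:9, 1))
    scan <- 1L
    for (j in seq_along(v)) if (v[j] > v[scan]) scan <- j
    expect_equal(wta(v), scan)
  }
})

test_that("motor states are exact one-hots", {
  expect_equal(motorState(2), c(0, 1, 0, 0, 0))
  expect_error(motorState(6), "out of range")
})

test_that("frame learning recruits at most one neuron per view and never forgets", {
  cfg <- peracConfig()
  img <- renderAvatar(avatarSpec(1), 1, jitterSeed = 3)
  net <- newVFNetwork(cfg$nRings * cfg$nAngles, cfg$gamma, cfg$epsilon)
  misp <- newAssociativeMap(5, 0, cfg$lmsRate)
  st <- learnFrame(img, 1, net, misp, cfg, t = 1)
  expect_lte(nNeurons(st$net), cfg$nPoints)
  expect_gt(nNeurons(st$net), 0)
  expect_equal(ncol(st$misp@weights), nNeurons(st$net))

  # the same frame again: every view recognized, no new recruits
  st2 <- learnFrame(img, 1, st$net, st$misp, cfg, t = 2)
  expect_equal(st2$log$recruits, 0)
  expect_equal(nNeurons(st2$net), nNeurons(st$net))

  # neuron count is non-decreasing over a frame stream
  counts <- nNeurons(st2$net)
  net <- st2$net; misp <- st2$misp
  for (t in 3:6) {
    st3 <- learnFrame(renderAvatar(avatarSpec(1), t %% 5 + 1, t),
                      t %% 5 + 1, net, misp, cfg, t = t)
    counts <- c(counts, nNeurons(st3$net))
    net <- st3$net; misp <- st3$misp
  }
  expect_true(all(diff(counts) >= 0))
})

test_that("higher vigilance never recruits fewer neurons", {
  s <- generateSession(tiny_specs(2), 30, seed = 21, imageSize = 64)
  sub <- subsampleSession(s, 5)
  counts <- sapply(c(0.80, 0.90, 0.95), function(g)
    nNeurons(trainModel(sub, peracConfig(seed = 1, gamma = g))))
  expect_true(all(diff(counts) >= 0))
})
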