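test_that("gradient norm matches hand-computed central differences", {
  expect_true(all(gradientNorm(matrix(1, 5, 5)) == 0))

  # vertical step of height h: central differences give h/2 on the two
  # columns astride the edge, 0 elsewhere
  h <- 0.8
  img <- cbind(matrix(0, 6, 3), matrix(h, 6, 3))
  g <- gradientNorm(img)
  expect_equal(g[, 3], rep(h / 2, 6))
  expect_equal(g[, 4], rep(h / 2, 6))
  expect_true(all(g[, c(1, 2, 5, 6)] == 0))

  expect_error(gradientNorm(matrix(0, 2, 5)), "3x3")
})

test_that("gradient norm is covariant with quarter-turn rotation", {
  set.seed(1)
  img <- matrix(runif(144), 12, 12)
  rot <- t(img)[, 12:1]   # 90 degree rotation
  g <- gradientNorm(img)
  grot <- gradientNorm(rot)
  expect_equal(t(g)[, 12:1][2:11, 2:11], grot[2:11, 2:11],
               tolerance = 1e-12)
})

test_that("DOG saliency is the expected linear band-pass filter", {
  expect_true(all(dogSaliency(matrix(0, 10, 10)) == 0))

  # impulse response reproduces the kernel built independently
  n <- 21L
  f <- matrix(0, n, n); f[11, 11] <- 1
  s <- dogSaliency(f, 1, 2)
  gk <- function(sig, r) { x <- dnorm(-r:r, sd = sig); x / sum(x) }
  r <- ceiling(3 * 2)
  kern <- outer(gk(1, r), gk(1, r)) - outer(gk(2, r), gk(2, r))
  expect_equal(s[(11 - r):(11 + r), (11 - r):(11 + r)], kern,
               tolerance = 1e-10)

  set.seed(2)
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  expect_equal(dogSaliency(a + b), dogSaliency(a) + dogSaliency(b),
               tolerance = 1e-10)

  expect_error(dogSaliency(f, -1, 2), "positive")
  expect_error(dogSaliency(f, 2, 2), "exceed")
})

test_that("focus-point competition matches the exhaustive oracle", {
  s <- matrix(0, 16, 16); s[4, 4] <- 2; s[12, 12] <- 1
  pts <- detectFocusPoints(s, nPoints = 5, suppressionRadius = 3)
  expect_equal(pts$row, c(4, 12))
  expect_equal(pts$col, c(4, 12))

  # equal peaks beyond the radius: both kept, tie broken row-major
  tie <- matrix(0, 16, 16); tie[9, 2] <- 1; tie[2, 9] <- 1
  pts <- detectFocusPoints(tie, nPoints = 2, suppressionRadius = 4)
  expect_equal(pts$row, c(2, 9))

  set.seed(3)
  for (i in 1:25) {
    sal <- matrix(runif(32 * 32), 32, 32)
    got <- detectFocusPoints(sal, nPoints = 5, suppressionRadius = 6)
    expect_equal(got, brute_focus(sal, 5, 6))
  }
})

test_that("no two focus points violate the suppression radius", {
  set.seed(4)
  for (i in 1:10) {
    sal <- matrix(runif(40 * 40), 40, 40)
    pts <- detectFocusPoints(sal, nPoints = 12, suppressionRadius = 5)
    if (nrow(pts) > 1) {
      d <- as.matrix(dist(pts[, c("row", "col")], method = "maximum"))
      expect_true(all(d[upper.tri(d)] > 5))
    }
  }
})

test_that("log-polar views have fixed length and flatten uniform images", {
  v <- logPolarView(matrix(0.4, 64, 64), 30, 35)
  expect_length(v, 256)
  expect_true(all(abs(v - 0.4) < 1e-12))
  expect_error(logPolarView(matrix(0, 16, 16), 20, 5), "outside")
  expect_error(logPolarView(matrix(0, 16, 16), 8, 8, rMax = 1), "at least 2")
})

test_that("rotating the scene circularly shifts the view's angle axis", {
  n <- 101L; ctr <- c(51, 51)
  nAngles <- 16L
  f0 <- function(r, th) 0.5 + 0.3 * sin(3 * th) * exp(-((r - 12) / 8)^2)
  dth <- 2 * pi / nAngles
  img1 <- polar_pattern(n, ctr, f0)
  img2 <- polar_pattern(n, ctr, function(r, th) f0(r, th - dth))
  v1 <- logPolarView(img1, ctr[1], ctr[2])
  v2 <- logPolarView(img2, ctr[1], ctr[2])
  expect_lt(mean(abs(v2 - shift_angles(v1, 16, 16, 1))), 0.01)
  # and clearly better than no shift at all
  expect_gt(mean(abs(v2 - v1)), 3 * mean(abs(v2 - shift_angles(v1, 16, 16, 1))))
})

test_that("rescaling the scene shifts the view's ring axis", {
  n <- 101L; ctr <- c(51, 51)
  nRings <- 16L; rMax <- 24
  rho <- rMax^(1 / (nRings - 1))   # exactly one ring bin
  f0 <- function(r, th) 0.5 + 0.4 * sin(r / 3)
  img1 <- polar_pattern(n, ctr, f0)
  img2 <- polar_pattern(n, ctr, function(r, th) f0(r * rho, th))
  v1 <- matrix(logPolarView(img1, ctr[1], ctr[2]), nRings, 16)
  v2 <- matrix(logPolarView(img2, ctr[1], ctr[2]), nRings, 16)
  # img2 at ring k samples what img1 sees at ring k+1
  expect_lt(mean(abs(v2[1:(nRings - 1), ] - v1[2:nRings, ])), 0.02)
})

test_that("frameViews wires the front-end together", {
  cfg <- peracConfig()
  fv <- frameViews(renderAvatar(avatarSpec(1), 1, 1), cfg)
  expect_equal(nrow(fv$views), cfg$nRings * cfg$nAngles)
  expect_equal(ncol(fv$views), nrow(fv$points))
  expect_lte(ncol(fv$views), cfg$nPoints)
  expect_true(all(fv$views >= 0 & fv$views <= 1))
})
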