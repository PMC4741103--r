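# --- convolution helpers -----------------------------------------------

# normalized 1-D Gaussian on an integer support of radius r
.gauss_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- -radius:radius
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# mirror-pad a matrix by r pixels on every side (symmetric reflection,
# edge row/column included)
.pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(pmin(r:1, nr), 1:nr, pmax(nr - (1:r) + 1L, 1L))
  ci <- c(pmin(r:1, nc), 1:nc, pmax(nc - (1:r) + 1L, 1L))
  m[ri, ci]
}

# 2-D convolution with reflected borders, via EBImage's FFT filter on the
# padded image (the pad absorbs the circular wrap-around)
.conv2_reflect <- function(m, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  p <- .pad_reflect(m, r)
  f <- EBImage::filter2(p, kernel)
  f[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m)), drop = FALSE]
}

.gauss_blur <- function(m, sigma) {
  g <- .gauss_kernel(sigma)
  .conv2_reflect(m, outer(g, g))
}

# --- reflex visual front-end -------------------------------------------

#' Gradient-norm map of an image
#'
#' Per-pixel Euclidean norm of the central-difference image gradient, with
#' reflected borders. The map is non-negative, zero on constant images, and
#' reaches `h/2` along a step edge of height `h`.
#'
#' @param image 2-D numeric matrix, at least 3x3.
#' @return Non-negative matrix of the same shape.
#' @examples
#' gradientNorm(matrix(1, 4, 4))
#' @export
gradientNorm <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be a matrix of at least 3x3")
  nr <- nrow(image); nc <- ncol(image)
  pc <- image[, c(1L, 1:nc, nc)]
  gx <- (pc[, 3:(nc + 2L)] - pc[, 1:nc]) / 2
  pr <- image[c(1L, 1:nr, nr), ]
  gy <- (pr[3:(nr + 2L), ] - pr[1:nr, ]) / 2
  sqrt(gx^2 + gy^2)
}

#' Difference-of-Gaussians saliency
#'
#' Convolves a scalar field (typically the gradient norm) with a
#' difference-of-Gaussians band-pass kernel `G_sigma1 - G_sigma2`, the
#' reflex saliency whose local maxima sit on corners and line ends.
#'
#' @param field 2-D numeric matrix.
#' @param sigma1 centre (narrow) Gaussian scale in pixels, > 0.
#' @param sigma2 surround (wide) Gaussian scale in pixels, > `sigma1`.
#' @return Matrix of the same shape.
#' @examples
#' f <- matrix(0, 17, 17); f[9, 9] <- 1
#' s <- dogSaliency(f)
#' which(s == max(s))
#' @export
dogSaliency <- function(field, sigma1 = 1.0, sigma2 = 2.0) {
  if (!is.matrix(field)) stop("field must be a matrix")
  if (sigma1 <= 0 || sigma2 <= 0) stop("sigmas must be positive")
  if (sigma2 <= sigma1) stop("sigma2 must exceed sigma1")
  radius <- ceiling(3 * sigma2)
  g1 <- .gauss_kernel(sigma1, radius)
  g2 <- .gauss_kernel(sigma2, radius)
  kern <- outer(g1, g1) - outer(g2, g2)
  .conv2_reflect(field, kern)
}

#' Focus-point detection by local competition
#'
#' Greedy selection of up to `nPoints` saliency maxima with non-max
#' suppression: pixels are visited in decreasing saliency (ties broken by
#' lexicographic `(row, col)` order); a selected point suppresses its
#' Chebyshev neighbourhood of radius `suppressionRadius`. Only strictly
#' positive saliency is eligible, so a map with fewer maxima yields a
#' shorter list. Returned points are ordered by decreasing saliency and at
#' least `suppressionRadius + 1` apart in Chebyshev distance.
#'
#' @param saliency 2-D numeric matrix.
#' @param nPoints maximum number of focus points (>= 1).
#' @param suppressionRadius Chebyshev suppression radius in pixels.
#' @return data.frame with columns `row`, `col`, `saliency`.
#' @examples
#' s <- matrix(0, 16, 16); s[4, 4] <- 2; s[12, 12] <- 1
#' detectFocusPoints(s, nPoints = 2, suppressionRadius = 3)
#' @export
detectFocusPoints <- function(saliency, nPoints = 20L,
                              suppressionRadius = 6L) {
  if (!is.matrix(saliency)) stop("saliency must be a matrix")
  nPoints <- as.integer(nPoints)
  if (nPoints < 1L) stop("nPoints must be at least 1")
  nr <- nrow(saliency); nc <- ncol(saliency)
  rows <- rep.int(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  vals <- as.vector(saliency)
  ord <- order(-vals, rows, cols)
  suppressed <- matrix(FALSE, nr, nc)
  outR <- integer(0); outC <- integer(0); outS <- numeric(0)
  for (i in ord) {
    if (vals[i] <= 0) break   # background is not a focus-point candidate
    r <- rows[i]; c <- cols[i]
    if (suppressed[r, c]) next
    outR <- c(outR, r); outC <- c(outC, c); outS <- c(outS, vals[i])
    if (length(outR) >= nPoints) break
    rr <- max(1L, r - suppressionRadius):min(nr, r + suppressionRadius)
    cc <- max(1L, c - suppressionRadius):min(nc, c + suppressionRadius)
    suppressed[rr, cc] <- TRUE
  }
  data.frame(row = outR, col = outC, saliency = outS)
}

# bilinear interpolation at fractional (row, col) coordinates, clamped to
# the image so out-of-frame samples take the border value
.bilinear <- function(image, r, c) {
  nr <- nrow(image); nc <- ncol(image)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- image[cbind(r0, c0)];     i10 <- image[cbind(r0 + 1L, c0)]
  i01 <- image[cbind(r0, c0 + 1L)]; i11 <- image[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
}

#' Log-polar local view around a focus point
#'
#' Samples the image on a log-polar grid centred on a focus point: radii
#' grow geometrically from 1 to `rMax` over `nRings` rings, angles are
#' uniform over `nAngles` bins, and samples use bilinear interpolation with
#' border clamping. A rotation of the scene about the centre circularly
#' shifts the angle axis; a rescaling shifts the ring axis — the robustness
#' to rotation and distance the local views rely on.
#'
#' @param image 2-D numeric matrix with intensities in \[0,1\].
#' @param row,col focus-point centre (1-based pixel coordinates, inside the
#'   image).
#' @param rMax outer sampling radius in pixels (>= 2).
#' @param nRings,nAngles grid size.
#' @return Numeric vector of length `nRings * nAngles` in \[0,1\], ring
#'   index varying fastest.
#' @examples
#' v <- logPolarView(matrix(0.5, 64, 64), 32, 32)
#' length(v)
#' @export
logPolarView <- function(image, row, col, rMax = 24, nRings = 16L,
                         nAngles = 16L) {
  if (rMax < 2) stop("rMax must be at least 2")
  if (row < 1 || row > nrow(image) || col < 1 || col > ncol(image))
    stop("focus point centre lies outside the image")
  radii <- rMax^((seq_len(nRings) - 1L) / (nRings - 1L))
  theta <- 2 * pi * (seq_len(nAngles) - 1L) / nAngles
  rr <- row + outer(radii, sin(theta))
  cc <- col + outer(radii, cos(theta))
  v <- .bilinear(image, as.vector(rr), as.vector(cc))
  v[v < 0] <- 0
  v[v > 1] <- 1
  v
}

#' Extract all local views of a frame
#'
#' Runs the full reflex front-end on one frame: gradient norm, DOG
#' saliency, focus-point competition, and one log-polar view per focus
#' point.
#'
#' @param image 2-D numeric matrix in \[0,1\].
#' @param config configuration list from [peracConfig()].
#' @return List with `views` (matrix, one column per focus point, rows the
#'   log-polar samples) and `points` (the focus-point data.frame).
#' @examples
#' fv <- frameViews(renderAvatar(avatarSpec(1), 1, 1), peracConfig())
#' dim(fv$views)
#' @export
frameViews <- function(image, config = peracConfig()) {
  sal <- dogSaliency(gradientNorm(image), config$dogSigma1, config$dogSigma2)
  pts <- detectFocusPoints(sal, config$nPoints, config$suppressionRadius)
  D <- config$nRings * config$nAngles
  views <- matrix(0, D, nrow(pts))
  for (k in seq_len(nrow(pts)))
    views[, k] <- logPolarView(image, pts$row[k], pts$col[k],
                               rMax = config$rMax, nRings = config$nRings,
                               nAngles = config$nAngles)
  list(views = views, points = pts)
}
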