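# shared small fixtures and independent oracles

# small-geometry avatars that fit a 64x64 frame (for fast unit tests)
tiny_specs <- function(n = 3L) {
  g <- expand.grid(armLength = c(14, 17, 20), torsoWidth = c(10, 14),
                   headRadius = c(5, 7))
  lapply(seq_len(n), function(i)
    avatarSpec(i, armLength = g$armLength[i], armWidth = 4,
               headRadius = g$headRadius[i], torsoWidth = g$torsoWidth[i],
               torsoHeight = 16))
}

# independent greedy non-max-suppression oracle: repeated full-matrix scan
# with explicit lexicographic tie-breaking and Chebyshev suppression
brute_focus <- function(sal, nPoints, radius) {
  nr <- nrow(sal); nc <- ncol(sal)
  alive <- matrix(TRUE, nr, nc)
  out <- data.frame(row = integer(), col = integer(), saliency = numeric())
  repeat {
    if (!any(alive) || nrow(out) >= nPoints) break
    m <- max(sal[alive])
    if (m <= 0) break
    hit <- which(sal == m & alive, arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    r <- hit[1L, 1L]; c <- hit[1L, 2L]
    out <- rbind(out, data.frame(row = r, col = c, saliency = m))
    rr <- max(1L, r - radius):min(nr, r + radius)
    cc <- max(1L, c - radius):min(nc, c + radius)
    alive[rr, cc] <- FALSE
  }
  rownames(out) <- NULL
  out
}

# analytic polar pattern sampled on a pixel grid about a given centre;
# smooth in both radius and angle so interpolation error stays small
polar_pattern <- function(n, centre, fun) {
  img <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dr <- i - centre[1L]; dc <- j - centre[2L]
      img[i, j] <- fun(sqrt(dr^2 + dc^2), atan2(dr, dc))
    }
  }
  img
}

# circular shift along the angle axis of a flattened log-polar view
shift_angles <- function(v, nRings, nAngles, by) {
  m <- matrix(v, nRings, nAngles)
  as.vector(m[, ((seq_len(nAngles) - 1L - by) %% nAngles) + 1L])
}
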