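#' Create an avatar specification
#'
#' @param avatarId integer identity of the partner.
#' @param armLength,armWidth,headRadius,torsoWidth,torsoHeight body geometry
#'   in pixels.
#' @param grayLevel body intensity in \[0,1\].
#' @param textureSeed seed of the static body texture (defaults to a value
#'   derived from `avatarId` so each avatar carries a distinct texture).
#' @return An [AvatarSpec-class] object.
#' @examples
#' avatarSpec(1, armLength = 36)
#' @export
avatarSpec <- function(avatarId, armLength = 36, armWidth = 6,
                       headRadius = 10, torsoWidth = 22, torsoHeight = 36,
                       grayLevel = 0.65, textureSeed = 1000L + avatarId) {
  new("AvatarSpec", avatarId = as.integer(avatarId),
      armLength = armLength, armWidth = armWidth, headRadius = headRadius,
      torsoWidth = torsoWidth, torsoHeight = torsoHeight,
      grayLevel = grayLevel, textureSeed = as.integer(textureSeed))
}

#' The default 12-avatar morphology grid
#'
#' Crosses arm length \{28, 36, 44\}, torso width \{18, 26\} and head radius
#' \{8, 12\} into 12 visually similar white humanoids that differ only in
#' these parametric traits — the package's stand-in for a panel of highly
#' similar partners whose arm, head and body sizes were systematically
#' manipulated.
#'
#' @return List of 12 [AvatarSpec-class] objects.
#' @examples
#' length(avatarGrid())
#' @export
avatarGrid <- function() {
  g <- expand.grid(armLength = c(28, 36, 44), torsoWidth = c(18, 26),
                   headRadius = c(8, 12))
  lapply(seq_len(nrow(g)), function(i)
    avatarSpec(i, armLength = g$armLength[i], torsoWidth = g$torsoWidth[i],
               headRadius = g$headRadius[i]))
}

# posture repertoire: arm angles in degrees from the downward vertical,
# c(left, right). 1 both down, 2 both horizontal, 3 both up, 4 left up /
# right down, 5 left down / right up.
.posture_angles <- list(c(15, 15), c(90, 90), c(160, 160),
                        c(160, 15), c(15, 160))

# anchor points of the figure for a given spec and frame size
.avatar_layout <- function(spec, S) {
  cx <- floor(S / 2)
  torsoTop <- round(0.36 * S)
  list(
    cx = cx, torsoTop = torsoTop,
    torsoBottom = torsoTop + spec@torsoHeight,
    shoulderRow = torsoTop + 3,
    headRow = torsoTop - 2 - spec@headRadius,
    legLen = round(0.18 * S), legWidth = 6
  )
}

# squared distance from every pixel to the segment p1-p2 (row, col coords)
.capsule_mask <- function(R, C, p1, p2, halfwidth) {
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 < 1e-12) {
    d2 <- (R - p1[1])^2 + (C - p1[2])^2
  } else {
    t <- ((R - p1[1]) * d[1] + (C - p1[2]) * d[2]) / len2
    t[t < 0] <- 0
    t[t > 1] <- 1
    d2 <- (R - p1[1] - t * d[1])^2 + (C - p1[2] - t * d[2])^2
  }
  d2 <= halfwidth^2
}

# arm endpoints for one posture (no jitter); angles in degrees from the
# downward vertical, measured outward on each side
.arm_segments <- function(spec, layout, posture, angleNoise = c(0, 0)) {
  ang <- .posture_angles[[posture]] + angleNoise
  rad <- ang * pi / 180
  halfT <- spec@torsoWidth / 2
  out <- list()
  for (side in c(-1, 1)) {
    a <- if (side < 0) rad[1] else rad[2]
    p1 <- c(layout$shoulderRow, layout$cx + side * halfT)
    p2 <- c(p1[1] + spec@armLength * cos(a),
            p1[2] + side * spec@armLength * sin(a))
    out[[length(out) + 1L]] <- list(p1 = p1, p2 = p2)
  }
  out
}

# verify the figure stays inside the frame with room for jitter and angle
# noise; names the offending geometric field on failure
.check_fit <- function(spec, posture, S) {
  layout <- .avatar_layout(spec, S)
  margin <- 2 + spec@armWidth / 2  # translation jitter + capsule halfwidth
  for (noise in list(c(-3, -3), c(0, 0), c(3, 3))) {
    for (seg in .arm_segments(spec, layout, posture, noise)) {
      p <- seg$p2
      if (p[1] < 1 + margin || p[1] > S - margin ||
          p[2] < 1 + margin || p[2] > S - margin)
        stop(sprintf(
          "avatar %d does not fit a %dx%d frame at posture %d: arm_length",
          spec@avatarId, S, S, posture))
    }
  }
  if (layout$headRow - spec@headRadius < 3)
    stop(sprintf("avatar %d does not fit: head_radius", spec@avatarId))
  if (layout$cx + spec@torsoWidth / 2 > S - 3 ||
      layout$cx - spec@torsoWidth / 2 < 3)
    stop(sprintf("avatar %d does not fit: torso_width", spec@avatarId))
  if (layout$torsoBottom + layout$legLen > S - 3)
    stop(sprintf("avatar %d does not fit: torso_height", spec@avatarId))
  invisible(TRUE)
}

# static body texture, memoised per (seed, size); low-pass filtered noise
# attached to the body so morphologically near-identical avatars still carry
# an individual surface signature
.texture_cache <- new.env(parent = emptyenv())
.avatar_texture <- function(textureSeed, S, amplitude = 0.17) {
  key <- sprintf("%d_%d", textureSeed, S)
  if (!is.null(.texture_cache[[key]])) return(.texture_cache[[key]])
  tex <- withr::with_seed(textureSeed, {
    raw <- matrix(stats::rnorm(S * S), S, S)
    sm <- .gauss_blur(raw, sigma = 2.5)
    amplitude * sm / stats::sd(sm)
  })
  .texture_cache[[key]] <- tex
  tex
}

#' Render one avatar frame
#'
#' Draws the avatar as filled primitives (disc head, rectangular torso,
#' capsule arms and legs) on a uniform dark background, adds the avatar's
#' static body texture, applies a small seeded translation jitter and
#' limb-angle noise, and finishes with additive Gaussian pixel noise. The
#' result is deterministic for a fixed `(spec, posture, jitterSeed)`.
#'
#' @param spec an [AvatarSpec-class].
#' @param posture posture index in 1..5.
#' @param jitterSeed integer seed of the per-frame jitter and noise.
#' @param imageSize side length of the square frame (>= 64).
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param scale apparent size factor in (0, 1\] emulating the partner's
#'   distance from the camera; the figure (texture included) shrinks about
#'   its torso centre.
#' @return Numeric `imageSize x imageSize` matrix with intensities in \[0,1\].
#' @examples
#' img <- renderAvatar(avatarSpec(1), posture = 2, jitterSeed = 5)
#' range(img)
#' @export
renderAvatar <- function(spec, posture, jitterSeed, imageSize = 128L,
                         noiseSd = 0.02, scale = 1) {
  validObject(spec)
  S <- as.integer(imageSize)
  if (S < 64L) stop("imageSize must be at least 64")
  posture <- as.integer(posture)
  if (posture < 1L || posture > 5L) stop("posture must be in 1..5")
  if (scale <= 0 || scale > 1)
    stop("scale must lie in (0, 1]")
  .check_fit(spec, posture, S)

  withr::with_seed(as.integer(jitterSeed), {
    dx <- sample(-2:2, 1L)
    dy <- sample(-2:2, 1L)
    angleNoise <- stats::runif(2L, -3, 3)
    noise <- matrix(stats::rnorm(S * S, sd = noiseSd), S, S)
  })

  layout <- .avatar_layout(spec, S)
  # evaluate the figure in its own (unscaled) coordinates: sampling at
  # centre + (pixel - centre)/scale draws the figure shrunk by `scale`
  cr <- layout$torsoTop + spec@torsoHeight / 2
  cc <- layout$cx
  R <- cr + (row(diag(0, S)) - cr) / scale
  C <- cc + (col(diag(0, S)) - cc) / scale

  mask <- R >= layout$torsoTop & R <= layout$torsoBottom &
    abs(C - layout$cx) <= spec@torsoWidth / 2
  mask <- mask |
    ((R - layout$headRow)^2 + (C - layout$cx)^2 <= spec@headRadius^2)
  for (seg in .arm_segments(spec, layout, posture, angleNoise))
    mask <- mask | .capsule_mask(R, C, seg$p1, seg$p2, spec@armWidth / 2)
  for (side in c(-1, 1)) {
    hip <- c(layout$torsoBottom, layout$cx + side * spec@torsoWidth / 4)
    foot <- c(layout$torsoBottom + layout$legLen, hip[2])
    mask <- mask | .capsule_mask(R, C, hip, foot, layout$legWidth / 2)
  }

  tex <- .avatar_texture(spec@textureSeed, S)
  ti <- pmin(pmax(round(R), 1L), S)
  tj <- pmin(pmax(round(C), 1L), S)
  img <- matrix(0.1, S, S)
  img[mask] <- spec@grayLevel + tex[cbind(ti[mask], tj[mask])]

  # integer translation jitter: the whole figure (texture included) moves
  shifted <- matrix(0.1, S, S)
  srcR <- max(1L, 1L - dy):min(S, S - dy)
  srcC <- max(1L, 1L - dx):min(S, S - dx)
  shifted[srcR + dy, srcC + dx] <- img[srcR, srcC]

  out <- shifted + noise
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# internal Session constructor: derives the schedule from the partner runs
.new_session <- function(frames, posture, partner, frameIndex, seed = NA) {
  if (length(partner)) {
    r <- rle(partner)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    schedule <- data.frame(partner_id = r$values,
                           start_frame = frameIndex[starts],
                           end_frame = frameIndex[ends])
  } else {
    schedule <- data.frame(partner_id = integer(), start_frame = integer(),
                           end_frame = integer())
  }
  new("Session", frames = frames, posture = as.integer(posture),
      partner = as.integer(partner), frameIndex = as.integer(frameIndex),
      schedule = schedule, seed = as.integer(seed))
}

#' Generate a synthetic imitation session
#'
#' Renders one contiguous block of frames per avatar, in the given order.
#' Within a block the commanded posture is held for a short seeded run (5 to
#' 15 frames) before switching; runs cycle through seeded shufflings of the
#' full repertoire so every posture recurs throughout the block — the
#' structure of a partner continuously imitating the agent's randomly chosen
#' postures.
#'
#' @param specs non-empty list of [AvatarSpec-class] objects.
#' @param framesPerPartner frames per avatar block (>= 10).
#' @param seed master seed of the posture schedule and all per-frame jitter.
#' @param imageSize frame side length in pixels.
#' @param noiseSd additive pixel noise standard deviation.
#' @return A [Session-class] with `length(specs) * framesPerPartner` frames.
#' @examples
#' s <- generateSession(avatarGrid()[1:2], framesPerPartner = 12, seed = 1,
#'                      imageSize = 64)
#' nFrames(s)
#' @export
generateSession <- function(specs, framesPerPartner = 200L, seed = 1L,
                            imageSize = 128L, noiseSd = 0.02) {
  if (length(specs) == 0L) stop("at least one avatar spec is required")
  if (framesPerPartner < 10L) stop("framesPerPartner must be at least 10")
  nF <- as.integer(framesPerPartner)
  nTotal <- length(specs) * nF

  plan <- withr::with_seed(as.integer(seed), {
    jitterSeeds <- sample.int(2147483646L, nTotal)
    posture <- integer(0)
    scale <- numeric(0)
    for (p in seq_along(specs)) {
      seqp <- integer(0)
      while (length(seqp) < nF) {
        for (po in sample(5L)) {
          k <- sample(5:15, 1L)
          seqp <- c(seqp, rep(po, k))
          if (length(seqp) >= nF) break
        }
      }
      posture <- c(posture, seqp[seq_len(nF)])
      # apparent-distance variation: a slow reflected random walk (the
      # partner sways toward and away from the camera) plus independent
      # per-frame scale noise (posture-to-posture distance adjustments)
      path <- cumsum(c(stats::runif(1L, 0.9, 1.0),
                       stats::rnorm(nF - 1L, 0, 0.015)))
      lo <- 0.85; hi <- 1.0
      walk <- lo + abs(((path - lo) %% (2 * (hi - lo))) - (hi - lo))
      scale <- c(scale, pmin(pmax(walk + stats::rnorm(nF, 0, 0.02),
                                  lo), hi))
    }
    list(jitterSeeds = jitterSeeds, posture = posture, scale = scale)
  })

  partner <- rep(vapply(specs, function(s) s@avatarId, integer(1L)),
                 each = nF)
  frames <- vector("list", nTotal)
  for (i in seq_len(nTotal)) {
    sp <- specs[[(i - 1L) %/% nF + 1L]]
    frames[[i]] <- renderAvatar(sp, plan$posture[i], plan$jitterSeeds[i],
                                imageSize = imageSize, noiseSd = noiseSd,
                                scale = plan$scale[i])
  }
  .new_session(frames, plan$posture, partner, seq_len(nTotal), seed)
}

#' Temporally subsample a session
#'
#' Keeps every `stride`-th frame (the first frame always survives),
#' preserving all labels and the original frame indices; the partner
#' schedule is recomputed on the surviving frames. Composes: subsampling by
#' `a` then `b` equals subsampling by `a * b`.
#'
#' @param session a [Session-class].
#' @param stride keep one frame in `stride` (>= 1).
#' @return The subsampled [Session-class].
#' @examples
#' s <- generateSession(avatarGrid()[1], framesPerPartner = 30, seed = 1,
#'                      imageSize = 64)
#' nFrames(subsampleSession(s, 10))
#' @export
subsampleSession <- function(session, stride = 10L) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be at least 1")
  if (stride == 1L) return(session)
  keep <- seq(1L, nFrames(session), by = stride)
  .new_session(session@frames[keep], session@posture[keep],
               session@partner[keep], session@frameIndex[keep],
               session@seed)
}

# frames of the session NOT kept by subsampleSession(session, stride)
.session_complement <- function(session, stride) {
  stride <- as.integer(stride)
  n <- nFrames(session)
  keep <- seq(1L, n, by = stride)
  drop <- setdiff(seq_len(n), keep)
  .new_session(session@frames[drop], session@posture[drop],
               session@partner[drop], session@frameIndex[drop],
               session@seed)
}

# subset a session by positions, preserving the given order (used by the
# test batteries, where a battery may repeat or shuffle frames; the result
# is a plain list-of-frames bundle, not a Session, because battery order
# need not be increasing in frame index)
.session_take <- function(session, positions) {
  list(frames = session@frames[positions],
       posture = session@posture[positions],
       partner = session@partner[positions],
       frameIndex = session@frameIndex[positions])
}
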