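#' Default configuration of the learning architecture
#'
#' Collects every tunable parameter of the pipeline in one flat list. The
#' defaults define the package's reference benchmark: 12 visually similar
#' humanoid avatars, 200 frames each, 1/10 subsampling into the learning
#' phase, and the four-condition recognition battery with 100 images per
#' partner and condition.
#'
#' @param seed master seed; every stochastic step derives its own seed from
#'   it deterministically.
#' @param imageSize frame side length in pixels (square frames).
#' @param framesPerPartner frames rendered per avatar in a session.
#' @param stride temporal subsampling stride of the learning phase (1 frame
#'   in `stride` is learned; the rest form the "unknown" pool).
#' @param noiseSd per-pixel Gaussian noise standard deviation.
#' @param nPoints focus points (local views) extracted per frame.
#' @param suppressionRadius Chebyshev non-max suppression radius in pixels.
#' @param dogSigma1,dogSigma2 difference-of-Gaussians scales (pixels),
#'   `dogSigma2 > dogSigma1`.
#' @param rMax outer radius of the log-polar view in pixels.
#' @param nRings,nAngles log-polar grid size; a view has
#'   `nRings * nAngles` entries.
#' @param gamma vigilance (recognition threshold) of the prototype network.
#' @param epsilon prototype long-term averaging rate.
#' @param lmsRate Widrow-Hoff learning rate of the associative maps.
#' @param stmDecay short-term-memory retention coefficient.
#' @param noveltyThreshold rising-edge threshold of the novelty detector.
#' @param noveltyWindow sliding-window length of the mean error E(t).
#' @param noveltyRefractory frames after an event during which no further
#'   event may fire.
#' @param noveltySmoothing leak coefficient of the gradient integrator V.
#' @param noveltyVfThreshold threshold of the visual-feature novelty
#'   channel: an event fires when the mean supra-vigilance excess of the
#'   frame's views — measured against the prototypes active in the recent
#'   context, not the whole long-term bank — exceeds its trailing-window
#'   mean by more than this (default 0.012 = 15% of the vigilance
#'   bandwidth `1 - gamma`).
#' @param noveltyContextWindow frames of winner history forming the
#'   "recent context" prototype set of the visual-feature channel; covers
#'   a few full passes through the posture repertoire so posture
#'   recurrence is never mistaken for partner novelty.
#' @param noveltyChannel which novelty stream drives partner detection:
#'   the posture-prediction error (`"error"`), the visual-feature context
#'   novelty (`"vf"`), or the two detectors OR-ed under a shared
#'   refractory period (`"both"`, default).
#' @param nImages test images per partner and condition.
#' @param nPostures size of the posture repertoire.
#' @return Named list of parameters.
#' @examples
#' cfg <- peracConfig(seed = 7)
#' cfg$gamma
#' @export
peracConfig <- function(seed = 1L,
                        imageSize = 128L,
                        framesPerPartner = 200L,
                        stride = 10L,
                        noiseSd = 0.02,
                        nPoints = 20L,
                        suppressionRadius = 6L,
                        dogSigma1 = 1.0,
                        dogSigma2 = 2.0,
                        rMax = 24,
                        nRings = 16L,
                        nAngles = 16L,
                        gamma = 0.92,
                        epsilon = 0.1,
                        lmsRate = 0.05,
                        stmDecay = 0.7,
                        noveltyThreshold = 0.05,
                        noveltyWindow = 10L,
                        noveltyRefractory = 15L,
                        noveltySmoothing = 0.9,
                        noveltyVfThreshold = 0.012,
                        noveltyContextWindow = 20L,
                        noveltyChannel = c("both", "error", "vf"),
                        nImages = 100L,
                        nPostures = 5L) {
  cfg <- list(
    seed = as.integer(seed), imageSize = as.integer(imageSize),
    framesPerPartner = as.integer(framesPerPartner),
    stride = as.integer(stride), noiseSd = noiseSd,
    nPoints = as.integer(nPoints),
    suppressionRadius = as.integer(suppressionRadius),
    dogSigma1 = dogSigma1, dogSigma2 = dogSigma2,
    rMax = rMax, nRings = as.integer(nRings), nAngles = as.integer(nAngles),
    gamma = gamma, epsilon = epsilon, lmsRate = lmsRate,
    stmDecay = stmDecay,
    noveltyThreshold = noveltyThreshold,
    noveltyWindow = as.integer(noveltyWindow),
    noveltyRefractory = as.integer(noveltyRefractory),
    noveltySmoothing = noveltySmoothing,
    noveltyVfThreshold = noveltyVfThreshold,
    noveltyContextWindow = as.integer(noveltyContextWindow),
    noveltyChannel = match.arg(noveltyChannel),
    nImages = as.integer(nImages), nPostures = as.integer(nPostures)
  )
  stopifnot(cfg$imageSize >= 64L, cfg$stride >= 1L,
            cfg$dogSigma2 > cfg$dogSigma1, cfg$dogSigma1 > 0,
            cfg$gamma > 0, cfg$gamma <= 1,
            cfg$epsilon >= 0, cfg$epsilon < 1)
  cfg
}

#' Read a configuration from a YAML file
#'
#' Reads a flat-key YAML file and merges it over the [peracConfig()]
#' defaults; unknown keys are an error.
#'
#' @param path YAML file with a subset of the [peracConfig()] argument names.
#' @return Resolved configuration list.
#' @export
readConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  user <- yaml::read_yaml(path)
  known <- names(formals(peracConfig))
  bad <- setdiff(names(user), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(peracConfig, user)
}

# Deterministic child seed derived from a master seed and a purpose tag.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483629)
}
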