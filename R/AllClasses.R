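#' @import methods
NULL

#' Parametric humanoid avatar specification
#'
#' Describes one synthetic partner by its body morphology: arm length and
#' width, head radius, torso width and height (all in pixels), a body gray
#' level in \[0,1\], and a seed for the fixed per-avatar body texture. Avatars
#' sharing all geometric fields render identically; changing any one of them
#' changes the render.
#'
#' @slot avatarId integer partner identity (1-based).
#' @slot armLength,armWidth,headRadius,torsoWidth,torsoHeight positive
#'   geometry in pixels.
#' @slot grayLevel body intensity in \[0,1\] on a darker uniform background.
#' @slot textureSeed integer seed of the static body texture.
#' @export
setClass("AvatarSpec",
  representation(
    avatarId    = "integer",
    armLength   = "numeric",
    armWidth    = "numeric",
    headRadius  = "numeric",
    torsoWidth  = "numeric",
    torsoHeight = "numeric",
    grayLevel   = "numeric",
    textureSeed = "integer"
  )
)

setValidity("AvatarSpec", function(object) {
  geo <- c(arm_length = object@armLength, arm_width = object@armWidth,
           head_radius = object@headRadius, torso_width = object@torsoWidth,
           torso_height = object@torsoHeight)
  if (any(!is.finite(geo)) || any(geo <= 0))
    return(sprintf("geometric fields must be positive (%s)",
                   paste(names(geo)[!(is.finite(geo) & geo > 0)],
                         collapse = ", ")))
  if (length(object@avatarId) != 1L || object@avatarId < 1L)
    return("avatarId must be a single positive integer")
  if (object@grayLevel < 0 || object@grayLevel > 1)
    return("grayLevel must lie in [0,1]")
  TRUE
})

#' Labelled imitation session
#'
#' An ordered stream of grayscale frames, each labelled with the commanded
#' posture (1..5) and the identity of the imitating partner, together with
#' the contiguous partner schedule. Frames keep their original `frameIndex`
#' through subsampling, so the learning subsample and its held-out complement
#' can always be traced back to the source stream.
#'
#' @slot frames list of numeric matrices with intensities in \[0,1\].
#' @slot posture integer vector of commanded postures, one per frame.
#' @slot partner integer vector of partner identities, one per frame.
#' @slot frameIndex strictly increasing integer vector of original indices.
#' @slot schedule data.frame with columns `partner_id`, `start_frame`,
#'   `end_frame` (frame-index units), one row per contiguous partner block.
#' @slot seed integer seed the session was generated from (NA for read-in
#'   data).
#' @export
setClass("Session",
  representation(
    frames     = "list",
    posture    = "integer",
    partner    = "integer",
    frameIndex = "integer",
    schedule   = "data.frame",
    seed       = "integer"
  )
)

setValidity("Session", function(object) {
  n <- length(object@frames)
  if (length(object@posture) != n || length(object@partner) != n ||
      length(object@frameIndex) != n)
    return("frames, posture, partner and frameIndex must have equal length")
  if (n == 0L) return(TRUE)
  if (any(diff(object@frameIndex) <= 0L))
    return("frameIndex must be strictly increasing")
  if (any(object@posture < 1L))
    return("postures must be positive integers")
  sch <- object@schedule
  need <- c("partner_id", "start_frame", "end_frame")
  if (!all(need %in% names(sch)))
    return("schedule must have partner_id, start_frame, end_frame")
  if (nrow(sch) > 1L &&
      any(sch$start_frame[-1L] <= sch$end_frame[-nrow(sch)]))
    return("schedule blocks must be non-overlapping and ordered")
  blk <- findInterval(object@frameIndex, sch$start_frame)
  if (any(blk < 1L) || any(object@frameIndex > sch$end_frame[blk]) ||
      any(object@partner != sch$partner_id[blk]))
    return("frame partner labels inconsistent with schedule")
  TRUE
})

#' Incremental visual-feature prototype network
#'
#' A growing bank of prototype weight vectors, one per recruited neuron,
#' each the length of a log-polar local view. A view whose best match falls
#' below the vigilance `gamma` recruits a new neuron (one-shot copy of the
#' view); otherwise the winning prototype is averaged toward the view at
#' rate `epsilon`, weighted by the residual mismatch.
#'
#' @slot prototypes numeric matrix, one column per recruited neuron.
#' @slot gamma vigilance (recognition threshold) in (0,1].
#' @slot epsilon long-term averaging rate in \[0,1).
#' @slot recruitLog data.frame (`time`, `neuron`) of recruitment events.
#' @export
setClass("VFNetwork",
  representation(
    prototypes = "matrix",
    gamma      = "numeric",
    epsilon    = "numeric",
    recruitLog = "data.frame"
  )
)

setValidity("VFNetwork", function(object) {
  if (object@gamma <= 0 || object@gamma > 1)
    return("gamma must lie in (0,1]")
  if (object@epsilon < 0 || object@epsilon >= 1)
    return("epsilon must lie in [0,1)")
  if (!all(is.finite(object@prototypes)))
    return("prototype weights must be finite")
  if (nrow(object@recruitLog) != ncol(object@prototypes))
    return("recruitLog must have one row per recruited neuron")
  TRUE
})

#' Least-mean-squares associative map
#'
#' A linear map from visual-feature activities to a one-hot target (the
#' motor internal state during posture learning, or the partner identity for
#' person recognition), trained by the Widrow-Hoff rule. Columns are added
#' (initialised to zero) as the prototype network recruits.
#'
#' @slot weights numeric matrix, outputs x feature neurons.
#' @slot learningRate positive LMS step size.
#' @export
setClass("AssociativeMap",
  representation(weights = "matrix", learningRate = "numeric")
)

setValidity("AssociativeMap", function(object) {
  if (!all(is.finite(object@weights))) return("weights must be finite")
  if (object@learningRate <= 0) return("learningRate must be positive")
  TRUE
})

#' Leaky short-term memory buffer
#'
#' First-order low-pass filter over class activations:
#' `state <- decay * state + (1 - decay) * input`.
#'
#' @slot state numeric vector, one entry per class.
#' @slot decay retention coefficient in \[0,1).
#' @export
setClass("STMBuffer",
  representation(state = "numeric", decay = "numeric")
)

setValidity("STMBuffer", function(object) {
  if (object@decay < 0 || object@decay >= 1) return("decay must lie in [0,1)")
  if (!all(is.finite(object@state))) return("state must be finite")
  TRUE
})

#' Prediction-error novelty detector state
#'
#' Tracks the scalar posture-prediction error e(t), its sliding-window mean
#' E(t), and a leaky integration V of the negative error gradient. A rising
#' edge of the mean error (a one-step drop of V exceeding `threshold`)
#' outside the refractory period is logged as a novelty event — the
#' detection of a new interacting partner. Time 1 always fires event 1
#' (the first partner has no preceding baseline). During training the
#' event log additionally receives the visual-feature context-novelty
#' channel's events (see [peracConfig()]'s `noveltyChannel`).
#'
#' @slot window integer sliding-window length for E(t).
#' @slot threshold rising-edge threshold on the integrated gradient.
#' @slot refractory frames during which no further event may fire.
#' @slot smoothing leak coefficient of the gradient integrator.
#' @slot errors recent raw errors (up to `window` of them).
#' @slot E,Eprev,V current filter values.
#' @slot refractoryLeft frames left in the refractory period.
#' @slot t time of the last update.
#' @slot events data.frame (`time`, `event`) of detected events.
#' @export
setClass("NoveltyState",
  representation(
    window         = "integer",
    threshold      = "numeric",
    refractory     = "integer",
    smoothing      = "numeric",
    errors         = "numeric",
    E              = "numeric",
    Eprev          = "numeric",
    V              = "numeric",
    refractoryLeft = "integer",
    t              = "integer",
    events         = "data.frame"
  )
)

setValidity("NoveltyState", function(object) {
  if (object@window < 1L) return("window must be >= 1")
  if (object@refractory < 0L) return("refractory must be >= 0")
  if (object@smoothing < 0 || object@smoothing >= 1)
    return("smoothing must lie in [0,1)")
  ev <- object@events
  if (nrow(ev) > 1L) {
    if (any(diff(ev$time) <= 0))
      return("event times must be strictly increasing")
    if (any(diff(ev$time) <= object@refractory))
      return("events closer than the refractory period")
  }
  TRUE
})

#' Emergent person-recognition model
#'
#' One artificial neuron per detected partner: a row of the person
#' associative map, recruited when the novelty detector fires. Carries its
#' own short-term memory for ordered test sequences.
#'
#' @slot map [AssociativeMap-class] from feature activities to partners.
#' @slot stm [STMBuffer-class] over partner activations.
#' @slot currentPerson index of the partner currently being learned.
#' @slot nPersons number of recruited person neurons.
#' @export
setClass("PersonModel",
  representation(
    map           = "AssociativeMap",
    stm           = "STMBuffer",
    currentPerson = "integer",
    nPersons      = "integer"
  )
)

setValidity("PersonModel", function(object) {
  if (nrow(object@map@weights) != object@nPersons)
    return("person map must have one row per recruited person neuron")
  TRUE
})

#' Trained sensory-motor model
#'
#' Checkpointable container for the whole learning stack: the visual-feature
#' prototype network, the posture map (motor-internal-state prediction), the
#' person model, the novelty-detector state, the resolved configuration and
#' the per-frame training log.
#'
#' @slot vf [VFNetwork-class].
#' @slot misp [AssociativeMap-class] posture predictor.
#' @slot person [PersonModel-class].
#' @slot novelty [NoveltyState-class].
#' @slot config resolved configuration list (see [peracConfig()]).
#' @slot trainLog per-frame data.frame: `frame`, `neuron_count`,
#'   `mean_error`, `predicted_posture`, `true_posture`, `recruits`, `event`,
#'   `partner`.
#' @export
setClass("ImitationModel",
  representation(
    vf       = "VFNetwork",
    misp     = "AssociativeMap",
    person   = "PersonModel",
    novelty  = "NoveltyState",
    config   = "list",
    trainLog = "data.frame"
  )
)

#' Four-condition recognition experiment result
#'
#' @slot results data.frame with one row per partner x condition:
#'   `partner`, `condition`, `known`, `randomized`, `n_images`, `hits`,
#'   `score`, `chance`.
#' @slot model the trained [ImitationModel-class].
#' @slot config resolved configuration list.
#' @export
setClass("RecognitionExperiment",
  representation(results = "data.frame", model = "ImitationModel",
                 config = "list")
)
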