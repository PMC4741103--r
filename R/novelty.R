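#' Scalar posture-prediction error of a frame
#'
#' Euclidean norm of the difference between the predicted posture
#' activation vector and the actual one-hot motor state, normalized by
#' `sqrt(2)` so that predictions bounded in \[0,1\] yield errors in \[0,1\]
#' (a one-hot prediction of the wrong class scores exactly 1).
#'
#' @param predicted numeric posture activation vector.
#' @param actual one-hot motor state of the same length.
#' @return Scalar error.
#' @examples
#' frameError(c(0, 1, 0, 0, 0), motorState(2))
#' frameError(rep(0.2, 5), motorState(1))
#' @export
frameError <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual vectors must have the same length")
  sqrt(sum((predicted - actual)^2)) / sqrt(2)
}

#' Create a novelty-detector state
#'
#' @param threshold rising-edge threshold.
#' @param window sliding-window length of the mean error.
#' @param refractory post-event dead time in frames.
#' @param smoothing leak coefficient of the gradient integrator.
#' @return A fresh [NoveltyState-class] (no updates seen yet).
#' @export
newNoveltyState <- function(threshold = 0.05, window = 10L,
                            refractory = 15L, smoothing = 0.9) {
  new("NoveltyState", window = as.integer(window), threshold = threshold,
      refractory = as.integer(refractory), smoothing = smoothing,
      errors = numeric(0), E = 0, Eprev = 0, V = 0, refractoryLeft = 0L,
      t = 0L, events = data.frame(time = integer(), event = integer()))
}

#' Novelty-detector update
#'
#' Pushes one prediction error through the detector: `E` is the
#' sliding-window mean of recent errors, `g = E(t) - E(t-1)` its gradient,
#' and `V <- smoothing * V - g` a leaky integration of the negative
#' gradient (the quantity learning progress is proportional to). A *rise*
#' of the mean error drives `V` down; a one-step drop of `V` larger than
#' `threshold` is the rising-edge event — the detection of a new partner —
#' and starts the refractory countdown. The first update always fires
#' event 1, since no edge can precede the first partner's baseline.
#'
#' @param state a [NoveltyState-class].
#' @param e finite scalar prediction error.
#' @return List with `state` (updated) and `event` (logical flag).
#' @examples
#' st <- newNoveltyState()
#' r <- noveltyStep(st, 0.2)   # t = 1 fires the baseline event
#' r$event
#' @export
noveltyStep <- function(state, e) {
  if (!is.finite(e)) stop("prediction error must be finite")
  st <- list(window = state@window, threshold = state@threshold,
             refractory = state@refractory, smoothing = state@smoothing,
             errors = state@errors, E = state@E, Eprev = state@Eprev,
             V = state@V, refractoryLeft = state@refractoryLeft,
             t = state@t, evTime = state@events$time,
             evIdx = state@events$event)
  up <- .novelty_step_impl(st, e)
  st <- up$state
  out <- new("NoveltyState", window = state@window,
             threshold = state@threshold, refractory = state@refractory,
             smoothing = state@smoothing, errors = st$errors, E = st$E,
             Eprev = st$Eprev, V = st$V,
             refractoryLeft = as.integer(st$refractoryLeft),
             t = as.integer(st$t),
             events = data.frame(time = st$evTime, event = st$evIdx))
  list(state = out, event = up$event)
}

#' Create an empty person model
#'
#' @param nInputs current number of visual-feature neurons.
#' @param learningRate LMS rate of the person map.
#' @param stmDecay short-term-memory retention coefficient.
#' @return A [PersonModel-class] with zero person neurons.
#' @export
newPersonModel <- function(nInputs = 0L, learningRate = 0.05,
                           stmDecay = 0.7) {
  new("PersonModel",
      map = newAssociativeMap(0L, nInputs, learningRate),
      stm = newSTMBuffer(1L, decay = stmDecay),
      currentPerson = 0L, nPersons = 0L)
}

#' Person-learning update for one frame
#'
#' On a novelty event, recruits a new person neuron (a zero-initialized row
#' of the person map) and makes it the current partner; then conditions
#' every view's visual-feature activity vector toward the current partner's
#' one-hot target with the Widrow-Hoff rule.
#'
#' @param viewActivities matrix of VF activities, one column per view
#'   (rows must match the person map's columns).
#' @param model a [PersonModel-class].
#' @param event logical novelty flag for this frame.
#' @return The updated [PersonModel-class].
#' @examples
#' pm <- newPersonModel(nInputs = 3)
#' pm <- personLearnFrame(matrix(runif(6), 3), pm, event = TRUE)
#' nPersons(pm)
#' @export
personLearnFrame <- function(viewActivities, model, event) {
  if (is.null(dim(viewActivities)))
    viewActivities <- matrix(viewActivities, ncol = 1L)
  if (event) {
    model@nPersons <- model@nPersons + 1L
    model@currentPerson <- model@nPersons
    model@map@weights <- rbind(model@map@weights, 0)
  }
  if (model@nPersons == 0L)
    stop("no person neuron exists: an event must precede conditioning")
  if (nrow(viewActivities) != ncol(model@map@weights))
    stop("activity length does not match the person map")
  target <- numeric(model@nPersons)
  target[model@currentPerson] <- 1
  for (k in seq_len(ncol(viewActivities)))
    model@map <- lmsStep(viewActivities[, k], target, model@map)
  validObject(model)
  model
}

#' Recognize the partner in a sequence of images
#'
#' Frozen-model inference: no recruitment and no weight update happens. For
#' each image the reflex front-end extracts local views, the prototype
#' network scores them, the person map turns each view into partner
#' activations, activations are averaged over the views of the frame,
#' optionally filtered by the short-term memory (reset at the start of the
#' sequence; disable it for shuffled sequences, where temporal continuity
#' carries no information), and the winner-take-all readout names the
#' partner.
#'
#' @param images a [Session-class], a battery bundle from
#'   [buildConditionBattery()], or a plain list of image matrices.
#' @param model a trained [ImitationModel-class].
#' @param useStm apply the short-term memory across the sequence.
#' @param truth optional integer vector of true person indices; defaults
#'   to the partner labels carried by `images` (mapped through the model's
#'   partner order) when present.
#' @return List with `predicted` (person index per image), `hits`,
#'   `n`, and `score` (percent correct, NA without truth labels).
#' @examples
#' \donttest{
#' s <- generateSession(avatarGrid()[1], framesPerPartner = 20, seed = 1)
#' m <- trainModel(subsampleSession(s, 10), peracConfig())
#' recognizePerson(subsampleSession(s, 10), m)$score
#' }
#' @export
recognizePerson <- function(images, model, useStm = TRUE, truth = NULL) {
  partnerLabels <- NULL
  if (is(images, "Session")) {
    partnerLabels <- images@partner
    images <- images@frames
  } else if (is.list(images) && !is.null(images$frames)) {
    partnerLabels <- images$partner
    images <- images$frames
  }
  if (length(images) == 0L) stop("empty image list")
  if (is.null(truth) && !is.null(partnerLabels))
    truth <- .person_index(model, partnerLabels)
  cfg <- model@config
  nP <- model@person@nPersons
  if (nP == 0L) stop("model has no person neurons")
  Wp <- model@person@map@weights
  proto <- model@vf@prototypes
  nW <- ncol(proto)
  stm <- newSTMBuffer(nP, decay = cfg$stmDecay)
  predicted <- integer(length(images))
  for (i in seq_along(images)) {
    fv <- frameViews(images[[i]], cfg)
    A <- vf_activity_cpp(proto, nW, fv$views)
    A[A < model@vf@gamma] <- 0  # same vigilance gate as during learning
    act <- rowMeans(Wp %*% A)
    if (useStm) {
      stm <- stmUpdate(stm, act)
      act <- stm@state
    }
    predicted[i] <- wta(act)
  }
  hits <- if (is.null(truth)) NA_integer_ else sum(predicted == truth)
  list(predicted = predicted, hits = hits, n = length(images),
       score = if (is.null(truth)) NA_real_
               else 100 * hits / length(images))
}

#' Predict the commanded posture of each frame
#'
#' Frozen-model posture readout — the validation phase in which the roles
#' reverse and the agent imitates the partner: local views are scored by
#' the prototype network, passed through the vigilance gate, mapped to
#' posture activations by the motor map, averaged over the frame's views
#' and read out by winner-take-all.
#'
#' @param images a [Session-class], battery bundle, or list of image
#'   matrices.
#' @param model a trained [ImitationModel-class].
#' @return Integer vector of predicted postures, one per frame.
#' @examples
#' \donttest{
#' s <- generateSession(avatarGrid()[1], framesPerPartner = 20, seed = 1)
#' m <- trainModel(subsampleSession(s, 10), peracConfig())
#' predictPosture(subsampleSession(s, 10), m)
#' }
#' @export
predictPosture <- function(images, model) {
  if (is(images, "Session")) images <- images@frames
  else if (is.list(images) && !is.null(images$frames))
    images <- images$frames
  if (length(images) == 0L) stop("empty image list")
  cfg <- model@config
  proto <- model@vf@prototypes
  Wm <- model@misp@weights
  vapply(images, function(img) {
    A <- vf_activity_cpp(proto, ncol(proto), frameViews(img, cfg)$views)
    A[A < model@vf@gamma] <- 0
    wta(rowMeans(Wm %*% A))
  }, integer(1L))
}

# map partner ids to person-neuron indices via the order in which partners
# appeared during training (person neurons are recruited in block order)
.person_index <- function(model, partnerIds) {
  order_seen <- unique(model@trainLog$partner)
  idx <- match(partnerIds, order_seen)
  idx[is.na(idx)] <- 0L
  idx
}
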