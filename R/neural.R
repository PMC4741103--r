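#' Create an empty visual-feature network
#'
#' @param viewLength length of the local-view vectors the network will
#'   store.
#' @param gamma vigilance (recognition threshold) in (0,1].
#' @param epsilon long-term averaging rate in \[0,1).
#' @return A [VFNetwork-class] with zero neurons.
#' @examples
#' newVFNetwork(256)
#' @export
newVFNetwork <- function(viewLength, gamma = 0.92, epsilon = 0.1) {
  new("VFNetwork",
      prototypes = matrix(numeric(0), nrow = as.integer(viewLength),
                          ncol = 0L),
      gamma = gamma, epsilon = epsilon,
      recruitLog = data.frame(time = integer(), neuron = integer()))
}

#' Create an associative map
#'
#' @param nOutputs number of output classes (rows).
#' @param nInputs number of feature neurons (columns); weights start at 0.
#' @param learningRate LMS step size.
#' @return An [AssociativeMap-class].
#' @export
newAssociativeMap <- function(nOutputs, nInputs = 0L, learningRate = 0.05) {
  new("AssociativeMap",
      weights = matrix(0, nrow = as.integer(nOutputs),
                       ncol = as.integer(nInputs)),
      learningRate = learningRate)
}

#' Create a short-term-memory buffer
#'
#' @param nClasses vector length (one entry per class); state starts at 0.
#' @param decay retention coefficient in \[0,1).
#' @return An [STMBuffer-class].
#' @export
newSTMBuffer <- function(nClasses, decay = 0.7) {
  new("STMBuffer", state = numeric(as.integer(nClasses)), decay = decay)
}

#' One-hot motor internal state
#'
#' @param posture active posture index.
#' @param nPostures repertoire size.
#' @return Numeric one-hot vector of length `nPostures`.
#' @examples
#' motorState(2)
#' @export
motorState <- function(posture, nPostures = 5L) {
  posture <- as.integer(posture)
  if (posture < 1L || posture > nPostures)
    stop("posture index out of range")
  s <- numeric(nPostures)
  s[posture] <- 1
  s
}

#' Prototype activities for local views
#'
#' Activity of neuron `j` for view `v` is
#' `max(0, 1 - mean(abs(v - W_j)))`: 1 at an exact match, decreasing with
#' the normalized L1 distance, floored at 0.
#'
#' @param views numeric vector (one view) or matrix (one view per column).
#' @param net a [VFNetwork-class].
#' @return Activity vector (one view) or matrix `neurons x views`; empty
#'   when the network has no neurons.
#' @examples
#' net <- vfLearn(rep(0.5, 16), newVFNetwork(16))$net
#' vfActivities(rep(0.5, 16), net)
#' @export
vfActivities <- function(views, net) {
  single <- is.null(dim(views))
  V <- if (single) matrix(views, ncol = 1L) else views
  A <- vf_activity_cpp(net@prototypes, ncol(net@prototypes), V)
  if (single) as.vector(A) else A
}

#' Incremental prototype learning step
#'
#' If the best activity falls below the vigilance `gamma` (or the network is
#' empty) a new neuron is recruited whose weights copy the view one-shot.
#' Otherwise only the winner `k = which.max(activities)` is averaged toward
#' the view: `W_k <- W_k + epsilon * (view - W_k) * (1 - a_k)`, so
#' near-perfect matches barely move and poorer matches are averaged harder.
#'
#' @param view numeric vector in \[0,1\].
#' @param net a [VFNetwork-class].
#' @param t integer time stamp recorded in the recruit log.
#' @return List with `net` (updated network), `winner` (1-based neuron
#'   index), `recruited` (flag) and `activities` (over the updated bank;
#'   pre-update values for existing neurons, 1 for a fresh recruit).
#' @examples
#' r <- vfLearn(runif(16), newVFNetwork(16))
#' r$recruited
#' @export
vfLearn <- function(view, net, t = nrow(net@recruitLog) + 1L) {
  if (any(!is.finite(view))) stop("non-finite view entries")
  nW <- ncol(net@prototypes)
  W <- matrix(0, nrow = length(view), ncol = nW + 1L)
  if (nW > 0L) W[, seq_len(nW)] <- net@prototypes
  res <- vf_learn_cpp(W, nW, as.numeric(view), net@gamma, net@epsilon)
  if (res$recruited) {
    net@prototypes <- W
    net@recruitLog <- rbind(net@recruitLog,
                            data.frame(time = as.integer(t),
                                       neuron = nW + 1L))
  } else {
    net@prototypes <- W[, seq_len(nW), drop = FALSE]
  }
  list(net = net, winner = res$winner, recruited = res$recruited,
       activities = res$activities)
}

#' Widrow-Hoff (least-mean-squares) conditioning step
#'
#' Predicts `y = W x` and moves the weights along the error:
#' `W <- W + rate * (target - y) x^T`.
#'
#' @param input feature activity vector.
#' @param target one-hot (or graded) target vector, length `nrow(weights)`.
#' @param map an [AssociativeMap-class] whose column count matches
#'   `length(input)`.
#' @return The updated [AssociativeMap-class].
#' @examples
#' m <- newAssociativeMap(1, 1, learningRate = 0.5)
#' lmsStep(1, 1, m)@weights
#' @export
lmsStep <- function(input, target, map) {
  if (length(input) != ncol(map@weights))
    stop("input length does not match map columns")
  if (length(target) != nrow(map@weights))
    stop("target length does not match map rows")
  y <- drop(map@weights %*% input)
  map@weights <- map@weights +
    map@learningRate * tcrossprod(target - y, input)
  map
}

#' Short-term-memory update
#'
#' `state <- decay * state + (1 - decay) * input`: a leaky integrator that
#' sums and filters class activations over a short period. With `decay = 0`
#' it is the identity; under constant input it converges to that input.
#'
#' @param buffer an [STMBuffer-class].
#' @param input instantaneous activation vector.
#' @return The updated [STMBuffer-class] (filtered vector in `@state`).
#' @examples
#' b <- newSTMBuffer(2, decay = 0.5)
#' stmUpdate(b, c(1, 0))@state
#' @export
stmUpdate <- function(buffer, input) {
  if (length(input) != length(buffer@state))
    stop("input length does not match buffer")
  buffer@state <- buffer@decay * buffer@state +
    (1 - buffer@decay) * input
  buffer
}

#' Winner-take-all readout
#'
#' @param activations non-empty numeric vector.
#' @return Index of the maximum; ties go to the smallest index.
#' @examples
#' wta(c(0.1, 0.9, 0.3))
#' @export
wta <- function(activations) {
  if (length(activations) == 0L) stop("empty activation vector")
  which.max(activations)
}

#' Learn one labelled frame
#'
#' Runs the posture-learning pathway on a single frame: every local view is
#' fed to the prototype network ([vfLearn()]) and its activity vector
#' (zero-padded to the current neuron count) is conditioned toward the
#' commanded posture by [lmsStep()]. The frame's mean prediction error uses
#' each view's prediction *before* its own conditioning step.
#'
#' @param image frame matrix in \[0,1\].
#' @param posture commanded posture index.
#' @param net a [VFNetwork-class].
#' @param misp posture [AssociativeMap-class] (columns grow with `net`).
#' @param config configuration list from [peracConfig()].
#' @param t frame time stamp.
#' @return List with updated `net` and `misp`, plus `log`: a one-row
#'   data.frame (`frame`, `neuron_count`, `mean_error`,
#'   `predicted_posture`, `true_posture`, `recruits`).
#' @examples
#' cfg <- peracConfig()
#' img <- renderAvatar(avatarSpec(1), 1, 1)
#' st <- learnFrame(img, 1, newVFNetwork(cfg$nRings * cfg$nAngles),
#'                  newAssociativeMap(5), cfg)
#' st$log$neuron_count
#' @export
learnFrame <- function(image, posture, net, misp, config = peracConfig(),
                       t = 1L) {
  eng <- .engine_from_objects(net, misp, config)
  out <- .engine_learn_frame(eng, image, posture, t, person = FALSE)
  packed <- .engine_to_objects(eng)
  list(net = packed$net, misp = packed$misp, log = out$log)
}
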