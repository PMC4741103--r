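# ---------------------------------------------------------------------
# Mutable learning engine.
#
# The exported classes are immutable S4 values; running the learning phase
# through them would copy the growing prototype bank once per view. The
# engine keeps the same state in an environment with spare-capacity
# matrices (doubling growth) that vf_learn_cpp() updates in place, and is
# packed back into S4 objects when a user-facing function returns.
# ---------------------------------------------------------------------

.engine_new <- function(D, config) {
  eng <- new.env(parent = emptyenv())
  eng$cfg <- config
  eng$D <- as.integer(D)
  eng$cap <- 256L
  eng$nW <- 0L
  eng$W <- matrix(0, D, eng$cap)
  eng$recruitT <- integer(0)
  eng$nPost <- config$nPostures
  eng$mispW <- matrix(0, eng$nPost, eng$cap)
  eng$nPersons <- 0L
  eng$currentPerson <- 0L
  eng$personW <- matrix(0, 0L, eng$cap)
  nov0 <- list(window = config$noveltyWindow,
               threshold = config$noveltyThreshold,
               refractory = config$noveltyRefractory,
               smoothing = config$noveltySmoothing,
               errors = numeric(0), E = 0, Eprev = 0, V = 0,
               refractoryLeft = 0L, t = 0L,
               evTime = integer(0), evIdx = integer(0))
  eng$nov <- nov0    # channel 1: posture-prediction error e(t)
  # channel 2: outliers in the VF stream (mean supra-vigilance excess,
  # compared against its own trailing-window mean)
  eng$novVF <- list(window = config$noveltyWindow,
                    threshold = if (is.null(config$noveltyVfThreshold))
                      0.012 else config$noveltyVfThreshold,
                    refractory = config$noveltyRefractory,
                    errors = numeric(0), E = 0,
                    refractoryLeft = 0L, t = 0L,
                    evTime = integer(0), evIdx = integer(0))
  eng$evTime <- integer(0)  # merged event log (shared refractory)
  eng$evIdx <- integer(0)
  eng$winnersHist <- list()  # per-frame recruited prototype indices
  eng
}

.engine_grow <- function(eng) {
  newcap <- eng$cap * 2L
  W <- matrix(0, eng$D, newcap)
  W[, seq_len(eng$nW)] <- eng$W[, seq_len(eng$nW)]
  eng$W <- W
  M <- matrix(0, eng$nPost, newcap)
  M[, seq_len(eng$nW)] <- eng$mispW[, seq_len(eng$nW)]
  eng$mispW <- M
  P <- matrix(0, eng$nPersons, newcap)
  if (eng$nPersons > 0L)
    P[, seq_len(eng$nW)] <- eng$personW[, seq_len(eng$nW)]
  eng$personW <- P
  eng$cap <- newcap
  invisible(eng)
}

.engine_from_objects <- function(net, misp, config, person = NULL,
                                 novelty = NULL) {
  D <- nrow(net@prototypes)
  eng <- .engine_new(D, config)
  nW <- ncol(net@prototypes)
  while (eng$cap < nW + 64L) eng$cap <- eng$cap * 2L
  eng$W <- matrix(0, D, eng$cap)
  eng$mispW <- matrix(0, eng$nPost, eng$cap)
  if (nW > 0L) {
    eng$W[, seq_len(nW)] <- net@prototypes
    eng$nW <- nW
    eng$recruitT <- net@recruitLog$time
  }
  if (ncol(misp@weights) > 0L)
    eng$mispW[, seq_len(ncol(misp@weights))] <- misp@weights
  eng$gamma <- net@gamma
  eng$epsilon <- net@epsilon
  eng$lmsRate <- misp@learningRate
  if (!is.null(person)) {
    eng$nPersons <- person@nPersons
    eng$currentPerson <- person@currentPerson
    eng$personW <- matrix(0, eng$nPersons, eng$cap)
    if (eng$nPersons > 0L && ncol(person@map@weights) > 0L)
      eng$personW[, seq_len(ncol(person@map@weights))] <-
        person@map@weights
  }
  if (!is.null(novelty)) {
    eng$nov <- list(window = novelty@window, threshold = novelty@threshold,
                    refractory = novelty@refractory,
                    smoothing = novelty@smoothing, errors = novelty@errors,
                    E = novelty@E, Eprev = novelty@Eprev, V = novelty@V,
                    refractoryLeft = novelty@refractoryLeft, t = novelty@t,
                    evTime = integer(0), evIdx = integer(0))
    eng$evTime <- novelty@events$time
    eng$evIdx <- novelty@events$event
  }
  eng
}

.engine_to_objects <- function(eng) {
  idx <- seq_len(eng$nW)
  net <- new("VFNetwork",
             prototypes = eng$W[, idx, drop = FALSE],
             gamma = eng$gamma, epsilon = eng$epsilon,
             recruitLog = data.frame(time = eng$recruitT,
                                     neuron = idx[seq_along(eng$recruitT)]))
  misp <- new("AssociativeMap", weights = eng$mispW[, idx, drop = FALSE],
              learningRate = eng$lmsRate)
  person <- new("PersonModel",
                map = new("AssociativeMap",
                          weights = eng$personW[, idx, drop = FALSE],
                          learningRate = eng$lmsRate),
                stm = newSTMBuffer(max(eng$nPersons, 1L),
                                   decay = eng$cfg$stmDecay),
                currentPerson = eng$currentPerson,
                nPersons = eng$nPersons)
  novelty <- new("NoveltyState",
                 window = as.integer(eng$nov$window),
                 threshold = eng$nov$threshold,
                 refractory = as.integer(eng$nov$refractory),
                 smoothing = eng$nov$smoothing,
                 errors = eng$nov$errors, E = eng$nov$E,
                 Eprev = eng$nov$Eprev, V = eng$nov$V,
                 refractoryLeft = as.integer(eng$nov$refractoryLeft),
                 t = as.integer(eng$nov$t),
                 events = data.frame(time = eng$evTime,
                                     event = eng$evIdx))
  list(net = net, misp = misp, person = person, novelty = novelty)
}

# shared novelty filter update on the plain-list state; returns the updated
# list plus the event flag (see noveltyStep() for the definition)
.novelty_step_impl <- function(st, e) {
  t <- st$t + 1L
  st$errors <- c(st$errors, e)
  if (length(st$errors) > st$window)
    st$errors <- st$errors[-1L]
  E <- mean(st$errors)
  g <- if (t == 1L) 0 else E - st$Eprev
  Vprev <- st$V
  V <- st$smoothing * Vprev - g
  # rising edge of the mean error: V (leaky integral of the negative
  # gradient) drops by more than the threshold in one step
  event <- FALSE
  if (t == 1L) {
    event <- TRUE
  } else if (st$refractoryLeft == 0L &&
             Vprev - V >= st$threshold - 1e-12) {
    event <- TRUE
  }
  if (event) {
    st$refractoryLeft <- st$refractory
    st$evTime <- c(st$evTime, t)
    st$evIdx <- c(st$evIdx, length(st$evIdx) + 1L)
  } else if (st$refractoryLeft > 0L) {
    st$refractoryLeft <- st$refractoryLeft - 1L
  }
  st$Eprev <- E
  st$E <- E
  st$V <- V
  st$t <- t
  list(state = st, event = event)
}

# excursion-style outlier detector for the VF novelty channel: fires when
# the statistic exceeds the trailing-window mean of its own past values by
# more than the threshold
.novelty_excursion_impl <- function(st, e) {
  t <- st$t + 1L
  event <- FALSE
  if (t == 1L) {
    event <- TRUE
  } else if (st$refractoryLeft == 0L &&
             e - mean(st$errors) > st$threshold) {
    event <- TRUE
  }
  st$errors <- c(st$errors, e)
  if (length(st$errors) > st$window) st$errors <- st$errors[-1L]
  st$E <- mean(st$errors)
  if (event) {
    st$refractoryLeft <- st$refractory
    st$evTime <- c(st$evTime, t)
    st$evIdx <- c(st$evIdx, length(st$evIdx) + 1L)
  } else if (st$refractoryLeft > 0L) {
    st$refractoryLeft <- st$refractoryLeft - 1L
  }
  st$t <- t
  list(state = st, event = event)
}

# one frame through the full learning stack; mutates eng, returns the log
.engine_learn_frame <- function(eng, image, posture, t, person = TRUE) {
  fv <- frameViews(image, eng$cfg)
  views <- fv$views
  K <- ncol(views)
  if (K == 0L) stop("frame yields no focus points (blank image?)")
  target <- motorState(posture, eng$nPost)
  preds <- matrix(0, eng$nPost, K)
  acts <- vector("list", K)
  depth <- numeric(K)     # 1 - best pre-learning activity, whole bank
  depthCtx <- numeric(K)  # same, against the recent-context prototypes
  # context = prototypes recruited in the trailing window: pure
  # recent-partner membership, immune to long-term library growth
  ctx <- unique(unlist(eng$winnersHist))
  recruits <- integer(0)
  nW0 <- eng$nW
  for (k in seq_len(K)) {
    if (eng$nW >= eng$cap) .engine_grow(eng)
    res <- vf_learn_cpp(eng$W, eng$nW, views[, k], eng$gamma, eng$epsilon)
    if (res$recruited) {
      eng$nW <- eng$nW + 1L
      eng$recruitT <- c(eng$recruitT, as.integer(t))
      recruits <- c(recruits, res$winner)
    }
    depth[k] <- 1 - res$best_pre
    a <- res$activities
    depthCtx[k] <- if (length(ctx)) 1 - max(a[ctx], 0) else 1
    # vigilance-gated conditioning input H_gamma(a)*a: recruitment ensures
    # at least one supra-threshold entry, and the sparse vector keeps the
    # Widrow-Hoff step well inside its stability region
    a[a < eng$gamma] <- 0
    idx <- seq_len(eng$nW)
    y <- drop(eng$mispW[, idx, drop = FALSE] %*% a)
    preds[, k] <- y
    eng$mispW[, idx] <- eng$mispW[, idx, drop = FALSE] +
      eng$lmsRate * tcrossprod(target - y, a)
    acts[[k]] <- a
  }
  e <- frameError(rowMeans(preds), target)
  eCtx <- mean(pmax(depthCtx - (1 - eng$gamma), 0))
  ctxWin <- eng$cfg$noveltyContextWindow
  if (is.null(ctxWin)) ctxWin <- 20L
  eng$winnersHist <- c(eng$winnersHist, list(recruits))
  if (length(eng$winnersHist) > ctxWin)
    eng$winnersHist <- eng$winnersHist[-1L]
  event <- FALSE
  if (person) {
    channel <- eng$cfg$noveltyChannel
    if (is.null(channel)) channel <- "both"
    upe <- .novelty_step_impl(eng$nov, e)
    eng$nov <- upe$state
    upv <- .novelty_excursion_impl(eng$novVF, eCtx)
    eng$novVF <- upv$state
    event <- switch(channel, error = upe$event, vf = upv$event,
                    upe$event || upv$event)
    if (event) {
      # shared refractory: one partner switch never double-counts across
      # channels
      eng$nov$refractoryLeft <- eng$nov$refractory
      eng$novVF$refractoryLeft <- eng$novVF$refractory
      eng$evTime <- c(eng$evTime, eng$nov$t)
      eng$evIdx <- c(eng$evIdx, length(eng$evIdx) + 1L)
      eng$nPersons <- eng$nPersons + 1L
      eng$currentPerson <- eng$nPersons
      eng$personW <- rbind(eng$personW, 0)
    }
    ptarget <- numeric(eng$nPersons)
    ptarget[eng$currentPerson] <- 1
    idx <- seq_len(eng$nW)
    for (k in seq_len(K)) {
      a <- acts[[k]]
      if (length(a) < eng$nW) a <- c(a, numeric(eng$nW - length(a)))
      yp <- drop(eng$personW[, idx, drop = FALSE] %*% a)
      eng$personW[, idx] <- eng$personW[, idx, drop = FALSE] +
        eng$lmsRate * tcrossprod(ptarget - yp, a)
    }
  }
  list(log = data.frame(frame = as.integer(t), neuron_count = eng$nW,
                        mean_error = e, vf_depth = mean(depth),
                        vf_excess = mean(pmax(depth - (1 - eng$gamma), 0)),
                        vf_ctx = eCtx,
                        predicted_posture = wta(rowMeans(preds)),
                        true_posture = as.integer(posture),
                        recruits = eng$nW - nW0, event = event),
       event = event)
}

#' Run the learning phase over a session
#'
#' Feeds every frame of the (typically 1/10-subsampled) session through the
#' full stack: local views are learned by the visual-feature prototype
#' network, conditioned toward the commanded posture by the motor map, the
#' frame's posture-prediction error drives the novelty detector, and each
#' novelty event recruits a fresh person neuron that all subsequent views
#' are conditioned toward. Learning is deterministic given the frame
#' stream.
#'
#' @param session a labelled [Session-class] (the learning subsample).
#' @param config configuration list from [peracConfig()].
#' @param progress print a progress line every 50 frames.
#' @return A trained [ImitationModel-class].
#' @examples
#' \donttest{
#' s <- generateSession(avatarGrid()[1:2], framesPerPartner = 20, seed = 1)
#' m <- trainModel(subsampleSession(s, 10), peracConfig())
#' nPersons(m)
#' }
#' @export
trainModel <- function(session, config = peracConfig(), progress = FALSE) {
  n <- nFrames(session)
  if (n == 0L) stop("cannot train on an empty session")
  D <- config$nRings * config$nAngles
  eng <- .engine_new(D, config)
  eng$gamma <- config$gamma
  eng$epsilon <- config$epsilon
  eng$lmsRate <- config$lmsRate
  logs <- vector("list", n)
  for (t in seq_len(n)) {
    out <- .engine_learn_frame(eng, session@frames[[t]],
                               session@posture[t], t, person = TRUE)
    logs[[t]] <- cbind(out$log, partner = session@partner[t])
    if (progress && t %% 50L == 0L)
      message(sprintf("frame %d/%d: %d VF neurons, %d person neuron(s)",
                      t, n, eng$nW, eng$nPersons))
  }
  packed <- .engine_to_objects(eng)
  new("ImitationModel", vf = packed$net, misp = packed$misp,
      person = packed$person, novelty = packed$novelty, config = config,
      trainLog = do.call(rbind, logs))
}
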