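#' Save a trained model checkpoint
#'
#' Serializes the whole stack — prototype bank, posture and person maps,
#' novelty state, resolved configuration and training log — to a single
#' versioned JSON file at full double precision, so a reloaded model
#' reproduces the original bit for bit.
#'
#' @param model an [ImitationModel-class].
#' @param path output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  payload <- list(
    format = "perac-checkpoint",
    version = 1L,
    config = model@config,
    vf = list(prototypes = model@vf@prototypes, gamma = model@vf@gamma,
              epsilon = model@vf@epsilon, recruitLog = model@vf@recruitLog),
    misp = list(weights = model@misp@weights,
                learningRate = model@misp@learningRate),
    person = list(weights = model@person@map@weights,
                  learningRate = model@person@map@learningRate,
                  stmDecay = model@person@stm@decay,
                  currentPerson = model@person@currentPerson,
                  nPersons = model@person@nPersons),
    novelty = list(window = model@novelty@window,
                   threshold = model@novelty@threshold,
                   refractory = model@novelty@refractory,
                   smoothing = model@novelty@smoothing,
                   errors = model@novelty@errors, E = model@novelty@E,
                   Eprev = model@novelty@Eprev, V = model@novelty@V,
                   refractoryLeft = model@novelty@refractoryLeft,
                   t = model@novelty@t, events = model@novelty@events),
    trainLog = model@trainLog
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path a file written by [saveModel()].
#' @return The reconstructed [ImitationModel-class].
#' @export
loadModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "perac-checkpoint"))
    stop("not a perac checkpoint file")
  as_mat <- function(m, nrow0, ncol0) {
    if (is.null(m) || length(m) == 0L) return(matrix(0, nrow0, ncol0))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    m
  }
  cfg <- x$config
  D <- cfg$nRings * cfg$nAngles
  proto <- as_mat(x$vf$prototypes, D, 0L)
  rl <- as.data.frame(x$vf$recruitLog)
  if (nrow(rl) == 0L) rl <- data.frame(time = integer(), neuron = integer())
  nW <- ncol(proto)
  nP <- as.integer(x$person$nPersons)
  vf <- new("VFNetwork", prototypes = proto, gamma = x$vf$gamma,
            epsilon = x$vf$epsilon, recruitLog = rl)
  misp <- new("AssociativeMap", weights = as_mat(x$misp$weights, cfg$nPostures, nW),
              learningRate = x$misp$learningRate)
  person <- new("PersonModel",
                map = new("AssociativeMap",
                          weights = as_mat(x$person$weights, nP, nW),
                          learningRate = x$person$learningRate),
                stm = newSTMBuffer(max(nP, 1L), decay = x$person$stmDecay),
                currentPerson = as.integer(x$person$currentPerson),
                nPersons = nP)
  ev <- as.data.frame(x$novelty$events)
  if (nrow(ev) == 0L) ev <- data.frame(time = integer(), event = integer())
  novelty <- new("NoveltyState", window = as.integer(x$novelty$window),
                 threshold = x$novelty$threshold,
                 refractory = as.integer(x$novelty$refractory),
                 smoothing = x$novelty$smoothing,
                 errors = as.numeric(x$novelty$errors),
                 E = x$novelty$E, Eprev = x$novelty$Eprev, V = x$novelty$V,
                 refractoryLeft = as.integer(x$novelty$refractoryLeft),
                 t = as.integer(x$novelty$t), events = ev)
  new("ImitationModel", vf = vf, misp = misp, person = person,
      novelty = novelty, config = cfg,
      trainLog = as.data.frame(x$trainLog))
}
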