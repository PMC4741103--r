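#' Accessors for perac classes
#'
#' Small accessor generics: `nFrames`, `sessionFrames`, `postures`,
#' `partners`, `frameIndices` and `partnerSchedule` for [Session-class];
#' `nNeurons`, `prototypes` and `recruitLog` for [VFNetwork-class];
#' `nPersons` for [PersonModel-class]/[ImitationModel-class];
#' `trainLog` for [ImitationModel-class]; `results` for
#' [RecognitionExperiment-class].
#'
#' @param x an object of the class documented with each method.
#' @return The corresponding slot value (scalar, vector or data.frame).
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("sessionFrames", function(x) standardGeneric("sessionFrames"))

#' @rdname accessors
#' @export
setGeneric("postures", function(x) standardGeneric("postures"))

#' @rdname accessors
#' @export
setGeneric("partners", function(x) standardGeneric("partners"))

#' @rdname accessors
#' @export
setGeneric("frameIndices", function(x) standardGeneric("frameIndices"))

#' @rdname accessors
#' @export
setGeneric("partnerSchedule", function(x) standardGeneric("partnerSchedule"))

#' @rdname accessors
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname accessors
#' @export
setGeneric("prototypes", function(x) standardGeneric("prototypes"))

#' @rdname accessors
#' @export
setGeneric("recruitLog", function(x) standardGeneric("recruitLog"))

#' @rdname accessors
#' @export
setGeneric("nPersons", function(x) standardGeneric("nPersons"))

#' @rdname accessors
#' @export
setGeneric("trainLog", function(x) standardGeneric("trainLog"))

#' @rdname accessors
#' @export
setGeneric("results", function(x) standardGeneric("results"))

#' @rdname accessors
#' @export
setMethod("nFrames", "Session", function(x) length(x@frames))

#' @rdname accessors
#' @export
setMethod("sessionFrames", "Session", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("postures", "Session", function(x) x@posture)

#' @rdname accessors
#' @export
setMethod("partners", "Session", function(x) x@partner)

#' @rdname accessors
#' @export
setMethod("frameIndices", "Session", function(x) x@frameIndex)

#' @rdname accessors
#' @export
setMethod("partnerSchedule", "Session", function(x) x@schedule)

#' @rdname accessors
#' @export
setMethod("nNeurons", "VFNetwork", function(x) ncol(x@prototypes))

#' @rdname accessors
#' @export
setMethod("prototypes", "VFNetwork", function(x) x@prototypes)

#' @rdname accessors
#' @export
setMethod("recruitLog", "VFNetwork", function(x) x@recruitLog)

#' @rdname accessors
#' @export
setMethod("nNeurons", "ImitationModel", function(x) nNeurons(x@vf))

#' @rdname accessors
#' @export
setMethod("nPersons", "PersonModel", function(x) x@nPersons)

#' @rdname accessors
#' @export
setMethod("nPersons", "ImitationModel", function(x) x@person@nPersons)

#' @rdname accessors
#' @export
setMethod("trainLog", "ImitationModel", function(x) x@trainLog)

#' @rdname accessors
#' @export
setMethod("results", "RecognitionExperiment", function(x) x@results)

setMethod("show", "AvatarSpec", function(object) {
  cat(sprintf(
    "AvatarSpec #%d: arms %gx%g px, head r=%g, torso %gx%g, gray %.2f\n",
    object@avatarId, object@armLength, object@armWidth, object@headRadius,
    object@torsoWidth, object@torsoHeight, object@grayLevel))
})

setMethod("show", "Session", function(object) {
  n <- nFrames(object)
  cat(sprintf("Session: %d frames, %d partner block(s)\n", n,
              nrow(object@schedule)))
  if (n > 0L) {
    d <- dim(object@frames[[1L]])
    cat(sprintf("  frames %dx%d, postures %s, frame indices %d..%d\n",
                d[1L], d[2L],
                paste(sort(unique(object@posture)), collapse = ","),
                object@frameIndex[1L], object@frameIndex[n]))
  }
})

setMethod("show", "VFNetwork", function(object) {
  cat(sprintf(
    "VFNetwork: %d prototype neuron(s) of length %d (gamma=%.3g, epsilon=%.3g)\n",
    ncol(object@prototypes), nrow(object@prototypes), object@gamma,
    object@epsilon))
})

setMethod("show", "NoveltyState", function(object) {
  cat(sprintf(
    "NoveltyState: t=%d, E=%.4f, V=%.4f, %d event(s) (window=%d, threshold=%.3g)\n",
    object@t, object@E, object@V, nrow(object@events), object@window,
    object@threshold))
})

setMethod("show", "ImitationModel", function(object) {
  cat(sprintf(
    "ImitationModel: %d VF neurons, %d person neuron(s), trained on %d frame(s)\n",
    nNeurons(object@vf), object@person@nPersons, nrow(object@trainLog)))
})

setMethod("show", "RecognitionExperiment", function(object) {
  cat("RecognitionExperiment\n")
  res <- object@results
  agg <- stats::aggregate(score ~ condition, data = res, FUN = mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-18s mean score %5.1f%% (chance %.1f%%)\n",
                agg$condition[i], agg$score[i], res$chance[1L]))
})
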