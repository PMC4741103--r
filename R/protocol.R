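#' Split a session into known and unknown pools
#'
#' The "known" pool is the 1-in-`stride` temporal subsample fed to the
#' learning phase; the "unknown" pool is its complement — frames of the
#' same partners and postures the model never saw. The two pools are
#' disjoint and together cover the session.
#'
#' @param session a [Session-class].
#' @param stride learning subsampling stride (>= 2).
#' @return List with [Session-class] elements `known` and `unknown`.
#' @examples
#' s <- generateSession(avatarGrid()[1], framesPerPartner = 30, seed = 1,
#'                      imageSize = 64)
#' p <- splitKnownUnknown(s, 10)
#' c(nFrames(p$known), nFrames(p$unknown))
#' @export
splitKnownUnknown <- function(session, stride = 10L) {
  stride <- as.integer(stride)
  if (stride < 2L) stop("stride must be at least 2")
  if (stride > nFrames(session))
    stop("stride exceeds the session length")
  list(known = subsampleSession(session, stride),
       unknown = .session_complement(session, stride))
}

#' Build one test-condition battery
#'
#' Draws `nImages` frames from a single-partner pool. When the pool is
#' smaller than `nImages` the draw falls back to sampling with replacement
#' (flagged in the result). Non-randomized batteries present the drawn
#' frames in their original temporal order; randomized batteries keep the
#' seeded shuffle order. For a fixed seed the randomized battery is a
#' permutation of the non-randomized one.
#'
#' @param pool a [Session-class] restricted to one partner (the known or
#'   unknown pool).
#' @param randomized shuffle the presentation order.
#' @param nImages battery length.
#' @param seed integer seed of the draw.
#' @return Battery bundle: list with `frames`, `posture`, `partner`,
#'   `frameIndex`, `randomized`, `replacement`.
#' @examples
#' s <- generateSession(avatarGrid()[1], framesPerPartner = 30, seed = 1,
#'                      imageSize = 64)
#' b <- buildConditionBattery(s, randomized = FALSE, nImages = 10, seed = 3)
#' b$frameIndex
#' @export
buildConditionBattery <- function(pool, randomized, nImages = 100L,
                                  seed = 1L) {
  m <- nFrames(pool)
  if (m == 0L) stop("empty frame pool")
  nImages <- as.integer(nImages)
  replace <- m < nImages
  sel <- withr::with_seed(as.integer(seed),
                          sample(seq_len(m), nImages, replace = replace))
  if (!randomized) sel <- sel[order(pool@frameIndex[sel])]
  out <- .session_take(pool, sel)
  out$randomized <- randomized
  out$replacement <- replace
  out
}

#' Run the full four-condition recognition experiment
#'
#' End-to-end benchmark: generate the avatar session, subsample it into
#' the learning phase, train the full stack, freeze it, and test every
#' partner under the four conditions (known/unknown crossed with
#' random/non-random order, 100 images each by default). The short-term
#' memory is active only in the non-random conditions, and is reset
#' between batteries. All randomness derives from `config$seed`.
#'
#' @param specs list of [AvatarSpec-class] partners (default the
#'   12-avatar morphology grid).
#' @param config configuration list from [peracConfig()].
#' @param progress print progress messages.
#' @return A [RecognitionExperiment-class].
#' @examples
#' \donttest{
#' cfg <- peracConfig(framesPerPartner = 50, nImages = 20)
#' ex <- runExperiment(avatarGrid()[1:3], cfg)
#' results(ex)
#' }
#' @export
runExperiment <- function(specs = avatarGrid(), config = peracConfig(),
                          progress = FALSE) {
  session <- generateSession(specs, config$framesPerPartner,
                             seed = derive_seed(config$seed, "session"),
                             imageSize = config$imageSize,
                             noiseSd = config$noiseSd)
  pools <- splitKnownUnknown(session, config$stride)
  if (progress) message("training on ", nFrames(pools$known), " frames")
  model <- trainModel(pools$known, config, progress = progress)
  partnersSeen <- unique(session@partner)
  chance <- 100 / length(partnersSeen)
  rows <- list()
  for (p in partnersSeen) {
    pIdx <- .person_index(model, p)
    for (known in c(TRUE, FALSE)) {
      pool <- if (known) pools$known else pools$unknown
      keep <- which(pool@partner == p)
      pool <- .new_session(pool@frames[keep], pool@posture[keep],
                           pool@partner[keep], pool@frameIndex[keep],
                           pool@seed)
      bseed <- derive_seed(config$seed,
                           sprintf("battery_%d_%d", p, known))
      for (randomized in c(FALSE, TRUE)) {
        battery <- buildConditionBattery(pool, randomized,
                                         config$nImages, bseed)
        rec <- recognizePerson(battery, model, useStm = !randomized,
                               truth = rep(pIdx, config$nImages))
        rows[[length(rows) + 1L]] <- data.frame(
          partner = p,
          condition = paste0(if (randomized) "random" else "non-random",
                             "/", if (known) "known" else "unknown"),
          known = known, randomized = randomized,
          n_images = rec$n, hits = rec$hits, score = rec$score,
          chance = chance)
      }
    }
    if (progress) message("partner ", p, " tested")
  }
  new("RecognitionExperiment", results = do.call(rbind, rows),
      model = model, config = config)
}

#' Exact one-sided binomial test against chance
#'
#' Upper-tail probability of observing at least `hits` successes in `n`
#' Bernoulli trials at the chance rate: `P(X >= hits)`.
#'
#' @param hits observed correct recognitions (0..n).
#' @param n number of trials.
#' @param chance success probability under the null, in (0,1).
#' @return The exact p-value.
#' @examples
#' binomialVsChance(10, 10, 0.5)   # 0.5^10
#' @export
binomialVsChance <- function(hits, n, chance) {
  if (chance <= 0 || chance >= 1) stop("chance must lie in (0,1)")
  if (hits < 0 || hits > n) stop("hits must lie in 0..n")
  stats::pbinom(hits - 1, n, chance, lower.tail = FALSE)
}

#' Percentile bootstrap confidence interval of a mean
#'
#' @param scores numeric vector (>= 2 values).
#' @param nBoot bootstrap replications.
#' @param level confidence level.
#' @param seed integer seed (the interval is deterministic given it).
#' @return Numeric vector `c(low, high)`.
#' @examples
#' bootstrapCI(c(80, 85, 90, 95), seed = 1)
#' @export
bootstrapCI <- function(scores, nBoot = 10000L, level = 0.95, seed = 1L) {
  if (length(scores) < 2L) stop("need at least two scores")
  means <- withr::with_seed(as.integer(seed), {
    idx <- matrix(sample.int(length(scores), length(scores) * nBoot,
                             replace = TRUE), nrow = nBoot)
    rowMeans(matrix(scores[idx], nrow = nBoot))
  })
  a <- (1 - level) / 2
  unname(stats::quantile(means, probs = c(a, 1 - a)))
}

#' Direction of the known and randomization contrasts
#'
#' Signs of the two planned mean differences over the four-condition
#' result table: `known - unknown` (expected positive: frames seen in
#' learning are recognized better) and `random - nonrandom` (expected
#' negative: shuffling removes the temporal continuity the short-term
#' memory exploits).
#'
#' @param res a [RecognitionExperiment-class] or its results data.frame.
#' @return List with `known_effect_sign` and `random_effect_sign`
#'   (each -1, 0 or +1).
#' @export
contrastCheck <- function(res) {
  if (is(res, "RecognitionExperiment")) res <- res@results
  need <- c("known", "randomized", "score")
  if (!all(need %in% names(res)))
    stop("results must contain known, randomized and score columns")
  if (length(unique(res$known)) < 2L ||
      length(unique(res$randomized)) < 2L)
    stop("all four conditions are required")
  list(known_effect_sign = sign(mean(res$score[res$known]) -
                                  mean(res$score[!res$known])),
       random_effect_sign = sign(mean(res$score[res$randomized]) -
                                   mean(res$score[!res$randomized])))
}

#' Condition-level summary of an experiment
#'
#' Per-condition mean score, bootstrap confidence interval over the
#' per-partner scores, and the exact binomial p-value of the pooled hit
#' count against chance.
#'
#' @param experiment a [RecognitionExperiment-class].
#' @param nBoot bootstrap replications.
#' @param level confidence level.
#' @param seed bootstrap seed.
#' @return data.frame with one row per condition: `condition`, `mean`,
#'   `ci_low`, `ci_high`, `hits`, `n`, `chance`, `p_binomial`.
#' @export
summarizeExperiment <- function(experiment, nBoot = 10000L, level = 0.95,
                                seed = 1L) {
  res <- experiment@results
  out <- lapply(split(res, res$condition), function(d) {
    ci <- bootstrapCI(d$score, nBoot = nBoot, level = level, seed = seed)
    data.frame(condition = d$condition[1L], mean = mean(d$score),
               ci_low = ci[1L], ci_high = ci[2L],
               hits = sum(d$hits), n = sum(d$n_images),
               chance = d$chance[1L],
               p_binomial = binomialVsChance(sum(d$hits), sum(d$n_images),
                                             d$chance[1L] / 100))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
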