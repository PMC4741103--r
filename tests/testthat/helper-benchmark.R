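# the default 12-avatar benchmark, computed once per test run and shared
# by the recruitment, novelty and recognition acceptance checks

.bench <- new.env(parent = emptyenv())

default_benchmark <- function() {
  if (is.null(.bench$ex))
    .bench$ex <- runExperiment(avatarGrid(), peracConfig(seed = 42))
  .bench$ex
}

default_benchmark_session <- function() {
  if (is.null(.bench$session)) {
    cfg <- peracConfig(seed = 42)
    .bench$session <- generateSession(
      avatarGrid(), cfg$framesPerPartner,
      seed = perac:::derive_seed(cfg$seed, "session"),
      imageSize = cfg$imageSize, noiseSd = cfg$noiseSd)
  }
  .bench$session
}
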