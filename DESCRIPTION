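Package: perac
Title: Perception-Action Imitation Learning with Emergent Person Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A sensory-motor (PerAc-style) learning stack in which an agent
    learns body postures by being imitated and, as an emergent property,
    learns to re-identify individual partners through a prediction-error
    novelty detector. Provides a log-polar visual front-end (difference-of-
    Gaussians saliency over the gradient norm, focus-point competition,
    log-polar local views), an incremental prototype network with a vigilance
    threshold, least-mean-squares perception-action conditioning with a leaky
    short-term memory and winner-take-all readout, rising-edge novelty
    detection on the posture prediction error, a parametric humanoid-avatar
    session generator, and the four-condition (known/unknown x random/ordered)
    person-recognition test battery with binomial and bootstrap statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    withr,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
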