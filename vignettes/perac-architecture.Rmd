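---
title: "Learning to recognize partners by being imitated: the perac architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning to recognize partners by being imitated: the perac architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

An agent plays an imitation game: it strikes a posture from a small
repertoire, and a partner mirrors it. Because the partner acts as a mirror,
every camera frame is implicitly labelled with the agent's own motor state —
learning needs no external teacher. `perac` implements a perception-action
learning stack for this setting and studies one emergent consequence: after
learning to map what it *sees* to what it *does*, the agent can re-identify
*who* it interacted with, without identity ever being a training target.

The package bundles four layers:

1. a reflex visual front-end (focus points and log-polar local views),
2. an incremental prototype network with a vigilance threshold,
3. least-mean-squares (Widrow-Hoff) conditioning from visual features to
   the motor internal state, with a leaky short-term memory and a
   winner-take-all readout,
4. a prediction-error novelty detector that recruits one "person neuron"
   per detected partner,

plus a parametric humanoid-avatar generator and the four-condition
recognition protocol with its statistics, so the whole study runs
end-to-end from a single seed with no external data.

## The visual front-end

A frame is reduced to `nPoints = 20` *local views*. Saliency is the
convolution of a difference-of-Gaussians filter (`dogSigma1 = 1`,
`dogSigma2 = 2` px) with the norm of the central-difference image gradient;
its local maxima sit on corners and line ends. Focus points are selected
greedily in decreasing saliency with Chebyshev non-max suppression
(`suppressionRadius = 6` px); ties break lexicographically by `(row, col)`
so the scan is deterministic, and zero-saliency background is never a
candidate. Around each focus point a log-polar view is sampled — 16 rings
growing geometrically from 1 to `rMax = 24` px by 16 uniform angles,
bilinear interpolation, border clamping. In this representation an image
rotation about the centre becomes a circular shift along the angle axis and
a change of apparent distance becomes a shift along the ring axis, which is
what makes the views tolerant to the partner's rotations and distance
changes.

All coordinates in the package are 1-based (rows, columns, postures
`1..5`, frame indices), the natural convention for R; the suppression and
tie-break rules are unaffected.

## Incremental prototype learning

Each view `I` is scored against every stored prototype `W_j` with a
normalized-L1 similarity,

    VF_j = max(0, 1 - mean(|I - W_j|)),

which is 1 exactly at a perfect match. If the best activity falls below
the vigilance `gamma = 0.92` the view is stored one-shot as a new neuron;
otherwise only the winner is averaged toward the view,

    W_k <- W_k + epsilon * (I - W_k) * (1 - VF_k),    epsilon = 0.1,

so close matches barely move a prototype while poorer matches average it
harder. Recruitment is the only way the bank changes size, hence the
neuron count never decreases. The vigilance sets the granularity of visual
memory: lower values recruit less and generalize more; the recruitment
count itself becomes a signal (see the novelty detector).

### Conditioning on gated activities

The functional form of the posture map is a linear Widrow-Hoff rule from
VF activities to the one-hot motor state. The package conditions on
*vigilance-gated* activities `H_gamma(a) * a` (entries below `gamma` are
zeroed) rather than raw ones, for two reasons. Numerically, the raw
activity vector is dense — every prototype is somewhat similar to every
view — so its squared norm grows linearly with the bank and the LMS step
`rate * ||a||^2` leaves its stability region once a few hundred neurons
exist; the gated vector keeps a handful of active entries regardless of
bank size. Conceptually, recruitment guarantees that every view has at
least one supra-threshold activity (a fresh recruit scores 1), so gating
never starves learning. The same gate is applied at recognition time.

`lmsRate = 0.05` and the STM retention `stmDecay = 0.7` (a leaky
integrator `s <- 0.7 s + 0.3 x`, i.e. a memory of roughly three frames)
are the remaining conditioning parameters.

## Novelty detection and the emergent person code

During learning the stack continuously predicts the current posture; the
scalar frame error is the Euclidean distance between the mean predicted
activation and the true one-hot, normalized by `sqrt(2)` to sit in
`[0, 1]`. Two detectors watch for the *rising edge* of unexpectedness that
a new partner produces, and either may fire (they share one refractory
period of `noveltyRefractory = 15` frames):

* **Error channel.** `E(t)` is a 10-frame sliding mean of the error,
  `V` a leaky integration (`noveltySmoothing = 0.9`) of its negative
  gradient — the quantity learning progress is proportional to. A one-step
  drop of `V` exceeding `noveltyThreshold = 0.05` marks an error rising
  edge. The exponential form of `V` is the package's own concrete
  choice for a quantity the classic presentations of this detector
  leave unspecified, and should be read as such.
* **Visual-feature channel.** A view is an *outlier* when no prototype
  recognizes it above the vigilance; its magnitude is the depth beyond the
  vigilance band. The channel statistic is the frame mean of that excess,
  measured against the prototypes recruited during the trailing
  `noveltyContextWindow = 20` frames — the agent's recent perceptual
  context — rather than the whole long-term bank. This distinction
  matters: as the bank grows it eventually covers view space densely
  enough that even a brand-new partner's views match *something* learned
  long ago, and any whole-bank statistic fades with library size; novelty
  relative to the recent context does not. The channel fires when the
  statistic exceeds its own trailing 10-frame mean by
  `noveltyVfThreshold = 0.012`, i.e. 15% of the vigilance bandwidth
  `1 - gamma`. The context window covers several full passes through the
  posture repertoire, so posture recurrence is not mistaken for partner
  novelty.

The first frame always fires a baseline event — no edge can precede the
first partner. Each event recruits one person neuron (a new zero row of a
second Widrow-Hoff map), and from then on every view's gated activity
vector is conditioned toward the current person on every frame. Person
identity is therefore never supervised: the number of person neurons, and
which frames each one absorbs, are entirely a product of self-assessment.

## The synthetic partner panel

The generator emulates a panel of 12 highly similar white humanoids whose
arm length (28/36/44 px), torso width (18/26 px) and head radius
(8/12 px) are crossed systematically — morphological individuality on a
shared body plan. Two further choices give the renders the statistical
structure of short interaction videos:

* **A static per-avatar body texture** (low-pass-filtered noise, blob
  scale 2.5 px, amplitude 0.2 about a body gray of 0.65) rigidly attached
  to the body. Real partners carry surface structure (clothing, shading)
  that morphology alone cannot stand in for at 128x128; the amplitude was
  chosen so that inter-avatar local-view distances clear the vigilance
  band `1 - gamma = 0.08` while intra-avatar distances under jitter stay
  well inside it. Much below that the texture is functionally invisible
  to the architecture; much above it recognition saturates at 100% and
  the protocol's contrasts degenerate into ties.
* **Apparent-distance variation**: each block follows a slow reflected
  random walk of the figure scale in `[0.85, 1]` (step sd 0.015) plus
  independent per-frame scale noise (sd 0.02). Without any within-partner
  appearance variability, trained and held-out frames are statistically
  identical and the known/unknown contrast the protocol is built around
  cannot exist; the iid component keeps single-frame errors uncorrelated
  in time, which is the regime in which the short-term memory helps
  ordered presentations.

Per-frame jitter adds ±2 px translation, ±3° limb-angle noise and
Gaussian pixel noise (sd 0.02). Postures are held for seeded runs of 5-15
frames, cycling through shuffled repertoire passes so every posture
recurs throughout each block. Every generator output is a pure function
of its seeds.

What the generator does *not* emulate: articulated 3-D bodies and
perspective, posture transition frames, backgrounds and lighting, or any
behavioural individuality (timing, sloppiness of imitation). Passing
tests therefore demonstrate the architecture's behaviour under controlled
morphological/textural identity and distance variation — not performance
on real video.

## The experimental protocol

A session renders one contiguous block of 200 frames per partner. The
learning phase sees the 1-in-10 temporal subsample (20 frames per
partner, mirroring a system that samples 1 image in 10 from video); the
9/10 complement is the held-out "unknown" pool. After learning the model
is frozen — no recruitment, no weight updates — and each partner is
tested under four conditions: known/unknown crossed with random/ordered
presentation, 100 images each. Small known pools are resampled with
replacement (flagged). The same seeded draw underlies the random and
ordered batteries of a pool, so one is a permutation of the other; the
STM is active only in the ordered conditions and is reset between
batteries to prevent cross-condition leakage. Scores are percent correct
per partner and condition; chance is exactly `100 / N`. The statistics
layer provides exact one-sided binomial tests against chance, 10,000-rep
percentile bootstrap intervals for condition means, and the signs of the
two planned contrasts (known - unknown, random - ordered). No multiple-
testing correction is applied, matching the protocol's use of raw
binomial p-values.

## Numerical and design notes

* Degenerate inputs: a blank frame (no positive saliency) is an error at
  training time; recognition of an empty image list is an error; an
  all-zero person activation resolves by the WTA tie rule to the first
  person.
* All ties (WTA, focus competition) break toward the smallest index for
  determinism; two runs from one seed are bit-identical.
* The learning engine mutates pre-allocated weight matrices in place
  (capacity doubling) and is repacked into immutable S4 objects at the
  API boundary; compiled code handles the activity inner loop.
* Checkpoints serialize to JSON at full double precision and reload
  bit-exactly.
* Problem sizes in the shipped tests: the reference benchmark is the
  full 12-avatar session (2400 frames, 240 learned); unit tests use 1-3
  small avatars at 64x64 with 10-60 frames per block.

## Known limitations

* The novelty thresholds are calibrated in the units of the view
  similarity; panels much less separable than the default one (e.g.
  texture amplitude below ~0.15 at these sizes) lose late partner
  switches first — the event count then undercounts the panel, and
  partners sharing a person neuron drag all four condition scores down.
* Person neurons are recruited only; there is no merging, forgetting, or
  open-set rejection of an unknown partner.
* The posture map's error channel rarely fires on this synthetic panel
  because posture prediction transfers well across partners; partner
  detection is carried almost entirely by the visual-feature context
  channel. On data where posture styles differ per partner the error
  channel would contribute more.

## A worked run

```{r}
library(perac)

cfg <- peracConfig(seed = 1)
experiment <- runExperiment(avatarGrid(), cfg)

experiment                      # mean score per condition
summarizeExperiment(experiment) # bootstrap CIs and binomial p-values
contrastCheck(experiment)       # directions of the two contrasts

model <- experiment@model
nNeurons(model)                 # recruited visual-feature prototypes
nPersons(model)                 # one person neuron per partner
model@novelty@events            # partner-switch detections
```
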