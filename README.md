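# kinedetect

Biomechanics-aware detection and localization of movement-related
injury events in skeletal motion-capture data.

Athletes' injuries often surface as dysfunctional motion dynamics —
transient velocity excursions, abnormal force absorption at a joint —
before any structural damage is visible. `kinedetect` is for
biomechanists, sports-medicine researchers and methods developers who
have joint trajectories (and optionally co-registered sensor streams)
and want a calibrated, interpretable answer to *whether*, *where* and
*when* a movement went wrong.

## The method

Motion is a tensor `X ∈ R^{T×J×D}` of joint positions at uniform
sampling. The pipeline:

1. **Kinematics** — velocity, acceleration and jerk by finite
   differences: `V_t = (X_t − X_{t−1})/Δt`, and so on.
2. **Mechanical energy** — per joint and frame,
   `E_t^j = ½ m_j ‖V_t^j‖² + m_j g h_t^j`.
3. **Anomaly scoring** — deviation from a reference window of normal
   motion, `S_t^j = |E_t^j − E[E^j]|`, and a z-score against
   corpus-level statistics, `z = (E − μ_E)/σ_E`. Cells with
   `|z| ≥ 2.5` are flagged (98.8% two-sided Gaussian coverage), and a
   sigmoid confidence weight `β = 1/(1+e^{−z})` (0.5 at typical
   behavior) attenuates unreliable joints' features.
4. **Spatial encoding** — graph convolution over the anatomical
   skeleton, `H^{(l+1)} = σ(D^{-1/2} A D^{-1/2} H^{(l)} W^{(l)})`,
   plus joint-level softmax attention over each neighborhood.
5. **Temporal encoding** — sinusoidal positional encoding and scaled
   dot-product self-attention `softmax(QKᵀ/√d′)V`, with smoothness and
   lag-k contrastive representation losses.
6. **Adaptive sensor fusion** — vision / IMU / plantar-pressure
   channels projected to a shared space and combined with softmax
   attention weights `α_i` from a shared scoring function with a
   causal temporal-context vector; a corrupted modality loses weight.
7. **Classification** — a two-layer perceptron on the attended
   embedding concatenated with the anomaly scores, per frame; the
   sequence probability is the temporal mean. Training combines
   cross-entropy with a temporal-consistency loss family
   (`L_total = L_class + λ₁L_consistency + λ₂L_smoothing + λ₃L_reg`)
   that suppresses one-frame spurious detections.

A seeded synthetic gait simulator (periodic multi-joint motion,
injectable raised-cosine injury events, three degradable sensor
modalities) provides a fully reproducible test substrate. See the
methods vignette (`vignettes/injury-detection-methods.Rmd`) for the
model details, defaults and design rationale.

## Worked example

```r
library(kinedetect)

## a labeled synthetic corpus: 60 gait sequences, half with an injected injury
corpus <- makeCorpus(syntheticSpec(nSequences = 60, seed = 7))
graph  <- corpus$graph

## pick the first injured sequence; its ground truth:
i   <- which(corpus$labels == 1L)[1]
ann <- corpus$annotations[[i]]
jointNames(graph)[ann$joint]   # "spine"   (injected joint)
ann$onset                      # 37        (event onset frame)

seq <- corpus$sequences[[i]]
seq
#> MotionSequence: 50 frames x 15 joints x 3D, 25 Hz (2 s)
#>   joints: pelvis, spine, head, l_shoulder, l_elbow, l_wrist ...

## energy profile and anomaly map, calibrated on the normal sequences
E <- totalEnergy(computeKinematics(seq), seq, graph)
stats <- energyStats(lapply(corpus$sequences[corpus$labels == 0L],
                            function(s) totalEnergy(computeKinematics(s), s, graph)))
sc <- scoreSequence(E, stats)
sc
#> AnomalyScores: 50 frames x 15 joints, |z| >= 2.5
#>   13 flagged cells, max |z| = 24.45
head(flagAnomalies(sc@z)$summary, 3)
#>   frame joint        z
#> 1    39     2 24.45323
#> 2    40     2 22.65464
#> 3    43     2 10.71018
```

The top-ranked cells sit at joint 2 (the spine) around frame 39 —
inside the injected event window starting at frame 37. The z value
says the spine's mechanical energy is 24 standard deviations above its
normal-corpus mean at the event peak.

```r
## train the detector end to end and evaluate on the held-out split
model <- trainDetector(corpus, detectorConfig(), seed = 1)
ev <- evaluateOnCorpus(model, corpus)
#> validation: accuracy 0.833 recall 0.667 F1 0.800 AUC 0.864

predictDetector(model, seq)
#> Predictions: 50 frames, sequence p = 0.5141, label 1 (threshold 0.50)
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/kinedetect`
(subcommands `simulate`, `features`, `score`, `train`, `detect`,
`eval`; global `--seed`, `--config`, `--out`, `--verbose`):

```sh
Rscript -e 'quit(status = kinedetect::cliMain(commandArgs(TRUE)))' \
  simulate --seed 7 --out corpus/
```

Every run writes a manifest JSON recording the resolved configuration
and its hash; identical configuration and seed reproduce outputs
byte-for-byte.

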