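# lusBline

Frame- and clip-level classification of A-line versus B-line artifacts
in lung ultrasound (LUS).

## The problem

On lung ultrasound, *A lines* (horizontal reverberations of the pleural
line) indicate normally aerated lung, while *B lines* (vertical rays
from the pleural line to the far field) indicate abnormal,
alveolar-interstitial parenchyma. Telling the two apart is the backbone
of point-of-care respiratory decision making, but the clinical question
is asked of a video clip while supervised learning happens on frames —
and in many pathological clips the B lines come in and out of view with
tidal respiration, so most frames of a B-positive clip look normal.

`lusBline` is for researchers building or studying automated LUS
interpretation pipelines. It provides the full chain:

* a **synthetic sector-scan phantom** (`generateFrame`, `generateClip`,
  `generateCohort`) with controllable artifact content, severity
  (mild = fewer than 3 B lines; moderate/severe split at 50% coverage of
  the pleural line), within-clip heterogeneity and patient grouping —
  so every stage is testable without patient data;
* **beam masking and stochastic augmentation** (`applyMask`,
  `augmentFrame`): rotation ±45°, shifts ±10%, zoom ±10%, one-sided 10°
  shear, horizontal flips, ±30% multiplicative brightness;
* **patient-grouped, leakage-free K-fold bookkeeping** (`makeFolds`,
  `routePools`): all clips of a patient stay in one set, and frame
  training only ever sees homogeneous clips disjoint from the
  clip-inference pool;
* a **truncated-VGG frame classifier** (`buildFrameClassifier`,
  `trainFrameClassifier`, `predictFrames`): the first three VGG16
  blocks — (2, 2, 3) convolutions of (64, 128, 256) 3×3 filters, the
  third max-pool removed — with a global-average-pooling + dropout +
  2-node softmax head emitting `p = [pA, pB]` per frame (1,734,850
  parameters at 128×128; compact single-precision Rcpp backend);
* the **clip-level contiguity rule** (`classifyClip`): a clip is
  B-positive iff at least one run of `tau` consecutive frames has
  `pB >= t`,

  ```
  y = 1[ OR_{i=1..n-tau+1} AND_{j=i..i+tau-1} ( pB_j >= t ) ]
  ```

  plus the clip-averaging baseline (`classifyClipAveraging`), the full
  `(t, tau)` sensitivity/specificity sweep (`thresholdSweep`,
  `plotSweep`) and operating-point selection (`selectOperatingPoint`);
* **evaluation** (`rocAuc`, `confusionCounts`, `metricReport`,
  `aggregateFolds`) and **Grad-CAM explainability** (`gradCAM`,
  `renderOverlay`).

## Worked example

Why clip averaging fails on heterogeneous clips, and what the
contiguity rule does about it:

```r
library(lusBline)

cfg  <- phantomConfig(imageHeight = 64L, imageWidth = 64L)
clip <- generateClip(cfg, clipId = "demo", patientId = "P001", "B",
                     severity = "moderate", homogeneity = "heterogeneous",
                     nFrames = 60L, seed = 7)
clip
#> LUSClip demo (patient P001)
#>   60 frames of 64 x 64 | B / moderate / heterogeneous
#>   B frames: 19 of 60

# ground-truth frame probabilities: B lines visible in 19 of 60 frames
pB <- ifelse(frameLabels(clip) == "B", 0.95, 0.05)

classifyClipAveraging(pB, 0.5)
#> ClipDecision NA : A (t = 0.50, tau = 1)

classifyClip(pB, t = 0.7, tau = 3)
#> ClipDecision NA : B (t = 0.70, tau = 3)
#>   triggering window: frames 15 - 17
```

The clip truly contains B lines, but they are visible in only 19 of 60
frames, so the mean probability (0.33) stays below 0.5 and averaging
calls the clip normal — a false negative. The contiguity rule finds the
first run of 3 consecutive B frames (frames 15–17) and calls it
B-positive. `thresholdSweep()` maps sensitivity and specificity over
the whole `(t, tau)` grid so the operating point can be matched to the
clinical use case, and `runExperiment()` drives the entire pipeline
(cohort → pools → grouped folds → training → frame metrics → sweep)
from one seeded configuration or YAML file.

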