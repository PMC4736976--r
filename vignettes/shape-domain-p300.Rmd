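---
title: "Shape-domain P300 detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-domain P300 detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpshape)
```

## The problem and the model

A P300 speller must decide, from a short EEG epoch following a stimulus,
whether the stimulus was the attended (rare) one. The premise of this
package is that a subject's P300 has a *consistent waveform*, so the
decision can be made in the shape domain: represent each trace by a short
symbolic description of its contour, build a per-subject template shape,
and classify candidates by their similarity to it.

The pipeline is:

1. **Conditioning** — zero-phase 4th-order Butterworth band-pass
   (0.1–12 Hz by default), DC removal, linear detrend, per trial and
   electrode.
2. **Coherent averaging** — the pointwise mean of `k` time-locked trials;
   background EEG, not being stimulus-locked, shrinks roughly as
   `1/sqrt(k)` while the P300 persists.
3. **SHCC encoding** — the averaged curve is resampled to `S + 1` of its
   own samples (spacing `Δ = T/(S+1)`, endpoints snapped, no
   interpolation), min–max normalized to the unit square, and each
   segment coded by its inclination over 90°, quantized to two decimals.
4. **Shape features** — per-segment trapezoid area differences against the
   template, their absolute sum, the `l1` chain distance, the candidate
   chain's tortuosity, and the candidate symbols: a `(2S+2)`-vector.
5. **Calibration** — the wrapper described below selects electrodes,
   templates, features and the optimum stimulation count per subject.
6. **Classification/validation** — SWLDA (stepwise-selected least-squares
   discriminant, threshold at the midpoint of class-mean scores) or a
   linear SVM, evaluated on balanced sets of held-out `K`-trial averages.

### Assumptions

- The P300 waveform is reproducible within a subject up to latency jitter
  and additive background activity; electrodes differ mainly in how
  strongly they pick the component up.
- Amplitude information may be discarded: the min–max normalization makes
  the code translation- and scale-free in `y`, so detection rests purely
  on contour. (This also makes the code sensitive to outliers that
  stretch the normalization; band-passing and averaging mitigate this.)
- Trials are exchangeable within a class, so uniform random subsets are
  valid for template building and cross-validation.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `S` | 16 | segments | chain length; 16 = `floor(800 ms × 20 Hz / 1000)`, a 20 Hz shape-preserving resampling of an 800 ms epoch (ERP content ≤ ~10 Hz, Nyquist ×2) |
| `A` | 180 | trials | P300 trials averaged per template; large enough that template noise is negligible while leaving trials for folds |
| `K` | 15 | stimulations | maximum per-candidate averaging depth; decremented during calibration |
| `O` | 10 | templates | candidate templates per electrode; bounds runtime at `U·O·C` extractions per `k` |
| `auroc_accept` / `auroc_fallback` | 0.8 / 0.6 | — | electrode-selector thresholds on the mean AUROC φ |
| `p_enter` / `p_remove` | 0.1 / 0.15 | — | stepwise-regression entry/removal p-values |
| `max_folds` | 20 | folds | cap on `U = floor((P − A)/k)`, recomputed at every `k`; 20 is its value in the reference regime (`floor((480 − 180)/15)`) |
| `mode` | `"angle"` | — | chain symbol convention (see below) |

## The calibration wrapper

For each stimulation count `k = K, K−1, …`: every electrode gets `O`
templates (coherent averages of `A` random P300 trials, encoded to
chains). Each template is scored over `U` folds: a fold averages `k`
fresh P300 trials (disjoint from the template and from other folds) and
`k` non-P300 trials, extracts both shape-feature vectors, and the
template's AUROC is computed from the chain-distance components of the
`U` P300 and `U` non-P300 vectors, oriented so that smaller P300
distances score toward 1. Stepwise regression reduces each template's
`2U × V` block. Electrodes with mean AUROC `φ ≥ 0.8` keep the loop
running at `k − 1`; when none passes, the profile from the smallest
passing `k` is returned. If no `k` ever passes, electrodes with
`φ > 0.6` are returned with a `fallback` status, and otherwise the
subject is declared `unsuitable`.

Two readings of the optimum stimulation count are possible from the
method's description ("K − 1" vs the last passing `k`); the package
records `K' =` the smallest `k` at which the acceptance condition still
held, and stores the full φ-vs-k trace in the profile so the other
reading is recoverable.

Stepwise selection is refit per template; the returned mask/weights are
those of the template with the highest AUROC per electrode (ties toward
the lowest template index, for determinism). A related published figure
of "38 features per electrode" is not derivable from the 34-component
vector and is not emulated.

## Numerical choices and degenerate inputs

- **Resampling indices** are `round(1 + mΔ)`, `m = 0..S`, clipped to
  `[1, T]`; at `S = T − 1` (`Δ = 1`) every sample is kept. Rounding is
  half-away-from-zero, the same symmetric rule used to quantize symbols,
  so positive and negative slopes are treated identically.
- **Flat curves**: if an axis has zero range, min–max normalization maps
  it to zeros rather than dividing by zero, so an all-zero epoch encodes
  to the all-zero chain (tortuosity 0).
- **Symbol saturation**: near-vertical segments at large `S` could round
  to ±1.00; symbols saturate at ±0.99 to stay inside the open alphabet.
  The two-decimal alphabet strictly inside (−1, 1) has 199 values.
- **Symbol convention**: the default `"angle"` mode codes
  `atan(dy/dx)/90°` on the unit square. A `"rise"` mode (normalized rise
  per segment, unit width) is kept behind a switch because the printed
  example chains have small magnitudes that the angle reading does not
  obviously produce; the raw curves behind them are not available, so the
  convention cannot be settled empirically. All shipped golden values
  operate on printed chains and are convention-independent.
- **Trapezoid count**: the vector layout requires `S − 1` area
  differences; they are the trapezoids over consecutive pairs of the
  first `S` normalized points. This keeps `V = 2S + 2 = 34` at `S = 16`.
- **AUROC** is the rank-based Mann–Whitney form; ties contribute ½. It is
  invariant under strictly monotone transforms of the pooled distances.
- **Stepwise regression** enters the candidate with the smallest
  partial-F p-value (`< p_enter`) and removes the worst retained term
  (`> p_remove`), iterating to a fixed point; constant columns are
  skipped with a note; ties break toward the lowest column index. With
  `p_enter < p_remove` a just-entered term is never immediately removed;
  a cycle guard caps iterations regardless.
- **SWLDA intercept**: the decision threshold is the midpoint of the
  projected class means — natural for the balanced training sets this
  pipeline produces, and left explicit because the method description
  never fixes an intercept.
- **Seeds**: every randomized operator (template selection, folds,
  balanced validation draws, the leave-one-out SVM pick) derives its own
  seed from the master seed by a fixed integer recurrence, so whole-run
  results are bit-reproducible and individual operators remain
  independently reproducible.

## The synthetic generator

`simulate_dataset()` emulates the reference acquisition regime: 10
electrodes (Fz, C4, Cz, C3, P4, Pz, P3, PO8, Oz, PO7) at 256 Hz, 800 ms
epochs (`T = 204`), 480 P300 + 2,400 non-P300 training trials and
150 + 750 validation trials. P300 epochs add a positive Gaussian
deflection (latency 350 ms, jitter SD 20 ms, width SD 45 ms) scaled per
electrode; background EEG is Gaussian noise band-limited to 0.1–12 Hz,
synthesized as one continuous stream per electrode and sliced into
epochs — the data are modeled *post*-conditioning, since the notch and
acquisition filters act before data ever reach this pipeline.

Defaults: peak amplitude 8 µV with per-electrode profile
`(1, 1, 1, ½, ½, ½, ½, 0, 0, 0)` — three full-amplitude, four attenuated,
three silent electrodes, mimicking distance-dependent attenuation and
giving recovery tests a known answer — and background SD 2 µV. The
default thus represents a favorable, artifact-free post-filter SNR under
which the full-amplitude electrodes are a high-SNR reference subject
(coherent averages of 180 trials correlate ≥ 0.95 with the injected
deflection); raising `noise_sd_uV` toward 10 µV gives realistic
single-trial SNR below 1 — a useful stress setting under which the
acceptance threshold is no longer a foregone conclusion.
An optional two-bump mode adds an echo one interstimulus interval
(125 ms) later, mimicking overlapping responses; it is provided but not
used by default.

What the generator does **not** model: 1/f spectra, alpha rhythm,
blink/muscle artifacts, inter-electrode correlation, non-Gaussian
outliers, or latency drift across the session. Passing recovery tests on
this generator therefore shows the algorithmic chain is correct and
self-consistent — not that the method attains any particular accuracy on
real recordings.

## Problem sizes used by the test suite

Unit tests run the pipeline on miniature subjects (tens of trials, 2–3
electrodes, `S = 6–8`). The end-to-end recovery checks use the full
reference regime — `P = 480`, `N = 2400`, `A = 180`, `K = 15`, `O = 10`,
10 electrodes — once for a high-SNR subject (three 8 µV electrodes over
2 µV noise: calibration must select exactly those three with φ ≥ 0.8)
and once for a null subject (zero amplitude everywhere: φ stays within
0.5 ± 0.1 and the unsuitable branch triggers). These sizes keep the whole
suite to a few minutes while exercising every operator at scale.

## Known limitations

- The chain-symbol convention ambiguity above; both modes are provided.
- Validation defaults to per-electrode classification; a concatenated
  mode (one vector joining all selected electrodes) is available via
  `electrode_mode = "concatenated"` where a single pooled decision is
  wanted.
- The package does not read vendor EEG formats (EDF/BDF/GDF); convert
  externally to the delimited epoch format.
- Online/real-time operation and speller-matrix integration are out of
  scope; the package is an offline research implementation.
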