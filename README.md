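# tfseize

Seizure detection in newborn EEG from **adaptive directional
time–frequency marginal features**.

Neonatal seizures show up in the time–frequency (TF) plane as ridges with
a very specific geometry: trains of spikes produce ridges parallel to the
frequency axis, and rhythmic discharges — sums of harmonically related
FM chirps with a slowly varying fundamental below ~4 Hz — produce ridges
parallel to the time axis. Background activity produces ridges in random
directions. `tfseize` turns that observation into a segment classifier:

1. average the channels, decimate to 32 Hz, first-difference;
2. compute the Wigner–Ville distribution (WVD) of the analytic signal,
   `W(t,f) = ∫ z(t+τ/2) z*(t−τ/2) e^{−j2πfτ} dτ`;
3. smooth it adaptively with an oriented kernel
   `γ_θ ∝ exp(−a²t_θ² − b²f_θ²)(1 − 2b²f_θ²)` whose direction `θ(t,f)`
   follows the local ridge (argmax of the directional response over a
   3° grid), yielding the adaptive directional TFD `ρ(t,f)` with
   cross-terms suppressed;
4. gate `ρ` by ridge direction: `ρ_t` keeps 80° < θ < 100° (spikes),
   `ρ_f` keeps θ < 10° or θ > 170° (tones/chirps),
   `ρ_FIL = ρ_t + ρ_f`;
5. per 8-s segment, compute 18 features: quarter-integrals T1–T4 of the
   modified time marginal `s(t) = ∫ρ_t df`, band integrals F1–F6 of the
   modified frequency marginal `s(f) = ∫ρ_f dt` over
   (0–1, 1–2, 2–3, 3–4, 4–8, 8–16) Hz, and statistics TF1–TF8 of
   `ρ_FIL` (mean, sd, CV, skewness, kurtosis, flatness, energy
   concentration, flux);
6. classify segments with a 500-tree random forest, evaluate with
   leave-one-patient-out cross-validation, smooth decisions with a
   5-tap median filter (≥ 3 of 5) and extend detected seizure runs by
   8 s at each end.

A seeded synthetic generator (spike trains, harmonic FM chirp sums, pink
background noise, multi-channel multi-patient recordings with
annotations) makes every stage testable without any external data, and
minimal EDF + delimited-text readers/writers cover interchange.

## Worked example

A single slow FM chirp (fundamental sweeping 1 → 3 Hz over 8 s) is the
rhythmic-seizure model; its feature vector shows the expected signature:

```r
library(tfseize)
x  <- gen_chirp_sum(cbind(c(0, 8), c(1, 3)), n_harmonics = 1,
                    rate = 32, duration = 8)
round(extract_features(x), 4)
#>      T1      T2      T3      T4      F1      F2      F3      F4      F5      F6
#>  0.0244  0.0000  0.0000  0.0431 -0.0400  0.2236  0.2455 -0.0525  0.0000  0.0002
#>     TF1     TF2     TF3     TF4     TF5     TF6     TF7     TF8
#>  0.0035  0.2394 69.2261  5.4381 66.0162  0.0000  7.0222  1.2239
```

The energy sits in F2/F3 (the 1–3 Hz bands swept by the chirp) while the
spike features T1–T4 are near zero; the high TF3/TF5 values say the
filtered distribution is sparse and heavy-tailed, as a clean ridge should
be. The fraction of smoothed TF energy surviving the ridge gates —
the seizure/background contrast — is

```r
r <- compute_adtfd(x)
energy_retention(r$tfd, r$dmap)
#> [1] 0.774
```

(background noise scores ~0.27 on the same measure).

The full synthetic study — 6 patients, 192 s each, spike-train and
chirp-sum seizures against pink noise — runs end to end in a few
minutes:

```r
recs <- gen_recording(seed = 1)
feats <- do.call(rbind, lapply(recs, extract_recording_features))
cv <- seizure_loocv(feats, seed = 1)
summary(cv)
#> Pooled metrics over all test segments:
#> sensitivity specificity    accuracy   precision          f1
#>      1.0000      0.8182      0.9167      0.8667      0.9286
```

Sensitivity is perfect and the specificity/precision cost is exactly the
two extension segments added around each detected seizure run — the
intended trade-off of the boundary-extension step.

## Command line

A thin CLI over the same functions is installed at
`inst/scripts/tfseize`:

```sh
tfseize simulate --out data/ --seed 1
tfseize features --rec data/P01.edf --ann data/annotations.csv --out P01.csv
tfseize loocv    --features all.csv --out pred.csv
tfseize eval     --pred pred.csv --truth data/annotations.csv
tfseize tfd      --rec data/P01.edf --out tfd.csv --segment 7 --plot tfd.png
```

## Scope

The published real-data evaluation (36-newborn database, ~16 h of EEG)
requires an external download and is out of scope for the test surface;
the EDF reader, annotation format and CLI provide the plumbing to run
it. See `vignettes/adtfd-seizure-detection.Rmd` for the model details,
parameter choices and known limitations.
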