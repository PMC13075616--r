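# iednet

Spectral and network analysis of **scalp-negative interictal epileptic
discharges (IEDs)** — medial temporal spikes that are conspicuous on
intracranial EEG (iEEG) but stay below the noise floor of simultaneous
scalp EEG. The package asks, and answers on synthetic cohorts with a known
ground truth, the question such recordings pose: do these "invisible"
discharges change band power, phase-locked activity, and the topology of
large-scale phase-coupling networks?

## Who this is for

Researchers analyzing simultaneous scalp/intracranial recordings (or any
spike-locked multichannel electrophysiology) who need a tested, seeded,
end-to-end chain from raw signals to group statistics — and a generator of
realistic surrogate cohorts to validate it against.

## What it computes

For each patient, condition (`IED` vs `no_IED`, balanced trial counts) and
unit system — bipolar iEEG channels, iEEG aggregated to atlas regions
("iEEG(ROI)"), and source-reconstructed scalp regions ("hdEEG(ROI)"):

- **Preprocessing**: EDF I/O, downsampling to 200 Hz, zero-phase 4th-order
  Butterworth band-pass 1–35 Hz, common-average or bipolar re-referencing
  (pairs kept if ≥ 1 contact is in gray matter).
- **Adaptive windows**: five cycles of the band's lowest frequency
  (5 s for delta [1–4 Hz]), discharge peak at 3/8 of the window, Tukey
  taper (r = 0.25) whose flat top covers the peak.
- **Time–frequency maps**: generalized Morse wavelet (γ = 3, P² = 40,
  10 voices/octave, 1–40 Hz) with cone of influence; ERSP in dB against a
  common control baseline, and inter-trial coherence
  ITC(f,t) = |mean_k exp(i·arg W_k(f,t))|.
- **Band measures**: tapered periodogram power density and spectral ITC,
  averaged within delta/theta/alpha/beta.
- **Connectivity**: weighted phase lag index
  wPLI_ij(f) = |Σ_k Im S_k,ij| / Σ_k |Im S_k,ij|, across trials per bin,
  band-averaged — blind to zero-lag leakage by construction.
- **Networks** (weighted, unthresholded): Onnela clustering coefficient
  (segregation) and nodal/global efficiency with lengths 1/w (integration).
- **Group statistics**: cluster-based sign-flip permutation tests on the
  hippocampal ERSP/ITC maps (2⁹ = 512 exhaustive flips for nine patients;
  cluster-forming p = 0.0005/0.05, cluster p = 0.001/0.05 for ERSP/ITC),
  one-sided exact Wilcoxon signed-rank tests, and Benjamini–Hochberg FDR
  per measure family, with region tests gated to regions sampled in ≥ 5
  patients.

A synthetic cohort generator (`synth_config()`, `generate_patient()`,
`synth_cohort()`) programs the ground truth: 1/f backgrounds, a
spike-and-slow-wave transient in the ipsilateral hippocampus rescaled to
stay below the scalp noise floor, and band-limited couplings with known
phase lags whose gain rises during discharge epochs. See the methods
vignette (`vignettes/iednet-methods.Rmd`) for the model, parameter
defaults and design rationale.

## Worked example

```r
library(iednet)

cfg <- synth_config(seed = 42)      # nine-patient study conditions
p   <- generate_patient(cfg, 1)
p$ieeg
#> <recording> 28 channel(s) x 108000 samples @ 400 Hz (intracranial, raw)

ie <- preprocess(p$ieeg)            # downsample, filter, bipolar montage
ie
#> <recording> 14 channel(s) x 54000 samples @ 200 Hz (intracranial, bipolar)

theta <- band_specs()[2, ]
win <- build_window(theta, ie$fs)
win
#> <analysis_window> theta [4-8 Hz]: 250 samples @ 200 Hz, peak at 94

ep <- extract_epochs(ie, p$events, win, "IED")
W  <- wpli(trial_cross_spectra(ep, theta))
round(W[c("S09C1-S09C2", "S12C1-S12C2", "S11C1-S11C2"),
        c("S09C1-S09C2", "S12C1-S12C2", "S11C1-S11C2")], 3)
#>             S09C1-S09C2 S12C1-S12C2 S11C1-S11C2
#> S09C1-S09C2          NA       0.390       0.534
#> S12C1-S12C2       0.390          NA       0.583
#> S11C1-S11C2       0.534       0.583          NA

network_metrics(W)
#> <network_metrics> 14 node(s): segregation 0.3782, integration 0.2857
```

The three channels shown are the hippocampal, amygdalar and fusiform
bipolar derivations — members of the theta coupling clique programmed into
the generator, hence theta wPLI well above the ~0.2 noise floor of a
20-trial estimate. Repeating the last three steps with `"no_IED"` epochs
gives segregation 0.2904: the discharge-locked gain increase raises
network segregation, which is what the group tests quantify across
patients.

The full chain (per-patient analysis of all three unit systems, cluster
tests, Wilcoxon + FDR tables) is one call:

```r
res <- run_pipeline(synth_config())
res$roi_tests       # region x band x measure, FDR-adjusted
res$network_tests   # whole-network segregation/integration per band
res$cluster_tests   # hippocampal ERSP/ITC sign-flip cluster tests
write_results(res, "out/")
```

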