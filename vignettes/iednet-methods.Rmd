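---
title: "Spectral and network analysis of scalp-negative interictal discharges: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral and network analysis of scalp-negative interictal discharges: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Interictal epileptiform discharges (IEDs) arising in medial temporal
structures -- hippocampus and amygdala -- are often invisible on scalp EEG:
the generating cortex is deep, small, and unfavourably oriented, so the
scalp projection of the spike stays below the background noise. Simultaneous
intracranial EEG (iEEG, depth macroelectrodes) and high-density scalp EEG
make it possible to mark these *scalp-negative* IEDs on the intracranial
traces and then ask what, if anything, they change in the signals that
*are* observable at large scale: band-limited spectral power, phase-locked
(evoked) activity, and the topology of phase-coupling networks.

`iednet` implements that analysis chain end to end, together with a
synthetic cohort generator that reproduces the statistical structure the
chain assumes -- so every stage can be verified against a programmed ground
truth without any patient data.

## Analysis model

### Epochs and adaptive windows

Events are markers of two conditions, `IED` and `no_IED`, balanced to an
equal trial count per patient by seeded subsampling. Two epoch families are
used:

* **Time-frequency epochs**: discharge trials span $-2$ to $+3$ s around
  the intracranial spike peak; control trials span $\pm 2.5$ s around their
  marker. No taper -- wavelet edge effects are tracked by the cone of
  influence (COI).
* **Band analysis windows**: for a band $[f_{low}, f_{high}]$ the window
  holds five cycles of $f_{low}$ ($n = \mathrm{round}(5 f_s / f_{low})$,
  e.g. 5 s for delta 1-4 Hz) and the discharge peak is placed at $3/8$ of
  the window, leaving more post-discharge than pre-discharge samples. A
  Tukey taper with cosine fraction $r = 0.25$ is applied; with $r = 0.25$
  the flat top spans $[1/8, 7/8]$ of the window, so the peak sample is
  untapered. (A Hann taper would attenuate the discharge itself.)

### Time-frequency maps

The generalized Morse wavelet with symmetry $\gamma = 3$ and time-bandwidth
$P^2 = 40$ is evaluated on a log axis of 10 voices/octave from 1 to 40 Hz.
The frequency response is peak-normalized to 2, so the analytic coefficient
of a unit sinusoid has magnitude 1; this makes coefficient magnitudes read
as amplitudes, and since both ERSP and the condition contrast are
baseline-relative, the normalization convention cancels in every reported
quantity. Per patient and condition,

$$\mathrm{ERSP}(f,t) = 10\log_{10}
  \frac{\overline{|W_k(f,t)|^2}}{B(f)}, \qquad
  \mathrm{ITC}(f,t) = \Big|\tfrac1N \sum_k e^{i\arg W_k(f,t)}\Big|,$$

where $B(f)$ is the mean control-condition power per frequency. Using one
common baseline for both conditions keeps the control map near 0 dB and
cancels exactly in the paired contrast, which is the quantity under test.
The COI half-width is the e-folding time of the wavelet envelope, computed
numerically once at 1 Hz and scaled as $1/f$; boundary pixels are flagged,
not removed.

### Band measures

Power is the one-sided periodogram density of the tapered trial,
$2|X(f)|^2 / (f_s \sum w^2)$, averaged across trials and across the FFT
bins whose centers fall in $[f_{low}, f_{high})$ -- half-open so the shared
edges 4, 8, 13 Hz are counted once. Spectral ITC is the per-bin resultant
length of trial phase vectors averaged over in-band bins.

### Connectivity: weighted phase lag index

$$\mathrm{wPLI}_{ij}(f) =
  \frac{\big|\sum_k \Im S_{k,ij}(f)\big|}{\sum_k |\Im S_{k,ij}(f)|},$$

estimated across trials per bin and averaged within the band. The
non-debiased estimator is used (recorded in the run log). Because only the
imaginary cross-spectrum enters, zero-lag mixing (volume conduction,
spatial leakage) cannot create spurious coupling; a numerical guard treats
bins whose imaginary mass is at machine rounding noise relative to the
pair's strongest in-band cross-magnitude as zero-lag (the $0/0 \to 0$
convention). Estimation across trials rather than across time is dictated
by the short band windows (five cycles of $f_{low}$).

### Networks

On the unthresholded weighted matrices (missing region pairs as weight 0):

* **Segregation**: Onnela's weighted clustering coefficient on the
  max-normalized matrix, $C_i = \sum_{jh}(\hat w_{ij}\hat w_{ih}\hat
  w_{jh})^{1/3} / k_i(k_i-1)$; mean over nodes. The weighted form is used
  because the matrices are unthresholded; the classic binary definition is
  recovered on 0/1 matrices.
* **Integration**: nodal efficiency with edge lengths $1/w$,
  $NE_i = \overline{1/d_{ij}}$; global efficiency is the mean of $NE_i$.
  Shortest paths are computed by Dijkstra (igraph); tests verify both
  metrics against exhaustive-enumeration oracles on all small graphs.

### Group statistics

* **Cluster-based sign-flip permutation tests** on per-patient map
  contrasts: one-sided paired $t$ per pixel, 4-connected clusters above the
  cluster-forming threshold ($p = 5\times10^{-4}$ for ERSP, $0.05$ for
  ITC), cluster mass = summed $t$, and a max-mass null over all $2^n$ sign
  flips for $n \le 20$ patients (512 for nine patients; the identity flip
  is included, so the smallest attainable $p$ is $1/2^n$). Cluster
  significance at $p < 10^{-3}$ (ERSP) and $p < 0.05$ (ITC). 4-connectivity
  is the conservative standard choice; clusters are formed over all pixels
  and their COI overlap is reported per cluster rather than used as a gate.
* **One-sided Wilcoxon signed-rank tests** (expectation of an increase
  during discharges) for band, region and whole-network measures, exact for
  $n \le 25$ via a dynamic-programming enumeration of the sign-flip
  distribution that remains exact under tied ranks; zero differences are
  discarded.
* **Benjamini-Hochberg FDR** at $q = 0.05$, per family: whole-network
  measures across the four bands; region measures across regions x bands.
  Region tests are restricted to regions sampled in at least five patients.

### Source reconstruction

The forward/inverse problem is consumed as input: any linear
sensors-to-sources operator with a source-to-region membership works. For
synthetic cohorts the operator is the ridge pseudo-inverse of the
generator's own mixing matrix, prewhitened with a diagonal sensor noise
covariance estimated from the control epochs, with $\lambda = 0.1$ of the
trace-normalized Gram diagonal; the common-average projection applied to
the data is also applied to the mixing before inversion. Each region is
summarized per epoch by the first temporal singular vector of its member
source series, scaled by the singular value, with the sign fixed to a
non-negative correlation with the region-mean series (the SVD sign is
otherwise arbitrary and would destroy phase locking across trials).
Computing the SVD per epoch keeps trials independent for ITC.

## The synthetic cohort

Each patient is generated from one root seed expanded into independent
per-component streams (events, sources, couplings, contacts, scalp), so a
cohort is bit-reproducible and the intracranial data do not change when the
scalp modality is skipped.

* **Background**: $1/f$ Gaussian noise per source (slope 1, SD 10 uV),
  matching the 2-30 Hz log-log periodogram slope to within the tested
  $\pm 0.3$.
* **Discharge**: a difference-of-Gaussians spike (70 ms, 150 uV) followed
  by a half-cosine slow wave (300 ms, 60 uV) added to the ipsilateral
  hippocampal source at every `IED` marker. Markers sit on a jittered grid
  with 6.5 s spacing so no analysis window overlaps two epochs.
* **Coupling**: per pair, a band-limited shared oscillation (white noise
  shaped by the forward-backward magnitude response of a 2nd-order
  Butterworth band-pass) added to both sources, one copy rotated by a
  constant phase via its analytic signal. Rotation in the analytic domain
  gives an exactly known, frequency-constant lag, verified to 0.01 rad.
  The default truth couples, per band, a hippocampus-anchored 4-region
  clique whose gain rises from 2 to 10 uV during discharge epochs, plus a
  condition-independent interhemispheric pair at 8 uV. The clique is what
  makes *both* network measures rise: triangles raise the clustering
  coefficient and short paths raise efficiency. The stationary backbone
  keeps the strongest matrix entry comparable across conditions -- Onnela's
  max-normalization otherwise *lowers* mean clustering when a handful of
  edges strengthen, which is a property of the metric, not of the data.
  Lags are spread over $(\pi/4, 3\pi/4)$, away from 0 and $\pi$ where
  lagged coupling is invisible to wPLI.
* **Scalp**: a random depth-attenuated mixing (medial temporal sources
  attenuated 20x) plus sensor noise; the discharge-source column is
  rescaled so the scalp transient peak is 0.5 background SDs
  (configurable, must be < 1). "Not visible" has no quantitative
  definition in clinical practice; the sub-1-SD margin is this package's
  operationalization, exposed as `scalp_negative_margin`.
* **Contacts**: every source is sampled by a two-contact depth shaft (deep
  gray-matter contact on the source, shallow white-matter contact at 0.2
  gain) sharing an amplifier reference that cancels in the bipolar
  derivation.
* **Sampling gate**: 12 core regions (bilateral lateral orbitofrontal,
  rostral middle frontal, inferior and middle temporal, hippocampus;
  ipsilateral fusiform and amygdala) appear in every patient; two extra
  regions per patient cycle through a pool of eight, so the "at least five
  patients" rule retains exactly the 12 core regions in the default
  nine-patient cohort.

### What the generator does not emulate

No head-model realism (depth attenuation is a single factor per source), no
realistic spike topographies, no arousal states, no artifacts, no bad
channels, no non-stationarity beyond the programmed gain switching.
Passing tests therefore demonstrate that the chain recovers effects of the
assumed structure at realistic SNR -- not that it is robust to everything
clinical data contain.

## Numerical and design choices

* Preprocessing order follows the described acquisition chain: downsample
  to 200 Hz, band-pass 1-35 Hz with a zero-phase 4th-order Butterworth
  (applied forward-backward in the frequency domain; identical to
  `filtfilt` away from the recording edges, and all epochs sit far from
  them), then re-reference (common average for scalp, bipolar for depth
  shafts). Anti-aliasing uses a zero-phase 8th-order Chebyshev-I at 0.8 of
  the output Nyquist.
* Bipolar pairs are retained if at least one contact is in gray matter;
  the pair's region is the gray member's, and the deeper (lower-index)
  contact wins when both are gray. Bad channels are dropped, not
  interpolated (synthetic data have none).
* `peak_index` uses round-half-up; the marker sample is the 1-based index
  `round(3/8 n)`.
* Both conditions are tapered identically in the band analyses.
* ERSP/ITC condition contrasts are formed by sample index (both epoch
  families are 5 s at 200 Hz), using per-patient maps as the paired unit.
* Cluster p-values compare the null to the observed mass with a relative
  tolerance of $10^{-9}$, since the identity flip recomputes the observed
  mass in a different summation order.

## Problem sizes

The default study conditions are nine patients, 20 epochs per condition,
270 s of recording at 400 Hz acquisition (downsampled to 200 Hz), 14
sources (12 core + 2 extras), 28 depth contacts and 32 scalp sensors per
patient. These sizes make a full cohort analysis run in about a minute
while leaving every estimate comfortably above its detection floor; the
acceptance checks additionally run 20 matched null cohorts (intracranial
path) for specificity and 200-repetition calibration nulls for the cluster
test. All statistics reported by the test suite and `scripts/acceptance.R`
are computed at run time under these conditions.

## Known limitations

* hdEEG(ROI) measures cover only regions with sources in the supplied
  operator (14 in the synthetic default), not the full 72-region atlas.
* With nine patients the smallest attainable signed-rank p is $1/512$, so
  single-region effects cannot survive a 48-test FDR family on their own;
  detectability relies on effects spanning several regions or bands, which
  the programmed truth (and the clinical phenomenon it mimics) does.
* wPLI across 20 trials has a noise floor around 0.2; programmed couplings
  are placed well above it.
* The EDF writer stores one data record per file for exactness; readers
  expecting short records may need the bundled reader.
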