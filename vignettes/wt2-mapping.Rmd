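---
title: "Water T2 mapping in fat-infiltrated muscle: model, assumptions and design choices"
author: "muscleWT2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water T2 mapping in fat-infiltrated muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleWT2)
```

## The problem

In muscular dystrophies, muscle tissue is progressively replaced by fat, and
disease activity shows up as edema. The transverse relaxation time of the
*water* component of muscle (wT2) tracks active disease, but a voxel's
multi-echo spin-echo (MESE) signal mixes water and fat, and a global
mono-exponential T2 ends up reflecting fat content rather than edema. On top
of that, MESE echo trains at imperfect (non-180°) refocusing flip angles
contain stimulated-echo pathways that make the train decay *slower* than
`exp(-t/T2)`, so naive exponential fits are biased by B1 inhomogeneity and
the slice profile.

`muscleWT2` estimates voxelwise wT2, fat fraction (FF) and the B1 factor
from conventional MESE magnitude series by simulating the full echo-train
physics and matching measured signals against a precomputed dictionary. An
externally derived fat-fraction map (e.g. from a multi-echo gradient-echo
water-fat reconstruction) can constrain the per-voxel fat fraction, which
stabilizes wT2 when few echoes are available.

## Signal model

Each voxel is a two-compartment system. The signal at echo `n` is

    S_n = (1 - FF) * sat_w * W_n(wT2, B1) + FF * sat_f * F_n(B1)

where `W` and `F` are water and fat echo trains simulated with the extended
phase graph (EPG) formalism, and `sat_c = 1 - exp(-TR/T1_c)` is an optional
per-compartment TR saturation factor (see below). The EPG simulation tracks
the transverse (`F±k`) and longitudinal (`Zk`) configuration states through
the CPMG train: excitation about x, per echo a half-interval of relaxation
plus one unit of crusher dephasing, refocusing about y, another
half-interval, and readout of `|F0|`. The maximum tracked order is
`2 * n_echoes + 1`, so order overflow cannot occur. This convention is
pinned by a test against an independent isochromat Bloch simulation (256
spins spanning 2π of dephasing per half interval), which agrees with the
EPG engine to better than 1e-6 — in practice to machine precision.

Fixed tissue constants follow common muscle protocols at 3T: water T1 =
1400 ms, fat T1 = 365 ms, and a single-peak fat compartment with T2 =
151 ms by default. The fat T2 can instead be estimated from
subcutaneous-fat voxels (`estimate_fat_t2()`), which matches
single-compartment dictionaries over a T2 × B1 search grid and aggregates
per-voxel best matches by the **median** (chosen over the mean for
robustness to partial-volume voxels in the ROI).

### Slice profile

The achieved flip angle varies across the slice. Profiles are computed from
hanning-windowed sinc pulses via a forward Shinnar-LeRoux (SLR) transform in
the hard-pulse approximation, with the refocusing slice 1.2× wider than the
excitation slice (`refocusing_width_factor`, matching the vendor sequence
this pipeline targets; configurable). The voxel signal averages the EPG
train over slice positions, with the B1 factor multiplying *both* the
excitation and refocusing flips (transmit inhomogeneity scales the whole
pulse train).

Defaults: time-bandwidth product 2.0 for both pulses, 128 waveform samples,
64 slice positions spanning ±1 excitation slice thickness. Positions are
**midpoint-rule** sample points: doubling the position count then changes
the simulated voxel signal by only ~4e-5 (relative), versus ~0.8% with
endpoint-inclusive sampling, so 64 positions are safely converged. The true
vendor pulse parameters matter: small profile changes shift absolute wT2 by
a few milliseconds, so a measured profile can be supplied as a plain-text
table (`load_profile_table()`) whenever it is available.

### TR saturation

Whether compartment signals should carry the steady-state factor
`1 - exp(-TR/T1)` is a genuine modelling choice: at TR = 4100 ms the factor
is ≈0.95 for water and ≈1.00 for fat, which slightly rescales the apparent
fat fraction. Both behaviors are available through
`sequence_params(apply_tr_saturation=)`; the default is `TRUE` (include the
factor), since a multi-slice protocol never waits for full recovery. The
choice only rescales the compartment weights — the matched wT2 is barely
affected — but it is recorded in the provenance sidecar.

## Dictionary matching

The dictionary spans 60 linearly spaced wT2 values (20–80 ms), 101 FF
values (0–1) and 20 B1 factors (0.4–1.4): 121 200 entries, each an
L2-normalized echo train. Entries are ordered FF-major (FF slowest, then
B1, then wT2 fastest), so every FF value owns one contiguous column block.
The dictionary is rebuilt at every run — the vectorized EPG engine builds
the default dictionary in seconds, and the water/fat factorization means
only `|wT2|×|B1|` water trains and `|B1|` fat trains are actually
simulated — so there is no cache layer to invalidate.

Matching computes `C = S × D` on L2-normalized signal rows in voxel
batches and takes the per-voxel argmax. Two deliberate choices:

* **Similarity metric.** The "correlation" is the plain normalized inner
  product (cosine similarity), not a mean-subtracted Pearson correlation:
  the matrix-product formulation has no centering step, and magnitude MESE
  trains are non-negative decays where the mean carries signal.
* **Tie-breaking.** Ties resolve to the lowest entry index (FF-major, then
  B1, then wT2), making results platform-reproducible. The only
  analytically degenerate entries are the FF = 1 columns, where wT2 is
  unidentifiable by construction.

With an external fat-fraction constraint, each voxel's FF is quantized to
the nearest grid value and the argmax is restricted to that FF's contiguous
block, so only wT2 and B1 are fitted and the output FF always equals the
quantized constraint.

Echo truncation (`truncate_echoes()`) keeps the leading echoes and
re-normalizes the dictionary columns, emulating shorter acquisitions
(8/5/3 echoes) without re-simulating.

## Exponential fitting

`fit_biexponential()` minimizes
`Σ (S(t) - A[(1-ff) exp(-t/wT2) + ff exp(-t/fatT2)])²` by bounded
Levenberg-Marquardt with `wT2 ∈ [1, 100]` ms, `ff ∈ [0, 1]`, `A ≥ 0`;
starts are `A` = first echo, `wT2` = 35 ms, `ff` = 0.2 (mid-range
physiological values). Fixing `ff` removes it from the parameter vector.
Non-convergent voxels are reported and emitted as NaN. By design this path
corrects neither B1 nor the slice profile — it is the fallback when the
sequence characteristics are unknown — and the stimulated-echo surplus
therefore inflates its apparent T2 (the package's tests quantify this
against the EPG forward model).

## Geometry and I/O

Input is a 4D NIfTI MESE series plus echo times (JSON sidecar or argument);
all affines map 0-based voxel indices to world mm (RAS), and voxel centers
are the sampling points. The fat-fraction volume may have arbitrary
resolution and field of view: it is resampled onto the MESE grid purely
from header geometry (no registration), with trilinear interpolation by
default (FF is smooth; nearest-neighbour is available for label-like
inputs). MESE voxels outside the FF volume get no constraint and fall back
to unconstrained matching, with a logged count. Volumes whose maximum
exceeds 1.5 are auto-detected as percent and divided by 100.

## The digital phantom

`make_phantom()` emulates a multi-slice MESE acquisition of elliptical
tissue regions with known wT2/FF/B1 plus a co-registered (optionally
shifted) fat-fraction volume. Defaults mirror the targeted acquisition
regime: 64×64×3 voxels, 17 echoes at 10.9 ms, six regions with wT2 between
25 and 45 ms and FF from 0 to 0.6, a linear B1 gradient over 0.8–1.2, and
Rician noise (magnitude MRI; Gaussian available).

`noise_sigma` is expressed as a fraction of the first-echo amplitude of a
pure-water reference voxel (wT2 = 35 ms, B1 = 1) under the same sequence
and profile — the usual image-SNR convention — so the default 0.02 means
first-echo SNR 50 on the images. Defining it against unit M0 instead would
conflate the slice-profile amplitude loss (~0.35 M0 at the first echo) with
the noise level.

What the phantom does *not* emulate: anatomy, partial-volume mixing beyond
the two-compartment model, B0 effects, motion between the MESE and
fat-fraction acquisitions (only a rigid header shift), magnetization
transfer, J-coupling, or a multi-peak fat spectrum. Passing phantom tests
therefore demonstrates the correctness of the simulation, matching and
plumbing — not absolute in-vivo accuracy, which hinges on knowing the true
pulse shapes and fat T2.

## Test and validation problem sizes

The test-suite and `scripts/acceptance.R` sizes are chosen so every check
runs comfortably on one CPU: the matching-vs-exhaustive-search oracle uses
1000 random voxels against a 10 000-entry dictionary; self-recovery uses a
15×26×10 (wT2×FF×B1) grid at 17 and 5 echoes; phantom recovery uses the
default phantom with a 60×51×20 dictionary and a 32-position profile; the
closed-form and Bloch-oracle checks span 5×3 (T2, spacing) and 5×3
(flip, T2) grids of full 17-echo trains. The constraint-benefit check fits
the same phantom at 5 echoes with and without the FF constraint and
compares the regression slopes of ROI-mean wT2 error against ROI fat
fraction.

## Known limitations

* Single-peak fat model with one global fat T2; no multi-peak spectrum and
  no chemical-shift displacement of the fat slice profile.
* Header-based alignment only; inter-scan motion produces constraint
  misregistration artifacts rather than failures.
* Absolute wT2 depends on the assumed pulse shape (time-bandwidth,
  apodization); use a measured slice profile for cross-vendor work.
* Magnitude-only input; no complex or phase-based processing.
* DICOM series are not read directly; convert to NIfTI + JSON echo-time
  sidecar first.
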