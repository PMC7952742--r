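# muscleWT2

Water-T2 mapping of muscle from multi-echo spin-echo (MESE) MRI in the
presence of fat infiltration.

## Why

In neuromuscular disease, quantitative MRI tracks two processes: fatty
replacement of muscle (fat fraction, FF) and active disease / edema, for
which the transverse relaxation time of the muscle **water** component
(wT2) is the established biomarker. A voxel's MESE signal mixes water and
fat, and echo trains acquired with imperfect refocusing pulses contain
stimulated echoes that slow the apparent decay, so a plain exponential fit
of the train confounds wT2 with fat content, B1 inhomogeneity and the slice
profile.

`muscleWT2` solves the forward problem instead: it simulates the full
echo-train physics with the extended phase graph (EPG) formalism and reads
the parameters off the best-matching simulation. It is aimed at
quantitative-MRI researchers running muscle relaxometry studies from
conventional 2D MESE protocols.

## The method

Each voxel is modelled as a two-compartment system,

    S_n = (1 − FF) · sat_w · W_n(wT2, B1) + FF · sat_f · F_n(B1),

where `W` and `F` are EPG-simulated water and fat CPMG echo trains
(fixed T1s of 1400/365 ms, single-peak fat with T2 = 151 ms by default),
averaged over the slice profile computed from hanning-windowed sinc pulses
via a Shinnar-LeRoux transform (refocusing slice 1.2× wider than the
excitation slice), with the B1 factor scaling every flip angle and
`sat_c = 1 − exp(−TR/T1_c)` an optional saturation factor.

Signals for all combinations of a parameter grid — by default 60 wT2 values
(20–80 ms) × 101 FF values (0–1) × 20 B1 factors (0.4–1.4), i.e. 121 200
entries — are placed in a dictionary of L2-normalized columns `D`. Matching
is the matrix product `C = S × D` on normalized voxel rows; the argmax of
each row gives the voxel's (wT2, FF, B1). If an externally derived
fat-fraction map is supplied (e.g. from a multi-echo gradient-echo
water-fat reconstruction), it is resampled onto the MESE grid by header
geometry alone and the argmax is restricted to the matching FF block, which
keeps wT2 independent of fat content even when only 5 echoes are used.
Mono- and biexponential least-squares fits are provided as conventional
fallbacks, and ROI-level indicators (pooled SD, intrasubject SD, FF bias)
summarize map quality across subjects.

Everything is testable offline through a built-in digital phantom with
known wT2/FF/B1 fields, Rician noise and a co-registered (optionally
shifted) fat-fraction volume.

## Worked example

Generate the default phantom (17 echoes at 10.9 ms, six tissue regions,
first-echo SNR 50) and fit it with FF-constrained dictionary matching:

```r
library(muscleWT2)

seqp    <- sequence_params()                       # 17 echoes, 10.9 ms, TR 4100 ms
profile <- build_profile_table(n_positions = 32)   # SLR slice profiles
phantom <- make_phantom(phantom_spec(noise_sigma = 0.02, seed = 42),
                        seqp, profile)

fit <- wt2_fit(phantom$mese, ff = phantom$ff_volume,
               grid = wt2_grid(ff = seq(0, 1, length.out = 51)),
               profile = profile, seq = seqp)
summary(fit)
#> Water-T2 fit: method epg, 17 echoes, 3876 voxels
#>                  25%     50%     75%
#> wt2_ms       29.1525 35.2542 42.3729
#> fat_fraction  0.1000  0.2000  0.4400
#> b1_factor     0.9263  0.9789  1.0842
#> correlation   0.9992  0.9995  0.9997

roi_summary(fit$maps, phantom$labels, subject = "phantom")
#>   subject roi n_voxels mean_wt2 sd_wt2 mean_ff sd_ff
#> 1 phantom   1      642     35.2   1.93    0.00     0
#> 2 phantom   2      648     25.3   2.29    0.10     0
#> 3 phantom   3      642     45.4   2.40    0.20     0
#> 4 phantom   4      642     30.3   3.70    0.30     0
#> 5 phantom   5      642     41.4   5.55    0.44     0
#> 6 phantom   6      642     35.7   5.46    0.60     0
```

The ROI means recover the regional ground truth (35, 25, 45, 30, 40,
35 ms at FF 0–0.6) to within the wT2 grid spacing (≈1 ms), the fitted FF
equals the constraint quantized to the FF grid (hence `sd_ff = 0`), and
the B1 quartiles reflect the phantom's 0.8–1.2 transmit gradient. `sd_wt2`
grows with FF: less water signal means noisier wT2, which is why the
constraint matters for reduced-echo protocols.

The same pipeline runs from the shell:

```sh
inst/cli/wt2map phantom --output ph --seed 42
inst/cli/wt2map fit --input ph/mese.nii.gz --ff-map ph/ff.nii.gz --output maps
inst/cli/wt2map stats --subjects cohort.csv --output stats
```

`fit` writes `wt2_ms.nii.gz`, `ff_fraction.nii.gz`, `b1_fraction.nii.gz`,
`correlation.nii.gz` and a `run_info.json` provenance sidecar.

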