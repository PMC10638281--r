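---
title: "Methods: peak-pair screening and retention-index annotation of FAHFAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak-pair screening and retention-index annotation of FAHFAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cilfahfa)
```

## The measurement model

Branched fatty acid esters of hydroxy fatty acids (FAHFAs) are low-abundance
lipids whose structural space is combinatorial: any fatty acid (FA) can sit
on any hydroxyl position of any hydroxy fatty acid (HFA).  The package
implements a targeted workflow built on three ideas:

1. **Chemical isotope labeling.**  The FAHFA free carboxyl (it belongs to
   the HFA) is amide-derivatized with DMED (2-dimethylaminoethylamine) and,
   in a parallel aliquot, with its four-deuterium isotopologue d4-DMED.
   Equal volumes are mixed and injected once.  A genuine analyte therefore
   appears as two co-eluting peaks of roughly equal height, 4.0251 Da apart
   in precursor m/z, in the light and heavy MRM channels of its compound.
   Noise and single-channel artifacts do not have this signature.
2. **Combinatorial MRM design.**  The transition list is not curated by
   hand: it is the Cartesian product of an FA registry and an HFA registry.
   Each family (FA x HFA backbone, ignoring the ester position — all
   regioisomers of a family are isobaric) gets one light and one heavy
   transition.  The product ion is the labeled HFA fragment after loss of
   dimethylamine + water, so it depends only on the HFA backbone, and the
   deuteriums reside in the lost neutral: light and heavy product m/z
   coincide while the precursors differ by the label mass.
3. **Retention indexing.**  Regioisomers of one family can only be told
   apart chromatographically.  Raw retention times drift between batches,
   so RTs are converted to retention indices (RI) against a homologous
   series of DMED-labeled C20–C30 saturated fatty acids: with the calibrant
   line RT = k·n + b fitted by least squares, RI = 100·(RT − b)/k, which
   puts a Cn calibrant at RI = 100 n by construction.  Within a family
   series that shares one HFA backbone, RI is affine in two structural
   descriptors — it rises with the carbon number of the FA partner (x1)
   and falls with the ester position (x2) — so a two-predictor linear
   model per backbone predicts the RI of every unmeasured regioisomer.
   Annotation matches measured RIs against these predictions.

## Shipped prediction models

Three backbone models are shipped (saturated C14:0, C16:0 and C18:0 HFA
series, FA partners C14–C18 saturated, default position grid 5–12):

```{r}
for (m in shipped_ri_models()) print(m)
```

The coefficients are taken verbatim from the published family-series
regressions; `expand_predictions()` materialises their grid, spanning 15
families.  The signs encode the two retention rules: each added FA carbon
is worth roughly one calibrant carbon (83–97 RI units), and moving the
ester one position toward the methyl end costs about 28–29 RI units, i.e.
roughly a third of a carbon — which is exactly why raw RT is too fragile
and retention indexing is needed.

`fit_ri_model()` refits the same model class by ordinary least squares
(through `lm()`), errors on rank-deficient designs, and records the fitted
predictor hull; predictions outside the hull warn but proceed, since the
family series themselves are used in extrapolation.  `simulate()` on a
model draws replicate noisy grids for coefficient-recovery studies.

## Tunable parameters and their defaults

| parameter | default | unit | why |
|---|---|---|---|
| scheduling capacity | 54 | channels/method | 27 light/heavy pairs per method; spreads the full 1058-channel design over 20 acquisition methods |
| `min_height` | 50 | counts | absolute floor for peak apexes |
| `snr` | 5 | – | apex height must also exceed 5x the robust per-trace noise level |
| smoothing window | 5 | points | minimal moving average before maxima detection; order-preserving |
| `min_width` | 0.01 | min | rejects one-sample spikes |
| `rt_tol` | 0.05 | min | "co-eluting": max light/heavy apex separation |
| `ratio_window` | [0.5, 2] | – | "similar height" for a 1:1 derivative mix |
| `ri_tol` | 10 | RI units | ~0.1 calibrant carbon; one ester position step is 28–29 units, so adjacent regioisomers cannot be confused |
| collision energy | 35 | eV | constant placeholder; instrument-optimized values come in via the transition-list CSV |

The screening thresholds deserve a note: "identical retention time" and
"similar peak height" are qualitative criteria, and no numeric thresholds
are published for them.  The values above are this package's own operating
point, chosen once to be chromatographically reasonable (a 0.05-min
co-elution window is under two peak widths at sigma = 0.03 min; a factor-2
height window is loose for a 1:1 mix) and exposed as arguments everywhere.

## Scheduling

`schedule_methods()` partitions the transition list into acquisition
methods.  Two constraints are treated as hard: no method exceeds its
channel capacity, and the light and heavy channels of one family always
share a method — a split pair can never be screened, because the pair
signature exists only within one injection.  Under pair co-location,
channel counts per method are necessarily even, so "as even as possible"
is enforced at pair granularity: family counts differ by at most one
(channel counts by at most two).  The default capacity of 54 channels (27
pairs) is the smallest even capacity that packs the full 529-family design
into 20 methods.

## Peak detection and pairing

Detection is deliberately simple: 5-point moving-average smoothing, local
maxima above `max(min_height, snr x noise)` where the noise level is the
MAD of the first differences of the raw trace (robust to the peaks
themselves), boundaries at the nearest valley or half-threshold crossing.
The apex RT and height are refined by log-parabolic interpolation through
the three raw samples around the maximum — exact for a noiseless Gaussian,
which removes the sampling-step quantisation that would otherwise dominate
the RI error budget (one 0.01-min step is ~2 RI units at the default
calibration).

Pairing is a greedy matching: candidate light/heavy pairs within `rt_tol`
are accepted in order of increasing RT difference, ties broken toward the
height ratio nearest 1; each peak is used at most once, and pairs outside
the ratio window are dropped.  Height, not area, drives the ratio filter,
matching the similar-peak-height criterion.

Annotation is likewise greedy and one-to-one within a family, by ascending
|measured − predicted| RI with ties broken toward the lower ester position.
One-to-one matters: a regioisomer ladder detected together must not
collapse onto the single nearest prediction.  Re-annotating an annotated
table changes nothing (idempotence), and the identified fraction is
monotone in `ri_tol`.

For cross-sample compilation, observations of one family are considered
the same regioisomer when their measured RIs fall in the same
single-linkage cluster (gap threshold `ri_tol`).  The published dataset
does not state its deduplication rule; this clustering rule is an explicit
assumption of the package, safe here because adjacent regioisomers are
~29 RI units apart while the tolerance is 10.

## The synthetic-data generator

`generate_ground_truth()` and `generate_sample_run()` produce runs with
the exact statistical structure the analysis assumes:

* planted regioisomers are drawn from the shipped models' coverage;
  their apexes sit at `ri_to_rt(predict_ri(...))` under the configured
  calibration line (default k = 0.45 min/carbon, b = 1.0 min, placing the
  C20–C30 calibrants at 10–14.5 min in a 31-min window);
* peaks are Gaussian (sigma = 0.03 min), sampled every 0.01 min;
* the light height is the abundance; the heavy height multiplies it by a
  log-normal jitter (sd 0.05) around the ideal 1:1 mix;
* per-family abundances are log-uniform over 1e4–1e6 counts, with
  regioisomers of one family varying by a further factor of 0.5–2 —
  regioisomer ladders have comparable responses, and this keeps the
  within-channel dynamic range compatible with a proportional-noise model;
* baseline noise is additive Gaussian at `noise_sd` (default 1%) of the
  trace's largest peak;
* decoys are planted as single-channel peaks (light only) or 5:1
  bad-ratio pairs, early in the gradient window, clear of the analyte RTs;
* one integer seed fixes every draw; repeated runs are byte-identical.

What the generator does **not** emulate: isotope-envelope crosstalk,
detector saturation, baseline drift, tailing/fronting peak shapes,
within-batch RT drift, and co-eluting isobaric interference within one
channel.  Passing the end-to-end tests therefore demonstrates that the
screening and annotation logic is correct under its own model assumptions,
not that the thresholds are optimal for any particular instrument.

## Numerical choices and degenerate inputs

* RT/RI conversion is kept as an exact affine pair; round-trips hold to
  1e-9.
* Calibration requires two distinct carbon numbers; an r-squared below
  0.95 warns (the homologous-series assumption has failed) but returns,
  so a drifting batch is flagged rather than silently dropped.
* RI model fits require ≥ 3 observations spanning both predictors; a
  single-valued predictor is reported as rank deficiency by name.
* Molecular formulas are integer count maps; subtraction that would drive
  a count negative errors, so condensation arithmetic cannot silently
  produce nonsense.  Isotope masses come from a fixed embedded table so
  masses are bit-stable across library versions; deuterium is a distinct
  symbol, which is what makes the light and heavy reagents differ only in
  their count maps.
* The heavy-channel product ion is modeled as the labeled **HFA** fragment
  (the label sits on the HFA carboxyl; the neutral losses 63.0684/67.0935
  differ by exactly the four H→D substitutions).  The loss masses are
  configurable per labeling scheme in case a different heavy diagnostic
  transition is wanted.

## Problem sizes used by the test-suite studies

The shipped studies run at sizes chosen to make their statistics sharp but
cheap: coefficient recovery uses 200 replicate grids (40 points each) at
noise sd 3 RI units per backbone model, under which the standard error of
the replicate mean is ~0.024 RI/carbon for the x1 coefficient; the
end-to-end study plants 30 regioisomers (15 families x 2 positions) plus
5 decoys in a single synthetic run at default noise.

## Limitations

* The default FA/HFA registries are placeholder lists of common species
  (the HFA hydroxyl fixed at C9); a laboratory's own standards table drops
  in via `read_registry()` without code changes.
* Only three backbone models ship; families outside their coverage are
  screened but stay `detected_only`.
* Quantification is relative (summed peak heights); no concentration units.
* The mzML writer emits a minimal chromatogram-list document (64-bit
  floats, uncompressed) sufficient for standards-compliant readers; it is
  not a general mzML exporter.
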