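---
title: "Retinal structure-function analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal structure-function analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinerg)
```

`retinerg` implements the analysis chain used to characterize retinal
structure and function in a cross-sectional mouse study: full-field
electroretinogram (ERG) decomposition into photoreceptoral, bipolar-cell
and ganglion-cell endpoints; optical coherence tomography (OCT) layer
thickness summarized over an annulus centered on the optic nerve head;
total-protein-normalized western-blot densitometry; and the statistical
layer tying them together (ROUT outlier screening, two-way
genotype-by-age ANOVA with Sidak post hoc comparisons, Deming regression
and Spearman correlation). A synthetic-cohort generator with known
ground truth makes every stage verifiable without animal data.

## The ERG measurement model

A flash ERG is a corneal voltage trace sampled, in the acquisition this
package emulates, at 4 kHz over 640 ms, with amplifier band-pass
filtering from 0.3 to 1000 Hz (−3 dB corners). The package decomposes a
family of such traces, recorded at ascending flash energies, into three
standard cellular endpoints.

### Photoreceptoral P3 (a-wave)

The leading edge of the a-wave is modelled by the delayed-Gaussian
saturation function of phototransduction:

$$P3(i, t) = -R_{mP3}\,\bigl(1 - e^{-\,i\,S\,(t - t_d)^2}\bigr), \qquad t > t_d,$$

where $i$ is the flash energy in linear cd·s/m², $R_{mP3}$ (µV) the
saturated photoreceptoral amplitude, $S$ the sensitivity scaling the
energy-time product, and $t_d$ (s) a short transduction delay. The model
only describes the leading edge, so `fit_p3()` restricts the fit to the
window from flash onset to the a-wave trough; the trough is located on a
46.9 Hz low-pass-smoothed copy of the trace so recording noise cannot
displace it. One parameter triple is fit jointly to the two brightest
flashes of the pathway (an *ensemble* fit: rod pair 1.55 and 2.07, cone
pair 2.20 and 2.72 log cd·s/m²), since a single saturated amplitude is
the endpoint of interest. The fit is nonlinear least squares
(`minpack.lm`); because the model is badly conditioned in $S$, the
starting sensitivity is chosen by a coarse logarithmic grid search
before the optimizer runs, and tests cross-check the optimum against an
independent parameter grid.

A per-flash-then-average variant of this fit also exists in practice;
the joint fit was chosen
because it estimates one triple from exactly the information the
ensemble contains, and it is the variant whose recovery could be
verified against generator truth.

### Bipolar-cell P2 (b-wave) and the Naka-Rushton fit

The fitted P3 is subtracted from every flash of the family to isolate
the P2-OP complex. `extract_p2()` removes the oscillatory potentials
with a zero-phase low-pass whose **net** magnitude response is −3 dB at
46.9 Hz, and measures the P2 peak as the maximum positive deflection
after flash onset relative to the pre-stimulus baseline (the mean of the
pre-flash samples). Peak amplitudes across the energy series are then
summarized by the saturated hyperbola (Naka-Rushton function with
exponent fixed at 1, a config flag frees it):

$$V(i) = V_{max}\,\frac{i^{\,n}}{i^{\,n} + K^{\,n}},$$

yielding the bipolar-cell amplitude $V_{max}$ (µV) and semi-saturation
energy $K$ (cd·s/m²). The amplitude series includes all flashes of the
protocol; at the two dimmest flashes the measured "peak" is in truth the
scotopic threshold response, but those points are two orders of
magnitude below saturation and shift the fitted $K$ by under 1% in the
recovery tests, so no exclusion rule was added.

### Filter realization

Only the corner frequencies and the −3 dB levels of the filters are
contractual; their order and family are not recoverable from an
endpoint table. The package uses 4th-order Butterworth low-pass (and
2nd-order stages for the acquisition band-pass) applied
forward-backward, for zero phase shift — amplitude endpoints must not
move in time. Two design details matter numerically:

* the single-pass cutoff is **pre-warped numerically** (root-finding on
  the designed transfer function) so the net two-pass gain is exactly
  $1/\sqrt{2}$ at the nominal corner, rather than −6 dB as naive
  double application would give; and
* both passes run on an odd-reflection-padded copy of the trace,
  because plain forward-backward filtering leaves edge transients that
  corrupt the pre-stimulus baseline (the padding length is at least
  1000 samples or three filter lengths).

DC gain is exactly 1 to within 1e−9, pinned by tests.

### Ganglion-cell pSTR

At the two dimmest flashes (−5.01 and −4.90 log cd·s/m²) the trace is
dominated by the positive scotopic threshold response. `measure_pstr()`
reports the arithmetic mean of the two baseline-corrected positive peaks
inside a 60-200 ms post-flash search window. Timing endpoints are
deliberately not produced anywhere in the package: the acquisition
band-pass distorts temporal information, so amplitudes are the only
endpoints carried forward.

## The waveform generator

`generate_erg()` composes, per flash: the P3 model above; a P2 waveform
whose *shape* is a gamma kernel $g(t) \propto (t/\tau)^4 e^{-t/\tau}$
(unit peak at $t_d^{syn} + 4\tau$) scaled by the Naka-Rushton amplitude
— any smooth positive kernel would do, since only its peak is measured;
oscillatory potentials as a Gaussian-windowed oscillation at the
geometric mean of the OP band (60-235 Hz), scaled with the Naka-Rushton
fraction so dim flashes carry none; a Gaussian pSTR bump (peak 110 ms,
present only at flashes at or below −4.5 log cd·s/m²); optionally the
acquisition band-pass; and white Gaussian noise under an explicit seed
(RNG state is saved and restored — nothing touches the caller's
stream).

Default pathway parameters are typical of an adult wildtype mouse: rod
$R_{mP3}$ 450 µV with $S = 2500$ and $t_d$ 4 ms (a-wave trough inside
15 ms at the brightest flashes), rod $V_{max}$ 600 µV with $K$ 0.03
cd·s/m² and kernel peak near 110 ms; cone responses smaller and faster
($R_{mP3}$ 35 µV, $V_{max}$ 250 µV, $K$ 15 cd·s/m², kernel peak near
66 ms). The cone P2 kernel carries a 10 ms synaptic onset delay; without
it the photopic b-wave rises into the a-wave fit window, the trough
arrives before the cone P3 saturates, and $S$ becomes unidentifiable —
with the delay, full-loop decomposition recovers cone $V_{max}$ and $K$
to well under 1%.

Two generator features deliberately simplify reality, and bound what
passing tests show: noise is white (real ERG noise has line components
and slow drift), and the P3 plateau never recovers (real photoreceptors
repolarize over hundreds of ms). Neither affects the leading-edge or
peak measurements the pipeline takes.

When the cohort simulator emits raw waveforms it disables the
acquisition band-pass by default: a 0.3 Hz zero-phase high-pass visibly
droops the sustained P3 plateau, which is a property of real recordings
too, but it would put a systematic bias between generator truth and
decomposed endpoints. The clean-signal default keeps "pipeline output
equals planted truth" a meaningful test; the band-pass stays available
via `accessory_params(acquisition_band = )` and its own contract is
pinned independently.

## OCT layer summaries

`thickness_from_boundaries()` differences an ordered stack of
segmentation surfaces into per-layer thickness rasters (crossing
surfaces are a hard error naming the pixels). `annulus_mean()`
implements the ETDRS-style outer-ring summary: a pixel belongs to the
annulus when its center's distance $r$ from the optic-nerve-head center
satisfies $r_{inner} \le r < r_{outer}$ (half-open, so concentric
annuli partition the raster); on a regular raster every pixel carries
equal area, so the area-weighted mean is the plain mean over included
pixels, with NA pixels excluded and counted. The outer diameter defaults
to 6 mm; the inner bound defaults to the 3 mm of the standard ETDRS
outer ring and is configurable. Total retinal thickness is always derived
as RNFL + GCIPL + INL + OPL + ONL (ILM to OLM) — additivity is exact on
NA-free grids and enforced by construction, since TRT is never stored.

Tests validate the pixel rule against the closed-form area integral of
a radial profile $T(r) = a + br$, whose annulus mean is
$a + b\,\tfrac{2}{3}\,(r_2^3 - r_1^3)/(r_2^2 - r_1^2)$, to 0.5% on a
768-pixel-wide raster (the B-scan width of the emulated scanner).

## Densitometry

`normalize_lane()` is band density over the same lane's automated
total-protein measurement — invariant to per-lane loading and gain.
`percent_of_reference()` scales to the mean of the 4-month wildtype
cohort; when that mean is zero — as for human and pSer129
alpha-synuclein, which wildtype retina does not express — it falls back
to the 4-month HOM mean and records the switch. "Zero" is detected
below a configurable tolerance (default 1e−12 of the data maximum)
because real densitometry never returns exact zeros, while the
simulator does. The composite "ALL" alpha-synuclein measure is the
arithmetic sum of mouse, human and pSer129 abundances; it is computed
on the percent-of-reference scale, since the three components
necessarily carry different reference groups — a documented limitation
of any reconstruction of that composite from per-target tables.

## The statistical layer

**ROUT outlier screening.** The robust-fit-plus-FDR outlier procedure
reduced to the constant model, which is the form appropriate for
screening replicate group measurements: robust center = median; robust
SD of residuals (RSDR) = 68.27th percentile of absolute residuals with
the small-sample correction $n/(n-K)$, $K = 1$; each residual converts
to a two-tailed p-value via $t = |r|/\text{RSDR}$ on $n-K$ degrees of
freedom, and flagging is FDR step-up at rate $Q$ (the scan-from-the-
extreme formulation of the published procedure selects the same set as
Benjamini-Hochberg step-up here, which is what the reference
implementation in the test suite uses). $Q$ defaults to 1%, the
procedure's customary default, and is applied per genotype-by-age
cell. On clean Gaussian data the
family-wise flag rate stays below 5% at $Q = 1\%$ (seeded simulation).

**Two-way ANOVA with Sidak post hoc.** Fixed-effects genotype × age
ANOVA with interaction. Group sizes differ across cells (9-29 in the
emulated cohort), so Type-III sums of squares with sum-to-zero
contrasts are used, the convention of the commercial statistics
packages standard in this field; on balanced designs these coincide with the textbook
decomposition, which the oracle tests check to 1e−10. The fit is an
`lm` and the Type-III table comes from `car::Anova`, except in the
zero-residual-variance corner, where `car` refuses the fit and the term
SS are computed directly as full-vs-reduced RSS differences on the same
design matrix; nonzero terms then report $F = \infty$, $p = 0$ with a
degenerate flag. Post hoc WT-vs-HOM contrasts within each age use the
pooled residual mean square, Sidak-adjusted with
$p_{adj} = 1 - (1-p)^m$, $m$ = number of ages — the per-age comparison convention of
genotype-by-age cohort presentations.

**Deming and Spearman.** Structure-function and burden-structure
associations pair variables that both carry measurement error, so the
line fit is Deming regression: with error-variance ratio $\lambda$
(default 1, i.e. orthogonal regression; no error-variance asymmetry is
assumed a priori), the slope is the closed-form
$\bigl(s_{yy} - \lambda s_{xx} + \sqrt{(s_{yy} - \lambda s_{xx})^2 +
4\lambda s_{xy}^2}\,\bigr) / (2 s_{xy})$. Association strength is
Spearman's $R_s$: Pearson correlation of mid-ranks (average ranks on
ties), with the asymptotic t-approximation p-value by default and a
seeded permutation option. Tests pin both to independent oracles
(eigen-decomposition of the covariance for Deming; brute-force counting
ranks for Spearman, enumerated over small tied inputs). Correlation
panels pool both genotypes; the
cohort table retains genotype so per-genotype fits are one subset away.

**Percent-relative presentation.** Endpoints are also expressed per age
as percent of the age-matched wildtype mean with the 95% t-interval of
the 4-month wildtype cohort as the reference band; for HOM-only
abundances the reference falls back to the youngest HOM cohort,
mirroring the densitometry rule.

## The cohort simulator

`simulate_cohort()` draws per-animal endpoints as Gaussians around
genotype-by-age means built from three ingredients, all in
baseline-SD units: a wildtype 4-month baseline per endpoint, an age
trend shared by both genotypes, and a genotype shift per age. The
default effect pattern defines the study conditions the generator
emulates: the earliest and largest deficits in ONL
thickness and cone P2 amplitude (already at 4 months), progressive OPL
thinning, slight GCIPL thickening, late-only RNFL thinning, increased
TH and alpha-synuclein in HOM, rod P2 and pSTR spared. Human and
pSer129 alpha-synuclein are identically zero in wildtype animals.
Magnitudes are configuration, not claims about effect sizes.

Correlation structure comes from a single per-animal latent severity
factor $s \sim N(0,1)$, present only in HOM animals, loading positively
on the three alpha-synuclein abundances and negatively on ONL and cone
$V_{max}$. This is the simplest structure that induces the observed
negative burden-structure-function correlations and stays analytically
checkable: endpoints are otherwise independent given their cell means.
Sex is recorded (alternating within cells by default) but carries no
effect. Default cell sizes mirror the emulated cross-sectional cohort:
WT 16/19/29 and HOM 16/15/24 at 4/6/14 months.

`run_study()` chains the whole pipeline — optionally regenerating raw
waveforms and thickness rasters per animal and re-measuring every
endpoint through `decompose()` and `summarize_layers()` — then applies
per-cell ROUT, ANOVA + Sidak per endpoint, percent-relative summaries
and the correlation panel. Everything is reproducible from one seed;
per-animal and per-stage child seeds are derived arithmetically and
stay within R's 32-bit integer range. Degenerate correlation inputs
(zero-variance calibration runs) are recorded as stage errors in the
bundle rather than aborting it.

## Problem sizes and numerical choices

The shipped verification uses desk-scale problem sizes chosen to give
stable Monte-Carlo estimates: 200 seeded repetitions for parameter
recovery under 20 µV noise and for power/coupling rates, 500 for the
null-calibration KS check, 1000 for the clean-data ROUT flag rate, a
768-pixel raster for the annulus integral, and a full raw-waveform
study of 2 genotypes × 3 ages × 16 animals (96 animals, 18 flashes
each), which completes in well under a minute on one core. Nonlinear
fits use analytic starting values plus the grid-searched sensitivity;
ties in rank correlations take mid-ranks; the annulus rule is half-open
to make pixel membership unambiguous; and all seeds are explicit
arguments.

## Known limitations

* The generator's P2 kernel shape, OP placement and STR width are
  conventions; only peak amplitudes are contractual, so conclusions
  about waveform morphology cannot be drawn from it.
* ROUT is applied per univariate group; the regression form of the
  procedure (robust nonlinear fit plus FDR on fit residuals) is out of
  scope, as are repeated-measures mixed models.
* Eyes are not modelled separately; animals are the exchangeable unit.
* The OCT stage consumes already-segmented surfaces or thickness
  rasters; segmentation itself, scan registration and mouse-eye optics
  corrections are out of scope.

## A worked example

```{r example, eval = FALSE}
library(retinerg)

# one animal's recording session, clean signal
fam <- generate_family(
  c(dark_protocol(), light_protocol()),
  p3  = list(dark = default_rod_p3(),  light = default_cone_p3()),
  p2  = list(dark = default_rod_p2(),  light = default_cone_p2()),
  acc = accessory_params(noise_sd = 0, acquisition_band = NULL),
  tb  = timebase(), seed = 1)
decompose(fam)

# the full synthetic study, endpoints re-measured from raw traces
res <- run_study(study_design(n_per_cell = matrix(16, 2, 3)),
                 effect_model(), seed = 1, from_raw = TRUE)
res$endpoints$ONL$anova
res$correlations$total_asyn_vs_ONL$spearman
```
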