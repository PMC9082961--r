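---
title: "Volumetric leaf area: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric leaf area: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vleaf)
```

## The measurement problem

Destructive leaf-area measurement is the reference against which indirect
canopy methods are calibrated, but it is slow: every leaf must be unfolded,
flattened and fed through a scanner or area meter individually. For dense
samples of small leaves — a wheat canopy at tillering is the motivating
case — the unfolding step dominates the cost of a field experiment.

The volumetric approach replaces per-leaf scanning with a single
measurement of the whole pile. A flat organ of area $A$, thickness $T$ and
volume $V$ obeys $V = A \cdot T$ regardless of how it is folded or twisted,
because volume is invariant under bending. So if the pile volume $V_l$ can
be measured at once, the *volumetric leaf area*

$$ VLA = \frac{V_l}{T_l} $$

needs only one more number: the mean lamina thickness $T_l$, which is
cheap to estimate by measuring a small random sample of leaves with a
micrometer. The package implements this estimator, the two hydrostatic
volumetry protocols that feed it, the optical (pixel-count) reference
method, the agreement statistics used to compare the two, and a seeded
synthetic-leaf generator that provides ground truth for validating the
whole chain.

## Hydrostatic volumetry

**Suspension technique.** A water container sits on a 0.001 g balance; the
sample, held under water by a suspended retainer (a weighted clip), never
touches the container. Because the suspended set is stationary, the balance
reading increases by exactly the weight of displaced water, so each reading
converts to a volume through the water density $\rho_T$ at the measured
temperature:

$$ V_r = \frac{\Delta W_r}{\rho_T}, \qquad
   V_l = \frac{\Delta W_t}{\rho_T} - V_r . $$

`water_density()` interpolates linearly on an embedded reference grid of
handbook values for air-free water (15–30 °C in 0.5 °C steps, stored in
g/cm³ and returned in g/mm³). Temperatures outside the grid raise an error
rather than extrapolate; bench water in the intended protocol sits near
21.5–23 °C, far from the grid edges.

**Specific Gravity Bench.** On an SGB the cage hangs from a load cell and
the water container is raised around it, so the load cell sees only the
sample and cage, not the water. With dry weights $W_{r1}$ (cage) and
$W_{l1}$ (leaf pile), and underwater readings $W_{r2}$ (cage) and $W_{T2}$
(cage plus pile), the force balance on the suspended set gives

$$ W_{T2} = W_{l1} + W_{r1} - (V_l + V_r)\,\rho_T , $$

and therefore

$$ V_l = \frac{W_{l1} - W_{T2} + W_{r2}}{\rho_T}
   \quad\text{or, eliminating } W_{r2}\text{ via } W_{r2} = W_{r1} - V_r \rho_T,\quad
   V_l = \frac{W_{l1} + W_{r1} - W_{T2} - V_r\,\rho_T}{\rho_T}. $$

`leaf_volume_sgb()` uses the first form when $W_{r2}$ was recorded and the
second otherwise; the two are algebraically identical on consistent
records, and a recorded $W_{r2}$ that contradicts $W_{r1} - V_r\rho_T$
(beyond a small tolerance) is rejected as a corrupted record. These are the
forms the simulated instrument obeys exactly: `simulate_sgb_weighing()`
constructs $W_{T2}$ from the force balance above, and the test suite
verifies that both volume formulas invert it to machine precision.

**Replicates and the bubble rule.** Underwater weighings are repeated two
or three times because trapped air bubbles inflate a reading. The protocol
description leaves the rejection rule open; the package uses a
median-anchored rule (`aggregate_replicates()`): a replicate whose absolute
deviation from the median exceeds three times the median absolute deviation
is discarded, and the remainder averaged. With two replicates nothing can
be rejected (the rule needs a majority); with all-equal replicates nothing
is rejected. A computed volume that is slightly negative — within one
balance step of zero — is clamped to zero with a warning, since it is
indistinguishable from rounding noise; a larger negative raises an error,
signalling a protocol failure rather than numeric noise.

## The midrib correction

The midrib is a three-dimensional rib that does not flatten with the
lamina, so its volume inflates $VLA$ relative to the true silhouette area.
It is modelled from two cheap measurements, sample length $L$ and basal
midrib diameter $T_{b.m}$:

$$ V_m^{cyl} = L\,\pi\left(\frac{T_{b.m}}{2}\right)^2
   \qquad\text{(pieces, near-constant midrib)}, \qquad
   V_m^{cone} = \frac{V_m^{cyl}}{3} \qquad\text{(complete leaves)}. $$

The cone applies to complete leaves, whose midrib tapers to nothing at the
tip; the choice defaults to the specimen's completeness but is an explicit
caller decision. The wording "base diameter equal to the thickness of leaf
base" is ambiguous between the basal *lamina* thickness and the basal
*midrib* diameter; the package follows the symbol definition ($T_{b.m}$,
basal midrib diameter), which is also the geometrically sensible reading —
a midrib is always at least as thick as the lamina it stiffens, and the
shape constructor enforces exactly that invariant.

## The synthetic leaf model

No raw bench data were published, so validation runs on synthetic wheat
leaves with known ground truth.

**Geometry.** A leaf of length $L$ and maximum width $W$ has the symmetric
width profile

$$ w(x) = W\,\bigl(4\,(x/L)\,(1 - x/L)\bigr)^a, $$

with $a = 0.5$ by default (a lanceolate outline, widest at mid-leaf;
$a = 0$ gives a rectangle, used for exact pixel-count fixtures). No leaf
silhouette model is prescribed by the protocol itself; this family was
chosen because it is the simplest positive, smooth, single-peaked profile
whose area and volume integrals are cheap to evaluate to high precision.
Lamina thickness is interpolated linearly through base/middle/tip readings
— deliberately no richer than the three-station scheme by which thickness
is actually measured in the field. True area and volume are adaptive
quadratures (`stats::integrate()`, relative tolerance $10^{-8}$) of $w$ and
$w \cdot t$; they are the internal oracle for everything downstream, and
are additive over any partition of the leaf into pieces (a property the
tests check at $10^{-6}$ relative tolerance).

**Midrib as an add-on.** The specimen's midrib volume is *defined* as the
cylinder/cone model volume times a mismatch factor. With mismatch 1,
midrib exclusion is exact on synthetic data — useful for algebraic tests.
The default bench emulation draws the mismatch uniformly in $1 \pm 0.2$,
representing how far a real midrib departs from its idealised solid; the
modelled midrib share of total volume is drawn uniformly over 2–8 %, the
range observed for wheat.

**Populations.** Dimension marginals are log-normal: size traits are
positive and right-skewed, and the protocol source reports only means and
coefficients of variation, which a log-normal matches with two parameters.
(This is a modelling choice, not a documented property of the original
populations.) Default CVs follow the seasonal field survey values
(length ≈ 21 %, width ≈ 19 %, lamina thickness ≈ 13–15 %, midrib
≈ 12–24 %); defaults for the means are 150 mm length, 12 mm width, and a
0.30/0.25/0.20 mm lamina taper, giving a mean thickness of about 0.25 mm.
A Gaussian copula with one exchangeable correlation (default
$\rho = 0.5$) induces the moderate positive inter-dimension correlations
seen in real canopies. Two invariants are enforced after the draw: lamina
base at least as thick as the tip, and basal midrib diameter at least the
basal lamina thickness. `sample_leaf_pieces()` additionally emulates the
bench specimen set: 14 samples with silhouette areas log-uniform over
60–3500 mm², cut from population leaves (or rescaled in plan when the
target exceeds the source leaf's area).

**Scans.** `render_scan()` rasterises the silhouette at 50–2400 dpi with a
seeded random sub-pixel offset and in-plane rotation. The default render is
a binary centre-in-silhouette test with no anti-aliasing, so one aligned
square inch at $r$ dpi contains exactly $r^2$ foreground pixels — the
fixture on which the pixel-to-area constant $25.4^2 = 645.16$ mm²/inch² is
verified. An optional grayscale mode supersamples pixel coverage (4×4
subsamples per pixel by default) and converts it to a green-channel
intensity, to exercise the threshold-segmentation path
(`segmentation_config()`); green is used because it carries the strongest
leaf/background contrast on white card. The rasteriser is compiled (Rcpp)
because it evaluates tens of millions of pixel tests per 1200-dpi scan.

**Instruments.** Weighing simulators add optional Gaussian reading noise
and then quantise to the instrument resolution (0.001 g by default); the
micrometer adds Gaussian reading noise with SD 0.01 mm — the instrument's
resolution — in the pipeline defaults. The low-level `mean_thickness()`
defaults to zero noise so that it doubles as the exact profile-sampling
operator in tests; the experiment configuration supplies the noisy default.
Thickness sampling schemes mirror the field protocols: three-station
averages, readings every 2 cm along the piece (a piece shorter than 2 cm
gets a single mid-piece reading), or a single mid-leaf reading.

**What the generator does not emulate.** Venation, leaf color and texture,
3-D curling and overlap, scanner optics (the scanner is treated as
metrically ideal), glue mounting, water absorption by tissue, and
line/hook volume are all outside the model. Passing tests therefore
demonstrate the *internal* consistency and noise robustness of the
measurement chain under the stated conditions, not the field behaviour of
a physical scanner or balance.

## Agreement statistics

`method_agreement()` is the package's comparison "fit": OLS of the
candidate method on the reference (both the free and through-origin slopes
are reported, since it is not documented whether the original regressions
were forced through zero), Pearson $r$, RMSE, the range-normalised RMSE

$$ NRMSE = 100 \cdot \frac{RMSE}{\max(ref) - \min(ref)} \; [\%], $$

and the Bland–Altman bias and limits of agreement
$\bar d \pm 1.96\,SD(d)$. Sample (n−1) standard deviations are used
throughout, including CV tables, and the 1.96 multiplier is fixed — both
are conventions the source plots do not spell out, documented here as
assumptions. Significance stars in `correlation_matrix()` follow the
two-class convention ($0.001 < P < 0.05$ and $P \le 0.001$, two-sided
t-test, no multiple-testing correction).

## Resampling experiments

**Pile analysis** groups the measured specimens into `n_groups` random
piles of `group_size` (defaults 100 × 7). "Without replacement" is
interpreted within a pile only — members of one pile are distinct, while
specimens recur across piles, since 100 disjoint groups of 7 cannot be
drawn from 14 specimens. The pile's volumetric area divides the *summed
volumes* by the unweighted mean of the member thicknesses:
$VLA_{pile} = \sum_i V_i \,/\, \overline{T}$. The protocol text literally
says to divide the summed *areas* by the mean thickness, which is
dimensionally inconsistent (mm² / mm); dividing summed volumes matches the
defining estimator and reproduces the documented ≈1:1 pile-level
agreement. The literal variant is deliberately kept available
(`pile_vla(mode = "sum_vlas")`) rather than silently corrected. Pile mean
thickness is unweighted (no area weighting is documented); the gap between
this unweighted mean and the volume-weighted truth is precisely the error
the experiment quantifies.

**Thickness sampling** draws 100 groups of 5 from a 35-leaf thickness
population and compares the grand mean of the group means against the
population mean, reporting the percent difference — the direct analogue of
the error that sampling introduces into a pile's $VLA$.

## Numerical and design choices, collected

* Quadrature: adaptive, relative tolerance $10^{-8}$, up to 500
  subdivisions; this is the ground-truth oracle, so its tolerance is set
  well below every test tolerance.
* Water density: embedded 15–30 °C grid at 0.5 °C steps, linear
  interpolation, no extrapolation; grid queries return grid values exactly.
* Balance/load-cell model: Gaussian noise (default 0) then rounding to
  resolution (default 0.001 g); zero-noise round trips recover volume
  within one rounding step divided by $\rho_T$ (≈ 0.5 mm³ per reading).
* Negative volumes: clamped to zero within the rounding bound (warning),
  error beyond it.
* Rotation is drawn uniformly on $[0, \pi)$ and the sub-pixel offset
  uniformly on $[0,1)^2$ pixels; fixed placements are available for exact
  fixtures, and whole-pixel canvas margins never change a pixel count.
* Reference resolution for multi-dpi comparisons is 1200 dpi — the role it
  plays in the resolution study — since the original comparisons do not
  name their reference explicitly.
* All randomness flows from explicit integer seeds through `with_seed()`;
  no hidden global state, and rerunning any pipeline stage with the same
  configuration reproduces its outputs byte-for-byte (timestamps aside).
* Regression orientation in `method_agreement()` is candidate-on-reference
  (VLA on OLA); the reciprocal orientation can be read off the reported
  through-origin slope or refitted from the returned data.

## Problem sizes

The validation suite and the reproduction script run entirely on synthetic
data at the scale of the original bench study: 14 specimens per replicate
set, 20 replicate sets for the agreement and resolution summaries, 100
piles of 7 for the pile analysis, 35-leaf populations with 100 groups of 5
for the thickness-sampling experiment (200 seeds), and 200 replicate sets
for the volume–area correlation. Generator calibration checks use
1000-leaf draws. These sizes were chosen to match the study design where it
is stated and to keep Monte-Carlo error comfortably below the tolerances
being tested elsewhere.

## Limitations

The rasteriser measures silhouettes of the parametric shape family only;
real scanned images can be segmented through the green-channel threshold
path, but no lens distortion, illumination gradient or shadow model is
provided. The midrib correction assumes a single basal diameter per
sample. The agreement module assumes paired, error-in-both-methods data
but fits plain OLS, as the original analysis does; a measurement-error
model (e.g. Deming regression) is out of scope.
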