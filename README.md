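# vleaf — volumetric leaf area measurement and validation

`vleaf` is an R package for estimating the area of a whole pile of leaves
from a single volume measurement. It targets plant scientists who need
destructive, reference-grade leaf area for samples that are tedious to
scan leaf by leaf — the motivating case is wheat at tillering, where
hundreds of small folded leaves arrive in one dense sample.

## The method

Because volume is invariant under folding, a flat organ satisfies
`V = A · T` however crumpled it is. The **volumetric leaf area** of a pile
is therefore

```
VLA = V_l / T_l        [mm² = mm³ / mm]
```

where `V_l` is the pile volume and `T_l` the mean lamina thickness,
estimated by measuring a few leaves with a micrometer. Volume comes from
hydrostatic weighing, in either of two protocols:

* **Suspension technique** — the sample, held under water by a suspended
  retainer, displaces its volume in water; a balance under the container
  reads the displaced-water weight, so `V = ΔW / ρ_T` with `ρ_T` the water
  density at the measured temperature.
* **Specific Gravity Bench (SGB)** — the caged sample hangs from a load
  cell and is immersed by raising the water container;
  `V_l = (W_l1 + W_r1 − W_T2 − V_r·ρ_T) / ρ_T` from the dry weights of pile
  and cage, the underwater weight of the set, and the cage volume `V_r`.

The thick central vein (midrib) does not flatten with the blade; its
volume can be excluded using a cylinder (pieces) or cone (complete leaves)
model, `V_m = L·π·(T_bm/2)²` (cone: one third of that).

The reference method is **optical leaf area** from flatbed scans:
`OLA = 645.16 · SP / r²` mm² for `SP` foreground pixels at `r` dpi
(645.16 = 25.4²). The package implements both methods, the method-agreement
statistics used to compare them (OLS slope, Pearson r, range-normalised
RMSE, Bland–Altman limits of agreement), virtual resampling experiments
(pile analysis, thickness-sampling error), and a fully seeded synthetic
wheat-leaf generator — parametric silhouettes with known area and volume,
rendered scans, simulated balance and micrometer readings — so the whole
chain can be validated against ground truth.

## Worked example

Simulate the reference bench experiment — 14 specimens from under 1 cm² to
full leaves, a 0.001 g balance at 22 °C, micrometer readings every 2 cm
with 0.01 mm noise, scans at 200 and 1200 dpi — and run the complete
analysis:

```r
library(vleaf)
exp <- run_experiment(vla_config(seed = 1))
print(exp)
#> Volumetric leaf-area experiment (n = 14 specimens, seed = 1)
#>   VLA vs OLA: NRMSE 1.759% (midrib incl.) / 1.190% (excl.); slopes 1.0326 / 0.9746
#>   biases 33.33 / -17.15 mm^2
#>   OLA 200 dpi vs 1200 dpi: NRMSE 0.0029%
#>   OLA 1200 dpi vs 1200 dpi: NRMSE 0.0000%
#>   pile analysis: NRMSE 4.116% / 3.366%, slopes 1.0134 / 0.9578
#>   thickness-sampling difference: 0.057%
```

Reading the output: volumetric area tracks the 1200-dpi optical reference
to within ~2 % of the measured area range; including the midrib volume
biases VLA upward (slope 1.03, bias +33 mm²) and excluding the modelled
midrib moves the slope back toward 1. Optical areas at 200 dpi are
practically indistinguishable from 1200 dpi. Estimating pile thickness
from 5 of 35 leaves perturbs the grand mean by well under 1 %.

Each stage is also available on its own:

```r
print(exp$agreement_excl)
#> Method agreement: VLA (midrib excl.) vs OLA (n = 14)
#>   OLS: slope 0.9746, intercept 5.442 (through origin: 0.9770), r = 0.9998
#>   NRMSE 1.190% of the OLA range (RMSE 38.390)
#>   Bland-Altman: bias -17.148, LoA [-87.010, 52.714]
```

`plot(exp$agreement_excl)` draws the scatter-with-identity and
Bland–Altman panels. For real bench data, `measure_vla()` converts a CSV
of weighing records (suspension or SGB columns) and thickness readings
into per-sample volumes and areas; `inst/scripts/vla.R` wraps the
simulate / run-all / measure entry points for shell use.

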