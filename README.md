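# mnlamina

Image-quantification and statistics for linking **micronucleus (MN)
chromosome content to nuclear-lamina organization and membrane rupture**.

Micronuclei form around missegregated chromosomes and are enclosed by their
own, often defective, nuclear envelope. Whether an MN ruptures depends on
the organization of its lamin meshwork: local discontinuities ("lamina
gaps") in the lamin A network precede membrane rupture, which is scored
photometrically as a >60% loss of H3K27ac signal relative to the main
nucleus. `mnlamina` provides the full quantitative tool-chain for this
analysis on super-resolution (STED-like) fluorescence stacks, plus a
synthetic image generator with known ground truth so that every stage is
testable without any raw-data download.

## What it computes

| Stage | Method |
|---|---|
| Meshwork segmentation | per-plane even second-order steerable Gaussian-derivative line filters (default scale 60 nm, 12 orientations) + non-maximum suppression → response-weighted 1-px centerlines |
| Equatorial split | Brenner best-focus score `Σ (I(x+2,y)−I(x,y))² + (I(x,y+2)−I(x,y))²` per plane; hemispheres projected in 2D |
| Gap calling | holes in the projected meshwork, accepted iff area > 0.12 µm² **and** gap/meshwork intensity ratio < 0.5 (both strict) |
| Morphometry | volume = mean of minimum-volume enclosing ellipsoid (Khachiyan) and convex hull of lamin-positive voxels; sphere-equivalent surface `π^{1/3}(6V)^{2/3}`; projected area |
| Intensity & classification | 4-px rim lamin B1 with background subtraction `F_N = F_I − (F_O−F_I)(A_I/A_O)`; rupture iff H3K27ac ratio < 0.4; FISH positive iff ≥ 2× background with centromere overlap; chromosome number = centromere foci |
| Spot density | scale-matched LoG detection at 0.2 µm nominal diameter, count per surface area, normalized to the nucleus |
| LAD genomics | per-chromosome `100·|LAD∖blacklist| / (length−|blacklist|)` on BED intervals |
| Statistics | family test (chi-square / ANOVA / Kruskal–Wallis by Shapiro–Wilk) gating pairwise **Barnard unconditional exact tests**; φ coefficient; Spearman ρ; noncentral chi-square post-hoc power |

## Worked example

Reconstruct the marker-validation contingency table (one group of 193 MN at
94.8% concordance, one of 116 at 7.7%) and test the association; then
generate a synthetic MN carrying one 0.3 µm² lamina gap and recover it:

```r
library(mnlamina)

t_nls <- generate_contingency(193, 0.948, 116, 0.077, expected = TRUE)
t_nls
#>          outcome
#> predictor pos neg
#>       pos 183  10
#>       neg   9 107
phi_coefficient(t_nls)        # 0.8691  -> phi = 0.87
barnard_exact(t_nls)
#> Barnard unconditional exact test (two.sided)
#> statistic = 15.2778, p = 3.24442e-60

spec <- synthetic_mn_spec(gaps = list(
  gap_spec(theta = 0.45, phi = 0.8, area_um2 = 0.3, residual_fraction = 0.1)))
g   <- generate_mn_stack(spec, seed = 7)
res <- analyze_mn_gaps(g$stack, g$truth$footprint)
res$gaps[res$gaps$accepted, c("hemisphere", "area_um2", "mfi_ratio")]
#>    hemisphere area_um2 mfi_ratio
#> 63        top     0.33     0.195
res$summary$has_gap           # TRUE
res$summary$gap_density       # 0.335 gaps per um^2 of MN area
```

The single inserted gap is recovered on the correct hemisphere with a
measured area of 0.33 µm² (truth 0.30 µm²) and an interior intensity ratio
of 0.20, well below the 0.5 cut-off; no normal meshwork face is accepted.

A full simulated run (population → per-MN measurements → family-gated
statistics) is one call:

```r
run_pipeline(analysis_config(), out_dir = "demo",
             n_per_class = c(A = 5L, B = 5L),
             intact_probability = c(0.9, 0.3), seed = 1L)
```

writing `measurements.csv`, `gaps.csv`, `stats.json` and a run manifest;
re-running with the same configuration is a cached no-op. A thin CLI over
the same functions is at `inst/cli/mnlamina.R`.

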