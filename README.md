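# dielniche

Temporal-niche analysis for camera-trapped carnivore guilds.

When several carnivore species share a landscape and a prey base, they
can partition their niche in *time*: shifting activity to different
hours of the day, or tracking the diel rhythm of shared prey. This
package implements the complete analysis chain for testing that with a
year of camera-trap data on a Mediterranean mesocarnivore guild (red
fox, stone marten, European badger, common genet, European wildcat) and
its small-mammal prey — and ships a synthetic-study generator with
exact numerical oracles so the whole pipeline is testable without field
data.

## What it computes

* **Independent contacts** — a greedy 30-min independence filter per
  (site, species), a two-season equinox calendar, and trap-night effort
  accounting.
* **Diel activity densities** — times of day mapped to the circle
  (2π = 24 h) and smoothed with a von Mises kernel whose concentration
  comes from a plug-in rule,
  κ\* = c·[3 n κ̂² I₂(2κ̂) / (4√π I₀(κ̂)²)]^(2/5),
  evaluated on a 144-point grid (one point per 10 min).
* **Activity overlap** — Δ = ∫ min(f, g) estimated by Dhat1 (grid sum,
  adjustment 0.8) when the smaller sample has < 50 contacts, otherwise
  Dhat4 (clipped density ratios at the observed times, adjustment 1.0);
  smooth-bootstrap confidence intervals (B = 1,000, bias-corrected
  percentile) and a pooled-density randomization test with
  p = (1 + #{Δ_null ≤ Δ̂})/(B + 1).
* **Relative Activity Index** — contacts per 100 trap nights per site /
  species / period, screened for spatial autocorrelation (Moran's I,
  inverse-distance weights, permutation test) and camera-model effects
  (permutation test on mean RAI differences, exhaustive mode for exact
  small-sample p).
* **Prey-abundance models** — for each focal species, seasonal RAI per
  linked site (< 3 km from a live-trapping plot) modelled by all 2³
  subsets of {small-mammal abundance, season, other-species RAI} as
  ML random-intercept mixed models; AICc ranking, Akaike weights, and
  cumulative-weight variable importance (influential at w⁺ ≥ 0.50).

## Worked example

The `analysis/` scripts run the full study end to end on synthetic
data (`01_simulate_study.R` … `05_prey_models.R`, outputs under
`results/`). Stage 2, ingestion and filtering, prints:

```
Raw images: 2735 -> independent contacts: 1681
Total effort: 5909 trap nights across 18 sites (mean 328.28 )
Mesocarnivore contacts: 951 - shares (%):
        label contacts share_pct
      red_fox      449     47.21
 stone_marten      232     24.40
       badger      131     13.77
        genet      118     12.41
      wildcat       21      2.21
```

Reading: 2,735 raw images collapse to 1,681 independent contacts once
photo bursts inside the 30-min window are removed; effort is 5,909
trap nights over 18 sites; and the guild's detection shares keep the
fox > marten > badger > genet > wildcat ordering the generator plants.

A single comparison in code:

```r
library(dielniche)
set.seed(1)
fox   <- rvonmises(300, 23/24 * 2*pi, 1.5)   # nocturnal, broad
genet <- sample_vonmises_mixture(
  vm_mixture(c(.5, .5), c(21, 5)/24 * 2*pi, c(2.5, 2.5)), 120)

smooth_bootstrap_ci(fox, genet, B = 1000, seed = 2)
#> Dhat4 = 0.732, 95% CI [0.649, 0.812] (B = 1000, smooth bootstrap, bias-corrected percentile interval)
null_overlap_test(fox, genet, B = 1000, seed = 3)
#> Dhat4 = 0.732 vs pooled null (mean 0.930): p = 0.0010 (B = 1000)
```

Both samples are nocturnal, so nearly three-quarters of the activity
area is shared (Δ̂₄ = 0.73) — but that is still far less overlap than
same-pattern sampling noise allows (null mean 0.93), so the bimodal
genet pattern differs significantly from the broad fox pattern
(p = .001).

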