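# paleoenamel

Micro-CT densitometry and X-ray-fluorescence screening for archaeological
teeth: is a discoloured enamel area an **ante-mortem hypomineralised lesion**
(MIH — Molar Incisor Hypomineralisation — or HSPM on second primary molars),
or **post-mortem taphonomic discoloration** (soil Fe/Mn staining, acid
dissolution)?

The two look alike. Expert panels rating photographs of archaeological
specimens agree at or below chance (Fleiss' κ < 0), so the call must come
from microanalysis. This package implements that analytical chain for
anthropologists and palaeopathologists, validated end-to-end on synthetic
enamel phantoms with known ground truth.

## The method

Grey level (GL) in a 16-bit micro-CT reconstruction is an uncalibrated proxy
for mineral density. For a tooth with a discoloured area:

* **3D densitometry** — five ≈49 µm cubes along a surface→DEJ transect in a
  normal area and in the discoloured area at the same coronal height (cube 1
  at the surface, cube 5 at the DEJ, the rest at midway splits), in two
  rounds. The ten paired differences mdd = GL(normal) − GL(discoloured) are
  tested with a two-sided Wilcoxon signed-rank test (normal approximation:
  z = (W − n(n+1)/4)/√(n(n+1)(2n+1)/24), no continuity correction; for ten
  same-sign pairs p = 0.005).
* **2D profiles** — 99 equidistant GL measurements from the DEJ to the
  surface per area. Normal enamel rises steadily DEJ→surface;
  hypomineralised enamel shows the *reverse* gradient, and the deficit curve
  (normal − lesion)/normal typically peaks mid-enamel (≈5–28% in
  hypomineralised teeth).
* **XRF screen** — paired discoloured (DC) vs normal (NO) relative
  concentrations of Mn, Fe, Cu, Pb; an element is flagged when the DC/NO
  fold change is ≥3 with non-overlapping repeats.
* **Diagnosis** — a rule table over predicates D (significant density
  deficit), R (gradient reversal), C (elemental contamination), S
  (surface-shell-restricted deficit):
  D∧R∧C → hypomineralised with post-mortem uptake; D∧R∧¬C →
  hypomineralised; ¬D∧C → taphonomic stain; D∧¬R∧S → acid-dissolution
  suspect; ¬D∧¬C → sound; otherwise indeterminate.

Self-contained statistics: exact (full 2^n enumeration with midranks) and
normal-approximation Wilcoxon signed-rank, and Fleiss' kappa.

## Worked example

```r
library(paleoenamel)
ph  <- generate_phantom(phantom_spec(lesion_class = "hypomineralised",
                                     deficit_mid = 0.10, noise_sd = 510,
                                     seed = 7))
ana <- analyse_phantom(ph)
ana$evidence$density_test
#> Paired cube densitometry (hypomineralised)
#>           mdd1   mdd2   mdd3   mdd4   mdd5
#> round 1 3452.3 3076.1 2569.2 2084.2 1686.4
#> round 2 3473.1 3053.7 2545.0 2109.5 1643.3
#>   two-sided p = 0.005 *
ana$evidence$profile_cmp
#> profile comparison: mid-enamel deficit 10.1%, max 14.6%
#>   normal: increasing  lesion: reversed
ana$diagnosis
#> Diagnosis: hypomineralised
#>   D (density deficit: p 0.005062 < 0.05 and median mdd 2557.1 > 0) = TRUE
#>   R (gradient reversal: lesion reversed, normal increasing) = TRUE
#>   C (elemental contamination: ) = FALSE
#>   S (surface-shell deficit, boundary u = 0.7) = FALSE
#>   fired: hypomineralised
```

Reading the output: all ten mineral-density differences are positive (the
discoloured area is less dense in every cube, both rounds), giving the
all-positive signed-rank p of 0.005; the profile comparison recovers the
programmed 10% mid-enamel deficit and the reverse gradient; with no XRF
enrichment the rule table lands on an ante-mortem hypomineralised lesion.

The same chain runs on real data (multi-page 16-bit TIFF + YAML voxel-size
sidecar, landmark CSV, XRF CSV) through `run_pipeline()` or the CLI:

```sh
inst/cli/paleoenamel run --config config.yaml --seed 1 --out results/
```

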