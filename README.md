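# casarabe

Population models for the Casarabe Culture of the Llanos de Moxos
(Amazonian Bolivia), the pre-Columbian society that built monumental
habitation mounds linked by causeways and canals across a seasonally
flooded forest–savanna mosaic between 400 and 1400 CE. The package is a
tested, reusable implementation of a three-part population analysis for
archaeologists and human-population ecologists:

* **Architectural energetics** — a *minimum* population from the labour
  embodied in the earthworks. Daily volumes `T_md = T_m/(D·Y)` and
  `T_cd = T_c/(D·Y)` are converted to a workforce
  `P_W = T_md/E_mx + T_md/E_mt + T_cd/E_cx + T_cd/E_ct`
  (excavators + transporters, mounds + network), with transport rates from
  the Pandolf load-carriage equation
  `Ė = 1.5M + 2(M+Q)(Q/M)² + μ(M+Q)(1.5V² + 0.35VG)`
  solved for loaded walking speed at constant energy expenditure.
* **Maximum carrying capacity** — a *maximum* sustainable population from
  per-capita land requirements: `L_PM = Cons_P·C/L_R` for swidden maize
  (cultivation factor `C = Fal_yr/Crop_yr + 1`) and `L_PF` for fuelwood,
  evaluated as `k = L_T/(L_PM + L_PF)`-style allocations under
  savanna-only, forest-only and mixed scenarios, on the full landscape and
  within a 7 km daily walking radius of the mounds.
* **A household-level settlement simulator** — an agent-based model of
  demography (annual birth draws `u ≤ b_h`, an age-specific mortality
  schedule with certain death at 80), resource-limited subsistence on a
  grid of 1-ha patches, and migration with settlement founding scored by
  weighted fertile-sediment, distance and crowding utilities. Latin
  hypercube experiment designs and a spatial-configuration distance metric
  (nearest-neighbour, centroid and dispersion components, in km) compare
  simulated settlement patterns against reference mound sets, with the
  settlement-count success window `round(n_ref·(1 ± 0.2))`.

A seeded synthetic landscape generator supplies gridded test landscapes
(dendritic forested levee corridors, compact water bodies, one contiguous
fertile sediment lobe) so the whole pipeline runs with no external data.

## Worked example

```r
library(casarabe)
library(dplyr)

# Carrying capacity from the published study-area figures
# (4887 km2 terrestrial, 39.87% forest)
areas_full <- tibble::tibble(forest_area = 4887 * 0.3987,
                             savanna_area = 4887 * (1 - 0.3987))
capacity_table(areas_full = areas_full, L_R_grid = c(300, 900, 1800)) |>
  select(maize_yield, forest_only, savanna_only, mixed)
#>   maize_yield forest_only savanna_only  mixed
#> 1         300       61740       114227 154853
#> 2         900      135228       334019 334019
#> 3        1800      192516       334019 334019

# Energetics sweep at daily volumes back-derived from the published table
inv <- build_inventory(mound_areas = 2043.85 * 18000 / 30000, ratio = 30000,
                       network_length = 729.2 * 18000 / 5)
sw <- energetics_sweep(inv, E_mt = 2043.85 / 2783, E_ct = 729.2 / 22)
head(select(sw, excavation_rate:population_1_2), 3)
#>   excavation_rate canal_excavators mound_excavators canal_transporters
#> 1             1.4              521             1460                 22
#> 2             1.3              561             1572                 22
#> 3             1.2              608             1703                 22
#>   mound_transporters total_workforce population_1_2
#> 1               2783            4786           9572
#> 2               2783            4938           9876
#> 3               2783            5116          10232

success_window(119)
#>  low high
#>   95  143
```

Reading the output: at the lowest assumed maize yield (300 kg/ha) the
savanna-only strategy supports about 114,000 people and becomes
fuelwood-limited (334,019, flat across yields) from 900 kg/ha upward. The
energetics sweep says that at the fastest digging-stick excavation rate
(1.4 m³/day) the earthworks required a standing labour force of about
4,800, i.e. a population near 9,600 at a 1:2 workforce ratio. A simulated
settlement pattern "matches" the 119 reference mounds when its count falls
in 95–143.

A full simulation run:

```r
land  <- generate_landscape(synth_params(n_rows = 100, n_cols = 100, seed = 1))
sites <- generate_sites(land, n = 20, seed = 1)
cfg   <- abm_config(seed = 1, migration_distance = 10)
ens   <- run_ensemble(cfg, land, sites, n_runs = 5, years = 200)
glance(ens)
autoplot(ens)
```

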