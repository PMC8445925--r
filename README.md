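# proboscipeda

Demographic inference from fossil elephant tracks.

A densely trampled surface is a snapshot census: every animal that crossed
the soft substrate left prints whose size scales with its body. This package
turns a table of proboscidean footprint measurements into per-individual
body-size, mass and age estimates, and from those into the age-class
frequency structure of the herd that made the tracks. It was built around
the track assemblage of the Matalascañas Trampled Surface (MTS, Huelva,
SW Spain; MIS 5), whose 34 measured prints of straight-tusked elephants are
packaged as the worked fixture `mts_table1()`.

## The model

Foot length *FL* (cm, the print's axial length) predicts shoulder height
(cm) through sex-specific linear regressions calibrated on extant savanna
elephants, and height predicts body mass (kg) through a species-specific
power law:

    ESH(male)   = 10.22 + 5.816 × FL
    ESH(female) = 3.044 + 5.466 × FL
    EBM         = 3.63e-4 × ESH^2.903

Age comes from inverting a Von Bertalanffy growth curve
`h(t) = H∞ (1 − exp(−k (t − t0)))`; heights near the asymptote yield
censored ("at least this old") estimates. Individuals are assigned to five
age classes — calves [0,2), juveniles [2,8), adolescents [8,15],
adults (>15), and old bulls (adults with tracks over 50 cm, a size no
female reaches) — and tabulated into a demographic frequency table.

A seeded herd simulator (`simulate_herd()`) generates synthetic assemblages
with known composition, closing the loop: `recovery_report()` measures how
well the pipeline recovers the heights, masses and class frequencies that
generated the tracks.

## Worked example

```r
library(proboscipeda)

tab <- mts_table1()                 # the packaged MTS track table
est <- estimate_tracks(tab)         # height, mass, age under both sexes
head(est[, c("record_id", "limb", "fl_cm", "esh_m_cm", "ebm_m_kg",
             "esh_f_cm", "ebm_f_kg")], 4)
#>      record_id  limb fl_cm esh_m_cm ebm_m_kg esh_f_cm ebm_f_kg
#> 1  PAT/MTS/005   pes   9.6       66       70       56       43
#> 2 PAT/MTS/012x manus   9.6       66       70       56       43
#> 3  PAT/MTS/016 manus  10.0       68       76       58       48
#> 4 PAT/MTS/011a manus  10.8       73       93       62       58
```

The smallest print (9.6 cm) belongs to an animal of about 56–66 cm at the
shoulder and 43–70 kg depending on sex — a newborn calf. Collapsing the 34
records to individuals and classifying:

```r
demographic_frequency(tab)
#> Demographic frequency ( 33 individuals )
#>   calf        15 ###############
#>   juvenile     7 #######
#>   adolescent   5 #####
#>   adult        4 ####
#>   old_bull     2 ##
#>   class conflicts resolved by representative track: 005.
```

Nearly half the individuals are calves and only two tracks exceed 50 cm —
the size structure of a matriarchal nursery herd visited by the odd
solitary bull. Validating the machinery on a simulated herd:

```r
sim <- simulate_herd(herd_config(n_individuals = 500), seed = 1)
recovery_report(sim)
#> Parameter recovery over 500 individuals
#>   height bias +0.836%, rel. RMSE 3.52%
#>   mass   bias +2.65%, rel. RMSE 10.8%
#>   class frequency error (pp):
#>       calf   juvenile adolescent      adult   old_bull
#>       -3.2        3.0       -2.0        2.2        0.0
```

See `vignettes/track-demography.Rmd` for the full account of the model,
the censoring rules, the default growth-curve anchors (the published
curves' parameters were never printed), the screening ambiguity, and what
the simulator does and does not emulate.

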