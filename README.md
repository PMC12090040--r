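# dendrotraits

Multi-proxy tree-ring analysis of long-term conifer decline. The package
is built for dendroecologists and tree ecophysiologists who want to ask,
from tree-ring archives alone, why co-occurring conifer species (and
healthy vs. declining individuals within a species) diverge under rising
atmospheric CO2 and recurring drought. It derives three trait families
from the same rings —

- **growth**: basal area increments `BAI_t = π(R_t² − R_{t−1}²)` with
  drought resistance/recovery/resilience ratios and recovery periods;
- **wood anatomy**: per-tracheid lumen area (LA), cell-wall thickness
  (CWT, mean of four walls), Mork earlywood/latewood partition
  (EW iff LD ≥ 4·CWT), Hagen–Poiseuille theoretical hydraulic
  conductivity `KH = Σ πd⁴/(128η)`, implosion safety `(T/B)²`, and
  standardized tracheidograms with dry/average/wet Kolmogorov–Smirnov
  contrasts;
- **physiology**: intrinsic water-use efficiency from tree-ring δ13C via
  `Δ13C = (δ_air − δ_tree)/(1 + δ_tree/1000)` and
  `iWUE = c_a (b − Δ13C)/(1.6 (b − a))` with a = 4‰, b = 27‰

— and then quantifies trait plasticity with per-species generalized
additive models

    iWUE ~ Status + s(CO2) + s(CO2, by Status) + s(SPEI12) + s(SPEI12, by Period×Status)

(four-knot cubic splines, AIC selection under ML, REML refit), including
first-derivative slope curves ΔiWUE/ΔCO2 with 95% intervals and
percent-change summaries. Drought is measured by the Standardised
Precipitation-Evapotranspiration Index (SPEI; Thornthwaite PET,
log-logistic fitted by unbiased probability-weighted moments) at 3/6/12
months, with August SPEI12 as the annual drought axis.

A seeded synthetic-data generator (`default_truth()`, `generate_*`)
emulates the full study design — three Mediterranean conifers × health
statuses, 1978–2016, planted extreme droughts, a post-1995 decline
divergence, 5-year pooled juniper isotope records — with known ground
truth, so the whole pipeline is testable without field data. The methods
vignette (`vignettes/methods.Rmd`) documents every model and choice.

## Worked example

End to end on the default synthetic scenario:

```r
library(dendrotraits)
cfg <- default_config(outdir = "results/run", seed = 1)
manifest <- run_pipeline(cfg)
read.csv("results/run/iwue_percent_change.csv")[1:8, c(1, 2, 5, 6)]
```

```
    species    status pct_change  interval
1 oxycedrus   healthy      10.18 1978-1995
2 oxycedrus   healthy      15.42 1996-2016
3  pinaster   healthy      31.42 1978-1995
4  pinaster      dead      21.66 1978-1995
5  pinaster declining      13.45 1978-1995
6  pinaster   healthy       5.88 1996-2016
7  pinaster      dead       1.45 1996-2016
8  pinaster declining       0.96 1996-2016
```

These are model-based iWUE changes per health status, evaluated on the
fitted iWUE–CO2 response at each interval's CO2 endpoints: while CO2 rose
~7.5% (335→360 ppm, 1978–1995), iWUE in the drought-sensitive pine rose
~31% in healthy but only ~13–22% in declining and dead trees; over the
subsequent ~12% CO2 rise (360→404 ppm) the non-healthy response is
essentially flat (≈1%) — the loss of stomatal-regulation sensitivity to
CO2 that marks the decline. The same run writes the BAI chronologies and
resilience indices, the ring-anatomy trait table with mixed-model letter
displays, the intra-ring dry/wet KS contrasts (significant for lumen area
in all groups, with the planted 40% earlywood reduction), the ΔiWUE/ΔCO2
derivative curves (non-healthy intervals covering zero above ~380 ppm),
and a manifest with row counts and MD5 checksums — two runs with the same
seed are byte-identical.

The numbered scripts under `analysis/` run the same stages with narrative
output: `Rscript analysis/01_simulate.R` through
`analysis/06_response_models.R`, writing tables under `results/`.

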