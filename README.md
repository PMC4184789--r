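# otoscape

Otolith oxygen-isotope isoscapes, sub-stock discrimination, and temperature
proxies for fish movement ecology.

## The problem

Fish otoliths ("ear-stones") accrete aragonite continuously and in
equilibrium-like exchange with ambient water, so the oxygen isotope ratio
(δ¹⁸O, per mil vs VPDB) laid down in each growth increment is a chemical
archive of the temperature and salinity a fish experienced. Two standard
relations link environment to otolith chemistry:

1. a linear seawater mixing line, δ¹⁸O_w (VSMOW) = γ·S + δ₀, because the
   freshwater end-member is isotopically light;
2. a temperature-dependent aragonite–water fractionation of the
   palaeothermometric form

   1000·ln α = a·10³/T + b,  α = (1000 + δ¹⁸O_o)/(1000 + δ¹⁸O_w),  T in K,

   with a > 0, so otolith δ¹⁸O falls as temperature rises
   (about −0.22 ‰ per °C in North Sea conditions).

`otoscape` turns these relations into a tested pipeline for the questions a
stock-assessment or sclerochronology group actually asks:

* **Isoscapes** — predict monthly otolith δ¹⁸O over a 0.5° grid from
  modelled bottom temperature and salinity fields.
* **Stock signatures** — simulate annual δ¹⁸O signatures per sub-stock by
  running occupancy-constrained random walks over monthly distribution maps
  (cells holding 80 % of geolocations) and weighting monthly values by
  otolith growth scenarios (OG1 constant; OG2 opaque zone = 60 % of annual
  growth; OG3 additionally 40 % slower during the three breeding months).
* **Assignment** — a univariate Gaussian linear discriminant with exact
  leave-one-out training accuracy, then assignment of measured annual
  values to sub-stocks.
* **Individual validation** — predict daily δ¹⁸O from archival-tag
  temperature records, align measured intra-annual ion-probe profiles to
  calendar time by matching seasonal turning points, and test
  measured-minus-predicted offsets at the annual extremes ("vital
  effects") with one-sided paired Wilcoxon tests.
* **Synthetic data** — seeded generators for every input (fields, tracks,
  tag records, otolith measurements) so the whole pipeline is testable
  without any proprietary hydrodynamic or tag data.

## Worked example

Isotope arithmetic (the core chain, salinity → water δ¹⁸O → scale
conversion → otolith δ¹⁸O → inverted temperature):

```r
library(otoscape)
dw <- convert_scale(salinity_to_water_d18O(35), "VPDB")
#> <delta_value> water d18O (VPDB), n = 1
#> [1] -29.68899
predict_otolith_d18O(283.15, dw)                 # 10 degC
#> <delta_value> otolith d18O (VPDB), n = 1
#> [1] 1.869854
invert_temperature(predict_otolith_d18O(283.15, dw), dw) - 273.15
#> [1] 10
temperature_bias_per_salinity()                  # North Sea mixing line
#> [1] 1.31      # degC of spurious warming per +1 salinity unit
temperature_bias_per_salinity("natl-mixing")
#> [1] 2.49      # the same error under the North Atlantic relation
delta_temperature_equivalent(-0.5)
#> [1] 2.30      # degC equivalent to a 0.5 permil otolith offset
```

So a 1-unit salinity mis-specification masquerades as a ~1.3 °C temperature
error (2.5 °C with the steeper open-ocean mixing line), and a half-per-mil
vital effect is worth ~2.3 °C — the core caveats for using otoliths as
thermometers.

Full pipeline on synthetic data:

```r
cfg <- pipeline_config(out_dir = "demo", seed = 1,
                       synth = synth_config(seed = 1, n_fish_per_stock = 4,
                                            record_days_range = c(300, 400),
                                            tag_cadence_min = 240),
                       n_paths = 2000)
s <- run_pipeline(cfg)
#> ... simulate: stock A -> 2000 paths, 6000 annual values ...
#> ... classify: LOO accuracy 90.23% on 18000 training values
#> ... assign: 12 measured values, accuracy 75.00%
s$ensemble
#>   stock    n  mean     sd
#>       A 6000 1.92  0.074
#>       B 6000 1.34  0.068
#>       C 6000 1.48  0.055
```

The ensemble means order A > C > B: the northern stock lives coldest and so
carries the heaviest signature, while the eastern stock's fresher water
depresses its δ¹⁸O below the western stock at similar temperatures. The
measured values are generated *with* stock-specific vital-effect offsets
(the default world), so assignment of individuals is imperfect and the
errors concentrate in the B/C overlap — exactly the failure mode this kind
of analysis needs to expose. Stage tables (`ensembles.csv`,
`assignment.csv`, `offsets.csv`), `summary.json` and a log are written to
`out_dir`.

A command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/otoscape.R", package="otoscape"))')" \
    all --out demo --seed 1
```

## Documentation

The methods vignette (`vignettes/otolith-isoscape-methods.Rmd`) describes
the model, the growth-weighting and random-walk assumptions, what the
synthetic world does and does not emulate, and the numerical choices;
function-level documentation is in the roxygen comments under `R/`.
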