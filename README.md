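# syntherm

Bioenergetics of competing acetate-degrading methanogenic pathways in a
defined thermophilic consortium.

## The problem

In methanogenic environments acetate is converted to CH₄ by two competing
routes. An aceticlastic methanogen (*Methanosaeta thermophila*) cleaves it
directly:

    CH₃COO⁻ + H₂O → CH₄ + HCO₃⁻              ΔG°′ = −31.0 kJ/mol

A syntrophic pair runs the same net reaction in two steps: a
syntrophic acetate-oxidizing bacterium (*Thermacetogenium phaeum*),

    CH₃COO⁻ + 4 H₂O → 2 HCO₃⁻ + 4 H₂ + H⁺    ΔG°′ = +104.6 kJ/mol

coupled to a hydrogenotrophic methanogen
(*Methanothermobacter thermautotrophicus*),

    4 H₂ + HCO₃⁻ + H⁺ → CH₄ + 3 H₂O          ΔG°′ = −135.6 kJ/mol

The oxidation step is feasible only at extremely low H₂ partial pressure,
and both partners must simultaneously clear the minimum catabolic energy
quantum of about −20 kJ per mol of reaction. Because bicarbonate is a
*product* of acetate oxidation (coefficient +2) but a *substrate* of
hydrogenotrophic methanogenesis (−1), elevated CO₂ squeezes the oxidizer
from both sides: the in-situ energy

    ΔG = ΔG°′ + RT ln Q

rises with [HCO₃⁻], while the compensating H₂ decrease is floored by the
hydrogenotroph's own threshold. `syntherm` implements this analysis
end-to-end: closed-vial carbonate speciation of the culture media, ΔG of
all three reactions along batch time courses, log-phase averaging,
threshold classification, H₂ counterfactuals and feasibility windows,
methanogenic rates, 16S copy-number normalization — plus a synthetic
tri-culture generator with known ground truth standing in for unpublished
culture measurements.

## Worked example

```r
library(syntherm)
library(dplyr)

tc <- simulate_cultures(generator_config(), seed = 1)   # 3 conditions x 3 replicates x 16 days
series <- compute_dg_series(tc)                         # per-replicate, per-day dG
logphase_summary(series) |>
  filter(reaction == "acetate_oxidation")
#>   condition reaction          day_start day_end     n mean_dg sd_dg exceeds
#> 1 low       acetate_oxidation         2       5    12     0.1    2.2   TRUE
#> 2 mid       acetate_oxidation         2       5    12     3.9    0.9   TRUE
#> 3 high      acetate_oxidation         2       5    12     5.2    0.7   TRUE
```

The acetate oxidizer's log-phase mean ΔG rises strictly as the initial
inorganic carbon load grows from 5.0 to 52.8 to 124.1 mmol per liter of
medium, while the aceticlastic mean moves by under 5 kJ/mol — the
thermodynamic signature of the switch from syntrophic to aceticlastic
dominance under elevated CO₂. The counterfactual of the classic worked
example — a hydrogenotrophic ΔG of −25.1 kJ/mol measured at 16.4 Pa H₂,
re-evaluated at 10 Pa and 55 °C — is one call:

```r
shift_h2(-25.1, "hydrogenotrophic", p_h2_from_pa = 16.4, p_h2_to_pa = 10)
#> [1] -19.70108
```

`run_pipeline("out/", seed = 1)` chains simulate → speciate → analyze and
writes `timecourse.csv`, `speciation.csv`, `deltag_series.csv`,
`logphase_summary.csv`, `counterfactual.csv`, `rates.csv`,
`relative_rates.csv`, `abundance_relative.csv`, a resolved `config.yaml`
and a `manifest.json`, all stamped with the configuration hash; rerunning
with the same seed reproduces every numeric output byte for byte. A thin
CLI wrapper with `simulate | speciate | deltag | analyze | run`
subcommands lives at `inst/cli/consortium.R`.

The methods vignette (`vignettes/consortium-bioenergetics.Rmd`) documents
the model conventions, the generator's design and what it does and does
not emulate, numerical choices, and known limitations.

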