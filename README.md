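# thermolegacy

Marine sediment and seawater microbiomes carry enzymes whose thermal
behaviour tracks the thermal history of their habitat: the warmer a site's
mean annual temperature (MAT), the higher the temperature optimum
(T<sub>opt</sub>), denaturation temperature (T<sub>d</sub>) and structural
phase transition temperature (T<sub>p</sub>) of its enzymes, and sites with
wide annual temperature swings select communities with broader thermal
plasticity. `thermolegacy` implements the computational chain needed to
quantify these phenotypes and relate them to habitat covariates, for
microbial ecologists and enzymologists working with microplate kinetics,
CD melting scans and protein structures.

## What it computes

* **T_opt** — specific activities from absorbance kinetics via
  `Rate = (ΔAbs/min / ε) · (1/0.4 cm) · 10⁶ · 0.0002 L · (1/mg protein)`
  (initial-rate slope on the longest linear prefix), relative thermal
  activity profiles, and the grid argmax.
* **T_d** — five-parameter sigmoid fits
  `θ(T) = y₀ + a / (1 + e^{-(T-T₀)/b})^c` of θ₂₂₀(T) melting curves;
  T_d is the max-slope temperature `T₀ + b ln c`.
* **T_p** — FIRST-style constraint networks (bodies = atoms; bars:
  rotatable covalent 5, locked 6, H-bond/salt bridge 5 with Mayo energies,
  hydrophobic tether 2), the (6,6) body-bar pebble game for rigid-cluster
  decomposition, thermal dilution of H-bonds over
  E_cut ∈ {-0.1, …, -6.0} kcal/mol mapped to temperature by
  `T = -(20 K·mol/kcal)·E_cut + 300 K` (302–420 K in 2 K steps), the
  cluster configuration entropy H_type2, and a double-sigmoid fit whose
  largest-slope transition is T_p (second transition when T_d > 50 °C).
* **Statistics** — OLS with AIC ladders over {MAT, pH, salinity},
  continuous two-segment (breakpoint) regression, Brown–Forsythe/Levene
  variance tests, thermal-variability summaries (ΔT and time-in-bin for
  {<28, 28–31, >31} °C), OD₆₀₀ growth rates with the 0.15 no-growth
  threshold, one-way ANOVA.
* **Synthetic data** — generators for all inputs (site tables, assay
  plates, melting curves, planted-transition constraint networks,
  seasonal temperature logs, logistic growth curves) with exposed ground
  truth, so the whole pipeline is testable offline.

## Worked example

```r
library(thermolegacy)

# Eq.-style specific activity: slope 0.4147 AU/min, eps 4147 /M/cm,
# 0.4 cm path, 0.0002 L, 0.001 mg protein
initial_rate(0:9, 0.4147 * (0:9), epsilon = 4147, protein_mass = 0.001)$rate
#> [1] 50    # umol min^-1 mg^-1

# rigidity: a 30-body toy network planted to collapse at E_cut = -3.0
tp <- compute_tp(dilute(gen_toy_network(30, -3, gen_config(seed = 1))))
tp
#> Tp = 359.0 K (85.8 degC), rule: single_transition
# (planted transition maps to 360 K; recovered within one 2 K step)

# full synthetic pipeline: simulate -> kinetics -> melting -> rigidity -> stats
rep <- run_pipeline(pipeline_config(seed = 1))
rep
#> Pipeline report (seed 1, hash 18b1446b, 3.9 s)
#>   14 sites | Topt~MAT slope 1.876 (R2 0.93) | Td~MAT slope 0.906 | Tp~MAT slope 0.909
rep$ladder
#>                 model df_treatment df_residual        r2     aic  best
#> 1           Intercept            0          13        NA 108.415 FALSE
#> 2                 MAT            1          12 0.9323751  72.702  TRUE
#> 3                  pH            1          12 0.4921102 100.930 FALSE
#> ...
```

The ladder reproduces the transect layout (n = 14; residual df 12 for a
one-covariate model) and attributes the simulated thermal response to MAT,
the planted driver. The recovered T_opt slope (1.876) sits near the
generating 1.944 °C/°C; T_d and T_p recover their planted values within
0.5 °C and 2 K respectively.

A command-line entry point covering every stage
(`simulate | profile | melt | rigidity | regress | segmented | variability |
growth | anova | run`) is installed at `inst/cli/thermolegacy.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/thermolegacy.R", package="thermolegacy"))')" \
  run --seed 1 --out run1
```

## Layout

`R/` implementation (simgen, kinetics, curves, rigidity, stats, io/cli) ·
`tests/testthat/` unit, property and acceptance suites with independent
oracles (generic rigidity-matrix rank oracle, duplicate Mayo-energy
implementation, `nls` cross-check) · `vignettes/thermolegacy-methods.Rmd`
the methods notes · `inst/extdata/` a small synthetic PDB fixture.
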