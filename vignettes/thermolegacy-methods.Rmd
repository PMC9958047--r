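---
title: "Methods: enzyme thermal phenotypes and habitat thermal legacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enzyme thermal phenotypes and habitat thermal legacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermolegacy)
```

`thermolegacy` quantifies three thermal phenotypes of microbial enzymes —
the activity optimum T_opt, the denaturation temperature T_d and the
rigidity phase transition temperature T_p — and relates them to the
thermal legacy of the habitat (mean annual temperature and its annual
variability). This vignette records the models, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and
do not establish.

## Kinetics and T_opt

Specific activity is computed from the initial slope of a blank-corrected
absorbance trace:

$$\mathrm{Rate}\;[\mu mol\,min^{-1}mg^{-1}] =
\frac{\Delta Abs/min}{\varepsilon}\cdot\frac{1}{0.4\,cm}\cdot 10^{6}
\cdot 0.0002\,L\cdot\frac{1}{mg\ protein}$$

with defaults matching the microplate assay (path 0.4 cm, volume 0.2 mL;
for the esterase substrate, 4-nitrophenol detection at 348 nm with
ε = 4147 M⁻¹cm⁻¹). The *initial* window is defined as the longest prefix
of the trace whose linear fit has R² ≥ 0.98 (minimum 5 points): the assay
literature reports "initial rates" without a window rule, and this prefix
rule is deterministic, trims substrate-depletion curvature, and degrades
gracefully to the full trace for linear data. Negative slopes are clipped
to zero with a flag — after blank correction an activity cannot be
negative.

T_opt is the argmax of the replicate-mean activity **on the tested grid**
(ties to the lowest temperature, flagged): reported optima in this field
are tested temperatures, not interpolants. A smoothed (quadratic-vertex)
mode exists but is off by default. The replicate SD of T_opt comes from
per-replicate argmaxes, the convention adopted for the ambiguous
"mean ± SD" of the source protocols.

## Melting curves and T_d

CD ellipticity at 220 nm versus temperature is fitted with the
five-parameter (Richards-type) sigmoid
θ(T) = y₀ + a/(1+e^{-(T-T₀)/b})^c — the "sigmoid, 5 parameter" family of
the plotting software named by the protocol, which names the tool rather
than the formula. T_d is the temperature of maximum |dθ/dT| of the fitted
curve, analytically T₀ + b·ln c; its SD uses the delta method on the
Gauss–Newton covariance (the "SD of the fit" phrasing in the protocols is
ambiguous between this and a linearized mid-region fit; the covariance
version is adopted and stated here). Optimisation is multi-start
(five starts at data quantiles, Nelder–Mead then BFGS, fixed order), so
convergence behaviour is deterministic. A fit explaining < 20% of the
signal variance (e.g. a flat, amplitude-zero curve) is flagged
non-converged and reports no T_d.

## Constraint networks, the pebble game and T_p

Atoms are rigid bodies; constraints are bars with the FIRST multiplicities:
rotatable covalent bonds 5 bars, locked bonds (peptide C–N, carbonyl C=O)
6 bars, hydrogen bonds and salt bridges 5 bars, hydrophobic tethers
(nonpolar C/S pairs within van der Waals contact + 0.25 Å, capped at
3.5 Å) 2 bars. Hydrogen bonds pass geometric screens (H…A ≤ 2.6 Å,
D…A ≤ 3.6 Å, ∠DHA ≥ 90°) plus a minimum covalent separation of 4 bonds
between donor and acceptor — without the separation rule the screens
accept chemically meaningless same-residue amide–carbonyl contacts. Each
bond gets the Mayo-form energy
E = V₀(5(R₀/R)¹² − 6(R₀/R)¹⁰)·cos²θ_DHA with V₀ = 8 kcal/mol and
R₀ = 2.8 Å; the angular factor is a deliberate single-term simplification
of the hybridization-dependent Mayo terms (ideal linear geometry at R₀
gives −V₀, perpendicular geometry gives 0). Salt bridges get Mayo energies
by default, with a config override to a fixed −10 kcal/mol (the original
tooling does not state which it uses).

Rigid clusters come from the (6,6) body-bar pebble game: every body holds
6 pebbles, a bar is independent iff 7 pebbles can be gathered on its
endpoints, and two bodies are mutually rigid iff a 7th pebble can no
longer be gathered on the pair. Mutual rigidity is an equivalence relation
for body-bar frameworks, and a rigid cluster is connected inside itself,
so clusters are computed by union-find over adjacent pairs. Bars are
processed in a canonical sort order, making the decomposition invariant
under permutation of the input rows. The implementation is validated
against an independent generic rigidity-matrix rank oracle (random
attachment points, bar direction = vector between them, null-space twist
comparison) on hundreds of seeded networks of up to 12 bodies.

Thermal unfolding removes H-bond/salt-bridge bars with E_HB > E_cut along
the schedule E_cut = −0.1 … −6.0 kcal/mol in 0.1 steps (covalent bars and
tethers are never diluted), recomputing the decomposition at each step.
The cutoff maps to temperature by the linear law T = −20·E_cut + 300
(in K), i.e. 302–420 K in 2 K steps; the two endpoints are the package's
exact acceptance targets.

Global stability is tracked by the cluster configuration entropy with
size-squared weights over clusters, H = −Σᵢ wᵢ ln wᵢ,
wᵢ = sᵢ²/Σⱼ sⱼ². **Normalization note:** the CNA literature's exact
H_type2 normalization is not printed in the source protocol; a
size-class-summed variant collapses k equal clusters to H = 0, while the
per-cluster form used here gives the required closed forms (0 for one
spanning cluster, ln k for k equal clusters) and the required jump when
the largest cluster stops dominating. T_p comes from a double-sigmoid fit
of H(T) — initialised at the two largest short-window jumps, widths
bounded below at a quarter grid step so step-like data cannot produce
divergent slopes — taking the largest-slope transition, or the second
(higher-T) transition when the experimental T_d exceeds 50 °C (a rule
that focuses on the decomposition of the protein core). Replicate T_p
values aggregate as mean ± SEM, mirroring the five-replicate ensemble
protocol; ensemble generation itself (MD) is out of scope — "ensemble
mode" is averaging over user-supplied structures.

## Statistical layer

* `ols_regress` / `compare_models`: base-R `lm` with `AIC` (full Gaussian
  likelihood including constants — the convention the printed ladders
  imply). All 8 covariate subsets of {MAT, pH, salinity} are ranked;
  collinearity raises a condition-number warning. Note that AIC retains a
  useless extra covariate with probability ≈ P(χ²₁ > 2) ≈ 0.16, so the
  true single-covariate model is the *modal*, not near-certain, winner;
  the tests assert that and that the winning model contains the true
  driver.
* `segmented_regress`: continuous two-segment least squares
  y = b₀ + b₁x + b₂(x−ψ)₊ with ψ profiled over interior unique x-values
  (1st–99th percentile, ≥3 points per side, RSS ties to the smaller ψ) and
  refined by golden-section between the neighbouring unique x-values (the
  optimum may fall between candidates). Improvement over a single line is
  an F-test charging two parameters. Zero-noise planted breakpoints are
  recovered exactly; at noise SD 1 °C the mean |error| over 200 seeds is
  ≈ 0.15 °C.
* `levene_test`: one-way ANOVA on absolute deviations from the group
  median (Brown–Forsythe; mean available) — robust and matching common R
  defaults.
* `variability_summary`: MAT, ΔT = max − min, and percent time in
  closed-open bins [−∞,28), [28,31), [31,∞) °C.
* `growth_rate`: wells never reaching OD 0.15 are "no-growth"; otherwise
  the rate is the maximum 5-point sliding-window slope of log OD
  (per hour), restricted to windows fully above the threshold because
  photometric noise dominates the log scale near the inoculum. At 3-h
  sampling the 12-h window spans a sizable part of a fast logistic curve,
  biasing the estimate low by ≈ 20–25% at r = 0.3 h⁻¹ — a documented
  estimator property, not noise; finer sampling removes it. GAM analyses
  of the source study are replaced by these ANOVA/OLS equivalents (out of
  scope by design).

## The synthetic world

Generators default to the stated study conditions: a 14-site transect
with a linear T_opt–MAT relation spanning 20–55 °C over MAT 12–30 °C;
a global-ocean piecewise relation with slopes 0.45/6.48 around a 27.7 °C
breakpoint for T_opt (0.54/4.45 around 25.1 °C for T_d); assay plates read
every 30 s for 180 min in triplicate; melting scans 4–95 °C; temperature
loggers sampled every 30 min for 18 months with seasonal + diel structure
tuned to annual ranges 12.8/8.8/6.7 °C (HTV/ITV/LTV) at equal means;
logistic growth read every 3 h for 72 h with a thermal performance curve
widened and warm-shifted for the high-variability class. Site-level noise
on true T_opt/T_d is 2 °C (chosen once as realistic between the printed
transect and single-enzyme R² values), absorbance noise 0.003 AU, melting
noise 2% of amplitude, OD noise 0.02. The activity-versus-temperature
shape is an asymmetric Gaussian (sharper decline above the optimum), a
phenomenological choice where the sources give no parametric form.

Toy constraint networks plant a rigidity transition by pairing a floppy
covalent chain with parallel H-bonds whose energies are drawn strictly
inside the schedule bin just above the planted cutoff, so the spanning
cluster collapses exactly when the schedule passes it. What a green test
establishes: every stage recovers its own planted parameter (T_opt within
the assay grid, T_d within 0.5 °C, T_p within one 2 K step, breakpoints
within 0.5 °C at the stated noise) and the composed pipeline attributes
the response to MAT. What it does not establish: agreement with the
study's deposited per-enzyme measurements (their reproduction requires
the external supplementary data and MD-generated ensembles), realistic
assay artefacts (drift, plate effects), or the behaviour of real protein
topologies beyond the shipped synthetic fixture.

## Degenerate inputs and tie-breaks

Flat activity profiles error on T_opt ("no Topt"); amplitude-zero melting
curves are flagged non-converged; a trajectory whose network is already
collapsed at the first schedule step has constant H and raises a
no-transition error; exact T_opt ties take the lowest temperature with a
flag; RSS ties in the breakpoint grid take the smaller ψ; `aggregate_replicates`
with n = 1 returns an undefined (NA) SEM rather than 0.

## Known limitations

No MD, structure prediction, tunnel analysis, proteomics or community
ecology statistics (out of scope by contract). The PDB reader handles the
ATOM/HETATM subset (altloc A, waters dropped) only. The pebble game is
pure R: comfortable for fixtures and single-domain proteins, not tuned
for proteome-scale batches. Locked-bond detection covers peptide and
carbonyl bonds; aromatic rings in real side chains would need an extended
rule. The H_type2 normalization is the per-cluster form discussed above
and should be cross-checked against CNA outputs where those are
available.
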