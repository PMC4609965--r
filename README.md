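# prekd

Inter-chain paramagnetic relaxation enhancement (PRE) analysis for
transient dimers of intrinsically disordered proteins.

Weakly self-associating IDPs — the synucleins are the motivating case —
form transient dimers at populations of a percent or less, invisible to
most structural methods. Inter-chain PRE NMR detects them: a spin-labelled
(MTSL, ¹⁴N, NMR-blind) chain is mixed with an unmodified ¹⁵N-visible
chain, and every visible residue that transiently approaches the label
relaxes measurably faster. `prekd` implements the full analysis from raw
per-residue peak-intensity decay tables to contact maps and
residue-specific dissociation constants:

1. **Relaxation fitting** — per-residue ¹H *R*₂ rates from
   mono-exponential decays *I(t) = I₀ e^(−R₂t)*, with a pooled noise
   level estimated from replicated delay points and propagated into rate
   uncertainties.
2. **PRE profiles** — Γ₂ = R₂^para − R₂^dia with quadrature errors, and a
   three-clause significance filter: Γ₂ ≥ 2× the strip mean, Γ₂ > the
   third quartile, and Γ₂ ≥ 8 s⁻¹.
3. **Contact maps** — multi-spin-label strips with N/NAC/C region
   annotation, >12 s⁻¹ saturated colour binning, contiguity-guarded
   region interactions, and head-to-head / head-to-tail dimer topology
   calls; global sequence alignment places homologous chains on a common
   residue axis.
4. **Titration fitting** — residue-specific *K*_D from the fast-exchange
   saturation isotherm

   Γ₂^app(x) = Γ₂^free + (Γ₂^bound − Γ₂^free) · x / (K_D + x)

   by error-weighted Levenberg–Marquardt, with profile-likelihood
   (Δχ² = 1) intervals and AICc-based classification of each profile as
   **specific** (saturating), **nonspecific** (linear), or
   **noninteracting** (below the 15 s⁻¹ selection threshold).
5. **Synthetic data** — a seeded generator for two-state fast-exchange
   transient dimers (exact dimerisation equilibrium or its hyperbolic
   limit, contact-segment-localised enhancements, multiplicative
   intensity noise) at the standard experimental design: 250 µM visible
   chain, titration ratios 0–1.5, a 10-delay schedule with two
   duplicated points. Three default scenarios (`"homo"`, `"hetero"`,
   `"beta-beta"`) encode the canonical α/α, α/β and β/β synuclein
   contact patterns.

## Worked example

Simulate a hetero (α-probe / β-visible) experiment, build its contact
map, and fit residue-specific dissociation constants. The hyperbolic
occupancy model is chosen here so the fitted constants are directly
comparable with the generating ones (the default, the exact dimerisation
equilibrium, yields *apparent* constants — see the methods vignette):

```r
library(prekd)

cfg  <- scenario("hetero", seed = 42)
cmap <- simulate_contact_map(cfg)
cmap
#> <contact_map> 4 strips (sites 11, 44, 90, 132), 134-aa visible chain, 45 significant cells
region_summary(cmap)$topology
#> [1] "head-to-tail"

cfg  <- scenario("hetero", seed = 42, occupancy_model = "hyperbolic")
sim  <- simulate_titration(cfg, site = 44)
fits <- fit_titration_set(sim$set)
table(fits$classification)
#> noninteracting       specific
#>            104             22

gs <- group_summary(fits, residues = 105:134)
sprintf("KD median %.0f uM, range %.0f-%.0f uM (n = %d)",
        gs$kd_median * 1e6, gs$kd_min * 1e6, gs$kd_max * 1e6, gs$n)
#> [1] "KD median 112 uM, range 58-307 uM (n = 22)"
```

The contact map shows significant contacts only between the α N-terminal
probes (sites 11 and 44) and the β C-terminus — a head-to-tail dimer —
and the fitted constants (median 112 µM here) recover the generating
cohort (median 108 µM for this seed). `plot(cmap)`,
`plot_titration(sim$set, fits)` and `plot_titration_surface(sim$set)`
draw the heat map, the per-residue isotherms and the residue × ratio
surface.

Real data enter through `read_intensity_table()` (delimited tables with a
delay header) or `read_sparky_peaks()` (peak-list exports, one file per
delay), then flow through `fit_profile()`, `compute_pre()`,
`build_contact_map()`, `titration_set()` and `fit_titration_set()`. The
`run_*()` functions (`run_simulate`, `run_fit_r2`, `run_compute_pre`,
`run_contact_map`, `run_fit_kd`) drive the same stages from a YAML/JSON
run configuration, and `inst/scripts/prekd` wraps them as a command-line
tool.

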