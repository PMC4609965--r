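---
title: "Inter-chain PRE analysis of transient IDP dimers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-chain PRE analysis of transient IDP dimers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prekd)
```

## The experiment this package analyses

Weakly self-associating intrinsically disordered proteins (IDPs) such as
α-synuclein form transient dimers at populations far too low for direct
observation. Inter-chain paramagnetic relaxation enhancement (PRE) makes
them visible: an NMR-blind (¹⁴N) chain carries a nitroxide spin label
(MTSL) at an engineered cysteine, and is mixed with an NMR-visible (¹⁵N)
unmodified chain. Any residue of the visible chain that transiently
approaches the label relaxes faster. The observable is the PRE rate

$$\Gamma_2 = R_2^{\mathrm{para}} - R_2^{\mathrm{dia}},$$

the residue-specific difference of amide-proton transverse relaxation
rates between the paramagnetic sample and a diamagnetic control in which
the label has been chemically reduced. Because exchange between free and
bound states is fast relative to the relaxation time scale, the observed
rate is the population-weighted average of the two states, which is what
lets a sub-percent dimer population produce a measurable signal.

The pipeline implemented here starts at per-residue peak-intensity decay
tables (spectral processing, peak picking and assignment are out of
scope) and proceeds in four stages: relaxation-rate fitting, PRE
computation and significance filtering, contact-map assembly, and
titration fitting of residue-specific dissociation constants.

## Relaxation-rate fitting

Each residue's intensity series over relaxation delays is modelled as a
two-parameter mono-exponential, $I(t) = I_0 e^{-R_2 t}$. The fit
minimises *relative* residuals $(I_i - m_i)/m_i$ by Levenberg–Marquardt,
which matches the noise model (below), makes the estimates exactly
invariant under rescaling of all intensities, and keeps the late, small
intensities from being ignored. Initialisation uses the log-linear
closed form (ordinary regression of $\log I$ on $t$), so on noiseless
data the nonlinear fit reproduces the closed form to full numerical
precision — one of the invariants the test suite asserts.

The standard delay schedule is 12, 32, 104, 12, 124, 64, 48, 94, 64,
20 ms. The duplicated 12 ms and 64 ms points serve two purposes: they
enter the fit as independent observations (preserving degrees of
freedom), and they feed the pooled noise estimator. For every replicate
pair the relative half-difference $|I_a - I_b| / (2\bar I)$ is computed,
and the pooled noise level is the root mean square of these values
across all residues. Under iid multiplicative Gaussian noise of standard
deviation $\sigma$ this statistic estimates $\sigma/\sqrt 2$, i.e. it is
deliberately conservative; we keep the plain pooled RMS because it is
the direct, assumption-light summary of what the replicates show.

Rate uncertainties propagate the noise level through the Gauss–Newton
covariance of the relative residuals; for the schedules used here this
reduces to approximately $\sigma_{R_2} \approx \sigma_{\mathrm{rel}} /
\sqrt{S_{tt}}$ with $S_{tt} = \sum_i (t_i - \bar t)^2$. A residue is
marked *failed* — and excluded from everything downstream, never
reported as zero — when the fit does not converge, the rate is negative
at the optimum, or the relative rate uncertainty exceeds 100%.

## PRE profiles and the significance filter

$\Gamma_2$ is formed residue-by-residue from the paramagnetic and
diamagnetic profiles with quadrature error propagation,
$\sigma_{\Gamma_2} = \sqrt{\sigma_{para}^2 + \sigma_{dia}^2}$. Only
residues fitted successfully in *both* arms appear.

A residue is called significantly interacting only if all three clauses
hold on its strip:

1. $\Gamma_2 \ge 2 \times$ the strip mean,
2. $\Gamma_2 >$ the third quartile of the strip,
3. $\Gamma_2 \ge 8\ \mathrm{s^{-1}}$ (absolute floor).

Two conventions had to be fixed because they are not uniquely
determined by the filter's verbal description. First, the population
over which the mean and quartile are computed: we use *all successfully
fitted residues of the strip* — prolines and unassigned residues never
enter (they are never fitted), and residues broadened beyond detection
are likewise absent rather than imputed. This is the most conservative
inclusive choice; including hypothetical zero rows for missing residues
would lower the mean and quartile and admit more passes. Second, the
quartile convention: linear interpolation between order statistics (R's
default type 7), stated explicitly so that independent re-implementations
can match the filter exactly; the suite checks clause-by-clause
agreement with a brute-force oracle on a thousand random vectors.

## Contact maps, regions and topology

Profiles from several spin-label sites against the same visible chain
are stacked into a contact map, strips ordered by site. Rendering is a
pure function of the stored $\Gamma_2$ values: bins are linear in
2 s⁻¹ steps up to 12 s⁻¹, values above 12 s⁻¹ saturate the top (red)
bin, and values below zero clamp to the bottom. Region annotation uses
the standard synuclein boundaries — for the 140-residue α chain
N = 1–60, NAC = 61–95, C = 96–140; for the 134-residue β chain
N = 1–60, NAC = 61–84, C = 85–134 — as overridable defaults, since the
literature displays the regions graphically without printing exact
boundaries.

A (strip, region) pair counts as *interacting* only when at least three
contiguous significant residues fall in the region; isolated
single-residue passes are treated as noise. Dimer topology follows from
the interacting pairs: an N-terminal probe contacting the N-terminal
region is a head-to-head configuration; an N-probe contacting the
C-terminal region (or vice versa) is head-to-tail.

Homologous chains are placed on a common axis by global
Needleman–Wunsch alignment (BLOSUM62, affine gaps, opening 10,
extension 0.5). For the α/β synuclein pair this produces the expected
single 11-residue gap on the β side inside the NAC region, plus small
C-terminal indels.

## Titration model and dissociation constants

Titrating the spin-labelled species at concentrations $x$ against a
fixed visible-chain concentration turns the PRE into a binding
isotherm. Under fast exchange,

$$\Gamma_2^{app}(x) = \Gamma_2^{free} +
  \left(\Gamma_2^{bound} - \Gamma_2^{free}\right) \frac{x}{K_D + x},$$

with three free parameters: the free-state rate, the saturation rate,
and the residue-specific dissociation constant. $x$ is the absolute
molar concentration of the labelled species (ratio × visible-chain
concentration), not the dimensionless ratio. $\Gamma_2^{free}$ is
fitted rather than pinned to zero even though the $x = 0$ point implies
it, mirroring the three-parameter scheme. The error-weighted
least-squares objective
$\sum_i [(\Gamma_{2,i} - \Gamma_2^{app}(x_i))/\sigma_i]^2$ is minimised
by Levenberg–Marquardt from two starts — the standard initialisation
($\Gamma_2^{free}$ from the $x=0$ point, $\Gamma_2^{bound} = 2\max
\Gamma_2$, $K_D$ at the median $x$) and a near-linear-limit start — so
that flat, weakly curved profiles are not abandoned at a premature
local stop. Box constraints keep $K_D \in (0, 1\ \mathrm{M}]$ and
$\Gamma_2^{bound} \in [0, 500\ \mathrm{s^{-1}}]$. Whether to weight by
per-point errors is not uniquely determined by convention; weighted
fitting is the default and the unweighted variant is exposed as an
option (a global rescaling of all errors provably leaves the point
estimates unchanged).

Two uncertainty routes are reported: the covariance at the optimum
scaled by the reduced chi-square, and a one-dimensional
profile-likelihood scan — $K_D$ fixed on a log grid, the two remaining
parameters re-optimised exactly (the model is linear in them at fixed
$K_D$) — whose $\Delta\chi^2 = 1$ interval gives the quoted $K_D$
range.

Fitting is restricted to residues whose PRE at a designated titration
point exceeds 15 s⁻¹ (strictly); the designated point is a configurable
ordinal defaulting to the highest retained point. Residues failing this
selection are *noninteracting*. For selected residues, the saturation
model competes against a two-parameter straight line under the
small-sample-corrected information criterion (AICc, with $\chi^2$
standing in for $-2\log L$ up to a model-independent constant):
*specific* requires the saturation model to win by at least 2 units —
the conventional weak-evidence boundary, configurable — with a $K_D$
interior to its bounds, $\Gamma_2^{bound} > \Gamma_2^{free}$, and an
identifiable constant; otherwise *nonspecific*. A $K_D$ is additionally
declared unidentifiable when its uncertainty exceeds the estimate or
when it lands more than tenfold beyond the largest sampled
concentration, where a hyperbola is indistinguishable from a line. The
reported `kd` column is populated only for specific residues; for the
others the constant is not defined.

With the six-point design used here ($n = 6$, $k = 3$ vs $k = 2$), the
AICc penalty difference is 10 units, so "specific" demands
$\chi^2_{lin} - \chi^2_{sat} \ge 12$ — a deliberately strict bar that
suppresses false saturation calls on noisy near-linear profiles.

## The synthetic-data generator

No experimental spectra accompany the study this pipeline addresses, so
the generator is a first-class module that emulates the statistical
structure the analysis assumes, at the study's own design: 250 µM
visible chain; titration ratios 0, 0.25, 0.5, 0.75, 1, 1.5; the
10-delay schedule with two duplicates for contact maps; and a 6-point
12–125 ms schedule with the first point duplicated for titrations (the
interior delay values 35, 58, 81, 103 ms are an even-spread choice, as
only the endpoints and count are fixed by the design).

**Occupancy.** The forward model computes the bound fraction of the
visible chain from the exact two-species dimerisation quadratic

$$f = \frac{(c_A + c_B + K_D) - \sqrt{(c_A + c_B + K_D)^2 - 4 c_A c_B}}
  {2 c_A},$$

with the hyperbolic form $f = c_B/(K_D + c_B)$ available as the
excess-titrant limit. The default for scenario simulation is the exact
model even though the titration *fit* assumes the hyperbola: at 250 µM
visible chain and $K_D$ of 100–1200 µM — the regime of interest — the
two differ materially, and running the estimator under this realistic
model mismatch is exactly the stress the qualitative checks should
apply. The quantitative recovery checks (round trips, cohort medians
against generating values) use hyperbolic generation, because under
exact-dimer generation the hyperbolic fit's $K_D$ is an *apparent*
constant, biased upward by titrant depletion — at $c_A = 250$ µM and
$K_D = 100$ µM the apparent value is several-fold higher, so a
generating-value round trip is not a meaningful check there.

**True PRE rates.** Each scenario defines contact segments on the
visible chain with per-residue bound-state amplitudes and per-residue
dissociation constants; $\Gamma_2^{true} = f \cdot A$ summed over
covering segments, zero elsewhere, with amplitudes tapering linearly
over the three edge residues of each segment.

**Default scenarios.** The three scenarios encode the canonical
synuclein findings as generator defaults. *homo* (α/α): N-terminal
probes 11 and 44 contact the hot-spot segment 36–44 nonspecifically
($K_D$ = 2.5 mM, tenfold beyond the top titrant concentration) and the
C-terminal segment 124–140 specifically (per-residue $K_D$ log-normal,
median 500 µM, clamped to 90–1200 µM; amplitudes uniform 30–60 s⁻¹).
*hetero* (α-probe / β-visible): segments 105–134 specific ($K_D$ median
100 µM, clamped 40–350 µM) and an extremely weak 37–41 contact
(amplitude 10 s⁻¹). *beta-beta*: no segments. The nonspecific hot-spot
amplitude (150 s⁻¹) is a plausibility choice fixed by the occupancy
algebra: no saturation amplitude is printed for this site, and 150 s⁻¹
at $K_D$ = 2.5 mM yields ≈ 12.6 Hz at 1:1 mixing (a strong, red-binned
contact) while keeping the titration profile linear over the sampled
range — the qualitative behaviour the hot spot shows. All bound-state
amplitude scales are, likewise, plausibility choices: the literature
reports no $\Gamma_2^{bound}$ values, only the 8–12+ Hz display range
that these defaults reproduce at the accessible occupancies.

**Noise.** Intensities receive multiplicative Gaussian noise at 2%
relative level by default — typical HSQC peak-height repeatability —
propagating to $\sigma_{\Gamma_2} \approx 0.26\ \mathrm{s^{-1}}$ on the
titration schedule, comfortably below the 2 Hz error ceiling the
experimental design targets. The fast titration path injects Gaussian
noise directly on $\Gamma_2$ at the analytically propagated level; the
full path runs peak tables through the decay fits. Both are seeded and
deterministic, and the suite checks they agree statistically. Baseline
diamagnetic rates are drawn once per configuration, uniform in
10–25 s⁻¹ (typical amide-proton rates for a disordered chain at
moderate field and 15 °C), constant across arms. Prolines carry no
amide peak and are absent from every table.

The synthetic grid keeps all six ratios including 1.5. In the real α
titration the top point was removed because of chemical-shift changes
in the HSQC — an artifact the generator does not emulate — which is
also why the "5th titration point" selection rule is implemented as a
configurable ordinal rather than a hard-coded index.

**What the generator does not emulate.** No lineshapes or FIDs, no
distance-based $r^{-6}$ enhancement geometry, no chemical-shift
perturbations, no conformational-ensemble structure, no inter-residue
noise correlations, and no baseline artifacts from incomplete label
reduction. Passing tests therefore demonstrate that the estimators
recover what this forward model puts in — localisation, shape
classification, constants — not that real spectra are free of the
systematic effects above.

## Numerical choices and degenerate inputs

* Decay fits need at least three points, two distinct delays, and at
  least two positive intensities; non-positive intensities drop out of
  the log-linear initialiser and the fit falls back to a positivity
  bound on $I_0$.
* The significance filter requires at least four residues (a quartile
  below that is not meaningful) and errors otherwise.
* Titration fits require at least four points including $x = 0$;
  all-zero profiles are reported with both rates at zero and the
  constant flagged unidentifiable.
* Problem sizes in the test suite — e.g. twenty seeded replicates for
  classification rates, one hundred for recovery medians, a thousand
  vectors for the filter oracle — were chosen as the smallest cohorts
  at which the asserted medians and rates are stable, and are stated in
  the tests themselves.

## Known limitations

* $\Gamma_2$ is treated purely as contact evidence; no
  Solomon–Bloembergen distance calibration is attempted.
* Constants are fitted residue-by-residue; no global shared-$K_D$ model
  across a segment is provided.
* The hyperbolic fit of exact-dimer data yields apparent constants
  (titrant depletion); users comparing absolute $K_D$ values across
  designs should keep the visible-chain concentration in mind.
* The replicate-based noise estimator is conservative by $\sqrt 2$
  under iid multiplicative noise; supplying an externally calibrated
  noise level through the configuration is supported everywhere.
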