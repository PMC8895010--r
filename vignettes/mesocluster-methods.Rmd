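---
title: "Models and methods behind mesocluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mesocluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesocluster)
```

# The scientific problem

Supersaturated and even undersaturated solutions of small organic molecules
can contain *mesoscale clusters*: solute-rich, liquid-like domains tens of
nanometres across that persist at a steady size and act as preferred sites
for crystal nucleation (the "two-step" nucleation picture). A bare
one-component cluster cannot be stable — the free-energy cost of inserting
monomers into a dense region grows with concentration, so Fickian transport
would dissolve it. Stability becomes possible when a second species, a
transient dimer, is produced in the bulk, enriched in the cluster, and
converted back to monomers inside it. The cluster is then a steady-state
object maintained by the interplay of reaction and diffusion rather than a
thermodynamic phase.

`mesocluster` implements the quantitative chain that supports this picture
for a monomer–dimer system, end to end:

1. **Solution thermodynamics** from static light scattering (SLS):
   osmotic virial fit of the Debye plot and the per-molecule excess free
   energy $\Delta g(c)$.
2. **Speciation**: monomer–dimer equilibrium at any total concentration and
   the dimerization constant $k_D$ fitted to concentration-dependent
   $^{13}$C chemical shifts.
3. **Transport**: diffusion coefficients from DOSY gradient attenuation and
   Stokes–Einstein inverse-radius scaling between species.
4. **Reaction–diffusion**: the steady spherical monomer/dimer density
   fields around a cluster, the screening length $\Lambda=\sqrt{D_2/k_2}$,
   and the decay rate $k_2 = D_2/R^2$ implied by the cluster size.
5. **Cluster dynamics**: the radius evolution ODE and its stable fixed
   point.

A seeded synthetic-data module generates every input data type from the
exact forward models, so the pipeline is fully testable without access to
instrument data.

# Thermodynamics from light scattering

SLS data enter as a Debye plot, $Kc/R_\theta$ versus mass concentration
$c$, where $K = 4\pi^2 n^2 (dn/dc)^2 / (N_A \lambda^4)$ is the optical
constant and $R_\theta$ the Rayleigh ratio. The central identity is that
$Kc/R_\theta$ equals the inverse osmotic compressibility
$(1/RT)\,\partial\Pi/\partial c$, so fitting the osmotic virial expansion

$$ \frac{Kc}{R_\theta} = \frac{1}{M_w} + 2A_2 c + 3A_3 c^2 $$

gives the apparent molar mass and the pairwise/triplet interaction
coefficients by *linear* (optionally $1/\sigma^2$-weighted) least squares.
The fit defaults to selecting between the quadratic and cubic models by a
partial F-test at the 0.05 level, because on realistic designs the cubic
term is often statistically indistinguishable from zero and retaining it
inflates the variance of $A_2$.

Writing the per-molecule chemical-potential increment as
$d\mu = (1/\rho_N)\, d\Pi$ with number density $\rho_N = c N_A / M$ gives
the excess free energy per molecule between two concentrations,

$$ \Delta g = \frac{M R T}{N_A} \int_{c_L}^{c_H}
   \frac{(Kc/R_\theta)(c)}{c}\, dc
 = \frac{M R T}{N_A}\Big[\tfrac{1}{M_w}\ln\tfrac{c_H}{c_L}
   + 2A_2(c_H - c_L) + \tfrac{3}{2}A_3(c_H^2 - c_L^2)\Big], $$

which reduces to the ideal $k_BT\ln(c_H/c_L)$ when $A_2 = A_3 = 0$ and
$M_w = M$. Both the closed form and adaptive quadrature are implemented;
their agreement (to $10^{-8}$ relative) is part of the test suite. The
integral diverges logarithmically at $c_L = 0$, which is rejected
explicitly. Concentrations are carried internally in g/ml; conversions
(mg/ml, molar with a user molar mass) are centralized in `conc_in()`.

A positive $A_2$ makes $\Delta g$ grow superlogarithmically with
concentration: inserting one more monomer into a solute-rich region is
increasingly costly. This is the thermodynamic argument for why stable
clusters must contain a second species.

# Monomer–dimer speciation and the NMR isotherm

With the dimerization constant defined as $k_D = [D]/[M]^2$ (no statistical
factor — population percentages depend on this convention, so it is fixed
and documented), mass balance $c = [M] + 2[D]$ gives the closed form

$$ [M] = \frac{2c}{1+\sqrt{8k_Dc+1}}, \qquad [D] = k_D[M]^2 . $$

This evaluation is algebraically identical to the textbook quadratic-root
expression but avoids its catastrophic cancellation at small $k_D c$ and
satisfies the equilibrium identity exactly. Two "dimer population"
conventions are exposed, because both appear in the literature: the
fraction of molecules living in dimers, $2[D]/c$, and the dimer fraction of
independent species, $[D]/([M]+[D])$.

Under fast exchange the observed chemical shift is the population-weighted
average of the two environments,

$$ \delta_{obs}(c) = \delta_M + (\delta_D-\delta_M)\,\frac{2[D]}{c}. $$

`fit_dimerization()` fits this isotherm jointly across carbons with one
shared $k_D$ and per-carbon limiting shifts. For fixed $k_D$ the limiting
shifts are linear parameters, so they are profiled out and the optimization
is one-dimensional in $\log k_D$; the profiled objective is minimized from
8 log-spaced starts spanning $10^{-3}$–$10^{2}$ M$^{-1}$ (dimerization
isotherms have a notoriously flat likelihood in $\log k_D$ when the
concentration window is narrow, and the multi-start guards against the
optimizer stalling on a shoulder). A final joint Levenberg–Marquardt polish
supplies the covariance, with the $\log k_D \to k_D$ delta transform on the
first row and column. The pooled $R^2$ uses the total sum of squares about
per-carbon means, so a carbon with a large baseline shift does not inflate
it. When the isotherm does not improve significantly on a
concentration-independent model (partial F-test at 0.05), the fit carries a
`flat_model` flag and warns: a nucleus whose shift does not respond to
association cannot identify $k_D$ — the expected behaviour for, e.g., a
remote aliphatic carbon.

# Transport: DOSY and Stokes–Einstein

Pulsed-field-gradient attenuation follows the Stejskal–Tanner decay
$I(g) = I_0 \exp[-D\gamma^2 g^2\delta^2(\Delta-\delta/3)]$.
`fit_dosy()` seeds a nonlinear fit with the exact log-linear regression of
$\log I$ on the encoding factor and constrains $D > 0$. Bipolar-pulse
corrections beyond the standard exponent are deliberately not modelled.

The Stokes–Einstein relation $D = k_BT/(6\pi\eta r_H)$ links diffusion to
hydrodynamic size, and its consequence $D \propto 1/r_H$ lets the dimer
coefficient be computed from the measured monomer one:
$D_2 = D_1 r_1/r_2$. With $D_1 = 4\times10^{-11}$ m$^2$/s and hydrodynamic
radii of 3.72 and 4.65 Å for monomer and dimer, $D_2 =
3.2\times10^{-11}$ m$^2$/s. The hydrodynamic radii are *inputs*: mapping
molecular dimensions to an effective $r_H$ (e.g. through a cylinder model)
involves shape conventions that the package does not attempt to fix, so
`diffusion_params()` takes the radii as given and enforces the
$D_1r_1 = D_2r_2$ consistency instead.

# The steady reaction–diffusion cluster

The density fields obey

$$ \partial_t n_1 = D_1\nabla^2 n_1 - 2k_1n_1^2 + 2k_2n_2, \qquad
   \partial_t n_2 = D_2\nabla^2 n_2 + k_1n_1^2 - k_2n_2, $$

with $k_1 n_{1\infty}^2 = k_2 n_{2\infty}$ far from the cluster (local
chemical equilibrium; `rd_params()` completes $k_1$ from this identity, and
`kd_to_rate_ratio()` converts the molar $k_D$ to the number-density
convention, $k_1/k_2 = k_D/(N_A\cdot10^3)$ m$^3$).

**Exact flux balance.** Adding the steady monomer equation to twice the
steady dimer equation cancels the reaction terms, leaving
$\nabla^2(D_1\delta n_1 + 2D_2\delta n_2) = 0$ with
$\delta n_i = n_i - n_{i\infty}$. A bounded harmonic function vanishing at
infinity is identically zero, so

$$ D_1\,\delta n_1 + 2D_2\,\delta n_2 = 0 \quad\text{pointwise.} $$

This identity is exact for the full nonlinear steady state, ties the
monomer depletion to the dimer enrichment without any further boundary
condition, and is asserted pointwise in the tests.

**Screened dimer field.** In the bulk, where dimers are dilute and the
monomer bath sits at its equilibrium value, the dimer excess obeys
$D_2\nabla^2\delta n_2 = k_2\,\delta n_2$, the screened (Yukawa-type)
equation with decay length $\Lambda = \sqrt{D_2/k_2}$. The spherically
symmetric solutions are the exterior mode $e^{-r/\Lambda}/r$ and the
interior mode $\sinh(r/\Lambda)/r$, regular at the origin. Treating the
monomer bath as fixed neglects the feedback of the monomer perturbation on
the formation term; the full linearized system would decay with
$\Lambda_{\rm eff} = \sqrt{D_2/(k_2 + 4k_1n_{1\infty}D_2/D_1)}$. The
bath approximation is the model the decay-length identification
$k_2 = D_2/R^2$ presumes, and the package states it rather than hiding it:
`evolve_rd(..., linearize = TRUE)` integrates exactly this approximation,
and its open-system steady state reproduces `steady_profiles()` (verified
to 1% in the tests), while the default nonlinear mode is used for the
conservation properties.

**Why an interior source.** The two homogeneous modes matched in both value
and flux at the cluster radius admit only the trivial solution — some
physical input must sustain a nonzero cluster. Inside the cluster the
monomer→dimer conversion is enhanced (monomers are thermodynamically
expensive there, as the $\Delta g$ analysis shows), and the minimal closed
model of that enhancement is a constant excess conversion source $s$ for
$r < R$. It shifts the interior solution by a plateau $s/k_2$, and the
three amplitudes (plateau, interior mode, exterior mode) are then uniquely
fixed by continuity of value and flux at $R$ plus one physical dial: the
core contrast $\delta n_2(0)/n_{2\infty}$. The source moves molecules
between species ($+s$ dimers, $-2s$ monomers), so it conserves
$n_1 + 2n_2$ exactly and preserves the flux-balance identity. An
independent finite-difference boundary-value solve of the same screened
problem (with the source amplitude fixed only by the central contrast)
agrees with the matched analytic profile to better than $10^{-3}$ of the
central amplitude.

The resulting picture matches the qualitative expectations for these
clusters: dimers enriched and monomers depleted in the core, both fields
relaxing smoothly over $\Lambda$ with no sharp boundary. Identifying
$\Lambda$ with the cluster radius — clusters of mean diameter 32 nm, hence
$R = 16$ nm — gives $k_2 = D_2/R^2 = 1.25\times10^5$ s$^{-1}$, and the
normalized profile shape is invariant under the core-contrast sweep
(3–35 is the plausible range; contrasts so large that the slaved monomer
field would go negative are clipped with a warning, which at 0.5 M total
concentration caps the contrast near 1.8).

**Numerics.** `evolve_rd()` discretizes the spherical Laplacian by a
conservative finite-volume scheme on an arbitrary (by default logarithmic)
radial grid: fluxes are evaluated on cell faces and divided by exact shell
volumes, so with closed boundaries the discrete total molecule content is
conserved to integrator tolerance (asserted to $10^{-6}$). The in-cluster
source is volume-weighted by each cell's overlap with the cluster sphere,
which keeps the discrete steady state second-order accurate in the cell
width at $R$. Time integration uses the stiff sparse solver (`lsodes`)
from **deSolve**; the inner boundary is always no-flux, the outer boundary
either clamped to the bulk (open system) or no-flux (closed box).

# Cluster-radius dynamics

The radius evolution is modelled with the canonical two-term form

$$ \frac{dR}{dt} = \frac{D_2}{R}\,\sigma_d - \frac{k_2}{3}\,\chi\,R , $$

a diffusive growth drive supplied by the dimer field (dimensionless
coefficient $\sigma_d$ multiplying the diffusive velocity scale $D_2/R$)
against reaction-limited shrinkage (excess dimers convert back to monomers
at rate $k_2$ and the monomers are expelled; $\chi$ defaults to 1). The
right-hand side is strictly decreasing in $R$, so the fixed point

$$ R^* = \sqrt{\frac{3\sigma_d D_2}{\chi k_2}} $$

is unique and globally attracting: small clusters grow, large clusters
shrink, nothing coarsens. The thermodynamic content of the drive (the
osmotic pressure of the dimer field relative to $k_BT$) is deliberately
collapsed into the single dimensionless $\sigma_d$ rather than being
predicted from first principles; the default $\sigma_d = 1/3$ is the
package's cross-module consistency convention, making $R^*$ coincide with
the screening length $\sqrt{D_2/k_2} = 16$ nm so that the radius dynamics
and the steady profiles describe the same cluster. It is a convention, not
a measured value, and both coefficients are plain user parameters.

With the default parameters, trajectories started at 1 nm grow
monotonically and reach 99% of $R^*$ in about $5\times10^{-5}$ s — cluster
formation is complete well within a millisecond, consistent with clusters
appearing as soon as solute dissolves. Near $R^*$ the decay of
$|R - R^*|$ is exponential with rate
$D_2\sigma_d/R^{*2} + k_2\chi/3 \approx 8.3\times10^4$ s$^{-1}$, which the
tests confirm against a log-linear fit of the trajectory tail. The
integrator is adaptive `lsoda` at $10^{-8}$ relative tolerance with a 1 pm
floor guarding the $1/R$ singularity.

# The synthetic-data generators

Each generator is the exact forward model of its fitter plus a simple noise
model chosen once:

* **SLS** (`gen_sls`): virial expansion at truth parameters
  ($M_w = 2\times10^4$ g/mol, $A_2 = 3\times10^{-4}$ mol ml g$^{-2}$,
  $A_3 = 0$ — an associating small-molecule solution with net repulsive
  pair interactions) on 12 concentrations spanning 10.0–98.2 mg/ml, times
  $(1 + \mathcal N(0, 0.02))$ relative noise.
* **NMR shifts** (`gen_nmr_shifts`): the fast-exchange isotherm at
  $k_D = 1.147$ M$^{-1}$ for 3 aromatic carbons on 12 concentrations in
  0.02–0.5 M, plus $\mathcal N(0, 0.002\ \mathrm{ppm})$. The limiting
  shifts are set so the *observed* downfield change across the measured
  window is 0.1, 0.3 and 0.5 ppm per carbon (limiting monomer→dimer
  differences of 0.28–1.38 ppm, the magnitude expected for ring-current
  shifts of stacking aromatics). With this design the shared-$k_D$
  estimator has a relative standard deviation near 2.5%, so recovery
  within ±5% is a reliable expectation and the pooled $R^2$ sits near
  0.999. An optional flat carbon (no concentration response) exercises the
  `flat_model` diagnostic.
* **DOSY** (`gen_dosy`): Stejskal–Tanner decay at $D = 4\times10^{-11}$
  m$^2$/s on 12 gradients over 0–0.5 T/m with $\delta = 5$ ms,
  $\Delta = 100$ ms (≈85% attenuation at the strongest gradient, a
  realistic cryoprobe setting), times 1% relative noise.

Seeds are decoupled per generator (`seed`, `seed+1`, `seed+2`), outputs are
byte-identical under a fixed seed, and generation restores the caller's RNG
state. What the generators do *not* emulate: baseline drift and phase
errors in spectra, concentration errors (the $x$-axis is exact),
polydispersity and angle dependence in SLS, convection or multi-component
decays in DOSY, and any higher-order association beyond dimers. Passing
tests therefore demonstrate correctness of the estimators under the assumed
statistical model, not robustness to instrument systematics.

# Problem sizes and tolerances

The test suite runs the Monte-Carlo recovery studies at 200 replicates
(SLS), 100 replicates (dimerization, DOSY); the finite-difference oracle
for the steady profile uses 8000 uniform nodes over $14\Lambda$; the
relaxation check uses 140 log-spaced nodes over $[0.05, 12]\Lambda$ to
1 ms. These sizes make the whole suite run in well under a minute while
leaving every tolerance with an order-of-magnitude margin. Speciation is
closed-form and exact to $10^{-10}$ against root bracketing; free-energy
quadrature agrees with the closed form to $10^{-8}$; reaction conservation
$\dot n_1 + 2\dot n_2 = 0$ is exact in floating point by construction of
the rate expressions.

# Interfaces

The package is function-first: `run_paper_chain()` executes the whole
derived-constant cascade and returns a structured report (value, unit,
provenance per entry) that `write_report()` serializes to JSON, and the CSV
readers/writers (`read_sls_csv()`, `read_shifts_csv()`, `read_dosy_csv()`,
`write_series_csv()`) carry schema validation with column- and row-level
error messages. A shell-level wrapper would add nothing over
`Rscript -e 'mesocluster::run_paper_chain()'`, so none is shipped;
`scripts/acceptance.R` in the source repository is the runnable end-to-end
example.

# Known limitations

* The growth-drive coefficient $\sigma_d$ is a convention, not a
  prediction; absolute growth amplitudes (though not the fixed-point
  structure) depend on it.
* The steady profiles are linearized about the bulk; deep in a dense core
  the mass-action nonlinearity would modify the plateau.
* Surface tension of the cluster interface, higher oligomers, cluster
  size distributions and inter-cluster ripening are all outside the model.
* Hydrodynamic radii are inputs; no molecular-shape model is fitted.
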