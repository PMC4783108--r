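---
title: "Methods: crystallin association in crowded media by scaled particle theory"
author: "sptcrowd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crystallin association in crowded media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptcrowd)
```

## The physical problem

Gamma-crystallins fill the fiber cells of the eye-lens nucleus at 200-400
mg/mL.  Their dimerization equilibrium in that crowded medium is controlled
by two competing effects: steric depletion by the surrounding crowders,
which favors the compact dimer, and attraction between proteins and
crowders, which stabilizes the monomers.  The package quantifies this
balance with the crowding factor

$$\ln\Gamma = \ln(K/K_0) = 2\ln\gamma_r - \ln\gamma_p,$$

the log-ratio of the association constant in the crowded medium to its
dilute-solution value, written through the activity coefficients of the
reactant (monomer) and product (dimer).  $\ln\Gamma > 0$ means crowding
pushes towards aggregation.

## Model components

**Geometry.**  Reactants and crowders are hard spheres of diameter
$\sigma = \sigma_0 = 3.6$ nm.  The dimer is a spherocylinder of asphericity
$\lambda = L/\sigma_p$ whose cap diameter follows from conservation of the
combined monomer volume, $\sigma_p = \sigma(4/(3\lambda+2))^{1/3}$; a
spherical dimer ($\lambda = 0$, diameter $2^{1/3}\sigma$) is the default
because the reference pressure and crossover analyses are stated for
spherical products, while $\lambda$ up to $\approx 0.3$ (the NMR estimate
for crystallin dimers) is exposed everywhere.

**Steric part (SPT).**  The insertion work of a convex solute into the
hard-sphere fluid is the scaled-particle-theory polynomial
$\ln\gamma^{st} = -\ln(1-\phi) + A_1 x + A_2 x^2 + A_3 x^3$ with
$x = \phi/(1-\phi)$ and shape coefficients $A_i(\varsigma, \lambda)$
(`shape_coefficients()`); for the monomer
$(A_1, A_2, A_3) = (7, 7.5, 3)$.  Note the pure-sphere $A_1$ is
$(1+\varsigma)^3 - 1$: the cubic binomial *minus one*, because the
$-\ln(1-\phi)$ free-volume term already carries the zeroth order.  In the
point-solute limit all $A_i \to 0$.

**TPM.**  The thermodynamic perturbation model treats an orientationally
averaged square-well attraction of depth $\varepsilon$ (kT) as a
first-order perturbation:
$\ln\gamma^{ch} = -\rho\,\varepsilon S\,[\delta r + (g_0^{max}-1)\theta]$,
with $S$ the solute surface area, $\delta r = 0.2\sigma$ the attraction
range (the ratio calibrated against Monte Carlo data for globular
proteins), $\theta = (2^{1/6}-1)\sigma/2$ the decay range of the contact
peak, and $g_0^{max} = (1-\phi/2)/(1-\phi)^3$ the Carnahan-Starling contact
value.  The bracket groups $\delta r$ with the correlation correction
$(g_0^{max}-1)\theta$; this grouping is asserted in a dedicated unit test,
and it independently reproduces the known compensation depth
$\varepsilon_c \approx 10$ kT, which we take as corroboration.

**CBM.**  The chemical binding model replaces the smeared attraction with
reversible binding of crowders at $n_s$ surface sites,
$\ln\gamma^{ch} = -n_s\ln(1 + K\,\gamma^{st}_x \gamma^{st}_b /
\gamma^{st}_{xb}\,\phi)$, where the steric factors correct the bare binding
constant $K$ for the insertion work of the free species versus the bound
complex.  Because reactants and crowders are the same protein, the
reactant-crowder complex is identified with the dimer
($\gamma^{st}_{rb} = \gamma^{st}_p$).

## Choices the sources leave open

* **Product-crowder complex.**  The binding term for the *product* species
  needs the geometry of a dimer-plus-crowder complex, which is never
  specified.  We use the same volume-conservation principle as for the
  dimer itself: a compact sphere of diameter $(2\sigma^3+\sigma_0^3)^{1/3}$
  ($= 3^{1/3}\sigma$ for identical crystallins).  With this choice the CBM
  at $(n_s = 2, K = 10.6)$ compensates at $\phi^* = 0.228$, consistent with
  the reported $\ln\Gamma \sim 0$ near $\phi = 0.2$.
* **Product site count.**  Sites are taken proportional to surface area
  (constant site density $\alpha = n_s/S_r$), so a spherical dimer carries
  $2^{2/3} n_s$ sites; the alternative "two sites consumed by the bond"
  rule ($2n_s - 2$) is available as `product_sites = "conserved"` in
  `crystallin_system()`.
* **Which activity enters the pressure.**  The osmotic pressure
  $\Pi = RT[\rho + \int_0^\rho \rho'\,(d\ln\gamma/d\rho')\,d\rho']$ uses
  the *reactant* total activity: the measured suspension is of monomeric
  crystallins.  $\Pi(\varepsilon = 0)$ is therefore the SPT hard-sphere
  equation of state, whose dilute limit $B_2 = 4v$ is verified against an
  analytic virial expansion.
* **Concentration mapping.**  The experimental axis (mg/mL) is mapped to
  packing fraction through a default molar mass of 21 kDa (typical
  gamma-crystallin); 400 mg/mL then corresponds to $\phi = 0.28$.  The
  molar mass is a `crystallin_system()` parameter.

## Numerics

* Quadrature: `stats::integrate` (adaptive Gauss-Kronrod) on the analytic
  activity derivative, relative tolerance $10^{-10}$; the analytic
  derivative is validated against central finite differences ($10^{-6}$
  relative) and the pressure against a fixed-mesh Simpson oracle.
* 1-D least squares: bounded Brent (`stats::optimize`), $\varepsilon \in
  [0, 30]$ kT, $K \in [0, 1000]$, with a second narrow-interval pass for
  `fit_cbm()` because Brent's attainable precision scales with the search
  interval.  The TPM pressure is exactly linear in $\varepsilon$, so the
  fit evaluates two basis curves once.  Minima at a search boundary are
  flagged `converged = FALSE`, never silent.
* Root solving: Brent (`stats::uniroot`) with a mandatory sign-change
  bracket; compensation roots are resolved to $|\ln\Gamma| < 10^{-10}$.
  `crossover_epsilon()` is checked against the closed form
  $\varepsilon_c = (2\ln\gamma^{st}_r - \ln\gamma^{st}_p) /
  (\rho\,(2S_r - S_p)[\delta r + (g_0^{max}-1)\theta])$ and refuses the
  degenerate surface-area ratio $2S_r = S_p$ where no crossover exists.
* Validity ceiling: SPT omits many-body correlations, so every entry point
  warns above $\phi = 0.4$; operations reject $\phi \ge 1$.

## The synthetic-data generator

No crystallin osmotic-pressure table is shipped: the generator
(`simulate_isotherm()`) emulates the structure of membrane-osmometry data
-- monotone $\Pi(c)$ on 16 points over 25-400 mg/mL at 298.15 K, below the
ideal law $\rho RT$ when attraction is present -- with multiplicative
Gaussian noise (default 5% relative, seed mandatory) because osmometry
error scales with the signal.  Parameter-recovery results on these fixtures
show self-consistency of the pipeline (unbiased recovery of $\varepsilon$
and $K$ at 5% noise over 200 seeded replicates, exact recovery at zero
noise); they cannot validate the models against real crystallin data, whose
error structure and possible systematic deviations from both models are
unknown.

```{r example}
sys <- crystallin_system()
iso <- simulate_isotherm(sys, tpm_model(13.9), noise_sd = 0.05,
                         seed = 20160308)
fit_tpm_epsilon(iso, sys)
```

Problem sizes used throughout the analyses: 16-point isotherms, 100-point
uniform grids for the ideal-matching fit, $\phi$ grids of step 0.01 for
sweep tables, and 200 replicates for the recovery studies.

## Known limitations

* Many-body effects are absent; nothing above $\phi \approx 0.4$ should be
  trusted, and crystallization or liquid-liquid phase separation are out of
  scope entirely.
* The attraction is a single scalar per model: no patchiness or
  orientation-resolved (Wertheim-type) association.
* One crowder species only; polydispersity is represented solely through
  the size ratio $\varsigma$.
* Strong attraction ($\varepsilon > 13$ kT) drives $d\Pi/dc$ negative at
  high concentration -- a mechanically unstable branch that signals the
  onset of aggregation rather than an equilibrium isotherm.
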