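---
title: "Modeling mixed-composition immune-complex binding and effector function"
author: "FcBindMix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mixed-composition immune-complex binding and effector function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FcBindMix)
```

## The scientific problem

Antibody-opsonized targets present many IgG Fc domains at once, and the
immune complexes (ICs) that form in vivo are rarely composed of a single
IgG subclass. Effector cells read these complexes through a family of
Fc-gamma receptors (FcgRs) whose monovalent affinities for individual
subclasses span four orders of magnitude, and the functional outcome is
driven not by monovalent occupancy but by avidity: multiple Fc sites of
one complex engaging multiple receptors on the same cell. FcBindMix
implements a quantitative chain from monovalent affinities to cell-level
outcomes:

1. an equilibrium model of multivalent, multi-ligand, multi-receptor
   binding;
2. Bayesian refinement of the monovalent affinity matrix from replicated
   IC binding panels;
3. a regression that links model-predicted receptor multimerization on
   effector cell types to in vivo target-cell depletion.

A synthetic-data generator reproduces the statistical structure of the
experimental designs so that every stage can be exercised and scored
end to end without any external data.

## The multivalent binding model

For $N_L$ IgG species and $N_R$ receptor species, with monovalent
association constants $K_{a,ij}$ (M$^{-1}$), total complex concentration
$L_0$ (M), effective valency $f$, monomer proportions $C_i$
($\sum_i C_i = 1$) and free receptor abundances $R_{eq,j}$ per cell, the
dimensionless engagement propensities are

$$\phi_{ij} = R_{eq,j}\,K_{a,ij}\,K_x^*\,C_i, \qquad \phi_{i0} = C_i,$$

where $K_x^*$ (cell$\cdot$M) is a phenomenological crosslinking constant:
every engagement after a complex's first is assigned association constant
$K_x^* K_{a,ij}$, so avidity is proportional to monovalent affinity. A
binding configuration of one complex is the vector $q$ of counts over the
$N_L(N_R{+}1)$ ligand-receptor pairings (including unbound), with
$\sum q = f$, and its equilibrium abundance is multinomial in $\phi$.
Summing the multinomial series gives closed forms in the grand total
$\Phi = \sum_{ij}\phi_{ij}$ (the unbound column contributes exactly 1):

$$L_{bound} = \frac{L_0}{K_x^*}\left(\Phi^f - 1\right), \qquad
R_{bound,n} = \frac{L_0 f}{K_x^*}\Big(\sum_i \phi_{in}\Big)\,\Phi^{f-1},
\qquad
R_{multi,n} = \frac{L_0 f}{K_x^*}\Big(\sum_i \phi_{in}\Big)
\left(\Phi^{f-1} - 1\right).$$

$L_{bound}$ counts complexes engaged through at least one site,
$R_{bound,n}$ receptors of species $n$ engaged by any complex, and
$R_{multi,n}$ receptors inside complexes engaged through at least two
sites -- the multimerized, signaling-relevant pool. Two checks pin the
prefactors down: at $f = 1$ the model must collapse to the Langmuir
isotherm ($R_{bound} = L_0 K_a R_{eq}$), and $L_0/K_x^*$ must carry units
of per-cell counts. Both are enforced in the test suite, together with an
exhaustive-enumeration oracle (`oracleMacroscopic()`) that recomputes all
three quantities by summing the multinomial series configuration by
configuration at integer $f$; the closed forms agree with it to a
relative $10^{-8}$ over randomized instances. The closed forms are smooth
in $f$, and fitted effective valencies are continuous; the oracle is
defined only at integer valency.

Free receptors follow from conservation of mass,
$R_{tot,n} = R_{eq,n} + R_{bound,n}(R_{eq})$, solved by Newton iteration
in $\log R_{eq}$ on the log-residual
$h_n = \log R_{eq,n} + \log(1 + L_0 f A_n \Phi^{f-1}) - \log R_{tot,n}$
with $A_n = \sum_i C_i K_{a,in}$. This parameterization matters: the
residual is nearly linear in $\log R_{eq}$ even at extreme avidity
($\Phi^{f-1}$ spanning tens of decades at $f = 33$), where a linear-space
Newton iteration converges only geometrically. Positivity is structural,
the iteration starts from the no-binding state $R_{eq} = R_{tot}$, and
convergence is declared at a relative conservation residual of $10^{-9}$
(default cap 100 iterations, both configurable). Receptors with zero
expression are carried with $R_{eq} = 0$ rather than dropped, preserving
index alignment across cell types. Degenerate parameter proposals
(overflowing powers, non-finite inputs) yield `NaN` predictions that the
samplers treat as rejections rather than errors.

## Priors and Bayesian affinity refinement

Binding panels measure relative fluorescence (RFU) of bound IC on
single-receptor cell lines across a factorial design: receptors x
valency classes (nominal 4 and 33) x IgG subclass pairs x mixture
compositions, replicated. Each readout is normalized to the mean of its
replicate (`normalizeReplicate()`), so absolute scale is not preserved.

Every fitted parameter is positive and carries a lognormal prior;
sampling and optimization work on the log scale throughout:

* **Affinities.** The documented association constant is the prior
  *mode* and its standard error the prior *interquartile range*.
  `lognormalFromModeIqr()` inverts $(\text{mode}, \text{IQR})$ to
  $(\mu, \sigma)$ by reducing to one monotone equation,
  $\text{IQR} = \text{mode}\, e^{\sigma^2} 2\sinh(z_{0.75}\sigma)$,
  solved to $10^{-10}$ relative accuracy. Documented non-binding pairs
  (zero or missing) are handled by clipping: the mode floor is
  $10^4\,$M$^{-1}$ and the IQR floor $10^5\,$M$^{-1}$, giving weak,
  broad priors rather than hard zeros.
* **Receptor abundances.** Lognormal maximum likelihood over replicated
  expression measurements ($\mu$ = mean log, $\sigma$ = population SD of
  logs), with a floor of 0.1 on $\sigma$ so that identical replicates do
  not produce a degenerate point prior.
* **Valencies and crosslinking.** $f_4 \sim \log N(\log 4, 0.2)$,
  $f_{33} \sim \log N(\log 33, 0.2)$,
  $K_x^* \sim \log N(\log 6.31\times 10^{-13}, 2)$.
* **Signal scale and noise.** One positive scale factor per receptor
  maps per-cell bound-complex counts to normalized RFU; because
  replicate normalization removes absolute intensity, this factor is not
  identified a priori and carries a broad prior ($\sigma = 2$). The
  observation model is multiplicative lognormal,
  $\log rfu \sim N(\log \widehat{rfu}, \sigma_{obs})$, with one shared
  fitted $\sigma_{obs}$: RFU is positive and spans decades, making a
  log-scale noise model the natural choice. Zero readouts are floored at
  $10^{-3}$ times the smallest positive readout before taking logs.

By default only single-composition (pure IgG) records enter the
likelihood; mixture records are held out and predicted from the fitted
posterior, which is the package's main internal validation of the
mixture model (`useMixtures = TRUE` overrides).

The MAP estimate is found by block-coordinate ascent: L-BFGS-B over all
parameters with $\sigma_{obs}$ held fixed, alternated with an exact
one-dimensional update of $\log\sigma_{obs}$ given the residual sum of
squares, iterated to convergence. The alternation is what keeps the
noise-free limit well behaved -- with exactly reproducible data the
posterior drives $\sigma_{obs}$ into the prior's lower tail, and a joint
or profiled objective becomes too stiff for finite-difference gradients,
while each conditional subproblem stays smooth.

Posterior sampling uses a MAP-initialized adaptive Metropolis sampler:
multivariate normal proposals whose covariance is learned during warmup
(scaled by $2.38^2/d$) with a global step size tuned toward 23%
acceptance, adaptation frozen after warmup. A gradient-based sampler
would mix faster per iteration, but the posterior here is
low-dimensional (a dozen to a few dozen parameters), each density
evaluation is a vectorized pass over the panel, and the contract is on
the posterior, not the kernel. Split-Rhat and bulk effective sample size
are attached per parameter; chains are seeded deterministically, so a
fixed configuration reproduces draws exactly. Default sampler settings
are 4 chains, 1000 warmup, 1000 kept draws. Random-walk mixing scales as
$\sim d^{-1}$ per iteration, so convergence-diagnostic studies in the
test suite use longer chains (the prior-recovery check runs 4 x 20000
draws after 4000 warmup, a few seconds at prior-only cost), while
parameter-recovery checks use short chains (4 x 500) and assess interval
coverage rather than tight Rhat.

## Effector activity and the depletion regression

For in vivo prediction, each effector cell type is modeled as a
`CellSurface` of FcgR abundances; the binding model is evaluated at
$L_0 = 1\,$nM and $f = 4$ (overridable), and the per-receptor
multimerized pools are combined with receptor signs $p_i$ (+1 activating,
-1 for the inhibitory FcgRIIB) into a cell activity
$x_n = \max(\sum_i p_i R_{multi,i}, 0)$. Observed depletion -- the
fractional reduction in target-cell counts -- is linked to the weighted
activity sum through the exponential CDF,
$\hat{y} = 1 - \exp(-\sum_n w_n x_n)$, which saturates at 1. The
cell-type weights $w_n \geq 0$ absorb effector abundance and potency;
they carry lognormal priors whose default location is scale-matched to
the activities (prior median set so typical total activity maps to about
half depletion, log-SD 3, i.e. essentially scale-free). The observation
model is Normal noise on the depletion fraction truncated to $[0, 1]$;
observed values outside $[0, 1]$ (e.g. a biological increase in target
cells) are clamped to the boundary with a warning, since the link cannot
emit them. Fitting mirrors the binding fit: MAP by L-BFGS-B, then
adaptive Metropolis.

## The synthetic-data generator

`factorialDesign()` enumerates the full measurement grid; with the
default six receptors (FcgRI, both FcgRIIA alleles, FcgRIIB, both
FcgRIIIA alleles), two valency classes, all six unordered pairs of the
four IgG subclasses and six compositions (1.0, 0.9, 0.67, 0.33, 0.1,
0.0 as the first species' fraction), that is 432 distinct conditions.
`sampleGroundTruth()` draws generating parameters: affinities
log-uniform over $10^4$--$10^8\,$M$^{-1}$ (bracketing the documented
human IgG--FcgR range), expression log-uniform over
$10^4$--$10^6$ sites/cell (typical stable transfectants), effective
valencies lognormal about their nominal values, $K_x^*$ at its
literature value $6.31\times10^{-13}$ cell$\cdot$M, and observation
noise $\sigma_{obs} = 0.1$ (a 10% coefficient of variation, typical of
replicated flow-cytometry medians). Binding noise is applied
multiplicatively on the log scale and depletion noise additively with
truncation, deliberately matching the fitted observation models so that
parameter-recovery studies are a fair test of the inference rather than
of model mismatch. Default panel sizes are 3 replicates and 6 animals
per condition.

Cell-type weights for depletion studies are drawn on a scale matched to
the activities the default effector profiles produce, so noise-free
depletions span roughly 20--90% rather than saturating the link --
saturated studies carry no information about individual weights. The
shipped effector profiles (classical monocytes, nonclassical monocytes,
neutrophils) are *synthetic* stand-ins chosen to reflect qualitative
expression patterns of human blood effector cells; they are not
measurements.

What the generator does **not** emulate: cytometer artifacts (spectral
spillover, gating errors, detection floors), day effects beyond the
replicate structure, correlated noise across conditions, and real
binding panels' background fluorescence. Passing recovery tests
therefore demonstrates that the inference machinery is self-consistent
under the assumed observation model, not that the model is correct for
any particular instrument's output.

## Numerical and design choices

* **Prefactor convention.** The macroscopic quantities divide by
  $K_x^*$; this is forced jointly by the Langmuir limit at $f = 1$ and
  by dimensional analysis ($L_0/K_x^*$ has units of per-cell counts).
* **Composition normalization** $\sum_i \phi_{i0} = 1$ is substituted
  wherever the unbound-only term appears.
* **PCA conventions.** `pcaVarianceExplained()` evaluates
  $1 - \|X - \hat{X}_k\|_F^2 / \|X\|_F^2$ on the reconstruction. With
  `center = TRUE` (default) the SVD is of the column-centered matrix and
  the means are re-added before the formula is applied, so $k = 0$
  returns the fraction captured by the means alone; `center = FALSE`
  gives the plain truncated-SVD convention, under which the fraction is
  guaranteed nondecreasing in $k$ and within $[0,1]$. Both are exposed
  because either convention is defensible for a positive median matrix.
* **Quantiles.** Medians and IQRs use linear-interpolation quantiles
  (type 7), the common default.
* **Held-out validation.** The pipeline's mixture check is a 90%
  posterior-predictive interval per held-out record (thinned posterior
  draws pushed through the model plus one observation-noise draw each),
  a sharper and better-calibrated criterion than a plug-in error band
  around the posterior-median prediction.
* **Desk-scale study sizes.** Recovery studies in the tests and the
  acceptance script use a two-receptor x two-subclass panel for
  parameter recovery (the smallest design in which all four affinities
  are identifiable from pure conditions) and a three-receptor x
  three-subclass panel for the single-IgG-to-mixture round trip. The
  2 x 2 panel deliberately stays in the suite for point recovery, but
  its mixtures interpolate between only two pure anchors per receptor
  and are visibly sensitive to small joint parameter errors; three
  pure anchors per receptor constrain the interpolation, which is why
  the round trip uses 3 x 3. The full 6 x 4 design runs in a few
  minutes and is the default for `runPipeline()`.

## Limitations

* The equilibrium model has no kinetics and no steric or geometric
  detail beyond the single $K_x^*$ phenomenology; complexes are assumed
  random assortments of monomers at fixed effective valency.
* Whether measured fluorescence tracks bound complexes ($L_{bound}$) or
  total bound monomers is not resolvable from the data modeled here;
  the package follows prior practice in using $L_{bound}$.
* The depletion regression absorbs effector abundance into the weights;
  it cannot separate potency from prevalence, and the receptor signs
  are fixed inputs, not inferred.
* The adaptive Metropolis sampler is adequate for the posteriors at
  hand but would need many more iterations for substantially larger
  parameter blocks; the fit surface deliberately exposes chain, warmup
  and draw counts.
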