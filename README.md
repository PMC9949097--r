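# FcBindMix

Modeling the binding of mixed-composition IgG immune complexes to
Fc-gamma receptors, Bayesian refinement of monovalent Fc–FcγR
affinities from replicated binding panels, and regression of in vivo
target-cell depletion on model-predicted receptor multimerization.

## The problem

Immune complexes (ICs) formed in vivo carry a mixture of IgG subclasses,
and effector cells read them through several Fcγ receptor species at
once. Function is driven by avidity — several Fc sites of one complex
engaging several receptors on one cell — so monovalent affinities alone
do not predict cell-level binding, and binding alone does not predict
effector function. FcBindMix is for quantitative immunologists who want
to (i) predict equilibrium binding of multivalent, mixed-composition
complexes to multi-receptor cells, (ii) update documented monovalent
affinities against replicated IC binding measurements, and (iii) connect
the model's multimerized-receptor predictions on effector cell types to
observed target-cell depletion.

## The model

With monovalent association constants `Ka[i,j]` (M⁻¹), complex
concentration `L0` (M), effective valency `f`, monomer proportions `C_i`
and free receptors `Req[j]` per cell, engagement propensities are

    phi[i,j] = Req[j] * Ka[i,j] * Kx* * C_i,     phi[i,0] = C_i,

where `Kx*` (cell·M) is the crosslinking constant that scales every
engagement after a complex's first. With `Phi` the grand sum of `phi`,

    Lbound     = L0/Kx* (Phi^f − 1)                       bound complexes/cell
    Rbound[n]  = L0 f/Kx* (Σ_i phi[i,n]) Phi^(f−1)        bound receptors/cell
    Rmulti[n]  = L0 f/Kx* (Σ_i phi[i,n]) (Phi^(f−1) − 1)  multimerized pool

Free receptors solve conservation of mass `Rtot = Req + Rbound(Req)`.
An exhaustive enumeration oracle over all binding configurations
verifies the closed forms at integer valency.

Affinity refinement places lognormal priors on every positive parameter
(documented affinity = prior mode, its standard error = prior IQR, with
non-binding pairs clipped to a 1e4 M⁻¹ mode / 1e5 M⁻¹ IQR floor;
`f4 ~ logN(log 4, 0.2)`, `f33 ~ logN(log 33, 0.2)`,
`Kx* ~ logN(log 6.31e-13, 2)`), uses a lognormal observation model on
normalized fluorescence, and samples with a MAP-initialized adaptive
Metropolis sampler. Depletion is linked to per-cell-type activities
`x_n = max(Σ_i p_i Rmulti[i], 0)` (sign `p = −1` for the inhibitory
FcγRIIB) through the exponential CDF `ŷ = 1 − exp(−Σ w_n x_n)`.

See `vignettes/binding-model-methods.Rmd` for the full account of the
model, priors, samplers, and the synthetic-data generator.

## Worked example

A 4-valent complex of 90% IgG1 / 10% IgG2 at 1 nM binding a cell that
expresses the activating FcγRI and the inhibitory FcγRIIB:

```r
library(FcBindMix)

ka <- affinityMatrix(
    matrix(c(6.1e7, 2.5e4,      # IgG1, IgG2 vs FcgRI
             1.2e5, 2.0e5),     # IgG1, IgG2 vs FcgRIIB
           nrow = 2,
           dimnames = list(c("IgG1", "IgG2"),
                           c("FcgRI", "FcgRIIB-232I"))))
spec    <- complexSpec(L0 = 1e-9, f = 4,
                       composition = c(IgG1 = 0.9, IgG2 = 0.1))
surface <- cellSurface(c(FcgRI = 1e5, "FcgRIIB-232I" = 3e4))

eq <- solveEquilibrium(spec, surface, ka, kxStar = 6.31e-13)
macroscopic(eq)
#> MacroscopicQuantities (per cell)
#>   Lbound: 30505
#>   Rbound: FcgRI=6.77e+04, FcgRIIB-232I=145.9
#>   Rmulti: FcgRI=6.061e+04, FcgRIIB-232I=130.6
```

Of the 100,000 FcγRI on the cell, 67,700 are engaged at equilibrium and
60,610 sit in multiply-bound (signaling-competent) complexes; the
low-affinity FcγRIIB engages only ~146. Combining the multimerized
pools with receptor signs and the exponential link:

```r
act <- cellActivity(multimerizedReceptors(macroscopic(eq)), c(1, -1))
act
#> [1] 60479.86
predictDepletion(act, 2e-5)
#> [1] 0.7016826
```

so at a cell-type weight of 2e-5 this activity predicts ~70% target-cell
depletion. Prior construction from a documented affinity:

```r
lognormalFromModeIqr(6.1e7, 5e6)
#> LognormalPrior(mu = 17.93, sigma = 0.0605234); median = 6.12239e+07
```

The full synthetic pipeline — simulate a factorial binding panel, fit
the posterior on single-IgG conditions, predict the held-out mixtures,
fit depletion weights, and write diagnostics plus a run manifest — is
one call:

```r
cfg <- defaultRunConfig()
cfg$out <- "my-run"
runPipeline(cfg)
```

A thin command-line wrapper with `simulate`, `fit-affinities`,
`fit-depletion` and `run-all` subcommands is installed at
`inst/scripts/fcbindmix.R`.

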