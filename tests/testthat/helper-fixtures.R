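# Shared fixtures: a reduced two-receptor / two-subclass binding study whose
# generating truth sits at the prior medians (the log-scale prior modes), so
# noise-free data admit exact MAP recovery and noisy data give a fair
# coverage test.

reducedReceptors <- c("FcgRI", "FcgRIIB-232I")
reducedSubclasses <- c("IgG1", "IgG2")

makeReducedPriors <- function() {
    doc <- affinityMatrix(matrix(c(6.1e7, 1e4, 2e5, 1.2e6), 2, 2,
                                 dimnames = list(reducedSubclasses,
                                                 reducedReceptors)))
    se <- doc@.Data * 0.25
    exprTrue <- c(1e5, 3e4)
    names(exprTrue) <- reducedReceptors
    expr <- lapply(stats::setNames(nm = reducedReceptors),
                   function(r) exprTrue[r] * exp(c(-0.1, 0, 0.1)))
    priorSet(buildAffinityPriors(doc, se), buildReceptorPriors(expr))
}

truthAtPriorMedians <- function(priors, sigmaObs = 0) {
    recs <- colnames(priors@affinityMu)
    subs <- rownames(priors@affinityMu)
    ka <- matrix(exp(priors@affinityMu), length(subs), length(recs),
                 dimnames = list(subs, recs))
    list(affinities = affinityMatrix(ka),
         receptorExpression = stats::setNames(exp(priors@receptorMu), recs),
         kxStar = exp(priors@kx@mu),
         f4 = exp(priors@f4@mu), f33 = exp(priors@f33@mu),
         scale = stats::setNames(exp(priors@scaleMu), recs),
         sigmaObs = sigmaObs)
}

makeReducedPanel <- function(sigmaObs = 0, seed = 12, replicates = 3) {
    priors <- makeReducedPriors()
    truth <- truthAtPriorMedians(priors, sigmaObs)
    design <- factorialDesign(receptors = reducedReceptors,
                              subclasses = reducedSubclasses)
    panel <- simulateBindingPanel(truth, design, replicates = replicates,
                                  seed = seed)
    list(priors = priors, truth = truth, design = design, panel = panel)
}

# Random phi matrix with a valid composition column.
randomPhi <- function(nL, nR, maxPhi = 5) {
    phi <- matrix(stats::runif(nL * (nR + 1), 0, maxPhi), nL, nR + 1)
    C <- stats::runif(nL)
    phi[, 1] <- C / sum(C)
    colnames(phi) <- c("unbound", paste0("R", seq_len(nR)))
    rownames(phi) <- paste0("L", seq_len(nL))
    phi
}

relErr <- function(a, b) abs(a - b) / pmax(abs(b), 1e-300)

affinityIndices <- function(priors) {
    lay <- getFromNamespace(".panelLayout", "FcBindMix")(priors)
    lay$idxKa
}

# Desk-scale round-trip design: three receptors x three subclasses is the
# smallest factorial that constrains mixture interpolation well.
roundTripReceptors <- c("FcgRI", "FcgRIIA-131R", "FcgRIIIA-158F")
roundTripSubclasses <- c("IgG1", "IgG2", "IgG3")

roundTripConfig <- function(out, seed = 7L) {
    cfg <- defaultRunConfig()
    cfg$out <- out
    cfg$seed <- seed
    cfg$synthetic$receptors <- roundTripReceptors
    cfg$synthetic$subclasses <- roundTripSubclasses
    cfg$sampler <- list(chains = 2L, warmup = 300L, draws = 300L)
    cfg
}
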