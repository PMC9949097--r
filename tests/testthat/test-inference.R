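test_that("prior-only log-posterior equals the sum of prior densities", {
    priors <- makeReducedPriors()
    lay <- FcBindMix:::.panelLayout(priors)
    pv <- FcBindMix:::.priorVectors(priors, lay)
    empty <- data.frame(receptor = character(), valency = numeric(),
                        igg_a = character(), igg_b = character(),
                        frac_a = numeric(), replicate = character(),
                        rfu = numeric())
    atModes <- stats::setNames(exp(pv$mu), lay$names)
    expect_equal(bindingLogPosterior(atModes, empty, priors),
                 sum(stats::dnorm(pv$mu, pv$mu, pv$sd, log = TRUE)))
    # outside the positive support the density is -Inf, not an error
    bad <- atModes; bad[1] <- 0
    expect_identical(bindingLogPosterior(bad, empty, priors), -Inf)
})

test_that("doubling the noise with zero residuals costs N log 2", {
    priors <- makeReducedPriors()
    lay <- FcBindMix:::.panelLayout(priors)
    pv <- FcBindMix:::.priorVectors(priors, lay)
    params <- stats::setNames(exp(pv$mu), lay$names)
    design <- factorialDesign(receptors = reducedReceptors,
                              subclasses = reducedSubclasses)
    design$replicate <- "1"
    design$rfu <- predictMeasurement(params, design, priors)
    lp1 <- bindingLogPosterior(params, design, priors)
    params2 <- params
    params2[["sigmaObs"]] <- 2 * params[["sigmaObs"]]
    lp2 <- bindingLogPosterior(params2, design, priors)
    priorDiff <- stats::dnorm(log(params2[["sigmaObs"]]),
                              pv$mu[lay$idxNoise], pv$sd[lay$idxNoise],
                              log = TRUE) -
        stats::dnorm(log(params[["sigmaObs"]]), pv$mu[lay$idxNoise],
                     pv$sd[lay$idxNoise], log = TRUE)
    expect_equal(lp1 - lp2, nrow(design) * log(2) - priorDiff,
                 tolerance = 1e-8)
})

test_that("forward predictions respect valency monotonicity and exchangeability", {
    priors <- makeReducedPriors()
    lay <- FcBindMix:::.panelLayout(priors)
    pv <- FcBindMix:::.priorVectors(priors, lay)
    params <- stats::setNames(exp(pv$mu), lay$names)
    base <- data.frame(receptor = "FcgRI", igg_a = "IgG1", igg_b = "IgG2",
                       replicate = "1")
    # higher effective valency never predicts less binding
    d4 <- cbind(base, valency = 4, frac_a = c(1, 0.67, 0))
    d33 <- cbind(base, valency = 33, frac_a = c(1, 0.67, 0))
    expect_true(all(predictMeasurement(params, d33, priors) >=
                        predictMeasurement(params, d4, priors)))
    # a 50/50 mixture of identical species equals the pure condition
    paramsEq <- params
    paramsEq[["Ka[IgG2,FcgRI]"]] <- params[["Ka[IgG1,FcgRI]"]]
    paramsEq[["Ka[IgG2,FcgRIIB-232I]"]] <- params[["Ka[IgG1,FcgRIIB-232I]"]]
    dmix <- cbind(base, valency = 4, frac_a = c(0.5, 1))
    p <- predictMeasurement(paramsEq, dmix, priors)
    expect_equal(p[1], p[2], tolerance = 1e-12)
})

test_that("MAP on an empty panel returns the prior locations, deterministically", {
    priors <- makeReducedPriors()
    lay <- FcBindMix:::.panelLayout(priors)
    pv <- FcBindMix:::.priorVectors(priors, lay)
    empty <- data.frame(receptor = character(), valency = numeric(),
                        igg_a = character(), igg_b = character(),
                        frac_a = numeric(), replicate = character(),
                        rfu = numeric())
    m1 <- fitMap(empty, priors, seed = 4)
    m2 <- fitMap(empty, priors, seed = 4)
    expect_identical(m1$estimate, m2$estimate)
    expect_equal(unname(log(m1$estimate)), unname(pv$mu), tolerance = 1e-9)
})

test_that("posterior sampling is reproducible and covers the prior when data are absent", {
    priors <- makeReducedPriors()
    empty <- data.frame(receptor = character(), valency = numeric(),
                        igg_a = character(), igg_b = character(),
                        frac_a = numeric(), replicate = character(),
                        rfu = numeric())
    cfg <- list(chains = 4L, warmup = 4000L, draws = 20000L, seed = 11L)
    ps1 <- runMcmc(empty, priors, config = cfg)
    ps2 <- runMcmc(empty, priors, config = cfg)
    expect_identical(posteriorDraws(ps1), posteriorDraws(ps2))

    lay <- FcBindMix:::.panelLayout(priors)
    pv <- FcBindMix:::.priorVectors(priors, lay)
    dr <- log(posteriorDraws(ps1))
    medErr <- vapply(seq_along(pv$mu), function(k)
        abs(stats::median(dr[, , k]) - pv$mu[k]) / pv$sd[k], 0)
    expect_lt(stats::median(medErr), 0.25)
    expect_lt(max(medErr), 0.6)
    # split-Rhat indicates convergence on the log-affinities
    dg <- mcmcDiagnostics(ps1)
    kaRows <- grepl("^Ka\\[", dg$parameter)
    expect_lt(max(dg$rhat[kaRows]), 1.05)
})

test_that("fixing the affinity block holds it constant and lowers the attainable posterior", {
    study <- makeReducedPanel(sigmaObs = 0.1, seed = 23)
    cfg <- list(chains = 2L, warmup = 200L, draws = 150L, seed = 3L)
    ps <- fixedAffinityFit(study$panel, study$priors,
                           study$truth$affinities, config = cfg)
    dr <- posteriorDraws(ps)
    kaIdx <- affinityIndices(study$priors)
    for (k in kaIdx)
        expect_equal(stats::sd(dr[, , k]), 0)
    dg <- mcmcDiagnostics(ps)
    expect_true(all(is.na(dg$rhat[kaIdx])))

    # nesting: fixing affinities at wrong values cannot beat the free fit
    free <- fitMap(study$panel, study$priors)
    wrong <- affinityMatrix(study$truth$affinities@.Data * 3)
    fixedWrong <- fitMap(study$panel, study$priors, fixedAffinities = wrong)
    fitRecords <- study$panel[study$panel$frac_a %in% c(0, 1), ]
    lpFree <- bindingLogPosterior(free$estimate, fitRecords, study$priors)
    lpWrong <- bindingLogPosterior(fixedWrong$estimate, fitRecords,
                                   study$priors)
    expect_gt(lpFree, lpWrong)
})

test_that("more replicates contract the affinity posterior", {
    cfg <- list(chains = 2L, warmup = 300L, draws = 300L, seed = 7L)
    few <- makeReducedPanel(sigmaObs = 0.1, seed = 31, replicates = 3)
    many <- makeReducedPanel(sigmaObs = 0.1, seed = 31, replicates = 30)
    psFew <- runMcmc(few$panel, few$priors, config = cfg)
    psMany <- runMcmc(many$panel, many$priors, config = cfg)
    kaIdx <- affinityIndices(few$priors)
    iqrOf <- function(ps) vapply(kaIdx, function(k)
        stats::IQR(log(posteriorDraws(ps)[, , k])), 0)
    expect_lt(stats::median(iqrOf(psMany)), stats::median(iqrOf(psFew)))
})

test_that("posterior summaries carry quantiles and diagnostics per parameter", {
    priors <- makeReducedPriors()
    empty <- data.frame(receptor = character(), valency = numeric(),
                        igg_a = character(), igg_b = character(),
                        frac_a = numeric(), replicate = character(),
                        rfu = numeric())
    ps <- runMcmc(empty, priors,
                  config = list(chains = 2L, warmup = 100L, draws = 100L,
                                seed = 2L))
    s <- posteriorSummary(ps)
    expect_setequal(names(s),
                    c("parameter", "median", "q25", "q75", "ess", "rhat"))
    expect_equal(nrow(s), dim(posteriorDraws(ps))[3])
    expect_true(all(s$q25 <= s$median & s$median <= s$q75))
})
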