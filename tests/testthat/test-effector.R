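test_that("cell activity is the sign-weighted, zero-clipped receptor sum", {
    expect_equal(cellActivity(c(5, 10), c(1, -1)), 0)
    expect_equal(cellActivity(c(3, 4), c(1, 1)), 7)
    expect_equal(cellActivity(c(0, 0), c(1, -1)), 0)
    expect_error(cellActivity(c(1, 2), c(1, 0.5)), "signs")
    expect_error(cellActivity(c(1, 2), 1), "align")
})

test_that("the exponential link maps activity to bounded depletion", {
    expect_equal(predictDepletion(0, 1), 0)
    expect_equal(predictDepletion(log(2), 1), 0.5)
    expect_equal(predictDepletion(1e6, 1), 1)
    expect_lt(predictDepletion(5, 1), 1)
    expect_error(predictDepletion(-1, 1), "activities")
    expect_error(predictDepletion(1, -1), "weights")
    # link inversion recovers the linear predictor
    x <- c(0.3, 1.2); w <- c(0.5, 0.1)
    yhat <- predictDepletion(x, w)
    expect_equal(-log(1 - yhat), sum(w * x))
    # zero-weight cell types never affect predictions
    expect_equal(predictDepletion(c(x, 99), c(w, 0)), yhat)
    # monotone in weights and activities
    expect_gte(predictDepletion(x * 2, w), yhat)
    expect_gte(predictDepletion(x, w * 2), yhat)
})

test_that("per-cell-type activities follow receptor content", {
    tr <- sampleGroundTruth(5, receptors = reducedReceptors,
                            subclasses = reducedSubclasses)
    signs <- defaultReceptorSigns(reducedReceptors)
    comp <- c(IgG1 = 1, IgG2 = 0)
    profiles <- list(
        inhibOnly = cellSurface(c("FcgRI" = 0, "FcgRIIB-232I" = 5e4)),
        none = cellSurface(c("FcgRI" = 0, "FcgRIIB-232I" = 0)),
        a = cellSurface(c("FcgRI" = 1e5, "FcgRIIB-232I" = 1e3)),
        b = cellSurface(c("FcgRI" = 1e5, "FcgRIIB-232I" = 1e3)))
    act <- activitiesForCondition(comp, profiles, tr$affinities, tr$kxStar,
                                  signs)
    expect_equal(unname(act["inhibOnly"]), 0)  # pure inhibition clips to 0
    expect_equal(unname(act["none"]), 0)       # no receptors, no activity
    expect_equal(act[["a"]], act[["b"]])       # identical profiles
    expect_error(activitiesForCondition(comp, profiles, tr$affinities,
                                        tr$kxStar, c(FcgRI = 1)),
                 "signs must cover")
})

test_that("depletion observations outside [0,1] are clamped with a warning", {
    expect_warning(y <- clampDepletion(c(-0.1, 0.5, 1.4)), "clamped")
    expect_equal(y, c(0, 0.5, 1))
    expect_silent(clampDepletion(c(0, 1)))
})

test_that("a single cell type with noise-free data is recovered to 1%", {
    tr <- sampleGroundTruth(21)
    st <- simulateDepletionStudy(tr, profiles = defaultEffectorProfiles()["cMO"],
                                 micePerCondition = 6, noiseSd = 0, seed = 3)
    fit <- fitDepletion(st$data, st$activities,
                        config = list(chains = 2L, warmup = 300L,
                                      draws = 300L, seed = 9L))
    wTrue <- tr$cellWeights[["cMO"]]
    expect_lt(abs(mapEstimate(fit)[["w[cMO]"]] - wTrue) / wTrue, 0.01)
})

test_that("multi-cell-type weights are recovered from a noisy study", {
    tr <- sampleGroundTruth(21)
    st <- simulateDepletionStudy(tr, micePerCondition = 6, noiseSd = 0.05,
                                 seed = 4)
    fit <- fitDepletion(st$data, st$activities,
                        config = list(chains = 4L, warmup = 800L,
                                      draws = 800L, seed = 9L))
    dr <- posteriorDraws(fit)
    for (tn in colnames(st$activities)) {
        tv <- tr$cellWeights[[tn]]
        d <- dr[, , paste0("w[", tn, "]")]
        expect_lt(stats::median(d) / tv, 2)
        expect_gt(stats::median(d) / tv, 0.5)
        q <- stats::quantile(d, c(0.05, 0.95))
        expect_true(tv >= q[[1]] && tv <= q[[2]])
    }
})

test_that("an all-zero activity matrix is rejected as unidentifiable", {
    d <- data.frame(condition = "c1", donor = "1", replicate = "1",
                    depletion_fraction = 0.4)
    X <- matrix(0, 1, 2, dimnames = list("c1", c("a", "b")))
    expect_error(fitDepletion(d, X), "unidentifiable")
})

test_that("a cell type with zero activity keeps (roughly) its prior", {
    tr <- sampleGroundTruth(21)
    st <- simulateDepletionStudy(tr, micePerCondition = 6, noiseSd = 0.05,
                                 seed = 4)
    X <- cbind(st$activities, inert = 0)
    prior <- list(mu = rep(log(1e-5), 4), sigma = rep(1, 4))
    fit <- fitDepletion(st$data, X,
                        config = list(chains = 2L, warmup = 400L,
                                      draws = 400L, seed = 2L),
                        weightPrior = prior)
    d <- log(posteriorDraws(fit)[, , "w[inert]"])
    expect_lt(abs(stats::median(d) - log(1e-5)), 0.5)
    expect_lt(abs(stats::sd(d) - 1), 0.35)
})
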