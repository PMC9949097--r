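test_that("the factorial design enumerates the full condition grid", {
    d <- factorialDesign()
    expect_equal(nrow(d), 432L)              # 6 x 2 x 6 x 6
    expect_equal(length(unique(d$condition_id)), 432L)
    expect_equal(ncol(utils::combn(panelSubclasses(), 2)), 6L)
    expect_setequal(unique(d$valency), c(4, 33))
    expect_setequal(unique(d$frac_a), c(1, 0.9, 0.67, 0.33, 0.1, 0))
    # a composition of 1.0 for (IgG1, IgG2) is the pure IgG1 condition;
    # deduplication keeps one pure record per (receptor, valency, subclass)
    dd <- factorialDesign(dedupePure = TRUE)
    pure <- dd[dd$frac_a %in% c(0, 1), ]
    species <- ifelse(pure$frac_a == 1, pure$igg_a, pure$igg_b)
    expect_equal(nrow(pure), 6 * 2 * 4)
    expect_equal(anyDuplicated(paste(pure$receptor, pure$valency, species)),
                 0L)
})

test_that("ground truth is a pure, range-respecting function of the seed", {
    t1 <- sampleGroundTruth(5)
    t2 <- sampleGroundTruth(5)
    t3 <- sampleGroundTruth(6)
    expect_identical(t1, t2)
    expect_false(identical(t1$affinities@.Data, t3$affinities@.Data))
    expect_true(all(t1$affinities@.Data >= 1e4 & t1$affinities@.Data <= 1e8))
    expect_true(all(t1$receptorExpression >= 1e4 &
                        t1$receptorExpression <= 1e6))
    expect_equal(t1$kxStar, 6.31e-13)
    expect_error(sampleGroundTruth(1, affinityRange = c(-1, 10)), "range")
})

test_that("the simulated panel has the factorial cardinality and noise structure", {
    tr <- sampleGroundTruth(3, receptors = reducedReceptors,
                            subclasses = reducedSubclasses)
    design <- factorialDesign(receptors = reducedReceptors,
                              subclasses = reducedSubclasses)
    pan <- simulateBindingPanel(tr, design, replicates = 3, seed = 4)
    expect_equal(nrow(pan), nrow(design) * 3L)
    # determinism under the seed
    expect_identical(pan,
                     simulateBindingPanel(tr, design, replicates = 3,
                                          seed = 4))
    # noise-free replicates are identical within a condition
    tr0 <- tr; tr0$sigmaObs <- 0
    p0 <- simulateBindingPanel(tr0, design, replicates = 3, seed = 4)
    spread <- tapply(p0$rfu,
                     paste(p0$receptor, p0$valency, p0$igg_a, p0$igg_b,
                           p0$frac_a), function(v) diff(range(v)))
    expect_true(all(spread < 1e-12))
    # replicate normalization holds
    expect_true(all(abs(tapply(pan$rfu, pan$replicate, mean) - 1) < 1e-12))
})

test_that("simulated median binding at valency 33 dominates valency 4 away from saturation", {
    # Higher valency increases bound complexes only while receptors are in
    # excess; under strong receptor depletion a 33-valent complex consumes
    # more receptors per complex, so fewer complexes can bind. The ordering
    # is therefore asserted where occupancy stays moderate.
    for (seed in 1:3) {
        tr <- sampleGroundTruth(seed)
        tr$sigmaObs <- 0.05
        pan <- simulateBindingPanel(tr, factorialDesign(), replicates = 3,
                                    seed = seed + 10)
        pure <- pan[pan$frac_a == 1, ]
        med <- stats::aggregate(
            pure["rfu"], pure[c("receptor", "igg_a", "valency")],
            stats::median)
        wide <- merge(med[med$valency == 4, ], med[med$valency == 33, ],
                      by = c("receptor", "igg_a"))
        occupancy <- vapply(seq_len(nrow(wide)), function(i) {
            rec <- wide$receptor[i]; igg <- wide$igg_a[i]
            spec <- complexSpec(1e-9, tr$f33, stats::setNames(1, igg))
            ka <- affinityMatrix(tr$affinities@.Data[igg, rec, drop = FALSE])
            rt <- tr$receptorExpression[rec]
            st <- solveEquilibrium(spec, cellSurface(rt), ka, tr$kxStar)
            unname(boundReceptors(macroscopic(st)) / rt)
        }, 0)
        open <- occupancy < 0.3
        expect_gt(sum(open), 0)
        expect_true(all(wide$rfu.y[open] >= wide$rfu.x[open]))
    }
})

test_that("the depletion study follows the link and its noise contract", {
    tr <- sampleGroundTruth(9)
    # zero noise reproduces the model predictions exactly
    st0 <- simulateDepletionStudy(tr, micePerCondition = 2, noiseSd = 0,
                                  seed = 5)
    expect_equal(st0$data$depletion_fraction,
                 rep(unname(st0$expected), each = 2))
    expect_true(all(st0$data$depletion_fraction >= 0 &
                        st0$data$depletion_fraction <= 1))
    # zero weights leave only clipped noise around zero
    trZ <- tr; trZ$cellWeights[] <- 0
    stZ <- simulateDepletionStudy(trZ, micePerCondition = 4, noiseSd = 0.05,
                                  seed = 6)
    expect_true(all(stZ$expected == 0))
    expect_true(all(stZ$data$depletion_fraction >= 0))
    expect_lt(max(stZ$data$depletion_fraction), 0.25)
    # doubling all weights never decreases a noiseless depletion
    tr2 <- tr; tr2$cellWeights <- tr$cellWeights * 2
    st2 <- simulateDepletionStudy(tr2, micePerCondition = 2, noiseSd = 0,
                                  seed = 5)
    expect_true(all(st2$expected >= st0$expected - 1e-12))
})
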