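test_that("computePhi matches the defining products and boundary cases", {
    ka <- affinityMatrix(matrix(1e7, 1, 1, dimnames = list("IgG1", "FcgRI")))
    spec <- complexSpec(1e-9, 4, c(IgG1 = 1))
    phi <- computePhi(1e5, spec, ka, 6.31e-13)
    expect_equal(unname(phi[1, 1]), 1)
    expect_equal(unname(phi[1, 2]), 1e5 * 1e7 * 6.31e-13, tolerance = 1e-12)

    # no free receptor -> no binding propensity, unbound column = C
    ka2 <- affinityMatrix(matrix(c(1e6, 1e7, 1e5, 1e8), 2, 2,
                                 dimnames = list(c("a", "b"), c("r1", "r2"))))
    spec2 <- complexSpec(1e-9, 4, c(a = 0.5, b = 0.5))
    phi0 <- computePhi(c(0, 0), spec2, ka2, 6.31e-13)
    expect_equal(unname(phi0[, 1]), c(0.5, 0.5))
    expect_true(all(phi0[, -1] == 0))

    # zero affinity -> zero propensity
    kaZ <- affinityMatrix(matrix(0, 2, 2,
                                 dimnames = list(c("a", "b"), c("r1", "r2"))))
    phiZ <- computePhi(c(1e5, 1e5), spec2, kaZ, 6.31e-13)
    expect_true(all(phiZ[, -1] == 0))
    expect_equal(unname(phiZ[, 1]), c(0.5, 0.5))

    # dimension mismatches name the offending axis
    expect_error(computePhi(c(1e5, 1e5, 1e5), spec2, ka2, 6.31e-13),
                 "receptor axis")
    expect_error(computePhi(c(1e5, 1e5), complexSpec(1e-9, 4, c(a = 1)),
                            ka2, 6.31e-13), "ligand axis")
})

test_that("closed-form macroscopic quantities match hand-enumerated values", {
    # single ligand, single receptor, f = 2, phi = (1, 0.5), units L0/Kx* = 1
    phi <- matrix(c(1, 0.5), 1, 2,
                  dimnames = list("L1", c("unbound", "R1")))
    m <- FcBindMix:::.macroFromPhi(phi, L0 = 1, kxStar = 1, f = 2)
    expect_equal(boundComplexes(m), 1.5^2 - 1)
    expect_equal(unname(boundReceptors(m)), 2 * 0.5 * 1.5)
    expect_equal(unname(multimerizedReceptors(m)), 2 * 0.5 * 0.5)

    # no affinity: Phi = 1 so everything vanishes
    phi0 <- matrix(c(1, 0), 1, 2,
                   dimnames = list("L1", c("unbound", "R1")))
    m0 <- FcBindMix:::.macroFromPhi(phi0, 1e-9, 6.31e-13, 4)
    expect_equal(boundComplexes(m0), 0)
    expect_equal(unname(boundReceptors(m0)), 0)

    # monovalent ligand cannot multimerize
    m1 <- FcBindMix:::.macroFromPhi(phi, 1e-9, 6.31e-13, 1)
    expect_equal(unname(multimerizedReceptors(m1)), 0)

    expect_error(FcBindMix:::.macroFromPhi(phi, 1, 1, 0), "valency")
    phiBad <- phi; phiBad[1, 2] <- Inf
    expect_error(FcBindMix:::.macroFromPhi(phiBad, 1, 1, 2), "finite")
})

test_that("configuration enumeration produces all weak compositions", {
    q <- enumerateConfigurations(2, 1, 1)
    expect_equal(nrow(q), 3L)
    expect_setequal(apply(q, 1, paste, collapse = ","),
                    c("2,0", "1,1", "0,2"))
    expect_equal(nrow(enumerateConfigurations(1, 2, 2)), 6L)
    expect_equal(nrow(enumerateConfigurations(4, 2, 2)), choose(9, 5))
    q4 <- enumerateConfigurations(4, 2, 2)
    expect_true(all(rowSums(q4) == 4))
    expect_equal(anyDuplicated(q4), 0L)
    expect_error(enumerateConfigurations(100, 3, 3), "smaller instance")
    expect_error(enumerateConfigurations(1.5, 1, 1), "integer")
})

test_that("enumeration oracle reproduces the hand-computed configuration sums", {
    phi <- matrix(c(1, 0.5), 1, 2,
                  dimnames = list("L1", c("unbound", "R1")))
    m <- oracleMacroscopic(phi, L0 = 1, kxStar = 1, f = 2)
    # v(2,0)=1, v(1,1)=2*0.5=1, v(0,2)=0.25
    expect_equal(boundComplexes(m), 1 + 0.25)
    expect_equal(unname(boundReceptors(m)), 1 * 1 + 2 * 0.25)
    expect_equal(unname(multimerizedReceptors(m)), 2 * 0.25)

    # all-unbound phi: nothing binds
    phiU <- matrix(c(0.4, 0.6, 0, 0), 2, 2,
                   dimnames = list(c("a", "b"), c("unbound", "R1")))
    mU <- oracleMacroscopic(phiU, 1e-9, 6.31e-13, 3)
    expect_equal(boundComplexes(mU), 0)
    expect_equal(unname(boundReceptors(mU)), 0)

    # f = 1: no configuration has two bound sites
    set.seed(41)
    m1 <- oracleMacroscopic(randomPhi(2, 2), 1e-9, 6.31e-13, 1)
    expect_equal(unname(multimerizedReceptors(m1)), c(0, 0))
})

test_that("closed forms agree with the enumeration oracle over random instances", {
    set.seed(90)
    for (i in 1:60) {
        nL <- sample(1:3, 1); nR <- sample(1:3, 1); f <- sample(1:6, 1)
        phi <- randomPhi(nL, nR)
        m1 <- FcBindMix:::.macroFromPhi(phi, 1e-9, 6.31e-13, f)
        m2 <- oracleMacroscopic(phi, 1e-9, 6.31e-13, f)
        expect_lt(relErr(boundComplexes(m1), boundComplexes(m2)), 1e-8)
        expect_lt(max(relErr(boundReceptors(m1), boundReceptors(m2))), 1e-8)
        expect_lt(max(relErr(multimerizedReceptors(m1),
                             multimerizedReceptors(m2))), 1e-8)
    }
})

test_that("equilibrium solve satisfies conservation of mass and bounds", {
    set.seed(91)
    for (i in 1:40) {
        nL <- sample(1:3, 1); nR <- sample(1:3, 1)
        ka <- affinityMatrix(matrix(10^stats::runif(nL * nR, 3, 9), nL, nR,
                                    dimnames = list(paste0("L", 1:nL),
                                                    paste0("R", 1:nR))))
        C <- stats::runif(nL); C <- C / sum(C)
        names(C) <- paste0("L", 1:nL)
        rt <- stats::setNames(10^stats::runif(nR, 3, 6), paste0("R", 1:nR))
        f <- stats::runif(1, 1, 33)
        st <- solveEquilibrium(complexSpec(1e-9, f, C), cellSurface(rt),
                               ka, 6.31e-13)
        m <- macroscopic(st)
        expect_lt(max(abs(rt - freeReceptors(st) - boundReceptors(m)) / rt),
                  1e-6)
        expect_true(all(freeReceptors(st) >= 0))
        expect_true(all(freeReceptors(st) <= rt))
        expect_true(all(multimerizedReceptors(m) <=
                            boundReceptors(m) * (1 + 1e-9)))
        expect_true(all(boundReceptors(m) <= rt * (1 + 1e-9)))
    }
})

test_that("no-binding limits return the full receptor complement", {
    ka0 <- affinityMatrix(matrix(0, 1, 2,
                                 dimnames = list("L1", c("R1", "R2"))))
    rt <- c(R1 = 1e5, R2 = 2e4)
    st <- solveEquilibrium(complexSpec(1e-9, 4, c(L1 = 1)), cellSurface(rt),
                           ka0, 6.31e-13)
    expect_identical(unname(freeReceptors(st)), unname(rt))
    expect_equal(boundComplexes(macroscopic(st)), 0)

    ka <- affinityMatrix(matrix(1e8, 1, 2,
                                dimnames = list("L1", c("R1", "R2"))))
    st0 <- solveEquilibrium(complexSpec(0, 4, c(L1 = 1)), cellSurface(rt),
                            ka, 6.31e-13)
    expect_identical(unname(freeReceptors(st0)), unname(rt))
})

test_that("monovalent binding reproduces the Langmuir isotherm", {
    ka <- affinityMatrix(matrix(1e9, 1, 1,
                                dimnames = list("IgG1", "FcgRI")))
    st <- solveEquilibrium(complexSpec(1e-9, 1, c(IgG1 = 1)),
                           cellSurface(c(FcgRI = 1e5)), ka, 6.31e-13)
    expect_lt(relErr(unname(freeReceptors(st)), 1e5 / (1 + 1e-9 * 1e9)),
              1e-9)
    m <- macroscopic(st)
    expect_lt(relErr(unname(boundReceptors(m)),
                     1e-9 * 1e9 * unname(freeReceptors(st))), 1e-9)
    expect_equal(unname(multimerizedReceptors(m)), 0)
})

test_that("zero-expression receptors are carried with Req = 0", {
    ka <- affinityMatrix(matrix(1e7, 1, 2,
                                dimnames = list("L1", c("R1", "R2"))))
    st <- solveEquilibrium(complexSpec(1e-9, 4, c(L1 = 1)),
                           cellSurface(c(R1 = 1e5, R2 = 0)), ka, 6.31e-13)
    expect_equal(unname(freeReceptors(st))[2], 0)
    expect_length(freeReceptors(st), 2L)
})

test_that("bound complexes increase with affinity and valency", {
    lb <- function(kaVal, f) {
        ka <- affinityMatrix(matrix(kaVal, 1, 1,
                                    dimnames = list("L1", "R1")))
        st <- solveEquilibrium(complexSpec(1e-9, f, c(L1 = 1)),
                               cellSurface(c(R1 = 1e5)), ka, 6.31e-13)
        boundComplexes(macroscopic(st))
    }
    kas <- 10^seq(4, 9, length.out = 8)
    expect_true(all(diff(vapply(kas, lb, 0, f = 4)) >= 0))
    fs <- c(1, 2, 4, 8, 16, 33)
    expect_true(all(diff(vapply(fs, lb, 0, kaVal = 1e6)) >= 0))
})

test_that("mixture binding shifts monotonically with composition", {
    ka <- affinityMatrix(matrix(c(1e8, 1e5), 2, 1,
                                dimnames = list(c("strong", "weak"), "R1")))
    lb <- vapply(seq(0, 1, by = 0.1), function(fr) {
        st <- solveEquilibrium(
            complexSpec(1e-9, 4, c(strong = fr, weak = 1 - fr)),
            cellSurface(c(R1 = 1e5)), ka, 6.31e-13)
        boundComplexes(macroscopic(st))
    }, 0)
    expect_true(all(diff(lb) >= 0))
})

test_that("macroscopic output is a function of phi and prefactors alone", {
    set.seed(92)
    ka <- affinityMatrix(matrix(10^stats::runif(4, 4, 8), 2, 2,
                                dimnames = list(c("a", "b"), c("r1", "r2"))))
    st <- solveEquilibrium(complexSpec(1e-9, 7.3, c(a = 0.3, b = 0.7)),
                           cellSurface(c(r1 = 2e5, r2 = 5e4)), ka, 6.31e-13)
    m1 <- macroscopic(st)
    m2 <- FcBindMix:::.macroFromPhi(phiMatrix(st), 1e-9, 6.31e-13, 7.3)
    expect_equal(boundComplexes(m1), boundComplexes(m2))
    expect_equal(boundReceptors(m1), boundReceptors(m2))
    expect_equal(multimerizedReceptors(m1), multimerizedReceptors(m2))
})
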