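#' @include AllClasses.R binding-model.R inference.R effector.R diagnostics.R
NULL

#' Receptor, subclass, valency and composition labels of the factorial panel
#'
#' The default design mirrors a mixed-composition immune-complex binding
#' panel: six human Fc-gamma receptor species (including both common
#' allelic variants of FcgRIIA and FcgRIIIA), complexes of nominal valency
#' 4 or 33, all six unordered pairs of the four IgG subclasses, and six
#' mixture compositions per pair.
#'
#' @name design-constants
NULL

#' @rdname design-constants
#' @export
panelReceptors <- function() c("FcgRI", "FcgRIIA-131H", "FcgRIIA-131R",
                               "FcgRIIB-232I", "FcgRIIIA-158F",
                               "FcgRIIIA-158V")

#' @rdname design-constants
#' @export
panelSubclasses <- function() c("IgG1", "IgG2", "IgG3", "IgG4")

#' @rdname design-constants
#' @export
panelCompositions <- function() c(1.0, 0.9, 0.67, 0.33, 0.1, 0.0)

#' Enumerate the factorial binding design
#'
#' Builds the full condition grid: receptors x valencies x unordered IgG
#' pairs x compositions (fraction of the first species). With the default
#' labels this yields 6 x 2 x 6 x 6 = 432 distinct conditions. Compositions
#' of 1.0 or 0.0 are pure single-subclass conditions of the pair's first or
#' second species; \code{dedupePure = TRUE} keeps a single record per pure
#' (receptor, valency, subclass) combination instead of one per pair.
#'
#' @param receptors,subclasses,valencies,compositions design levels.
#' @param dedupePure drop duplicate pure conditions across pairs.
#' @return data.frame with columns \code{receptor}, \code{valency},
#'   \code{igg_a}, \code{igg_b}, \code{frac_a}, \code{condition_id}.
#' @examples
#' nrow(factorialDesign())  # 432
#' @export
factorialDesign <- function(receptors = panelReceptors(),
                            subclasses = panelSubclasses(),
                            valencies = c(4, 33),
                            compositions = panelCompositions(),
                            dedupePure = FALSE) {
    pairs <- utils::combn(subclasses, 2L)
    grid <- expand.grid(pair = seq_len(ncol(pairs)),
                        frac_a = compositions, valency = valencies,
                        receptor = receptors,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$igg_a <- pairs[1L, grid$pair]
    grid$igg_b <- pairs[2L, grid$pair]
    grid$pair <- NULL
    grid <- grid[, c("receptor", "valency", "igg_a", "igg_b", "frac_a")]
    if (dedupePure) {
        pureSpecies <- ifelse(grid$frac_a == 1, grid$igg_a,
                              ifelse(grid$frac_a == 0, grid$igg_b, NA))
        key <- ifelse(is.na(pureSpecies),
                      paste(grid$receptor, grid$valency, grid$igg_a,
                            grid$igg_b, grid$frac_a),
                      paste(grid$receptor, grid$valency, pureSpecies, "pure"))
        grid <- grid[!duplicated(key), , drop = FALSE]
    }
    rownames(grid) <- NULL
    grid$condition_id <- sprintf("%s|v%g|%s-%s|%g", grid$receptor,
                                 grid$valency, grid$igg_a, grid$igg_b,
                                 grid$frac_a)
    grid
}

#' Draw a ground-truth parameter set
#'
#' Samples a complete generating parameter set for synthetic studies:
#' affinities log-uniform over a configurable span bracketing the
#' documented human IgG--FcgR range, receptor expression log-uniform over
#' typical CHO transfectant levels, effective valencies lognormal about the
#' nominal 4 and 33, the crosslinking constant at its literature value,
#' per-receptor signal scales, observation noise, and effector cell-type
#' weights. Pure function of the seed.
#'
#' @param seed integer seed.
#' @param receptors,subclasses design labels.
#' @param affinityRange span of generating affinities, M^-1.
#' @param expressionRange span of receptor expression, sites/cell.
#' @param kxStar generating crosslinking constant, cell * M.
#' @param sigmaObs generating lognormal noise sd on binding readouts.
#' @param cellTypes labels of effector cell types for depletion studies.
#' @return Named list: \code{affinities} ([AffinityMatrix-class]),
#'   \code{receptorExpression}, \code{kxStar}, \code{f4}, \code{f33},
#'   \code{scale}, \code{sigmaObs}, \code{cellWeights}.
#' @export
sampleGroundTruth <- function(seed = 1L,
                              receptors = panelReceptors(),
                              subclasses = panelSubclasses(),
                              affinityRange = c(1e4, 1e8),
                              expressionRange = c(1e4, 1e6),
                              kxStar = 6.31e-13, sigmaObs = 0.1,
                              cellTypes = c("cMO", "ncMO", "Neu")) {
    if (any(affinityRange <= 0) || diff(affinityRange) < 0)
        stop("invalid affinity range")
    if (any(expressionRange <= 0) || diff(expressionRange) < 0)
        stop("invalid expression range")
    set.seed(as.integer(seed))
    nL <- length(subclasses); nR <- length(receptors)
    ka <- matrix(exp(stats::runif(nL * nR, log(affinityRange[1L]),
                                  log(affinityRange[2L]))), nL, nR,
                 dimnames = list(subclasses, receptors))
    expr <- exp(stats::runif(nR, log(expressionRange[1L]),
                             log(expressionRange[2L])))
    names(expr) <- receptors
    truth <- list(affinities = affinityMatrix(ka),
                  receptorExpression = expr,
                  kxStar = kxStar,
                  f4 = exp(stats::rnorm(1, log(4), 0.05)),
                  f33 = exp(stats::rnorm(1, log(33), 0.05)),
                  scale = stats::setNames(rep(1e-4, nR), receptors),
                  sigmaObs = sigmaObs)
    ## Cell-type weights are drawn on a scale matched to the effector
    ## activities the default profiles produce, so that noise-free
    ## depletions span a realistic, informative range (roughly 20-90%)
    ## instead of saturating the exponential link.
    nT <- length(cellTypes)
    u <- exp(stats::runif(nT, log(0.3), log(2)))
    act <- tryCatch({
        profiles <- defaultEffectorProfiles(receptors)[cellTypes]
        signs <- defaultReceptorSigns(receptors)
        X <- do.call(rbind, lapply(subclasses, function(s)
            activitiesForCondition(
                stats::setNames(as.numeric(subclasses == s), subclasses),
                profiles, truth$affinities, kxStar, signs)))
        colMeans(X)
    }, error = function(e) rep(1e4, nT))
    act[!is.finite(act) | act <= 0] <- mean(act[is.finite(act) & act > 0],
                                            na.rm = TRUE)
    if (any(!is.finite(act))) act <- rep(1e4, nT)
    truth$cellWeights <- stats::setNames(u / (nT * act), cellTypes)
    truth
}

#' Simulate the replicated binding panel
#'
#' Forward-simulates relative fluorescence for every design condition and
#' replicate: the multivalent model's bound-complex count at the
#' condition's composition and effective valency, scaled per receptor, with
#' multiplicative lognormal noise, then (optionally) normalized so each
#' replicate has mean 1 -- the same normalization applied to real panels.
#'
#' @param truth ground truth from [sampleGroundTruth()].
#' @param design condition grid from [factorialDesign()].
#' @param replicates number of replicates per condition.
#' @param seed integer seed.
#' @param L0 complex concentration of the assay, M.
#' @param normalize apply [normalizeReplicate()] to the simulated panel.
#' @return Measurement data.frame (columns \code{receptor}, \code{valency},
#'   \code{igg_a}, \code{igg_b}, \code{frac_a}, \code{replicate},
#'   \code{rfu}) with attribute \code{"scaleEffective"}: the per-receptor
#'   scale after replicate normalization (the generating scale divided by
#'   the noise-free replicate mean).
#' @export
simulateBindingPanel <- function(truth, design = factorialDesign(),
                                 replicates = 3L, seed = 1L, L0 = 1e-9,
                                 normalize = TRUE) {
    set.seed(as.integer(seed))
    ka <- truth$affinities@.Data
    lig <- rownames(ka)
    ai <- match(design$igg_a, lig); bi <- match(design$igg_b, lig)
    ri <- match(design$receptor, colnames(ka))
    if (anyNA(ai) || anyNA(bi) || anyNA(ri))
        stop("design labels not covered by the ground truth (condition ",
             design$condition_id[which(is.na(ai * bi * ri))[1L]], ")")
    A <- design$frac_a * ka[cbind(ai, ri)] +
        (1 - design$frac_a) * ka[cbind(bi, ri)]
    f <- ifelse(design$valency == 33, truth$f33, truth$f4)
    lb <- .lboundSingleReceptor(truth$receptorExpression[ri], A, L0, f,
                                truth$kxStar)
    signal <- truth$scale[ri] * lb
    out <- design[rep(seq_len(nrow(design)), times = replicates),
                  c("receptor", "valency", "igg_a", "igg_b", "frac_a"),
                  drop = FALSE]
    out$replicate <- rep(seq_len(replicates), each = nrow(design))
    eps <- stats::rnorm(nrow(out))
    out$rfu <- rep(signal, times = replicates) * exp(truth$sigmaObs * eps)
    rownames(out) <- NULL
    scaleEff <- truth$scale
    if (normalize) {
        out <- normalizeReplicate(out)
        scaleEff <- truth$scale / mean(signal)
    }
    attr(out, "scaleEffective") <- scaleEff
    out
}

#' Reference effector-cell receptor profiles (synthetic)
#'
#' Plausible per-cell-type Fc-gamma-receptor abundances (sites/cell,
#' geometric-mean scale) for classical monocytes, nonclassical monocytes
#' and neutrophils. These are synthetic stand-in values chosen to reflect
#' the qualitative expression patterns of human blood effector cells
#' (monocytes express FcgRI/IIA/IIB, nonclassical monocytes are
#' FcgRIIIA-high, neutrophils are dominated by FcgRIIA), not measured data.
#'
#' @param receptors receptor labels (order defines the profile columns).
#' @return Named list of [CellSurface-class] objects.
#' @export
defaultEffectorProfiles <- function(receptors = panelReceptors()) {
    base <- list(
        cMO = c("FcgRI" = 1e4, "FcgRIIA-131H" = 1e5, "FcgRIIA-131R" = 1e5,
                "FcgRIIB-232I" = 1e4, "FcgRIIIA-158F" = 3e3,
                "FcgRIIIA-158V" = 3e3),
        ncMO = c("FcgRI" = 3e3, "FcgRIIA-131H" = 5e4, "FcgRIIA-131R" = 5e4,
                 "FcgRIIB-232I" = 8e3, "FcgRIIIA-158F" = 8e4,
                 "FcgRIIIA-158V" = 8e4),
        Neu = c("FcgRI" = 1e3, "FcgRIIA-131H" = 2e5, "FcgRIIA-131R" = 2e5,
                "FcgRIIB-232I" = 2e3, "FcgRIIIA-158F" = 1e4,
                "FcgRIIIA-158V" = 1e4))
    lapply(base, function(v) cellSurface(v[receptors]))
}

#' Default receptor activation signs
#'
#' +1 for every activating receptor, -1 for the inhibitory FcgRIIB.
#'
#' @param receptors receptor labels.
#' @return Named numeric vector of +1/-1.
#' @export
defaultReceptorSigns <- function(receptors = panelReceptors()) {
    stats::setNames(ifelse(grepl("^FcgRIIB", receptors), -1, 1), receptors)
}

#' Simulate an in vivo depletion study
#'
#' Generates observed depletion fractions for a set of antibody treatment
#' conditions: per condition, effector activities from the binding model at
#' the in vivo defaults (1 nM, valency 4), the exponential-CDF link with
#' the ground-truth cell-type weights, plus truncated-Normal noise clamped
#' to \eqn{[0, 1]}.
#'
#' @param truth ground truth from [sampleGroundTruth()].
#' @param profiles named list of effector profiles
#'   ([defaultEffectorProfiles()]).
#' @param conditions named list of composition vectors, one per treatment
#'   condition (defaults to each pure IgG subclass).
#' @param micePerCondition animals per condition.
#' @param noiseSd additive noise sd on the depletion fraction.
#' @param seed integer seed.
#' @param signs receptor signs ([defaultReceptorSigns()]).
#' @return List with \code{data} (columns \code{condition}, \code{donor},
#'   \code{replicate}, \code{depletion_fraction}), \code{activities}
#'   (condition x cell-type matrix) and \code{expected} (noise-free
#'   predictions).
#' @export
simulateDepletionStudy <- function(truth,
                                   profiles = defaultEffectorProfiles(
                                       receptorIds(truth$affinities)),
                                   conditions = NULL,
                                   micePerCondition = 6L, noiseSd = 0.05,
                                   seed = 1L,
                                   signs = defaultReceptorSigns(
                                       receptorIds(truth$affinities))) {
    lig <- ligandIds(truth$affinities)
    if (is.null(conditions)) {
        conditions <- lapply(lig, function(s)
            stats::setNames(as.numeric(lig == s), lig))
        names(conditions) <- lig
    }
    X <- do.call(rbind, lapply(conditions, function(comp)
        activitiesForCondition(comp, profiles, truth$affinities,
                               truth$kxStar, signs)))
    rownames(X) <- names(conditions)
    colnames(X) <- names(profiles)
    w <- truth$cellWeights[colnames(X)]
    expected <- 1 - exp(-as.vector(X %*% w))
    names(expected) <- rownames(X)
    set.seed(as.integer(seed))
    data <- data.frame(
        condition = rep(names(conditions), each = micePerCondition),
        donor = rep(seq_len(micePerCondition), times = length(conditions)),
        replicate = 1L)
    data$depletion_fraction <- pmin(pmax(
        rep(expected, each = micePerCondition) +
            stats::rnorm(nrow(data), 0, noiseSd), 0), 1)
    list(data = data, activities = X, expected = expected)
}
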