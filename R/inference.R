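#' @include AllClasses.R binding-model.R priors.R mcmc.R
NULL

## Parameter layout for the binding fit. All parameters are positive and
## sampled on the log scale; the vector is ordered: affinity block
## (column-major over ligands x receptors), receptor abundances, f4, f33,
## Kx*, per-receptor signal scales, observation noise.
.panelLayout <- function(priors) {
    lig <- rownames(priors@affinityMu)
    rec <- colnames(priors@affinityMu)
    kaNames <- as.vector(outer(lig, rec, function(i, j)
        sprintf("Ka[%s,%s]", i, j)))
    nms <- c(kaNames, sprintf("Rtot[%s]", rec), "f4", "f33", "KxStar",
             sprintf("scale[%s]", rec), "sigmaObs")
    nKa <- length(kaNames); nR <- length(rec)
    list(ligands = lig, receptors = rec, names = nms,
         idxKa = seq_len(nKa),
         idxRtot = nKa + seq_len(nR),
         idxF4 = nKa + nR + 1L, idxF33 = nKa + nR + 2L,
         idxKx = nKa + nR + 3L,
         idxScale = nKa + nR + 3L + seq_len(nR),
         idxNoise = nKa + 2L * nR + 4L)
}

.priorVectors <- function(priors, layout) {
    mu <- c(as.vector(priors@affinityMu), priors@receptorMu,
            priors@f4@mu, priors@f33@mu, priors@kx@mu,
            priors@scaleMu, priors@noise@mu)
    sd <- c(as.vector(priors@affinitySigma), priors@receptorSigma,
            priors@f4@sigma, priors@f33@sigma, priors@kx@sigma,
            priors@scaleSigma, priors@noise@sigma)
    names(mu) <- names(sd) <- layout$names
    list(mu = mu, sd = sd)
}

.panelColumns <- c("receptor", "valency", "igg_a", "igg_b", "frac_a",
                   "replicate", "rfu")

## Index a measurement table against the layout and floor zero readouts at
## 1e-3 x the smallest positive value (lognormal likelihood support).
.prepPanel <- function(data, layout) {
    missingCols <- setdiff(setdiff(.panelColumns, "rfu"), names(data))
    if (length(missingCols))
        stop("measurement table lacks column(s): ",
             paste(missingCols, collapse = ", "))
    if (nrow(data) == 0L)
        return(list(n = 0L))
    b <- ifelse(is.na(data$igg_b) | data$igg_b == "", data$igg_a, data$igg_b)
    ai <- match(data$igg_a, layout$ligands)
    bi <- match(b, layout$ligands)
    ri <- match(data$receptor, layout$receptors)
    if (anyNA(ai) || anyNA(bi))
        stop("unknown IgG species in measurement table: ",
             paste(unique(c(data$igg_a, b)[is.na(c(ai, bi))]), collapse = ", "))
    if (anyNA(ri))
        stop("unknown receptor in measurement table: ",
             paste(unique(data$receptor[is.na(ri)]), collapse = ", "))
    if (!all(data$valency %in% c(4, 33)))
        stop("valency class must be 4 or 33")
    if (any(data$frac_a < 0 | data$frac_a > 1))
        stop("frac_a must lie in [0, 1]")
    rfu <- data$rfu
    if (!is.null(rfu)) {
        if (any(rfu < 0)) stop("rfu must be >= 0")
        if (any(rfu == 0)) {
            pos <- rfu[rfu > 0]
            if (!length(pos)) stop("all rfu values are zero")
            rfu[rfu == 0] <- min(pos) * 1e-3
        }
    }
    list(n = nrow(data), ai = ai, bi = bi, ri = ri,
         is33 = data$valency == 33, fracA = data$frac_a, rfu = rfu)
}

.predictPrep <- function(theta, prep, layout, L0) {
    nL <- length(layout$ligands); nR <- length(layout$receptors)
    Ka <- matrix(exp(theta[layout$idxKa]), nL, nR)
    Rtot <- exp(theta[layout$idxRtot])
    f4 <- exp(theta[[layout$idxF4]]); f33 <- exp(theta[[layout$idxF33]])
    kx <- exp(theta[[layout$idxKx]])
    scale <- exp(theta[layout$idxScale])
    A <- prep$fracA * Ka[cbind(prep$ai, prep$ri)] +
        (1 - prep$fracA) * Ka[cbind(prep$bi, prep$ri)]
    f <- ifelse(prep$is33, f33, f4)
    lb <- .lboundSingleReceptor(Rtot[prep$ri], A, L0, f, kx)
    scale[prep$ri] * lb
}

#' Log-posterior of the binding model
#'
#' Joint log-density of the Bayesian binding fit, parameterized on the log
#' scale: independent Normal priors on the log parameters (equivalently,
#' lognormal priors on the natural scale) plus a lognormal observation
#' likelihood, \eqn{\log rfu \sim N(\log \hat{rfu}, \sigma_{obs})}. Returns
#' \code{-Inf} (never an error) outside the support so samplers can reject.
#'
#' @param params named numeric vector of positive parameter values, in the
#'   layout produced by the fit functions (see [fitMap()]).
#' @param data measurement table (columns \code{receptor}, \code{valency},
#'   \code{igg_a}, \code{igg_b}, \code{frac_a}, \code{replicate},
#'   \code{rfu}); may have zero rows for a prior-only density.
#' @param priors a [PriorSet-class].
#' @param L0 total complex concentration of the assay, M.
#' @return Scalar log-density.
#' @export
bindingLogPosterior <- function(params, data, priors, L0 = 1e-9) {
    layout <- .panelLayout(priors)
    if (any(params <= 0) || any(!is.finite(params))) return(-Inf)
    theta <- log(params[layout$names])
    if (anyNA(theta)) stop("params must carry the fit layout names")
    prep <- .prepPanel(data, layout)
    pv <- .priorVectors(priors, layout)
    .thetaLogPost(theta, prep, layout, pv, L0)
}

.thetaLogPost <- function(theta, prep, layout, pv, L0, freeIdx = NULL) {
    if (any(!is.finite(theta))) return(-Inf)
    idx <- if (is.null(freeIdx)) seq_along(theta) else freeIdx
    lp <- sum(stats::dnorm(theta[idx], pv$mu[idx], pv$sd[idx], log = TRUE))
    if (prep$n > 0L) {
        pred <- .predictPrep(theta, prep, layout, L0)
        if (any(!is.finite(pred)) || any(pred <= 0)) return(-Inf)
        sig <- exp(theta[[layout$idxNoise]])
        lp <- lp + sum(stats::dnorm(log(prep$rfu), log(pred), sig, log = TRUE))
    }
    if (!is.finite(lp)) return(-Inf)
    lp
}

#' Predict binding readouts for a set of conditions
#'
#' Runs the multivalent binding model forward for each row of a measurement
#' table: solves the single-receptor equilibrium at the condition's mixture
#' composition and effective valency, and maps bound complexes to relative
#' fluorescence through the per-receptor scale factor.
#'
#' @param params named positive parameter vector in the fit layout (e.g.
#'   from [mapEstimate()] or posterior medians).
#' @param data measurement table; the \code{rfu} column is ignored and may
#'   be absent.
#' @param priors a [PriorSet-class] defining the ligand/receptor layout.
#' @param L0 total complex concentration, M.
#' @return Numeric vector of predicted RFU, one per row of \code{data}.
#' @export
predictMeasurement <- function(params, data, priors, L0 = 1e-9) {
    layout <- .panelLayout(priors)
    theta <- log(params[layout$names])
    if (anyNA(theta)) stop("params must carry the fit layout names")
    if (nrow(data) == 0L) return(numeric(0))
    prep <- .prepPanel(data[, setdiff(names(data), "rfu")], layout)
    .predictPrep(theta, prep, layout, L0)
}

.filterFitRecords <- function(data, useMixtures) {
    if (useMixtures || nrow(data) == 0L) return(data)
    data[data$frac_a %in% c(0, 1), , drop = FALSE]
}

.fixedTheta <- function(layout, pv, fixedAffinities) {
    theta <- pv$mu
    free <- seq_along(theta)
    if (!is.null(fixedAffinities)) {
        stopifnot(is(fixedAffinities, "AffinityMatrix"))
        ka <- fixedAffinities@.Data[layout$ligands, layout$receptors,
                                    drop = FALSE]
        if (any(ka <= 0))
            stop("fixed affinities must be > 0 (use the prior floor for ",
                 "documented non-binding pairs)")
        theta[layout$idxKa] <- log(as.vector(ka))
        free <- setdiff(free, layout$idxKa)
    }
    list(theta = theta, free = free)
}

#' Maximum a posteriori fit of the binding model
#'
#' Maximizes the log-posterior over the log-parameter scale with L-BFGS-B,
#' started from the prior locations. By default only single-composition
#' (pure IgG) records are fitted; mixture records are held out for
#' validation.
#'
#' @param data measurement table (see [bindingLogPosterior()]).
#' @param priors a [PriorSet-class].
#' @param seed integer; the optimizer is deterministic, the seed is recorded
#'   for provenance.
#' @param fixedAffinities optional [AffinityMatrix-class]; when given, the
#'   affinity block is held at these values and excluded from optimization.
#' @param useMixtures logical; include mixture-composition records in the
#'   fit (default \code{FALSE}).
#' @param L0 assay complex concentration, M.
#' @param maxit optimizer iteration cap.
#' @return List with \code{estimate} (named natural-scale parameter
#'   vector), \code{logPosterior}, \code{convergence} (0 = converged), and
#'   \code{counts}.
#' @export
fitMap <- function(data, priors, seed = 1L, fixedAffinities = NULL,
                   useMixtures = FALSE, L0 = 1e-9, maxit = 1000L) {
    layout <- .panelLayout(priors)
    pv <- .priorVectors(priors, layout)
    fit <- .filterFitRecords(data, useMixtures)
    prep <- .prepPanel(fit, layout)
    fx <- .fixedTheta(layout, pv, fixedAffinities)
    theta <- fx$theta
    iNoise <- layout$idxNoise
    free <- setdiff(fx$free, iNoise)
    ## Block-coordinate ascent: L-BFGS-B over all parameters with the
    ## observation noise held fixed (a smooth, well-scaled subproblem even
    ## for noise-free data), alternated with an exact 1-d update of
    ## log sigma_obs given the residual sum of squares. Noise-free panels
    ## drive sigma_obs into the prior's lower tail; the subproblem stays
    ## conditioned because sigma enters it as a constant weight.
    muN <- pv$mu[iNoise]; sdN <- pv$sd[iNoise]
    residSS <- function(th) {
        pred <- .predictPrep(th, prep, layout, L0)
        if (any(!is.finite(pred)) || any(pred <= 0)) return(Inf)
        sum((log(prep$rfu) - log(pred))^2)
    }
    updateNoise <- function(ss) {
        if (!is.finite(ss)) return(muN)
        n <- prep$n
        f1d <- function(ls)
            -n * ls - ss / (2 * exp(2 * ls)) +
                stats::dnorm(ls, muN, sdN, log = TRUE)
        lower <- muN - (n + 5) * sdN^2 - 6 * sdN
        upper <- max(muN + 12 * sdN, 0.5 * log(ss / n + 1e-300) + 3)
        stats::optimize(f1d, c(lower, upper), maximum = TRUE,
                        tol = 1e-10)$maximum
    }
    set.seed(as.integer(seed))
    opt <- NULL
    if (prep$n == 0L || length(free) == 0L) {
        opt <- list(convergence = 0L, counts = c(0L, 0L))
        if (prep$n > 0L) theta[iNoise] <- updateNoise(residSS(theta))
    } else {
        for (round in seq_len(12L)) {
            ## working-noise floor: keeps the weighted least-squares
            ## subproblem conditioned once noise-free data have driven
            ## sigma_obs into the prior tail
            sig2 <- max(exp(2 * theta[[iNoise]]), 1e-12)
            obj <- function(thFree) {
                th <- theta; th[free] <- thFree
                ss <- residSS(th)
                if (!is.finite(ss)) return(1e10)
                ss / (2 * sig2) -
                    sum(stats::dnorm(th[free], pv$mu[free], pv$sd[free],
                                     log = TRUE))
            }
            opt <- stats::optim(theta[free], obj, method = "L-BFGS-B",
                                control = list(maxit = maxit, factr = 1e3))
            ## 52 = line-search breakdown at the resolution limit; the
            ## best-so-far point is still returned and later rounds polish it
            if (!opt$convergence %in% c(0L, 1L, 52L))
                stop("MAP optimization failed (code ", opt$convergence,
                     "): ", opt$message)
            theta[free] <- opt$par
            newNoise <- updateNoise(residSS(theta))
            done <- abs(newNoise - theta[[iNoise]]) < 1e-3
            theta[iNoise] <- newNoise
            if (done) break
        }
    }
    list(estimate = stats::setNames(exp(theta), layout$names),
         logPosterior = .thetaLogPost(theta, prep, layout, pv, L0,
                                      freeIdx = fx$free),
         convergence = opt$convergence, counts = opt$counts)
}

#' Posterior sampling for the binding model
#'
#' Samples the binding-fit posterior with a MAP-initialized adaptive
#' Metropolis sampler on the log-parameter scale. Chains are independent
#' and seeded deterministically from \code{config$seed}; identical
#' configuration reproduces the draws exactly. Per-parameter bulk effective
#' sample size and split-Rhat are attached; a low acceptance rate is
#' recorded in the configuration, not fatal.
#'
#' @param data measurement table (see [bindingLogPosterior()]).
#' @param priors a [PriorSet-class].
#' @param config list with elements \code{chains}, \code{warmup},
#'   \code{draws}, \code{seed}.
#' @param fixedAffinities optional [AffinityMatrix-class] to hold the
#'   affinity block constant (it still appears in the draws, flagged with
#'   \code{NA} diagnostics).
#' @param useMixtures logical; include mixture records in the likelihood.
#' @param L0 assay complex concentration, M.
#' @return A [PosteriorSamples-class]; draws are on the natural (positive)
#'   scale.
#' @export
runMcmc <- function(data, priors,
                    config = list(chains = 4L, warmup = 1000L,
                                  draws = 1000L, seed = 1L),
                    fixedAffinities = NULL, useMixtures = FALSE, L0 = 1e-9) {
    config <- utils::modifyList(
        list(chains = 4L, warmup = 1000L, draws = 1000L, seed = 1L), config)
    layout <- .panelLayout(priors)
    pv <- .priorVectors(priors, layout)
    fit <- .filterFitRecords(data, useMixtures)
    prep <- .prepPanel(fit, layout)
    fx <- .fixedTheta(layout, pv, fixedAffinities)
    map <- fitMap(data, priors, seed = config$seed,
                  fixedAffinities = fixedAffinities,
                  useMixtures = useMixtures, L0 = L0)
    thetaMap <- log(map$estimate)
    theta <- fx$theta; theta[fx$free] <- thetaMap[fx$free]
    lp <- function(thFree) {
        th <- theta; th[fx$free] <- thFree
        .thetaLogPost(th, prep, layout, pv, L0, freeIdx = fx$free)
    }
    am <- .adaptiveMetropolis(lp, theta[fx$free], chains = config$chains,
                              warmup = config$warmup, draws = config$draws,
                              seed = config$seed)
    full <- array(rep(theta, each = config$draws * config$chains),
                  c(config$draws, config$chains, length(theta)),
                  dimnames = list(NULL, NULL, layout$names))
    full[, , fx$free] <- am$draws
    diag <- .mcmcDiagnostics(exp(full))
    diag$rhat[-fx$free] <- NA_real_
    diag$ess[-fx$free] <- NA_real_
    new("PosteriorSamples", draws = exp(full),
        map = map$estimate,
        diagnostics = diag,
        config = c(config, list(acceptance = am$acceptance,
                                fixedAffinities = !is.null(fixedAffinities))))
}

#' Posterior sampling with the affinity block held fixed
#'
#' Convenience wrapper around [runMcmc()] that fits every nuisance
#' parameter (receptor abundances, effective valencies, crosslinking
#' constant, signal scales, noise) while holding the affinity matrix at the
#' supplied values -- the "all parameters but affinities" workflow.
#'
#' @inheritParams runMcmc
#' @param affinitiesFixed an [AffinityMatrix-class] of affinities to hold
#'   constant.
#' @return A [PosteriorSamples-class].
#' @export
fixedAffinityFit <- function(data, priors, affinitiesFixed,
                             config = list(chains = 4L, warmup = 1000L,
                                           draws = 1000L, seed = 1L),
                             useMixtures = FALSE, L0 = 1e-9) {
    runMcmc(data, priors, config = config, fixedAffinities = affinitiesFixed,
            useMixtures = useMixtures, L0 = L0)
}

#' Summarize posterior draws
#'
#' @param ps a [PosteriorSamples-class].
#' @param probs quantiles to report (median and quartiles by default).
#' @return data.frame with one row per parameter: posterior quantiles,
#'   effective sample size, and split-Rhat.
#' @export
posteriorSummary <- function(ps, probs = c(0.25, 0.5, 0.75)) {
    stopifnot(is(ps, "PosteriorSamples"))
    pars <- dimnames(ps@draws)[[3L]]
    qs <- t(vapply(pars, function(p)
        stats::quantile(ps@draws[, , p], probs = probs, names = FALSE),
        numeric(length(probs))))
    out <- data.frame(parameter = pars,
                      median = qs[, match(0.5, probs)],
                      row.names = NULL)
    out$q25 <- if (0.25 %in% probs) qs[, match(0.25, probs)] else NA_real_
    out$q75 <- if (0.75 %in% probs) qs[, match(0.75, probs)] else NA_real_
    merge(out, ps@diagnostics, by = "parameter", sort = FALSE)
}
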