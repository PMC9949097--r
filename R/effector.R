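#' @include AllClasses.R binding-model.R mcmc.R
NULL

#' Effector-cell activity from multimerized receptors
#'
#' Combines per-receptor multimerized-receptor predictions into one
#' activity scalar per cell type: the signed sum
#' \eqn{x = \max(\sum_i p_i R_{multi,i}, 0)} where each receptor sign
#' \eqn{p_i} is +1 (activating) or -1 (inhibitory; FcgRIIB). Negative net
#' activity is clipped to zero.
#'
#' @param Rmulti numeric vector of multimerized receptors per cell.
#' @param signs numeric vector of the same length, entries in \{+1, -1\}.
#' @return Nonnegative activity scalar.
#' @examples
#' cellActivity(c(5, 10), c(1, -1))  # inhibition dominates -> 0
#' @export
cellActivity <- function(Rmulti, signs) {
    if (length(Rmulti) != length(signs))
        stop("Rmulti and signs must align")
    if (!all(signs %in% c(-1, 1)))
        stop("receptor signs must be +1 or -1")
    max(sum(signs * Rmulti), 0)
}

#' Depletion from weighted effector activities
#'
#' Maps the weighted sum of effector-cell activities to a bounded depletion
#' fraction through the exponential-CDF link
#' \eqn{\hat{y} = 1 - \exp(-\sum_n w_n x_n)}, so that predicted depletion
#' saturates at 1 (one cannot deplete more than 100\% of target cells).
#'
#' @param activities nonnegative per-cell-type activity vector.
#' @param weights nonnegative per-cell-type weights (units: inverse
#'   activity).
#' @return Predicted depletion fraction in \eqn{[0, 1)}.
#' @examples
#' predictDepletion(log(2), 1)  # analytic half-depletion point: 0.5
#' @export
predictDepletion <- function(activities, weights) {
    if (length(activities) != length(weights))
        stop("activities and weights must align")
    if (any(activities < 0)) stop("activities must be >= 0")
    if (any(weights < 0)) stop("weights must be >= 0")
    1 - exp(-sum(weights * activities))
}

#' Per-cell-type activities for an antibody condition
#'
#' For each effector-cell profile, solves the multivalent binding model at
#' the in vivo defaults (complex concentration 1 nM, effective valency 4),
#' extracts the multimerized receptor pool, and applies the receptor signs.
#'
#' @param composition named numeric vector of IgG monomer proportions
#'   (summing to 1) describing the treatment condition.
#' @param profiles named list of [CellSurface-class] objects (or named
#'   numeric vectors), one per effector cell type; receptor order must
#'   match the affinity columns.
#' @param affinities an [AffinityMatrix-class].
#' @param kxStar crosslinking constant, cell * M.
#' @param signs named numeric vector of +1/-1 receptor signs, aligned with
#'   the receptors.
#' @param L0 complex concentration, M (default 1e-9).
#' @param f effective valency (default 4).
#' @return Named numeric vector of activities, one per cell type.
#' @export
activitiesForCondition <- function(composition, profiles, affinities, kxStar,
                                   signs, L0 = 1e-9, f = 4) {
    spec <- complexSpec(L0, f, composition)
    rec <- receptorIds(affinities)
    if (!all(rec %in% names(signs)))
        stop("signs must cover every receptor: missing ",
             paste(setdiff(rec, names(signs)), collapse = ", "))
    vapply(profiles, function(pr) {
        surf <- if (is(pr, "CellSurface")) pr else cellSurface(pr)
        st <- solveEquilibrium(spec, surf, affinities, kxStar)
        cellActivity(multimerizedReceptors(macroscopic(st)), signs[rec])
    }, 0)
}

## Truncated-Normal([0,1]) log-likelihood of observed depletion fractions.
.depletionLogLik <- function(y, yhat, s) {
    z <- stats::pnorm(1, yhat, s) - stats::pnorm(0, yhat, s)
    if (any(z <= 0)) return(-Inf)
    sum(stats::dnorm(y, yhat, s, log = TRUE) - log(z))
}

.depletionLogPost <- function(theta, X, y, priorMu, priorSd) {
    if (any(!is.finite(theta))) return(-Inf)
    w <- exp(theta[-length(theta)])
    s <- exp(theta[[length(theta)]])
    lp <- sum(stats::dnorm(theta, priorMu, priorSd, log = TRUE))
    yhat <- 1 - exp(-as.vector(X %*% w))
    ll <- .depletionLogLik(y, yhat, s)
    out <- lp + ll
    if (!is.finite(out)) return(-Inf)
    out
}

#' Clamp observed depletion fractions to [0, 1]
#'
#' Observed values below 0 (a biological increase in target cells) or above
#' 1 cannot be emitted by the exponential link; they are clamped to the
#' boundary with a warning.
#'
#' @param y numeric vector of observed depletion fractions.
#' @return Clamped vector in \eqn{[0, 1]}.
#' @export
clampDepletion <- function(y) {
    bad <- sum(y < 0 | y > 1)
    if (bad > 0)
        warning(bad, " observed depletion value(s) outside [0, 1] clamped ",
                "to the boundary")
    pmin(pmax(y, 0), 1)
}

#' Fit cell-type weights to observed depletion
#'
#' Bayesian regression of observed target-cell depletion on model-predicted
#' effector activities: lognormal priors on the nonnegative cell-type
#' weights, truncated-Normal observation noise on the depletion fraction,
#' MAP initialization followed by adaptive-Metropolis sampling. The default
#' weight prior is weakly informative and scale-matched to the activities
#' (prior median set so that typical total activity maps to ~50\%
#' depletion, log-sd 3).
#'
#' @param data data.frame with columns \code{condition}, \code{donor},
#'   \code{replicate} (optional), \code{depletion_fraction}.
#' @param activityMatrix numeric matrix, conditions x cell types, of
#'   effector activities (rownames = condition ids), e.g. built with
#'   [activitiesForCondition()] per condition.
#' @param config list with \code{chains}, \code{warmup}, \code{draws},
#'   \code{seed}.
#' @param weightPrior optional list with numeric vectors \code{mu},
#'   \code{sigma} (log scale) per cell type; computed from the activity
#'   scale when omitted.
#' @param noisePrior a [LognormalPrior-class] on the observation sd.
#' @return A [PosteriorSamples-class] over \code{w[cellType]} and
#'   \code{sigmaDep}.
#' @export
fitDepletion <- function(data, activityMatrix,
                         config = list(chains = 4L, warmup = 1000L,
                                       draws = 1000L, seed = 1L),
                         weightPrior = NULL,
                         noisePrior = lognormalPrior(log(0.1), 1)) {
    config <- utils::modifyList(
        list(chains = 4L, warmup = 1000L, draws = 1000L, seed = 1L), config)
    need <- c("condition", "depletion_fraction")
    if (!all(need %in% names(data)))
        stop("depletion table lacks column(s): ",
             paste(setdiff(need, names(data)), collapse = ", "))
    if (is.null(rownames(activityMatrix)))
        stop("activityMatrix requires condition rownames")
    ci <- match(data$condition, rownames(activityMatrix))
    if (anyNA(ci))
        stop("conditions missing from activityMatrix: ",
             paste(unique(data$condition[is.na(ci)]), collapse = ", "))
    X <- activityMatrix[ci, , drop = FALSE]
    if (all(X == 0))
        stop("all effector activities are zero; weights are unidentifiable")
    y <- clampDepletion(data$depletion_fraction)
    nW <- ncol(activityMatrix)
    types <- colnames(activityMatrix)
    if (is.null(types)) types <- paste0("cellType", seq_len(nW))
    if (is.null(weightPrior)) {
        meanAct <- mean(X[X > 0])
        weightPrior <- list(mu = rep(log(log(2) / (nW * meanAct)), nW),
                            sigma = rep(3, nW))
    }
    priorMu <- c(weightPrior$mu, noisePrior@mu)
    priorSd <- c(weightPrior$sigma, noisePrior@sigma)
    obj <- function(th) -.depletionLogPost(th, X, y, priorMu, priorSd)
    set.seed(as.integer(config$seed))
    opt <- stats::optim(priorMu, obj, method = "L-BFGS-B",
                        control = list(maxit = 1000L, factr = 1e4))
    am <- .adaptiveMetropolis(
        function(th) .depletionLogPost(th, X, y, priorMu, priorSd),
        stats::setNames(opt$par, c(sprintf("w[%s]", types), "sigmaDep")),
        chains = config$chains, warmup = config$warmup,
        draws = config$draws, seed = config$seed)
    draws <- exp(am$draws)
    new("PosteriorSamples", draws = draws,
        map = stats::setNames(exp(opt$par), dimnames(am$draws)[[3L]]),
        diagnostics = .mcmcDiagnostics(draws),
        config = c(config, list(acceptance = am$acceptance)))
}
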