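#' @include AllClasses.R
NULL

#' Lognormal prior from mode and interquartile range
#'
#' Finds the lognormal \eqn{(\mu, \sigma)} whose analytic mode equals
#' \code{mode} and whose interquartile range equals \code{iqr}. Documented
#' affinities enter the model this way: the documented value is taken as the
#' prior mode and its standard error as the prior IQR. Substituting
#' \eqn{\mu = \log(mode) + \sigma^2} reduces the problem to one monotone
#' equation in \eqn{\sigma},
#' \eqn{IQR = mode \cdot e^{\sigma^2} \cdot 2\sinh(z_{0.75}\sigma)},
#' solved by bisection/Newton to 1e-10 relative accuracy.
#'
#' @param mode prior mode, > 0.
#' @param iqr prior interquartile range, > 0.
#' @return A [LognormalPrior-class].
#' @examples
#' p <- lognormalFromModeIqr(exp(-1), 2 * exp(1) * sinh(qnorm(0.75)))
#' c(p@mu, p@sigma)  # ~ (0, 1)
#' @export
lognormalFromModeIqr <- function(mode, iqr) {
    if (length(mode) != 1L || !is.finite(mode) || mode <= 0)
        stop("mode must be a single finite value > 0")
    if (length(iqr) != 1L || !is.finite(iqr) || iqr <= 0)
        stop("iqr must be a single finite value > 0")
    z <- stats::qnorm(0.75)
    ## f(sigma) strictly increasing from 0, so a positive root always exists
    fn <- function(s) mode * exp(s^2) * 2 * sinh(z * s) - iqr
    upper <- 1
    while (fn(upper) < 0) {
        upper <- upper * 2
        if (upper > 1e4) stop("no positive-sigma solution for the given mode/iqr")
    }
    sigma <- stats::uniroot(fn, c(0, upper), tol = 1e-15)$root
    ## Newton polish for relative accuracy near machine precision
    for (i in 1:5) {
        g <- fn(sigma)
        dg <- mode * exp(sigma^2) *
            (4 * sigma * sinh(z * sigma) + 2 * z * cosh(z * sigma))
        sigma <- sigma - g / dg
    }
    if (!is.finite(sigma) || sigma <= 0)
        stop("no positive-sigma solution for the given mode/iqr")
    lognormalPrior(mu = log(mode) + sigma^2, sigma = sigma)
}

#' Analytic mode and IQR of a lognormal prior
#'
#' @param prior a [LognormalPrior-class].
#' @return Named numeric vector with elements \code{mode} and \code{iqr}.
#' @export
lognormalModeIqr <- function(prior) {
    stopifnot(is(prior, "LognormalPrior"))
    z <- stats::qnorm(0.75)
    c(mode = exp(prior@mu - prior@sigma^2),
      iqr = exp(prior@mu + z * prior@sigma) - exp(prior@mu - z * prior@sigma))
}

#' Affinity priors from documented values and standard errors
#'
#' Builds the lognormal affinity prior block: per ligand-receptor pair the
#' prior mode is the documented association constant and the prior IQR its
#' standard error, with floors applied to handle documented non-binding
#' pairs -- the mode is clipped up to 1e4 M^-1 and the IQR up to 1e5 M^-1.
#' A documented value of zero (or below the floor) therefore receives the
#' floor prior.
#'
#' @param documented an [AffinityMatrix-class] of documented affinities,
#'   M^-1 (zero = documented non-binding).
#' @param standardErrors numeric matrix of the same shape, M^-1.
#' @param modeFloor,iqrFloor clip floors, M^-1.
#' @return List with matrices \code{mu} and \code{sigma} (log scale),
#'   dimnames matching \code{documented}.
#' @export
buildAffinityPriors <- function(documented, standardErrors,
                                modeFloor = 1e4, iqrFloor = 1e5) {
    stopifnot(is(documented, "AffinityMatrix"))
    se <- as.matrix(standardErrors)
    if (!identical(dim(se), dim(documented@.Data)))
        stop("standard-error matrix shape does not match the affinity matrix")
    if (any(!is.finite(se)) || any(se < 0))
        stop("standard errors must be finite and >= 0")
    mu <- sigma <- documented@.Data * 0
    for (i in seq_len(nrow(mu))) {
        for (j in seq_len(ncol(mu))) {
            p <- lognormalFromModeIqr(max(documented@.Data[i, j], modeFloor),
                                      max(se[i, j], iqrFloor))
            mu[i, j] <- p@mu
            sigma[i, j] <- p@sigma
        }
    }
    list(mu = mu, sigma = sigma)
}

#' Receptor-abundance priors by lognormal maximum likelihood
#'
#' Fits a lognormal to replicated receptor-expression measurements
#' (sites/cell) per receptor by maximum likelihood: \eqn{\mu} is the mean of
#' the log measurements and \eqn{\sigma} their population (divisor n)
#' standard deviation. When replicates are identical the MLE spread is zero;
#' a configurable floor keeps the prior proper.
#'
#' @param measurements named list, one numeric vector of positive
#'   measurements (length >= 2) per receptor.
#' @param sigmaFloor lower bound applied to the fitted spread.
#' @return List with numeric vectors \code{mu} and \code{sigma}, named by
#'   receptor.
#' @examples
#' buildReceptorPriors(list(FcgRI = c(1e5, 2e5, 4e5)))
#' @export
buildReceptorPriors <- function(measurements, sigmaFloor = 0.1) {
    stopifnot(is.list(measurements), length(measurements) >= 1L)
    mu <- sigma <- numeric(length(measurements))
    for (k in seq_along(measurements)) {
        x <- measurements[[k]]
        if (length(x) < 2L)
            stop("receptor '", names(measurements)[k],
                 "': at least 2 measurements are required")
        if (any(!is.finite(x)) || any(x <= 0))
            stop("receptor '", names(measurements)[k],
                 "': measurements must be finite and > 0")
        lx <- log(x)
        mu[k] <- mean(lx)
        sigma[k] <- max(sqrt(mean((lx - mu[k])^2)), sigmaFloor)
    }
    names(mu) <- names(sigma) <- names(measurements)
    list(mu = mu, sigma = sigma)
}

#' Default valency and crosslinking hyperpriors
#'
#' The effective valencies of the nominal 4- and 33-valent complex classes
#' and the crosslinking constant carry lognormal hyperpriors
#' \eqn{f_4 \sim logN(\log 4, 0.2)}, \eqn{f_{33} \sim logN(\log 33, 0.2)}
#' and \eqn{K_x^* \sim logN(\log 6.31\times 10^{-13}, 2)}.
#'
#' @return Named list of [LognormalPrior-class] objects \code{f4},
#'   \code{f33}, \code{kx}.
#' @export
defaultHyperpriors <- function() {
    list(f4 = lognormalPrior(log(4), 0.2),
         f33 = lognormalPrior(log(33), 0.2),
         kx = lognormalPrior(log(6.31e-13), 2.0))
}

#' Assemble the full prior set for a binding fit
#'
#' Combines the affinity block, receptor-abundance priors, valency and
#' crosslinking hyperpriors, weakly-informative per-receptor signal-scale
#' priors, and the observation-noise prior into one [PriorSet-class].
#' The signal scale maps per-cell bound-complex counts to normalized
#' relative fluorescence units and is not identified by the data alone;
#' its prior is broad (sigma = 2) and centered so that typical panels map
#' near unit signal.
#'
#' @param affinityPriors result of [buildAffinityPriors()].
#' @param receptorPriors result of [buildReceptorPriors()] (receptor order
#'   must match the affinity columns).
#' @param hyper result of [defaultHyperpriors()].
#' @param scaleMu,scaleSigma log-scale location/spread of the per-receptor
#'   scale priors (scalars, recycled over receptors).
#' @param noise a [LognormalPrior-class] for the lognormal observation
#'   noise sigma.
#' @return A [PriorSet-class].
#' @export
priorSet <- function(affinityPriors, receptorPriors,
                     hyper = defaultHyperpriors(),
                     scaleMu = log(1e-4), scaleSigma = 2,
                     noise = lognormalPrior(log(0.1), 1)) {
    nR <- ncol(affinityPriors$mu)
    if (length(receptorPriors$mu) != nR)
        stop("receptor priors (", length(receptorPriors$mu),
             ") do not match the affinity receptor axis (", nR, ")")
    new("PriorSet",
        affinityMu = affinityPriors$mu, affinitySigma = affinityPriors$sigma,
        receptorMu = receptorPriors$mu, receptorSigma = receptorPriors$sigma,
        f4 = hyper$f4, f33 = hyper$f33, kx = hyper$kx,
        scaleMu = rep_len(scaleMu, nR), scaleSigma = rep_len(scaleSigma, nR),
        noise = noise)
}
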