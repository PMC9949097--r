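#' @include AllClasses.R
NULL

## Split-Rhat (Gelman-Rubin on half-chains). x: iterations x chains, one
## parameter. Returns NA for (near-)constant draws.
.splitRhat <- function(x) {
    n <- nrow(x)
    if (n < 4L) return(NA_real_)
    half <- floor(n / 2)
    sub <- cbind(x[seq_len(half), , drop = FALSE],
                 x[(n - half + 1):n, , drop = FALSE])
    if (stats::sd(as.vector(sub)) < 1e-12) return(NA_real_)
    m <- ncol(sub); len <- nrow(sub)
    means <- colMeans(sub)
    vars <- apply(sub, 2L, stats::var)
    B <- len * stats::var(means)
    W <- mean(vars)
    if (W < 1e-300) return(NA_real_)
    sqrt(((len - 1) / len * W + B / len) / W)
}

## Bulk ESS summed over chains via coda's spectral estimator.
.essByChain <- function(x) {
    if (stats::sd(as.vector(x)) < 1e-12) return(NA_real_)
    sum(vapply(seq_len(ncol(x)), function(ch)
        as.numeric(coda::effectiveSize(x[, ch])), 0))
}

## Adaptive-Metropolis sampler (Haario-style) on an unconstrained parameter
## vector. The proposal covariance is learned from the chain history during
## warmup (scaled 2.38^2/d, the optimal random-walk scaling) with a global
## step tuned toward ~23% acceptance; adaptation stops after warmup so the
## kept draws target the posterior exactly. Returns a draws x chains x d
## array plus per-chain acceptance rates.
.adaptiveMetropolis <- function(logPost, init, chains = 4L, warmup = 1000L,
                                draws = 1000L, seed = 1L, initJitter = 0.01) {
    d <- length(init)
    out <- array(NA_real_, c(draws, chains, d),
                 dimnames = list(NULL, NULL, names(init)))
    accept <- numeric(chains)
    for (ch in seq_len(chains)) {
        set.seed(as.integer((seed * 1000L + ch) %% .Machine$integer.max))
        cur <- init + stats::rnorm(d, 0, initJitter)
        lpCur <- logPost(cur)
        if (!is.finite(lpCur)) { cur <- init; lpCur <- logPost(cur) }
        if (!is.finite(lpCur))
            stop("log-posterior is not finite at the initial point")
        cholProp <- diag(0.1 / sqrt(d), d)
        logStep <- 0
        history <- matrix(NA_real_, warmup, d)
        nAcc <- 0L
        total <- warmup + draws
        for (it in seq_len(total)) {
            prop <- cur + exp(logStep) * as.vector(stats::rnorm(d) %*% cholProp)
            lpProp <- logPost(prop)
            if (is.finite(lpProp) &&
                stats::runif(1) < exp(min(lpProp - lpCur, 0))) {
                cur <- prop; lpCur <- lpProp
                if (it > warmup) nAcc <- nAcc + 1L
                acc <- 1
            } else acc <- 0
            if (it <= warmup) {
                history[it, ] <- cur
                logStep <- logStep + (acc - 0.234) / sqrt(it)
                if (it >= 50L && it %% 50L == 0L) {
                    covEst <- stats::cov(history[max(1L, it - 999L):it, ,
                                                 drop = FALSE])
                    covEst <- covEst * (2.38^2 / d) + diag(1e-10, d)
                    ch2 <- tryCatch(chol(covEst), error = function(e) NULL)
                    if (!is.null(ch2)) { cholProp <- ch2; logStep <- 0 }
                }
            } else {
                out[it - warmup, ch, ] <- cur
            }
        }
        accept[ch] <- nAcc / draws
    }
    list(draws = out, acceptance = accept)
}

## Per-parameter diagnostics table for an iterations x chains x params
## array of positive draws; computed on the log scale so thresholds are
## scale-free.
.mcmcDiagnostics <- function(draws) {
    pars <- dimnames(draws)[[3L]]
    ld <- log(draws)
    data.frame(
        parameter = pars,
        ess = vapply(pars, function(p) .essByChain(ld[, , p]), 0),
        rhat = vapply(pars, function(p) .splitRhat(ld[, , p]), 0),
        row.names = NULL)
}
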