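#' @include AllClasses.R
NULL

#' Normalize binding readouts within each replicate
#'
#' Divides every readout by the arithmetic mean of all readouts in its
#' replicate, so each replicate has mean exactly 1. This removes
#' experiment-to-experiment intensity differences before any model fitting.
#'
#' @param data data.frame with columns \code{replicate} and \code{rfu}.
#' @return The same data.frame with \code{rfu} rescaled.
#' @examples
#' d <- data.frame(replicate = 1, rfu = c(2, 4, 6))
#' normalizeReplicate(d)$rfu  # 0.5 1.0 1.5
#' @export
normalizeReplicate <- function(data) {
    stopifnot(all(c("replicate", "rfu") %in% names(data)))
    means <- tapply(data$rfu, data$replicate, mean)
    if (any(!is.finite(means)) || any(means <= 0))
        stop("every replicate must have a positive finite mean")
    data$rfu <- data$rfu / as.numeric(means[as.character(data$replicate)])
    data
}

#' Normalize readouts to unit geometric mean per day
#'
#' Divides every (strictly positive) readout by the geometric mean of its
#' acquisition day, so each day's measurements have geometric mean 1.
#'
#' @param data data.frame with columns \code{day} and \code{rfu}.
#' @return The same data.frame with \code{rfu} rescaled.
#' @export
normalizeDayGeomean <- function(data) {
    stopifnot(all(c("day", "rfu") %in% names(data)))
    if (any(!is.finite(data$rfu)) || any(data$rfu <= 0))
        stop("geometric-mean normalization requires all values > 0")
    gm <- exp(tapply(log(data$rfu), data$day, mean))
    data$rfu <- data$rfu / as.numeric(gm[as.character(data$day)])
    data
}

#' PCA variance explained by a rank-k reconstruction
#'
#' Fraction of variance captured by the first \code{k} principal
#' components, evaluated through the Frobenius-norm reconstruction formula
#' \eqn{1 - \|X - \hat{X}_k\|_F^2 / \|X\|_F^2}. With \code{center = TRUE}
#' (default) the SVD is taken of the column-centered matrix and the column
#' means are re-added to the reconstruction before the formula is
#' evaluated (so \code{k = 0} returns the fraction captured by the means
#' alone); \code{center = FALSE} uses the plain truncated SVD of X.
#'
#' @param X numeric matrix (e.g. condition medians x receptors).
#' @param k number of components, \code{0 <= k <= min(dim(X))}.
#' @param center logical, column-mean centering convention.
#' @return Fraction in \eqn{[0, 1]}; equals 1 at full rank.
#' @examples
#' pcaVarianceExplained(diag(c(3, 4)), 1, center = FALSE)  # 0.64
#' @export
pcaVarianceExplained <- function(X, k, center = TRUE) {
    X <- as.matrix(X)
    if (any(!is.finite(X))) stop("X must be finite")
    if (k < 0 || k > min(dim(X)))
        stop("k must lie in [0, min(dim(X))]")
    mu <- if (center) colMeans(X) else numeric(ncol(X))
    Xc <- sweep(X, 2L, mu)
    if (k == 0) {
        Xhat <- matrix(mu, nrow(X), ncol(X), byrow = TRUE)
    } else {
        sv <- svd(Xc, nu = k, nv = k)
        Xhat <- sv$u %*% (diag(sv$d[seq_len(k)], k) %*% t(sv$v))
        Xhat <- sweep(Xhat, 2L, mu, `+`)
    }
    1 - sum((X - Xhat)^2) / sum(X^2)
}

#' Median and IQR summaries per experimental condition
#'
#' @param data data.frame with columns \code{receptor}, \code{valency},
#'   \code{igg_a}, \code{igg_b}, \code{frac_a}, \code{rfu}.
#' @return data.frame with one row per condition: the condition key plus
#'   \code{median_rfu} and \code{iqr_rfu} (linear-interpolation quantiles).
#' @export
conditionSummaries <- function(data) {
    key <- c("receptor", "valency", "igg_a", "igg_b", "frac_a")
    stopifnot(all(c(key, "rfu") %in% names(data)))
    agg <- stats::aggregate(
        data["rfu"], data[key],
        function(v) c(median = stats::median(v),
                      iqr = stats::IQR(v, type = 7)))
    out <- agg[key]
    out$median_rfu <- agg$rfu[, "median"]
    out$iqr_rfu <- agg$rfu[, "iqr"]
    out
}

#' Ratio of median binding between the two valency classes
#'
#' For every (receptor, IgG condition) key present at both valencies,
#' returns median(33-valent) / median(4-valent). Keys missing one valency
#' are skipped with a warning; ratios whose denominator is at or below
#' \code{floor} are flagged and carry \code{NA}.
#'
#' @param summaries output of [conditionSummaries()].
#' @param floor smallest trusted denominator.
#' @return data.frame with the condition key, \code{ratio}, and a logical
#'   \code{flagged} column.
#' @export
intervalencyRatio <- function(summaries, floor = 0) {
    key <- c("receptor", "igg_a", "igg_b", "frac_a")
    stopifnot(all(c(key, "valency", "median_rfu") %in% names(summaries)))
    lo <- summaries[summaries$valency == 4, c(key, "median_rfu")]
    hi <- summaries[summaries$valency == 33, c(key, "median_rfu")]
    m <- merge(hi, lo, by = key, suffixes = c("_33", "_4"))
    dropped <- (nrow(lo) + nrow(hi)) - 2L * nrow(m)
    if (dropped > 0)
        warning(dropped, " condition(s) lacked a valency counterpart and ",
                "were skipped")
    m$flagged <- m$median_rfu_4 <= floor
    m$ratio <- ifelse(m$flagged, NA_real_, m$median_rfu_33 / m$median_rfu_4)
    m[, c(key, "ratio", "flagged")]
}

#' Between-condition variance fraction (one-way ANOVA)
#'
#' Eta-squared of the one-way layout: the fraction of total sum of squares
#' explained by differences between experimental conditions,
#' \eqn{SS_{between}/SS_{total}}. Values near 1 indicate that replicate
#' scatter within conditions is small relative to biological differences
#' between conditions.
#'
#' @param values numeric readouts.
#' @param groups condition labels, same length.
#' @return Fraction in \eqn{[0, 1]}.
#' @examples
#' anovaConditionVariance(c(0, 2, 10, 12), c("a", "a", "b", "b"))
#' @export
anovaConditionVariance <- function(values, groups) {
    groups <- factor(groups)
    if (length(values) != length(groups))
        stop("values and groups must align")
    if (nlevels(groups) < 2L)
        stop("at least two conditions are required")
    if (max(table(groups)) < 2L)
        stop("at least one condition needs replicate measurements")
    if (stats::var(values) == 0) return(0)
    ss <- summary(stats::aov(values ~ groups))[[1L]][["Sum Sq"]]
    ss[1L] / sum(ss)
}
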