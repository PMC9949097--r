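#' @include AllClasses.R
NULL

#' Accessors for model objects
#'
#' Small accessor generics for the package's value classes: ligand and
#' receptor labels, solved free-receptor abundances, the engagement
#' propensity matrix, and the macroscopic binding outputs.
#'
#' @param x a model object.
#' @return The requested component (vector, matrix, or scalar).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ligandIds", function(x) standardGeneric("ligandIds"))

#' @rdname accessors
#' @export
setGeneric("receptorIds", function(x) standardGeneric("receptorIds"))

#' @rdname accessors
#' @export
setGeneric("freeReceptors", function(x) standardGeneric("freeReceptors"))

#' @rdname accessors
#' @export
setGeneric("phiMatrix", function(x) standardGeneric("phiMatrix"))

#' @rdname accessors
#' @export
setGeneric("boundReceptors", function(x) standardGeneric("boundReceptors"))

#' @rdname accessors
#' @export
setGeneric("boundComplexes", function(x) standardGeneric("boundComplexes"))

#' @rdname accessors
#' @export
setGeneric("multimerizedReceptors",
           function(x) standardGeneric("multimerizedReceptors"))

#' @rdname accessors
#' @export
setMethod("ligandIds", "AffinityMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("receptorIds", "AffinityMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("ligandIds", "ComplexSpec", function(x) names(x@composition))

#' @rdname accessors
#' @export
setMethod("receptorIds", "CellSurface", function(x) names(x))

#' @rdname accessors
#' @export
setMethod("freeReceptors", "EquilibriumState", function(x) x@Req)

#' @rdname accessors
#' @export
setMethod("phiMatrix", "EquilibriumState", function(x) x@phi)

#' @rdname accessors
#' @export
setMethod("boundReceptors", "MacroscopicQuantities", function(x) x@Rbound)

#' @rdname accessors
#' @export
setMethod("boundComplexes", "MacroscopicQuantities", function(x) x@Lbound)

#' @rdname accessors
#' @export
setMethod("multimerizedReceptors", "MacroscopicQuantities",
          function(x) x@Rmulti)

#' Posterior accessors
#'
#' @param x a [PosteriorSamples-class] object.
#' @param parameter optional character vector selecting parameters.
#' @return \code{posteriorDraws}: iterations x chains x parameters array
#'   (natural scale); \code{mapEstimate}: named numeric vector;
#'   \code{mcmcDiagnostics}: data.frame of per-parameter effective sample
#'   size and split-Rhat.
#' @name posterior-accessors
NULL

#' @rdname posterior-accessors
#' @export
setGeneric("posteriorDraws",
           function(x, parameter = NULL) standardGeneric("posteriorDraws"))

#' @rdname posterior-accessors
#' @export
setGeneric("mapEstimate", function(x) standardGeneric("mapEstimate"))

#' @rdname posterior-accessors
#' @export
setGeneric("mcmcDiagnostics", function(x) standardGeneric("mcmcDiagnostics"))

#' @rdname posterior-accessors
#' @export
setMethod("posteriorDraws", "PosteriorSamples", function(x, parameter = NULL) {
    if (is.null(parameter)) return(x@draws)
    missing <- setdiff(parameter, dimnames(x@draws)[[3L]])
    if (length(missing))
        stop("unknown parameter(s): ", paste(missing, collapse = ", "))
    x@draws[, , parameter, drop = FALSE]
})

#' @rdname posterior-accessors
#' @export
setMethod("mapEstimate", "PosteriorSamples", function(x) x@map)

#' @rdname posterior-accessors
#' @export
setMethod("mcmcDiagnostics", "PosteriorSamples", function(x) x@diagnostics)

setMethod("show", "AffinityMatrix", function(object) {
    cat(sprintf("AffinityMatrix: %d ligand(s) x %d receptor(s) [M^-1]\n",
                nrow(object), ncol(object)))
    print(object@.Data)
})

setMethod("show", "ComplexSpec", function(object) {
    cat(sprintf("ComplexSpec: L0 = %.3g M, f = %.3g\n",
                object@L0, object@f))
    cat("  composition:",
        paste(sprintf("%s=%.3g", names(object@composition),
                      object@composition), collapse = ", "), "\n")
})

setMethod("show", "EquilibriumState", function(object) {
    cat("EquilibriumState\n")
    cat("  free receptors/cell:",
        paste(sprintf("%s=%.4g", names(object@Req), object@Req),
              collapse = ", "), "\n")
    cat(sprintf("  phi: %d x %d (column 1 = composition)\n",
                nrow(object@phi), ncol(object@phi)))
})

setMethod("show", "MacroscopicQuantities", function(object) {
    cat("MacroscopicQuantities (per cell)\n")
    cat(sprintf("  Lbound: %.6g\n", object@Lbound))
    cat("  Rbound:",
        paste(sprintf("%s=%.4g", names(object@Rbound), object@Rbound),
              collapse = ", "), "\n")
    cat("  Rmulti:",
        paste(sprintf("%s=%.4g", names(object@Rmulti), object@Rmulti),
              collapse = ", "), "\n")
})

setMethod("show", "LognormalPrior", function(object) {
    cat(sprintf("LognormalPrior(mu = %.6g, sigma = %.6g); median = %.6g\n",
                object@mu, object@sigma, exp(object@mu)))
})

setMethod("show", "PriorSet", function(object) {
    cat(sprintf("PriorSet: %d x %d affinity priors, %d receptor priors\n",
                nrow(object@affinityMu), ncol(object@affinityMu),
                length(object@receptorMu)))
    cat(sprintf("  f4 median %.3g | f33 median %.3g | Kx* median %.3g\n",
                exp(object@f4@mu), exp(object@f33@mu), exp(object@kx@mu)))
})

setMethod("show", "PosteriorSamples", function(object) {
    d <- dim(object@draws)
    cat(sprintf("PosteriorSamples: %d draws x %d chain(s) x %d parameter(s)\n",
                d[1L], d[2L], d[3L]))
    if (nrow(object@diagnostics)) {
        cat(sprintf("  max split-Rhat %.3f | min bulk ESS %.0f\n",
                    max(object@diagnostics$rhat, na.rm = TRUE),
                    min(object@diagnostics$ess, na.rm = TRUE)))
    }
})
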