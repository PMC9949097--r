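#' @import methods
NULL

#' Monovalent Fc--Fc-gamma-receptor affinity matrix
#'
#' An \code{AffinityMatrix} holds monovalent association constants
#' \eqn{K_{a,ij}} (units \eqn{M^{-1}}) for each IgG (ligand) species \eqn{i}
#' crossed with each Fc-gamma receptor species \eqn{j}. It is an ordinary
#' numeric matrix with mandatory row names (ligand identifiers) and column
#' names (receptor identifiers); entries of zero encode documented
#' non-binding pairs.
#'
#' @slot .Data numeric matrix of association constants, M^-1.
#' @seealso [affinityMatrix()], [ligandIds()], [receptorIds()]
#' @export
setClass("AffinityMatrix", contains = "matrix")

setValidity("AffinityMatrix", function(object) {
    v <- object@.Data
    if (!is.numeric(v)) return("affinity values must be numeric")
    if (any(!is.finite(v))) return("affinity values must be finite")
    if (any(v < 0)) return("association constants must be >= 0")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("AffinityMatrix requires ligand row names and receptor column names")
    if (anyDuplicated(rownames(v))) return("duplicated ligand ids")
    if (anyDuplicated(colnames(v))) return("duplicated receptor ids")
    TRUE
})

#' Construct an AffinityMatrix
#'
#' @param values numeric matrix, ligands in rows, receptors in columns, M^-1.
#' @param ligandIds,receptorIds optional character vectors of labels; taken
#'   from \code{dimnames(values)} when omitted.
#' @return An [AffinityMatrix-class] object.
#' @examples
#' ka <- affinityMatrix(matrix(c(1e7, 0, 5e5, 2e6), 2, 2),
#'                      ligandIds = c("IgG1", "IgG2"),
#'                      receptorIds = c("FcgRI", "FcgRIIB"))
#' ligandIds(ka)
#' @export
affinityMatrix <- function(values, ligandIds = rownames(values),
                           receptorIds = colnames(values)) {
    values <- as.matrix(values)
    if (length(ligandIds) != nrow(values))
        stop("ligandIds length (", length(ligandIds),
             ") does not match ligand axis (", nrow(values), " rows)")
    if (length(receptorIds) != ncol(values))
        stop("receptorIds length (", length(receptorIds),
             ") does not match receptor axis (", ncol(values), " columns)")
    dimnames(values) <- list(as.character(ligandIds), as.character(receptorIds))
    new("AffinityMatrix", values)
}

#' Immune-complex population specification
#'
#' Describes one immune-complex (IC) population: the total complex
#' concentration \eqn{L_0} (molar), the effective valency \eqn{f} (number of
#' Fc sites per complex available to engage receptors; real-valued because
#' fitted effective valencies are continuous), and the monomer mixture
#' composition \eqn{C} (proportions of each IgG species among the monomers,
#' summing to one).
#'
#' @slot L0 total complex concentration, M.
#' @slot f effective valency, > 0.
#' @slot composition named numeric vector of monomer proportions.
#' @export
setClass("ComplexSpec",
    representation(L0 = "numeric", f = "numeric", composition = "numeric"))

setValidity("ComplexSpec", function(object) {
    if (length(object@L0) != 1L || !is.finite(object@L0) || object@L0 < 0)
        return("L0 must be a single finite value >= 0")
    if (length(object@f) != 1L || !is.finite(object@f) || object@f <= 0)
        return("f must be a single finite value > 0")
    C <- object@composition
    if (length(C) < 1L || any(!is.finite(C)) || any(C < 0))
        return("composition proportions must be finite and >= 0")
    if (abs(sum(C) - 1) > 1e-12)
        return(sprintf("composition must sum to 1 (got %.15g)", sum(C)))
    TRUE
})

#' Construct a ComplexSpec
#'
#' @param L0 total complex concentration, M.
#' @param f effective valency (> 0, real-valued).
#' @param composition numeric vector of monomer proportions, summing to 1.
#' @return A [ComplexSpec-class] object.
#' @examples
#' complexSpec(1e-9, 4, c(IgG1 = 0.9, IgG2 = 0.1))
#' @export
complexSpec <- function(L0, f, composition) {
    if (is.null(names(composition)))
        names(composition) <- paste0("L", seq_along(composition))
    new("ComplexSpec", L0 = as.numeric(L0), f = as.numeric(f),
        composition = composition)
}

#' Receptor complement of a cell surface
#'
#' Total receptor abundances \eqn{R_{tot,n}} (binding sites per cell) for
#' each modeled receptor species. Receptors with zero expression are carried
#' (not dropped) to keep index alignment across cell types.
#'
#' @export
setClass("CellSurface", contains = "numeric")

setValidity("CellSurface", function(object) {
    v <- object@.Data
    if (length(v) < 1L) return("at least one receptor is required")
    if (any(!is.finite(v)) || any(v < 0))
        return("receptor abundances must be finite and >= 0")
    if (is.null(names(object))) return("receptor names are required")
    TRUE
})

#' Construct a CellSurface
#'
#' @param rtot named numeric vector, receptors (binding sites) per cell.
#' @return A [CellSurface-class] object.
#' @examples
#' cellSurface(c(FcgRI = 1e5, FcgRIIB = 3e4))
#' @export
cellSurface <- function(rtot) {
    if (is.null(names(rtot))) names(rtot) <- paste0("R", seq_along(rtot))
    v <- as.numeric(rtot)
    names(v) <- names(rtot)
    new("CellSurface", v)
}

#' Solved equilibrium of one cell--complex system
#'
#' Holds the free-receptor abundances \eqn{R_{eq}} solved from conservation
#' of mass together with the dimensionless engagement-propensity matrix
#' \eqn{\phi} (ligands in rows; column \code{"unbound"} holds
#' \eqn{\phi_{i0} = C_i}, remaining columns hold
#' \eqn{\phi_{ij} = R_{eq,j} K_{a,ij} K_x^* C_i}).
#'
#' @slot Req named numeric, free receptors per cell at equilibrium.
#' @slot phi numeric matrix, ligands x (1 + receptors).
#' @slot spec the [ComplexSpec-class] solved against.
#' @slot surface the [CellSurface-class] solved against.
#' @slot kxStar crosslinking constant used, cell * M.
#' @export
setClass("EquilibriumState",
    representation(Req = "numeric", phi = "matrix", spec = "ComplexSpec",
                   surface = "CellSurface", kxStar = "numeric"))

setValidity("EquilibriumState", function(object) {
    rtot <- object@surface@.Data
    if (length(object@Req) != length(rtot))
        return("Req length does not match the receptor axis")
    if (any(object@Req < -1e-9) || any(object@Req > rtot * (1 + 1e-9) + 1e-9))
        return("Req must satisfy 0 <= Req <= Rtot")
    C <- object@spec@composition
    if (nrow(object@phi) != length(C) ||
        ncol(object@phi) != length(rtot) + 1L)
        return("phi must be n_ligands x (n_receptors + 1)")
    if (max(abs(object@phi[, 1L] - C)) > 1e-12)
        return("phi column 1 must equal the composition")
    TRUE
})

#' Macroscopic equilibrium binding quantities
#'
#' Per-cell outputs of the multivalent binding model: \code{Rbound} (bound
#' receptors of each species), \code{Lbound} (complexes bound through at
#' least one site), and \code{Rmulti} (receptors engaged inside complexes
#' bound through at least two sites -- the multimerized, signaling-relevant
#' pool).
#'
#' @export
setClass("MacroscopicQuantities",
    representation(Rbound = "numeric", Lbound = "numeric", Rmulti = "numeric"))

setValidity("MacroscopicQuantities", function(object) {
    if (length(object@Lbound) != 1L) return("Lbound must be scalar")
    if (length(object@Rbound) != length(object@Rmulti))
        return("Rbound and Rmulti must align")
    if (any(!is.finite(c(object@Rbound, object@Lbound, object@Rmulti))))
        return("macroscopic quantities must be finite")
    if (any(object@Rbound < -1e-12) || object@Lbound < -1e-12 ||
        any(object@Rmulti < -1e-12))
        return("macroscopic quantities must be >= 0")
    if (any(object@Rmulti > object@Rbound * (1 + 1e-9) + 1e-9))
        return("Rmulti cannot exceed Rbound")
    TRUE
})

#' Lognormal prior
#'
#' Location/scale of a lognormal prior on a positive parameter:
#' \eqn{\log X \sim N(\mu, \sigma)}.
#'
#' @slot mu log-scale location.
#' @slot sigma log-scale spread, > 0 (0 is rejected).
#' @export
setClass("LognormalPrior", representation(mu = "numeric", sigma = "numeric"))

setValidity("LognormalPrior", function(object) {
    if (length(object@mu) != 1L || !is.finite(object@mu))
        return("mu must be a single finite number")
    if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
        object@sigma <= 0)
        return("sigma must be a single finite number > 0")
    TRUE
})

#' Construct a LognormalPrior
#' @param mu log-scale location.
#' @param sigma log-scale spread (> 0).
#' @return A [LognormalPrior-class] object.
#' @export
lognormalPrior <- function(mu, sigma)
    new("LognormalPrior", mu = as.numeric(mu), sigma = as.numeric(sigma))

#' Complete prior specification for the binding fit
#'
#' Lognormal priors for every fitted parameter of the immune-complex binding
#' model: the affinity block (matrices of log-scale locations and spreads
#' aligned with an [AffinityMatrix-class]), per-receptor abundance priors,
#' effective-valency priors for the nominal 4- and 33-valent complex
#' classes, the crosslinking constant, per-receptor signal scaling factors,
#' and the observation noise.
#'
#' @export
setClass("PriorSet",
    representation(affinityMu = "matrix", affinitySigma = "matrix",
                   receptorMu = "numeric", receptorSigma = "numeric",
                   f4 = "LognormalPrior", f33 = "LognormalPrior",
                   kx = "LognormalPrior",
                   scaleMu = "numeric", scaleSigma = "numeric",
                   noise = "LognormalPrior"))

setValidity("PriorSet", function(object) {
    if (!identical(dim(object@affinityMu), dim(object@affinitySigma)))
        return("affinity mu/sigma shapes differ")
    if (any(object@affinitySigma <= 0)) return("affinity sigma must be > 0")
    if (length(object@receptorMu) != length(object@receptorSigma))
        return("receptor mu/sigma lengths differ")
    if (any(object@receptorSigma <= 0)) return("receptor sigma must be > 0")
    if (length(object@scaleMu) != length(object@scaleSigma))
        return("scale mu/sigma lengths differ")
    if (any(object@scaleSigma <= 0)) return("scale sigma must be > 0")
    TRUE
})

#' Posterior draws with diagnostics
#'
#' MCMC output: \code{draws} is an iterations x chains x parameters array of
#' samples on the natural (positive) scale; \code{diagnostics} holds
#' per-parameter bulk effective sample size and split-Rhat; \code{map} is
#' the maximum a posteriori point the chains were initialized from.
#'
#' @slot draws numeric array, iterations x chains x parameters.
#' @slot map named numeric MAP point estimate (natural scale).
#' @slot diagnostics data.frame with columns parameter, ess, rhat.
#' @slot config list of sampler settings (chains, warmup, draws, seed).
#' @export
setClass("PosteriorSamples",
    representation(draws = "array", map = "numeric",
                   diagnostics = "data.frame", config = "list"))

setValidity("PosteriorSamples", function(object) {
    d <- dim(object@draws)
    if (length(d) != 3L)
        return("draws must be iterations x chains x parameters")
    if (is.null(dimnames(object@draws)[[3L]]))
        return("parameter names are required on draws")
    TRUE
})
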