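#' @include AllClasses.R AllGenerics.R
NULL

## Engagement-propensity bookkeeping: phi is ligands x (1 + receptors); the
## first column ("unbound") holds the composition C_i, so sum(phi[,1]) == 1
## and the grand sum Phi = 1 + sum over bound cells.

#' Engagement propensity matrix
#'
#' Computes the dimensionless propensity matrix \eqn{\phi} of the
#' multivalent binding model: \eqn{\phi_{ij} = R_{eq,j} K_{a,ij} K_x^* C_i}
#' for receptor columns and \eqn{\phi_{i0} = C_i} for the unbound column.
#'
#' @param Req numeric vector of free receptors per cell (one per receptor).
#' @param spec a [ComplexSpec-class] (only the composition is used here).
#' @param affinities an [AffinityMatrix-class], ligands x receptors, M^-1.
#' @param kxStar crosslinking constant, cell * M (> 0).
#' @return numeric matrix, ligands x (1 + receptors); first column named
#'   \code{"unbound"}.
#' @examples
#' ka <- affinityMatrix(matrix(1e7, 1, 1, dimnames = list("IgG1", "FcgRI")))
#' computePhi(1e5, complexSpec(1e-9, 4, c(IgG1 = 1)), ka, 6.31e-13)
#' @export
computePhi <- function(Req, spec, affinities, kxStar) {
    C <- spec@composition
    if (nrow(affinities) != length(C))
        stop("ligand axis mismatch: affinity matrix has ", nrow(affinities),
             " ligand rows but composition has ", length(C), " species")
    if (length(Req) != ncol(affinities))
        stop("receptor axis mismatch: affinity matrix has ", ncol(affinities),
             " receptor columns but Req has length ", length(Req))
    if (any(!is.finite(Req)) || any(Req < 0))
        stop("Req entries must be finite and >= 0")
    if (length(kxStar) != 1L || !is.finite(kxStar) || kxStar <= 0)
        stop("kxStar must be a single finite value > 0")
    bound <- sweep(affinities@.Data, 2L, Req * kxStar, `*`) * C
    phi <- cbind(unbound = C, bound)
    rownames(phi) <- rownames(affinities)
    phi
}

## Closed-form macroscopic quantities from phi. With Phi the grand sum of
## phi (unbound column included; it contributes exactly 1):
##   Lbound    = L0/Kx* (Phi^f - 1)
##   Rbound_n  = L0 f/Kx* (sum_i phi_in) Phi^(f-1)
##   Rmulti_n  = L0 f/Kx* (sum_i phi_in) (Phi^(f-1) - 1)
.macroFromPhi <- function(phi, L0, kxStar, f) {
    if (length(f) != 1L || !is.finite(f) || f <= 0)
        stop("effective valency f must be a single finite value > 0")
    if (any(!is.finite(phi)))
        stop("phi contains non-finite entries")
    Phi <- sum(phi)
    S <- colSums(phi)[-1L, drop = FALSE]
    pre <- L0 / kxStar
    new("MacroscopicQuantities",
        Rbound = pre * f * S * Phi^(f - 1),
        Lbound = unname(pre * (Phi^f - 1)),
        Rmulti = pre * f * S * (Phi^(f - 1) - 1))
}

#' Macroscopic binding quantities at equilibrium
#'
#' Evaluates the closed-form per-cell outputs of the multivalent binding
#' model from a solved [EquilibriumState-class]: the number of complexes
#' bound through at least one site (\code{Lbound}), receptors of each
#' species engaged by any complex (\code{Rbound}), and receptors engaged
#' inside multiply-bound complexes (\code{Rmulti}). The effective valency
#' may be real-valued; the closed forms are smooth in \eqn{f}.
#'
#' @param state an [EquilibriumState-class], e.g. from [solveEquilibrium()].
#' @return A [MacroscopicQuantities-class] object (per-cell units).
#' @seealso [oracleMacroscopic()] for the exhaustive-enumeration cross-check
#'   at integer valency.
#' @export
macroscopic <- function(state) {
    stopifnot(is(state, "EquilibriumState"))
    .macroFromPhi(state@phi, state@spec@L0, state@kxStar, state@spec@f)
}

#' Solve the equilibrium free-receptor abundances
#'
#' Solves conservation of mass \eqn{R_{tot,n} = R_{eq,n} + R_{bound,n}} for
#' every receptor species simultaneously, by a damped Newton iteration in
#' \eqn{\log R_{eq}} (positivity is structural) started from the no-binding
#' state \eqn{R_{eq} = R_{tot}}. Receptors with zero expression are carried
#' with \eqn{R_{eq} = 0} to keep index alignment.
#'
#' @param spec a [ComplexSpec-class].
#' @param surface a [CellSurface-class] (receptor order must match the
#'   affinity columns).
#' @param affinities an [AffinityMatrix-class].
#' @param kxStar crosslinking constant, cell * M.
#' @param relTol relative residual tolerance on each conservation equation
#'   (absolute when \eqn{R_{tot,n} = 0}).
#' @param maxIter maximum Newton iterations.
#' @return An [EquilibriumState-class].
#' @examples
#' ka <- affinityMatrix(matrix(1e9, 1, 1, dimnames = list("IgG1", "FcgRI")))
#' st <- solveEquilibrium(complexSpec(1e-9, 1, c(IgG1 = 1)),
#'                        cellSurface(c(FcgRI = 1e5)), ka, 6.31e-13)
#' freeReceptors(st)  # Langmuir: Rtot / (1 + L0 * Ka) = 5e4
#' @export
solveEquilibrium <- function(spec, surface, affinities, kxStar,
                             relTol = 1e-9, maxIter = 100L) {
    stopifnot(is(spec, "ComplexSpec"), is(surface, "CellSurface"),
              is(affinities, "AffinityMatrix"))
    rtot <- stats::setNames(as.vector(surface@.Data), names(surface))
    if (length(rtot) != ncol(affinities))
        stop("receptor axis mismatch: surface has ", length(rtot),
             " receptors but affinity matrix has ", ncol(affinities),
             " receptor columns")
    C <- spec@composition
    if (length(C) != nrow(affinities))
        stop("ligand axis mismatch: composition has ", length(C),
             " species but affinity matrix has ", nrow(affinities),
             " ligand rows")
    L0 <- spec@L0; f <- spec@f
    A <- as.numeric(C %*% affinities@.Data)      # sum_i C_i Ka_in, per receptor

    Req <- rtot
    active <- rtot > 0 & A > 0 & L0 > 0
    if (any(active)) {
        ui <- which(active)
        ## Newton in u = log(Req) on the log-residual
        ## h_n = u_n + log(1 + L0 f A_n Phi^(f-1)) - log(Rtot_n),
        ## which is nearly linear in u even under extreme avidity; |h_n| is
        ## the relative conservation residual. Receptors couple only
        ## through the grand sum Phi, giving a diagonal-plus-rank-one
        ## Jacobian.
        u <- log(Req[ui])
        resid <- function(u) {
            R <- Req; R[ui] <- exp(u)
            s <- kxStar * R * A              # column sums of bound phi
            Phi <- 1 + sum(s)
            lt <- log(L0 * f * A[ui]) + (f - 1) * log(Phi)
            big <- lt > 30
            soft <- ifelse(big, lt, log1p(exp(pmin(lt, 30))))
            frac <- ifelse(big, 1,
                           exp(pmin(lt, 30)) / (1 + exp(pmin(lt, 30))))
            list(h = u + soft - log(rtot[ui]), R = R, Phi = Phi, s = s,
                 frac = frac)
        }
        st <- resid(u)
        for (it in seq_len(maxIter)) {
            if (anyNA(st$h))
                stop("equilibrium solver produced a non-finite residual")
            if (max(abs(st$h)) <= relTol) break
            J <- diag(1, nrow = length(ui)) +
                outer(st$frac * (f - 1), st$s[ui] / st$Phi)
            step <- tryCatch(solve(J, st$h),
                             error = function(e) st$h / diag(J))
            lambda <- 1
            repeat {
                st2 <- resid(u - lambda * step)
                if ((!anyNA(st2$h) && sum(st2$h^2) < sum(st$h^2)) ||
                    lambda < 1e-8) break
                lambda <- lambda / 2
            }
            u <- u - lambda * step; st <- st2
            if (it == maxIter && max(abs(st$h)) > relTol)
                stop(sprintf(paste0("equilibrium solver did not converge in ",
                                    "%d iterations (max relative residual ",
                                    "%.3g)"), maxIter, max(abs(st$h))))
        }
        Req[ui] <- st$R[ui]
    }
    Req[rtot == 0] <- 0
    phi <- computePhi(Req, spec, affinities, kxStar)
    new("EquilibriumState", Req = stats::setNames(Req, names(rtot)), phi = phi,
        spec = spec, surface = surface, kxStar = as.numeric(kxStar))
}

#' Enumerate multivalent binding configurations
#'
#' Lists every way a complex of integer valency \eqn{f} can distribute its
#' sites over the \eqn{N_L (N_R + 1)} ligand-receptor pairings (including
#' the unbound state of each ligand species): all weak compositions of
#' \eqn{f} into that many cells. Supports the exhaustive enumeration oracle;
#' instances above \code{1e6} configurations are rejected.
#'
#' @param f integer valency (> 0).
#' @param nLigands,nReceptors counts of ligand and receptor species.
#' @return Integer matrix with one configuration per row; columns are
#'   labelled \code{q[i,j]} with \code{j = 0} the unbound cell, in the order
#'   \code{q[1,0], q[1,1], ..., q[1,NR], q[2,0], ...}.
#' @examples
#' enumerateConfigurations(2, 1, 1)  # (2,0), (1,1), (0,2)
#' @export
enumerateConfigurations <- function(f, nLigands, nReceptors) {
    if (f != round(f) || f < 1) stop("f must be a positive integer")
    k <- nLigands * (nReceptors + 1L)
    count <- choose(f + k - 1, k - 1)
    if (count > 1e6)
        stop(sprintf(paste0("enumeration would produce %.3g configurations ",
                            "(> 1e6); use a smaller instance"), count))
    compose <- function(total, cells) {
        if (cells == 1L) return(matrix(total, 1L, 1L))
        do.call(rbind, lapply(0:total, function(q1)
            cbind(q1, compose(total - q1, cells - 1L))))
    }
    q <- compose(as.integer(f), as.integer(k))
    colnames(q) <- as.vector(t(outer(seq_len(nLigands), 0:nReceptors,
                                     function(i, j) sprintf("q[%d,%d]", i, j))))
    rownames(q) <- NULL
    q
}

#' Exhaustive-enumeration oracle for the macroscopic quantities
#'
#' Computes \code{Lbound}, \code{Rbound} and \code{Rmulti} by brute force:
#' the relative abundance of each binding configuration \eqn{q} is
#' \eqn{v_q = \binom{f}{q} (L_0/K_x^*) \prod \phi_{ij}^{q_{ij}}}
#' (multinomial coefficient over all cells), and the macroscopic quantities
#' are sums of \eqn{v_q} over the appropriate configuration sets. Defined
#' for integer valency only; it must agree with [macroscopic()] to
#' floating-point accuracy and is used as an independent cross-check of the
#' closed forms.
#'
#' @param phi propensity matrix as returned by [computePhi()] (ligands x
#'   (1 + receptors), first column unbound).
#' @param L0 total complex concentration, M.
#' @param kxStar crosslinking constant, cell * M.
#' @param f integer valency.
#' @return A [MacroscopicQuantities-class] object.
#' @export
oracleMacroscopic <- function(phi, L0, kxStar, f) {
    if (f != round(f) || f < 1) stop("oracle requires a positive integer f")
    nL <- nrow(phi); nR <- ncol(phi) - 1L
    q <- enumerateConfigurations(f, nL, nR)
    ## phi cells flattened in the same q[i,j] order (row-major over ligands)
    phiFlat <- as.vector(t(phi))
    logCoef <- lgamma(f + 1) - rowSums(lgamma(q + 1))
    logPhiTerm <- q %*% ifelse(phiFlat > 0, log(phiFlat), 0)
    zeroBase <- q %*% as.numeric(phiFlat == 0) > 0   # any q_ij > 0 with phi_ij = 0
    v <- exp(logCoef + as.numeric(logPhiTerm)) * (L0 / kxStar)
    v[zeroBase] <- 0
    unboundCols <- seq(1L, nL * (nR + 1L), by = nR + 1L)
    nBound <- f - rowSums(q[, unboundCols, drop = FALSE])
    recCount <- function(n) {  # total ligands bound to receptor n per config
        cols <- seq(n + 1L, by = nR + 1L, length.out = nL)
        rowSums(q[, cols, drop = FALSE])
    }
    Rbound <- vapply(seq_len(nR),
                     function(n) sum(recCount(n) * v * (nBound >= 1)), 0)
    Rmulti <- vapply(seq_len(nR),
                     function(n) sum(recCount(n) * v * (nBound >= 2)), 0)
    names(Rbound) <- names(Rmulti) <- colnames(phi)[-1L]
    new("MacroscopicQuantities",
        Rbound = Rbound, Lbound = sum(v[nBound >= 1]), Rmulti = Rmulti)
}

## Vectorized single-receptor equilibrium used on CHO-style binding panels,
## where each condition involves one receptor species. With
## A = sum_i C_i Ka_i the conservation equation is scalar and monotone:
##   Rtot = Req (1 + L0 f A Phi^(f-1)),  Phi = 1 + Kx* A Req.
## Newton from Req = Rtot decreases monotonically; all conditions iterate
## in lockstep. Returns Lbound per condition.
.lboundSingleReceptor <- function(Rtot, A, L0, f, kxStar,
                                  relTol = 1e-12, maxIter = 200L) {
    if (any(!is.finite(A)) || any(!is.finite(f)) || !all(is.finite(kxStar)) ||
        any(!is.finite(Rtot)))
        return(rep(NaN, length(Rtot)))
    n <- length(Rtot)
    out <- numeric(n)
    live <- Rtot > 0 & A > 0 & L0 > 0
    if (any(live)) {
        Rt <- Rtot[live]; Al <- rep_len(A, n)[live]
        fl <- rep_len(f, n)[live]
        ## Newton on h(u) = u + log(1 + L0 f A Phi^(f-1)) - log(Rtot),
        ## u = log(Req): h is close to linear in u even at extreme avidity
        ## (where occupancy ~ Phi^(f-1) ~ e^((f-1)u)), so convergence is
        ## fast and uniform; |h| is the relative conservation residual.
        u <- log(Rt)
        for (it in seq_len(maxIter)) {
            kaR <- kxStar * Al * exp(u)
            Phi <- 1 + kaR
            lt <- log(L0 * fl * Al) + (fl - 1) * log(Phi)
            big <- lt > 30
            soft <- ifelse(big, lt, log1p(exp(pmin(lt, 30))))
            h <- u + soft - log(Rt)
            if (anyNA(h)) return(rep(NaN, n))
            if (max(abs(h)) <= relTol) break
            frac <- ifelse(big, 1, exp(pmin(lt, 30)) / (1 + exp(pmin(lt, 30))))
            dh <- 1 + frac * (fl - 1) * kaR / Phi
            u <- u - h / dh
        }
        Phi <- 1 + kxStar * Al * exp(u)
        out[live] <- (L0 / kxStar) * expm1(pmin(fl * log(Phi), 690))
    }
    out
}
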