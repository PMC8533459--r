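## Combinatorial rule model of orcinol depside / depsidone assembly:
## starter choice, malonyl-CoA extensions, side-chain length, the ester
## bond joining the two orcinol rings, and the oxidative ether bond that
## turns a depside into a depsidone. Structural bookkeeping only - no
## stereochemistry, masses or kinetics.

#' RingSpec: one orcinol ring of a depside/depsidone
#'
#' @slot starterCarbons acyl starter length in carbons: 2 (acetyl-CoA),
#'   4, 6 or 8 (FAS-delivered acyl chains).
#' @slot malonylExtensions number of malonyl-CoA additions: 3 or 4.
#' @slot sideChainCarbons derived ring side-chain length:
#'   \code{starter + 2 * (extensions - 3) - 1}, always odd (1/3/5/7).
#' @slot betaKeto derived: a fourth extension leaves the starter's
#'   carbonyl oxygen as a beta-keto group on the side chain.
#' @exportClass RingSpec
setClass("RingSpec",
    representation(starterCarbons = "integer",
                   malonylExtensions = "integer",
                   sideChainCarbons = "integer",
                   betaKeto = "logical"))

setValidity("RingSpec", function(object) {
    if (!object@starterCarbons %in% c(2L, 4L, 6L, 8L))
        return("starterCarbons must be 2, 4, 6 or 8")
    if (!object@malonylExtensions %in% c(3L, 4L))
        return("malonylExtensions must be 3 or 4")
    want <- object@starterCarbons + 2L * (object@malonylExtensions - 3L) - 1L
    if (object@sideChainCarbons != want)
        return("sideChainCarbons inconsistent with starter and extensions")
    if (object@betaKeto != (object@malonylExtensions == 4L))
        return("betaKeto inconsistent with malonylExtensions")
    TRUE
})

#' CompoundSpec: a depside or depsidone assembled from two orcinol rings
#'
#' The ester bond (A-ring carboxyl to the B ring's 4' OH) is constitutive
#' for the compound class; the additional ether bond (A-ring C2 OH to the
#' B ring's 5' carbon) is what makes a depsidone.
#'
#' @slot ringA,ringB [RingSpec-class] objects.
#' @slot etherBond logical; \code{TRUE} iff the compound is a depsidone.
#' @exportClass CompoundSpec
setClass("CompoundSpec",
    representation(ringA = "RingSpec", ringB = "RingSpec",
                   etherBond = "logical"))

setMethod("show", "RingSpec", function(object) {
    cat(sprintf(
        "RingSpec: C%d starter, %d extensions -> C%d side chain%s\n",
        object@starterCarbons, object@malonylExtensions,
        object@sideChainCarbons,
        if (object@betaKeto) " (beta-keto)" else ""))
})

setMethod("show", "CompoundSpec", function(object) {
    cat(sprintf("CompoundSpec: %s; side chains C%d / C%d\n",
                compoundClass(object),
                object@ringA@sideChainCarbons,
                object@ringB@sideChainCarbons))
})

#' Build one orcinol ring
#'
#' @param starterCarbons 2 (acetyl-CoA) or 4/6/8 (acyl starters).
#' @param malonylExtensions 3 or 4 malonyl-CoA additions.
#' @return a [RingSpec-class] with derived side-chain length and
#'   beta-keto flag.
#' @examples
#' buildRing(6, 3)   # C5 side chain (olivetoric acid B ring)
#' buildRing(6, 4)   # C7 side chain with beta-keto (A ring)
#' @export
buildRing <- function(starterCarbons, malonylExtensions) {
    s <- as.integer(starterCarbons); m <- as.integer(malonylExtensions)
    if (!s %in% c(2L, 4L, 6L, 8L))
        lbgcError("schemeError", "starterCarbons must be 2, 4, 6 or 8")
    if (!m %in% c(3L, 4L))
        lbgcError("schemeError", "malonylExtensions must be 3 or 4")
    new("RingSpec", starterCarbons = s, malonylExtensions = m,
        sideChainCarbons = s + 2L * (m - 3L) - 1L,
        betaKeto = m == 4L)
}

#' Assemble a depside from two rings
#'
#' The PKS cyclizes both polyketide chains, esterifies the A-ring
#' carboxyl with the B ring's 4' OH and releases the depside by
#' hydrolysis of the B-ring thioester. No ether bond is formed.
#'
#' @param ringA,ringB [RingSpec-class] objects (A is the ester-donor
#'   ring).
#' @return a [CompoundSpec-class] of class depside.
#' @examples
#' oliv <- assembleDepside(buildRing(6, 4), buildRing(6, 3))
#' compoundClass(oliv)   # "depside"
#' @export
assembleDepside <- function(ringA, ringB) {
    stopifnot(is(ringA, "RingSpec"), is(ringB, "RingSpec"))
    new("CompoundSpec", ringA = ringA, ringB = ringB, etherBond = FALSE)
}

#' Oxidative ether coupling: depside to depsidone
#'
#' A dedicated cytochrome P450 couples the A ring's C2 OH to the B
#' ring's 5' carbon. Ring specifications are preserved exactly; only the
#' ether bond is added.
#'
#' @param compound a [CompoundSpec-class] of class depside.
#' @return the corresponding depsidone [CompoundSpec-class].
#' @examples
#' phys <- depsidonize(assembleDepside(buildRing(6, 4), buildRing(6, 3)))
#' compoundClass(phys)   # "depsidone"
#' @export
depsidonize <- function(compound) {
    stopifnot(is(compound, "CompoundSpec"))
    if (compound@etherBond)
        lbgcError("schemeError", "compound is already a depsidone")
    new("CompoundSpec", ringA = compound@ringA, ringB = compound@ringB,
        etherBond = TRUE)
}

#' Compound class of a CompoundSpec
#'
#' @param compound a [CompoundSpec-class].
#' @return \code{"depside"} or \code{"depsidone"} (depsidone iff the
#'   ether bond is present).
#' @export
compoundClass <- function(compound) {
    stopifnot(is(compound, "CompoundSpec"))
    if (compound@etherBond) "depsidone" else "depside"
}

#' Starter provenance of each ring
#'
#' The default setting of orcinol depside PKSs is to accept free
#' acetyl-CoA as starter but not free longer acyl-CoAs; longer starters
#' (C4/C6/C8) must be synthesized and handed over protein-to-protein by a
#' dedicated metabolite FAS (HexA/HexB). In a host without such a FAS
#' (e.g. yeast) rings requiring a long starter are unreachable and the
#' PKS falls back to its acetyl-CoA default - which is why a heterologous
#' host yields the C1-side-chain depside instead of the native compound.
#'
#' @param compound a [CompoundSpec-class].
#' @param fasAvailable is a dedicated metabolite FAS present?
#' @return a \code{data.frame} with one row per ring: \code{ring},
#'   \code{starter_carbons}, \code{source} (\code{"acetyl-CoA-default"}
#'   or \code{"FAS-delivered"}) and \code{reachable} (\code{FALSE} marks
#'   an unreachable-in-host ring).
#' @examples
#' oliv <- assembleDepside(buildRing(6, 4), buildRing(6, 3))
#' starterSource(oliv, fasAvailable = FALSE)   # both rings unreachable
#' @export
starterSource <- function(compound, fasAvailable) {
    stopifnot(is(compound, "CompoundSpec"), is.logical(fasAvailable))
    one <- function(ring, label) {
        if (ring@starterCarbons == 2L)
            data.frame(ring = label, starter_carbons = 2L,
                       source = "acetyl-CoA-default", reachable = TRUE,
                       stringsAsFactors = FALSE)
        else
            data.frame(ring = label,
                       starter_carbons = ring@starterCarbons,
                       source = if (fasAvailable) "FAS-delivered"
                                else "acetyl-CoA-default",
                       reachable = fasAvailable,
                       stringsAsFactors = FALSE)
    }
    rbind(one(compound@ringA, "A"), one(compound@ringB, "B"))
}

## serializable form for reports
compoundToList <- function(compound) {
    ring <- function(r) list(starter_carbons = r@starterCarbons,
                             malonyl_extensions = r@malonylExtensions,
                             side_chain_carbons = r@sideChainCarbons,
                             beta_keto = r@betaKeto)
    list(class = compoundClass(compound),
         ether_bond = compound@etherBond,
         ring_a = ring(compound@ringA), ring_b = ring(compound@ringB))
}
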