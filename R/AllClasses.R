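#' @import methods
NULL

#' Parsed molecular topology of one structural form
#'
#' Container for the hydrogen-centred view of a metabolite structure that all
#' feature counting operates on: the atom and bond lists (hydrogens explicit),
#' elemental composition, nominal mass, tetrahedral stereocentre count and --
#' once derived -- the proton equivalence classes and carbon symmetry orbits.
#'
#' @slot smiles the line notation the topology was parsed from.
#' @slot atoms data.frame with one row per atom: \code{element}, \code{charge},
#'   \code{isH}, \code{parent} (heavy-atom index for hydrogens, \code{NA}
#'   otherwise) and, after \code{\link{classifyExchangeable}},
#'   \code{exchangeable}.
#' @slot bonds data.frame with columns \code{a1}, \code{a2}, \code{order}.
#' @slot tokens internal tokenisation of the SMILES used by the substitution
#'   test (one row per atom token).
#' @slot nStereocenters number of perceived tetrahedral stereocentres.
#' @slot protonClasses data.frame of proton equivalence classes (filled by
#'   \code{\link{protonEquivalenceClasses}}).
#' @slot carbonOrbits list of integer vectors: carbon symmetry orbits.
#' @export
setClass("MolecularTopology",
    representation(
        smiles = "character",
        atoms = "data.frame",
        bonds = "data.frame",
        tokens = "data.frame",
        nStereocenters = "integer",
        protonClasses = "data.frame",
        carbonOrbits = "list"
    ),
    prototype(
        nStereocenters = NA_integer_,
        protonClasses = data.frame(),
        carbonOrbits = list()
    )
)

setValidity("MolecularTopology", function(object) {
    msg <- character()
    at <- object@atoms
    if (!all(c("element", "charge", "isH", "parent") %in% names(at)))
        msg <- c(msg, "atoms must have element/charge/isH/parent columns")
    bd <- object@bonds
    if (nrow(bd) && !all(c(bd$a1, bd$a2) %in% seq_len(nrow(at))))
        msg <- c(msg, "bond endpoints outside atom table")
    if (length(msg)) msg else TRUE
})

#' Counted spectroscopic features of one metabolite
#'
#' The seven counted identification-information features of a metabolite:
#' number of 1H chemical shifts, multiplicities, 2/3-bond H,H coupling
#' constants, the second-order flag, and the COSY, HSQC and HMBC cross-peak
#' counts.  \code{provenance} distinguishes theoretical counts derived from
#' the structure from counts tallied out of experimental data.
#'
#' @slot nShifts,nMultiplicities,nCouplings,nCosy,nHsqc,nHmbc non-negative
#'   integer feature counts.
#' @slot secondOrderFlag 0 or 1.
#' @slot provenance \code{"theoretical"} or \code{"observed"}.
#' @slot notes character vector of warning flags (e.g. for molecules without
#'   any non-exchanging proton).
#' @export
setClass("SpectralFeatureCounts",
    representation(
        nShifts = "integer",
        nMultiplicities = "integer",
        nCouplings = "integer",
        secondOrderFlag = "integer",
        nCosy = "integer",
        nHsqc = "integer",
        nHmbc = "integer",
        provenance = "character",
        notes = "character"
    ),
    prototype(notes = character())
)

setValidity("SpectralFeatureCounts", function(object) {
    msg <- character()
    cnt <- c(object@nShifts, object@nMultiplicities, object@nCouplings,
             object@nCosy, object@nHsqc, object@nHmbc)
    if (any(is.na(cnt)) || any(cnt < 0L))
        msg <- c(msg, "feature counts must be non-negative")
    if (!object@secondOrderFlag %in% c(0L, 1L))
        msg <- c(msg, "secondOrderFlag must be 0 or 1")
    if (!object@provenance %in% c("theoretical", "observed"))
        msg <- c(msg, "provenance must be 'theoretical' or 'observed'")
    if (identical(object@provenance, "theoretical")) {
        if (object@nCosy != object@nCouplings)
            msg <- c(msg, "theoretical COSY count must equal coupling count")
        if (object@nMultiplicities != object@nShifts)
            msg <- c(msg, "theoretical multiplicity count must equal shift count")
    }
    if (length(msg)) msg else TRUE
})

#' Cumulative identification bits at the four NMR evidence levels
#'
#' Bit totals for the four nested acquisition strategies: 1D 1H only; plus
#' COSY; plus HSQC; plus HMBC.  Totals are cumulative sums of the feature
#' counts and therefore non-decreasing across levels.
#'
#' @slot bits1d,bitsCosy,bitsHsqc,bitsHmbc integer bit totals.
#' @export
setClass("LevelBits",
    representation(bits1d = "integer", bitsCosy = "integer",
                   bitsHsqc = "integer", bitsHmbc = "integer"))

setValidity("LevelBits", function(object) {
    v <- c(object@bits1d, object@bitsCosy, object@bitsHsqc, object@bitsHmbc)
    if (any(is.na(v)) || any(v < 0L)) return("bit totals must be non-negative")
    if (is.unsorted(v)) return("bit totals must be non-decreasing across levels")
    TRUE
})

#' A metabolite of the study cohort
#'
#' One metabolite with its identifiers, compound class, one or more structural
#' forms (sugars carry both anomers), optional named fragments used for
#' coverage assessment, and an optional curated override of the algorithmic
#' theoretical feature counts.
#'
#' @slot id short stable identifier.
#' @slot commonName,iupacName,hmdbAccession,classLabel metadata strings.
#' @slot forms character vector of SMILES, one per structural form.
#' @slot fragmentAnnotations named list; each element is a character vector of
#'   assignment labels belonging to that molecular fragment.
#' @slot overrides \code{NULL} or a complete theoretical
#'   \linkS4class{SpectralFeatureCounts} replacing the algorithmic profile.
#' @export
setClass("MetaboliteRecord",
    representation(
        id = "character",
        commonName = "character",
        iupacName = "character",
        hmdbAccession = "character",
        classLabel = "character",
        forms = "character",
        fragmentAnnotations = "list",
        overrides = "ANY"
    ),
    prototype(fragmentAnnotations = list(), overrides = NULL)
)

setValidity("MetaboliteRecord", function(object) {
    msg <- character()
    if (!length(object@forms)) msg <- c(msg, "at least one structural form required")
    if (!is.null(object@overrides)) {
        if (!is(object@overrides, "SpectralFeatureCounts"))
            msg <- c(msg, "overrides must be a SpectralFeatureCounts")
    }
    if (length(msg)) msg else TRUE
})

#' Experimentally observed spectral features for one metabolite
#'
#' Peak-list level record of what was actually seen for a metabolite in the
#' spectra: shifts with assignment labels, read multiplicities, measured
#' coupling constants, COSY/HSQC/HMBC peak lists, and ancillary evidence items
#' (long-range or heteronuclear couplings and literature notes) that support
#' an identification without contributing counted bits.
#'
#' @slot metaboliteId id of the metabolite the observations belong to.
#' @slot shifts data.frame \code{ppm}, \code{assignment}.
#' @slot multiplicities data.frame \code{assignment}, \code{label}.
#' @slot couplings data.frame \code{assignment1}, \code{assignment2}, \code{hz}.
#' @slot cosyPeaks data.frame \code{assignment1}, \code{assignment2}.
#' @slot hsqcPeaks data.frame \code{ppmH}, \code{ppmC}, \code{assignment}.
#' @slot hmbcPeaks data.frame \code{ppmC}, \code{assignment}.
#' @slot evidence data.frame \code{kind}, \code{description}, \code{hz}.
#' @slot secondOrder observed second-order flag (0 or 1).
#' @slot provenance free-text provenance note (e.g. curated vs simulated).
#' @export
setClass("ObservedFeatureSet",
    representation(
        metaboliteId = "character",
        shifts = "data.frame",
        multiplicities = "data.frame",
        couplings = "data.frame",
        cosyPeaks = "data.frame",
        hsqcPeaks = "data.frame",
        hmbcPeaks = "data.frame",
        evidence = "data.frame",
        secondOrder = "integer",
        provenance = "character"
    ),
    prototype(secondOrder = 0L, provenance = "curated")
)

.evidenceKinds <- c("long_range_cosy", "long_range_coupling",
                    "heteronuclear_coupling", "literature_note")

setValidity("ObservedFeatureSet", function(object) {
    msg <- character()
    if (nrow(object@shifts) && !all(is.finite(object@shifts$ppm)))
        msg <- c(msg, "shift ppm values must be finite")
    if (nrow(object@couplings) && any(object@couplings$hz < 0))
        msg <- c(msg, "coupling constants must be >= 0 Hz")
    if (nrow(object@evidence) && !all(object@evidence$kind %in% .evidenceKinds))
        msg <- c(msg, paste("evidence kind must be one of:",
                            paste(.evidenceKinds, collapse = ", ")))
    cp <- object@cosyPeaks
    if (nrow(cp)) {
        key <- apply(cbind(pmin(cp$assignment1, cp$assignment2),
                           pmax(cp$assignment1, cp$assignment2)), 1L,
                     paste, collapse = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, "COSY peak pairs must be unique (unordered)")
    }
    if (length(msg)) msg else TRUE
})

#' Tolerances for matching observed values against reference data
#'
#' @slot dH 1H chemical shift tolerance in ppm (default 0.03).
#' @slot dC 13C chemical shift tolerance in ppm (default 0.5).
#' @slot dJ proton coupling tolerance in Hz (default 0.2).
#' @export
setClass("MatchTolerances",
    representation(dH = "numeric", dC = "numeric", dJ = "numeric"),
    prototype(dH = 0.03, dC = 0.5, dJ = 0.2))

setValidity("MatchTolerances", function(object) {
    if (any(c(object@dH, object@dC, object@dJ) <= 0))
        return("all tolerances must be positive") else TRUE
})

#' Retention model for the synthetic observation generator
#'
#' Per feature-family probabilities that a theoretically available
#' identification bit is actually retrieved from the spectra, together with
#' the seed making simulations reproducible.  The defaults are the
#' cohort-level observed/theoretical ratios of the study data.
#'
#' @slot pShift,pMultiplicity,pCosy,pHsqc,pHmbc retention probabilities in
#'   \eqn{[0, 1]}; couplings share the COSY family probability.
#' @slot seed integer seed.
#' @export
setClass("RetentionModel",
    representation(pShift = "numeric", pMultiplicity = "numeric",
                   pCosy = "numeric", pHsqc = "numeric", pHmbc = "numeric",
                   seed = "integer"),
    prototype(pShift = 0.68, pMultiplicity = 0.68, pCosy = 0.58,
              pHsqc = 0.52, pHmbc = 0.113, seed = 1L))

setValidity("RetentionModel", function(object) {
    p <- c(object@pShift, object@pMultiplicity, object@pCosy,
           object@pHsqc, object@pHmbc)
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        return("retention probabilities must lie in [0, 1]") else TRUE
})

#' Identification confidence call
#'
#' @slot label \code{"confidently_identified"} or \code{"putatively_annotated"}.
#' @slot reasons ordered character vector recording every rule firing that led
#'   to the call.
#' @export
setClass("ConfidenceCall",
    representation(label = "character", reasons = "character"))

setValidity("ConfidenceCall", function(object) {
    msg <- character()
    if (!object@label %in% c("confidently_identified", "putatively_annotated"))
        msg <- c(msg, "unknown confidence label")
    if (!length(object@reasons))
        msg <- c(msg, "reasons must be non-empty")
    if (length(msg)) msg else TRUE
})
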