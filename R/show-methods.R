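#' Compact display of nmrbits objects
#'
#' @param object the object to display.
#' @return invisibly \code{NULL}.
#' @rdname show-methods
#' @export
setMethod("show", "MolecularTopology", function(object) {
    el <- elementCounts(object)
    cat(sprintf("MolecularTopology: %s\n", object@smiles))
    cat(sprintf("  formula C%dH%dN%dO%dS%d  nominal mass %d Da  heavy atoms %d\n",
                el[["nC"]], el[["nH"]], el[["nN"]], el[["nO"]], el[["nS"]],
                nominalMass(object), heavyAtomCount(object)))
    cat(sprintf("  tetrahedral stereocentres: %d\n", object@nStereocenters))
    if (nrow(object@protonClasses)) {
        ne <- object@protonClasses[!object@protonClasses$exchangeable, ]
        cat(sprintf("  proton classes: %d (%d non-exchanging)\n",
                    nrow(object@protonClasses), nrow(ne)))
    }
    invisible(NULL)
})

#' @rdname show-methods
#' @export
setMethod("show", "SpectralFeatureCounts", function(object) {
    cat(sprintf(
        "SpectralFeatureCounts (%s): shifts %d, multiplicities %d, J %d, 2nd-order %d, COSY %d, HSQC %d, HMBC %d\n",
        object@provenance, object@nShifts, object@nMultiplicities,
        object@nCouplings, object@secondOrderFlag, object@nCosy,
        object@nHsqc, object@nHmbc))
    invisible(NULL)
})

#' @rdname show-methods
#' @export
setMethod("show", "LevelBits", function(object) {
    v <- bitsVector(object)
    cat("LevelBits:", paste(sprintf("%s=%d", names(v), v), collapse = "  "),
        "\n")
    invisible(NULL)
})

#' @rdname show-methods
#' @export
setMethod("show", "MetaboliteRecord", function(object) {
    cat(sprintf("MetaboliteRecord %s (%s)\n", object@id, object@commonName))
    cat(sprintf("  class: %s   HMDB: %s\n", object@classLabel,
                if (nzchar(object@hmdbAccession)) object@hmdbAccession
                else "-"))
    cat(sprintf("  forms: %s\n", paste(object@forms, collapse = " ; ")))
    if (!is.null(object@overrides)) cat("  curated override present\n")
    invisible(NULL)
})

#' @rdname show-methods
#' @export
setMethod("show", "ObservedFeatureSet", function(object) {
    cat(sprintf(
        "ObservedFeatureSet for %s (%s): %d shifts, %d multiplicities, %d J, %d COSY, %d HSQC, %d HMBC, %d evidence item(s)\n",
        object@metaboliteId, object@provenance, nrow(object@shifts),
        nrow(object@multiplicities), nrow(object@couplings),
        nrow(object@cosyPeaks), nrow(object@hsqcPeaks),
        nrow(object@hmbcPeaks), nrow(object@evidence)))
    invisible(NULL)
})

#' @rdname show-methods
#' @export
setMethod("show", "ConfidenceCall", function(object) {
    cat(sprintf("ConfidenceCall: %s\n", object@label))
    cat(paste0("  - ", object@reasons, collapse = "\n"), "\n")
    invisible(NULL)
})
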