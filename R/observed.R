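# Observed feature sets: reading curated observation files, tallying the
# experimentally retrieved bits, and validating them against theory.

.emptyDf <- function(...) {
    cols <- list(...)
    as.data.frame(lapply(cols, function(type) vector(type, 0L)),
                  stringsAsFactors = FALSE)
}

.obsTemplate <- function() {
    list(shifts = .emptyDf(ppm = "numeric", assignment = "character"),
         multiplicities = .emptyDf(assignment = "character",
                                   label = "character"),
         couplings = .emptyDf(assignment1 = "character",
                              assignment2 = "character", hz = "numeric"),
         cosyPeaks = .emptyDf(assignment1 = "character",
                              assignment2 = "character"),
         hsqcPeaks = .emptyDf(ppmH = "numeric", ppmC = "numeric",
                              assignment = "character"),
         hmbcPeaks = .emptyDf(ppmC = "numeric", assignment = "character"),
         evidence = .emptyDf(kind = "character", description = "character",
                             hz = "numeric"))
}

.asObsDf <- function(x, template, rename = c()) {
    if (is.null(x) || (is.data.frame(x) && !nrow(x)) || !length(x))
        return(template)
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    for (i in seq_along(rename))
        names(df)[names(df) == names(rename)[i]] <- rename[[i]]
    for (col in setdiff(names(template), names(df)))
        df[[col]] <- vector(class(template[[col]]), nrow(df))
    df[names(template)]
}

#' Construct an observed feature set
#'
#' Low-level constructor used by the readers and the simulator.  All
#' arguments except \code{metaboliteId} are optional data.frames following
#' the slot layouts of \linkS4class{ObservedFeatureSet}.
#'
#' @param metaboliteId metabolite id the observations belong to.
#' @param shifts,multiplicities,couplings,cosyPeaks,hsqcPeaks,hmbcPeaks,evidence
#'   peak-list data.frames (missing pieces default to empty).
#' @param secondOrder observed second-order flag, 0 or 1.
#' @param provenance provenance note.
#' @return an \linkS4class{ObservedFeatureSet}.
#' @export
observedFeatureSet <- function(metaboliteId, shifts = NULL,
                               multiplicities = NULL, couplings = NULL,
                               cosyPeaks = NULL, hsqcPeaks = NULL,
                               hmbcPeaks = NULL, evidence = NULL,
                               secondOrder = 0L, provenance = "curated") {
    tpl <- .obsTemplate()
    obj <- new("ObservedFeatureSet",
        metaboliteId = metaboliteId,
        shifts = .asObsDf(shifts, tpl$shifts),
        multiplicities = .asObsDf(multiplicities, tpl$multiplicities),
        couplings = .asObsDf(couplings, tpl$couplings),
        cosyPeaks = .asObsDf(cosyPeaks, tpl$cosyPeaks),
        hsqcPeaks = .asObsDf(hsqcPeaks, tpl$hsqcPeaks,
                             rename = c(ppm_h = "ppmH", ppm_c = "ppmC")),
        hmbcPeaks = .asObsDf(hmbcPeaks, tpl$hmbcPeaks,
                             rename = c(ppm_c = "ppmC")),
        evidence = .asObsDf(evidence, tpl$evidence),
        secondOrder = as.integer(secondOrder),
        provenance = provenance)
    obj@evidence$hz[is.na(obj@evidence$hz)] <- 0
    validObject(obj)
    obj
}

#' Read observed feature sets from a JSON file
#'
#' Reads a JSON array of per-metabolite observation entries (the schema
#' shipped in \code{inst/extdata}) into \linkS4class{ObservedFeatureSet}
#' objects.
#'
#' @param file path to the JSON file.
#' @param knownIds optional character vector of valid metabolite ids; an
#'   entry referencing any other id raises an error listing the known ids.
#' @return a named list of \linkS4class{ObservedFeatureSet}.
#' @export
readObservations <- function(file, knownIds = NULL) {
    raw <- jsonlite::fromJSON(file, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
    if (!length(raw)) return(list())
    if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
    out <- list()
    for (entry in raw) {
        e <- as.list(entry)
        e <- lapply(e, function(x) if (is.list(x) && is.data.frame(x[[1]]))
            x[[1]] else x)
        id <- e$metabolite_id
        if (is.null(id) || !nzchar(id))
            stop("observation entry without metabolite_id", call. = FALSE)
        if (!is.null(knownIds) && !id %in% knownIds)
            stop(sprintf("unknown metabolite id '%s'; known ids: %s", id,
                         paste(knownIds, collapse = ", ")), call. = FALSE)
        out[[id]] <- observedFeatureSet(
            metaboliteId = id,
            shifts = e$shifts, multiplicities = e$multiplicities,
            couplings = e$couplings, cosyPeaks = e$cosy,
            hsqcPeaks = e$hsqc, hmbcPeaks = e$hmbc, evidence = e$evidence,
            secondOrder = if (is.null(e$second_order)) 0L else e$second_order,
            provenance = if (is.null(e$provenance)) "curated" else e$provenance)
    }
    out
}

.dedupPairs <- function(df) {
    if (!nrow(df)) return(df)
    key <- paste(pmin(df$assignment1, df$assignment2),
                 pmax(df$assignment1, df$assignment2))
    df[!duplicated(key), , drop = FALSE]
}

#' Tally the observed identification bits of a feature set
#'
#' Converts an observed peak-list record into primed feature counts: one
#' shift bit per distinct assigned resonance, one multiplicity bit per
#' resonance with a read multiplicity label, one coupling bit per measured
#' J value, the observed second-order flag, and deduplicated COSY/HSQC/HMBC
#' peak counts.  Evidence items (long-range or heteronuclear couplings)
#' contribute no bits.
#'
#' @param set an \linkS4class{ObservedFeatureSet}.
#' @return a \linkS4class{SpectralFeatureCounts} with provenance
#'   \code{"observed"}.
#' @export
tallyObserved <- function(set) {
    stopifnot(is(set, "ObservedFeatureSet"))
    sh <- set@shifts[!duplicated(set@shifts$assignment), , drop = FALSE]
    mu <- set@multiplicities[nzchar(set@multiplicities$label), , drop = FALSE]
    mu <- mu[!duplicated(mu$assignment), , drop = FALSE]
    cp <- .dedupPairs(set@couplings)
    cs <- .dedupPairs(set@cosyPeaks)
    hq <- set@hsqcPeaks[!duplicated(set@hsqcPeaks[c("ppmH", "ppmC")]), ,
                        drop = FALSE]
    hb <- set@hmbcPeaks[!duplicated(set@hmbcPeaks[c("ppmC", "assignment")]), ,
                        drop = FALSE]
    .featureCounts(nrow(sh), nrow(mu), nrow(cp), set@secondOrder,
                   nCosy = nrow(cs), nHsqc = nrow(hq), nHmbc = nrow(hb),
                   provenance = "observed")
}

#' Validate observed counts against the theoretical profile
#'
#' Compares an observed tally feature-by-feature with the theoretical counts
#' of the same metabolite and returns one warning string per feature where
#' more was observed than is theoretically available.  Nothing is modified.
#'
#' @param observed observed \linkS4class{SpectralFeatureCounts}.
#' @param theoretical theoretical \linkS4class{SpectralFeatureCounts}.
#' @return character vector of warnings (empty when consistent).
#' @export
validateVsTheory <- function(observed, theoretical) {
    stopifnot(is(observed, "SpectralFeatureCounts"),
              is(theoretical, "SpectralFeatureCounts"))
    feats <- c(shifts = "nShifts", multiplicities = "nMultiplicities",
               couplings = "nCouplings", `second-order flag` =
                   "secondOrderFlag", COSY = "nCosy", HSQC = "nHsqc",
               HMBC = "nHmbc")
    out <- character()
    for (i in seq_along(feats)) {
        o <- methods::slot(observed, feats[i])
        t <- methods::slot(theoretical, feats[i])
        if (o > t)
            out <- c(out, sprintf(
                "observed %s count (%d) exceeds theoretical (%d)",
                names(feats)[i], o, t))
    }
    out
}
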