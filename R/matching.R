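# Matching observed shift/coupling values against reference data and
# assessing molecular coverage.

#' Construct match tolerances
#'
#' @param dH 1H shift tolerance in ppm (default 0.03).
#' @param dC 13C shift tolerance in ppm (default 0.5).
#' @param dJ coupling tolerance in Hz (default 0.2).
#' @return a \linkS4class{MatchTolerances}.
#' @export
matchTolerances <- function(dH = 0.03, dC = 0.5, dJ = 0.2) {
    new("MatchTolerances", dH = dH, dC = dC, dJ = dJ)
}

#' Read reference entries from a JSON file
#'
#' Reference (database/literature) shift and coupling values with assignment
#' labels, one entry per metabolite.
#'
#' @param file path to the JSON file.
#' @return named list of reference entries (lists with \code{metabolite_id},
#'   \code{source}, and data.frames \code{shifts_h}, \code{shifts_c},
#'   \code{couplings}).
#' @export
readReferences <- function(file) {
    raw <- jsonlite::fromJSON(file, simplifyDataFrame = TRUE)
    if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
    out <- list()
    for (entry in raw) {
        e <- as.list(entry)
        e <- lapply(e, function(x) if (is.list(x) && is.data.frame(x[[1]]))
            x[[1]] else x)
        out[[e$metabolite_id]] <- e
    }
    out
}

.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))

#' Match observed features against reference values
#'
#' Pairs observed and reference values by assignment label (never by value
#' proximity, which mis-pairs in crowded regions) and compares each pair
#' under the appropriate tolerance: 1H shifts against \code{dH}, 13C shifts
#' (from HSQC peaks) against \code{dC}, couplings against \code{dJ}.  Values
#' exactly on a tolerance boundary pass ("within +/-").  Observations
#' without a reference counterpart are listed as unpaired, not failed.
#'
#' @param observed an \linkS4class{ObservedFeatureSet}.
#' @param reference a reference entry (see \code{\link{readReferences}}).
#' @param tol a \linkS4class{MatchTolerances}.
#' @return list: \code{records} data.frame (type, assignment, observed,
#'   reference, delta, pass), \code{nMatched}, \code{nFailed},
#'   \code{matchOk}, \code{unpaired}.
#' @export
matchFeatures <- function(observed, reference, tol = matchTolerances()) {
    stopifnot(is(observed, "ObservedFeatureSet"), is(tol, "MatchTolerances"))
    rows <- list()
    unpaired <- character()
    compare <- function(type, assignment, obsVal, refMap, tolVal) {
        for (i in seq_along(assignment)) {
            ref <- refMap[[assignment[i]]]
            if (is.null(ref)) {
                unpaired <<- c(unpaired, paste(type, assignment[i]))
            } else {
                d <- abs(obsVal[i] - ref)
                # boundary values pass ("within +/-"); the epsilon guards
                # against decimal values that are not binary-representable
                rows[[length(rows) + 1L]] <<- data.frame(
                    type = type, assignment = assignment[i],
                    observed = obsVal[i], reference = ref, delta = d,
                    pass = d <= tolVal + 1e-9)
            }
        }
    }
    asMap <- function(df, key, val) {
        if (is.null(df) || !nrow(df)) return(list())
        stats::setNames(as.list(df[[val]]), df[[key]])
    }
    hRef <- asMap(reference$shifts_h, "assignment", "ppm")
    cRef <- asMap(reference$shifts_c, "assignment", "ppm")
    jdf <- reference$couplings
    jRef <- if (is.null(jdf) || !nrow(jdf)) list() else
        stats::setNames(as.list(jdf$hz),
                        .pairKey(jdf$assignment1, jdf$assignment2))
    compare("1H", observed@shifts$assignment, observed@shifts$ppm, hRef,
            tol@dH)
    compare("13C", observed@hsqcPeaks$assignment, observed@hsqcPeaks$ppmC,
            cRef, tol@dC)
    if (nrow(observed@couplings))
        compare("J", .pairKey(observed@couplings$assignment1,
                              observed@couplings$assignment2),
                observed@couplings$hz, jRef, tol@dJ)
    if (!length(rows))
        stop(sprintf(
            "no shared assignments between observations and reference %s",
            reference$source), call. = FALSE)
    records <- do.call(rbind, rows)
    list(records = records, nMatched = sum(records$pass),
         nFailed = sum(!records$pass), matchOk = all(records$pass),
         unpaired = unpaired)
}

#' Assess molecular coverage of the observations
#'
#' Checks that the observed identification bits cover all annotated parts of
#' the molecule.  Each fragment of
#' \code{record@fragmentAnnotations} is covered when at least one observed
#' assignment label belongs to it; records without fragment annotations are
#' treated as a single whole-molecule fragment covered by any observation.
#'
#' @param observed an \linkS4class{ObservedFeatureSet}.
#' @param record the \linkS4class{MetaboliteRecord}.
#' @return list \code{coverageFraction} (in \eqn{[0,1]}) and
#'   \code{coverageOk} (fraction equal to 1).
#' @export
assessCoverage <- function(observed, record) {
    stopifnot(is(observed, "ObservedFeatureSet"), is(record, "MetaboliteRecord"))
    labels <- unique(c(observed@shifts$assignment,
                       observed@multiplicities$assignment,
                       observed@couplings$assignment1,
                       observed@couplings$assignment2,
                       observed@cosyPeaks$assignment1,
                       observed@cosyPeaks$assignment2,
                       observed@hsqcPeaks$assignment,
                       observed@hmbcPeaks$assignment))
    labels <- labels[nzchar(labels)]
    frags <- record@fragmentAnnotations
    if (!length(frags)) {
        frac <- if (length(labels)) 1 else 0
        return(list(coverageFraction = frac, coverageOk = frac == 1))
    }
    known <- unique(unlist(frags))
    stray <- setdiff(labels, known)
    if (length(stray))
        stop(sprintf(
            "assignment(s) %s reference atoms outside the annotated fragments of %s",
            paste(sQuote(stray), collapse = ", "), record@id), call. = FALSE)
    covered <- vapply(frags, function(f) any(labels %in% f), logical(1))
    frac <- mean(covered)
    list(coverageFraction = frac, coverageOk = frac == 1)
}
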