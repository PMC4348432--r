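# Identification efficiency indices and the confidence classifier.

#' Round half away from zero for reporting
#'
#' Reporting convention used for MIE/MICE values: one decimal, ties rounded
#' away from zero (0.75 -> 0.8, 0.375 -> 0.4).  Raw values are retained
#' everywhere internally; only reports round.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
reportRound <- function(x, digits = 1L) {
    f <- 10^digits
    sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Metabolite identification efficiency (MIE)
#'
#' Identification information bits divided by the number of heavy
#' (non-hydrogen) atoms in the metabolite.
#'
#' @param bits identification bits (integer, any evidence level).
#' @param nHeavy heavy atom count (>= 1).
#' @return bits per heavy atom (unrounded; see \code{\link{reportRound}}).
#' @examples
#' reportRound(mie(25, 11))   # 2.3
#' @export
mie <- function(bits, nHeavy) {
    if (any(nHeavy < 1L))
        stop("MIE undefined: heavy atom count must be >= 1", call. = FALSE)
    bits / nHeavy
}

#' Metabolite identification carbon efficiency (MICE)
#'
#' Identification information bits divided by the number of carbon atoms.
#'
#' @param bits identification bits.
#' @param nC carbon count (>= 1).
#' @return bits per carbon atom (unrounded).
#' @examples
#' reportRound(mice(11, 6))   # 1.8 (ketoleucine at the HSQC level)
#' @export
mice <- function(bits, nC) {
    if (any(nC < 1L))
        stop("MICE undefined: carbon count must be >= 1", call. = FALSE)
    bits / nC
}

#' Metabolite identification hydrogen fraction (MIHF)
#'
#' Observed identification bits divided by the theoretically available bits;
#' computable for a single metabolite, a sub-group or a whole cohort.
#'
#' @param observedBits observed bit count (NMIIo).
#' @param theoreticalBits theoretical bit count (NMIIt, >= 1).
#' @return fraction in \eqn{[0, 1]} for validated observations.
#' @export
mihf <- function(observedBits, theoreticalBits) {
    if (any(theoreticalBits < 1L))
        stop("MIHF undefined: theoretical bit count must be >= 1",
             call. = FALSE)
    observedBits / theoreticalBits
}

#' Efficiency scores at the four evidence levels
#'
#' Tabulates bits, MIE, MICE and (when theoretical bits are supplied) MIHF
#' for each of the four nested NMR evidence levels.
#'
#' @param counts a \linkS4class{SpectralFeatureCounts}.
#' @param nC,nHeavy carbon and heavy-atom counts of the metabolite (for
#'   multi-form records these come from a single form).
#' @param theoretical optional theoretical \linkS4class{SpectralFeatureCounts}
#'   of the same metabolite, enabling the MIHF column.
#' @return data.frame with one row per level: \code{level}, \code{bits},
#'   \code{mie}, \code{mice}, \code{mihf}, \code{provenance}.
#' @export
efficiencyScores <- function(counts, nC, nHeavy, theoretical = NULL) {
    stopifnot(is(counts, "SpectralFeatureCounts"))
    bits <- bitsVector(levelBits(counts))
    out <- data.frame(level = .levelNames, bits = as.integer(bits),
                      mie = mie(bits, nHeavy), mice = mice(bits, nC),
                      mihf = NA_real_, provenance = counts@provenance,
                      row.names = NULL)
    if (!is.null(theoretical)) {
        tb <- bitsVector(levelBits(theoretical))
        out$mihf <- ifelse(tb >= 1L, bits / tb, NA_real_)
    }
    out
}

.diagnosticKinds <- c("long_range_cosy", "long_range_coupling",
                      "heteronuclear_coupling")

#' Classify an identification as confident or putatively annotated
#'
#' Applies the identification-confidence guidelines at the 1D+COSY+HSQC
#' reference level: the call is \code{confidently_identified} iff the
#' reference match is acceptable, the observations cover all annotated parts
#' of the molecule, and at least one of the following holds -- experimental
#' MICE at the reference level at least \code{miceThreshold} (default 1
#' bit/carbon), experimental MIE above \code{mieThreshold} (default 0.5
#' bits/heavy atom), orthogonal carbon-13 evidence (any observed HSQC or
#' HMBC cross-peak), or a diagnostic evidence item (long-range or
#' heteronuclear coupling).  Otherwise the metabolite is
#' \code{putatively_annotated}.  Every clause evaluation is recorded.
#'
#' @param miceHsqc,mieHsqc experimental MICE and MIE at the 1D+COSY+HSQC
#'   level (unrounded).
#' @param observed observed \linkS4class{SpectralFeatureCounts}.
#' @param evidence data.frame of evidence items (may be empty).
#' @param coverageOk logical from \code{\link{assessCoverage}}.
#' @param matchOk logical from \code{\link{matchFeatures}} (TRUE when no
#'   reference comparison was requested).
#' @param miceThreshold,mieThreshold configurable guideline thresholds.
#' @return a \linkS4class{ConfidenceCall}.
#' @export
classifyConfidence <- function(miceHsqc, mieHsqc, observed,
                               evidence = NULL, coverageOk = TRUE,
                               matchOk = TRUE, miceThreshold = 1.0,
                               mieThreshold = 0.5) {
    stopifnot(is(observed, "SpectralFeatureCounts"))
    reasons <- character()
    note <- function(fmt, ...) reasons <<- c(reasons, sprintf(fmt, ...))
    hasC13 <- observed@nHsqc >= 1L || observed@nHmbc >= 1L
    nDiag <- if (is.null(evidence) || !nrow(evidence)) 0L
             else sum(evidence$kind %in% .diagnosticKinds)
    note("reference match %s", if (matchOk) "acceptable" else "failed")
    note("molecular coverage %s", if (coverageOk) "complete" else "incomplete")
    note("MICE %.3f %s threshold %.2f", miceHsqc,
         if (miceHsqc >= miceThreshold) "meets" else "below", miceThreshold)
    note("MIE %.3f %s threshold %.2f", mieHsqc,
         if (mieHsqc > mieThreshold) "exceeds" else "at or below",
         mieThreshold)
    note("orthogonal 13C evidence (HSQC %d, HMBC %d) %s", observed@nHsqc,
         observed@nHmbc, if (hasC13) "present" else "absent")
    note("diagnostic evidence items: %d", nDiag)
    ok <- matchOk && coverageOk &&
        (miceHsqc >= miceThreshold || mieHsqc > mieThreshold ||
         hasC13 || nDiag > 0L)
    new("ConfidenceCall",
        label = if (ok) "confidently_identified" else "putatively_annotated",
        reasons = reasons)
}

#' Score one metabolite end to end
#'
#' Convenience wrapper: theoretical profile, observed tally, per-level
#' efficiency scores, optional reference matching and coverage, and the
#' confidence call.
#'
#' @param record a \linkS4class{MetaboliteRecord}.
#' @param observed an \linkS4class{ObservedFeatureSet} for the record.
#' @param reference optional reference entry (see \code{\link{matchFeatures}}).
#' @param tolerances a \linkS4class{MatchTolerances}.
#' @param miceThreshold,mieThreshold guideline thresholds passed to
#'   \code{\link{classifyConfidence}}.
#' @return list with elements \code{scores} (observed and theoretical
#'   data.frames), \code{counts}, \code{theoretical}, \code{warnings},
#'   \code{match}, \code{coverage} and \code{call}.
#' @export
scoreMetabolite <- function(record, observed, reference = NULL,
                            tolerances = new("MatchTolerances"),
                            miceThreshold = 1.0, mieThreshold = 0.5) {
    stopifnot(is(record, "MetaboliteRecord"),
              is(observed, "ObservedFeatureSet"))
    theo <- theoreticalProfile(record)
    obs <- tallyObserved(observed)
    topo <- .topologyOf(record@forms[1])
    nC <- carbonCount(topo)
    nHeavy <- heavyAtomCount(topo)
    scoresObs <- efficiencyScores(obs, nC, nHeavy, theoretical = theo)
    scoresTheo <- efficiencyScores(theo, nC, nHeavy)
    match <- NULL
    matchOk <- TRUE
    if (!is.null(reference)) {
        match <- matchFeatures(observed, reference, tolerances)
        matchOk <- match$matchOk
    }
    cov <- assessCoverage(observed, record)
    call <- classifyConfidence(
        miceHsqc = scoresObs$mice[scoresObs$level == "1D+COSY+HSQC"],
        mieHsqc = scoresObs$mie[scoresObs$level == "1D+COSY+HSQC"],
        observed = obs, evidence = observed@evidence,
        coverageOk = cov$coverageOk, matchOk = matchOk,
        miceThreshold = miceThreshold, mieThreshold = mieThreshold)
    list(id = record@id, scores = scoresObs, scoresTheoretical = scoresTheo,
         counts = obs, theoretical = theo,
         warnings = validateVsTheory(obs, theo), match = match,
         coverage = cov, call = call)
}
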