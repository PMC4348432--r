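# Theoretical feature counting: features 8-14 from the proton classes and
# carbon orbits of a topology, and the cumulative level bit totals.

.requireClasses <- function(topology) {
    if (!nrow(topology@protonClasses))
        stop("derive proton equivalence classes first", call. = FALSE)
    topology@protonClasses[!topology@protonClasses$exchangeable, ,
                           drop = FALSE]
}

#' Count theoretical chemical shifts and multiplicities
#'
#' The number of 1H chemical shifts (feature 8) equals the number of
#' non-exchanging proton equivalence classes; one multiplet is counted per
#' resonance however complex its fine structure, so the multiplicity count
#' (feature 9) equals the shift count.
#'
#' @param topology a topology with derived proton classes.
#' @return integer vector \code{c(nShifts, nMultiplicities)}; a molecule with
#'   no non-exchanging proton gets zeros and an \code{"NMR-invisible"}
#'   attribute.
#' @export
countShiftsAndMultiplicities <- function(topology) {
    ne <- .requireClasses(topology)
    n <- nrow(ne)
    out <- c(nShifts = n, nMultiplicities = n)
    if (n == 0L) attr(out, "note") <- "NMR-invisible"
    out
}

# class pairs with a 2- or 3-bond proton-proton path
.couplingPairs <- function(topology) {
    ne <- .requireClasses(topology)
    if (nrow(ne) < 2L) return(data.frame(a = character(), b = character()))
    D <- .bondDistances(topology)
    pairs <- utils::combn(seq_len(nrow(ne)), 2L)
    keep <- apply(pairs, 2L, function(ij) {
        d <- D[ne$members[[ij[1]]], ne$members[[ij[2]]], drop = FALSE]
        any(d == 2L | d == 3L)
    })
    data.frame(a = ne$label[pairs[1L, keep]], b = ne$label[pairs[2L, keep]])
}

#' Count theoretical 2/3-bond H,H coupling constants
#'
#' Feature 10: the number of unordered pairs of distinct non-exchanging
#' proton classes connected by a two-bond (geminal) or three-bond (vicinal)
#' path; the path may run through any heavy atoms (amide H-N-C-H couplings
#' count).  Couplings within one class and long-range (>= 4-bond) couplings
#' are not counted.
#'
#' @inheritParams countShiftsAndMultiplicities
#' @return integer count.
#' @export
countCouplings <- function(topology) {
    nrow(.couplingPairs(topology))
}

#' Second-order spin system flag
#'
#' Feature 11: 1 if the molecule contains chemically equivalent but
#' magnetically non-equivalent protons (AA'BB'-type systems), detected
#' topologically -- some member of a class lies two or three bonds from a
#' proton outside the class while another member does not -- and 0 otherwise.
#' Second-order behaviour caused by accidental chemical shift proximity is
#' out of scope of the theoretical count.
#'
#' @inheritParams countShiftsAndMultiplicities
#' @return integer 0 or 1.
#' @export
secondOrderFlag <- function(topology) {
    ne <- .requireClasses(topology)
    if (nrow(ne) < 2L) return(0L)
    D <- .bondDistances(topology)
    for (i in which(ne$size >= 2L)) {
        others <- unlist(ne$members[-i])
        for (b in others) {
            d <- D[ne$members[[i]], b]
            inRange <- d == 2L | d == 3L
            if (any(inRange) && !all(inRange)) return(1L)
        }
    }
    0L
}

#' Count theoretical HSQC cross-peaks
#'
#' Feature 13: the number of distinct (non-exchanging proton class, attached
#' carbon orbit) pairs.  Non-equivalent methylene protons on one carbon
#' contribute two peaks; symmetry-equivalent pairs are counted once.
#'
#' @inheritParams countShiftsAndMultiplicities
#' @return integer count.
#' @export
countHsqc <- function(topology) {
    ne <- .requireClasses(topology)
    if (!nrow(ne)) return(0L)
    at <- topology@atoms
    orbitOf <- integer(nrow(at))
    for (k in seq_along(topology@carbonOrbits))
        orbitOf[topology@carbonOrbits[[k]]] <- k
    pairs <- unique(unlist(lapply(seq_len(nrow(ne)), function(i) {
        parents <- at$parent[ne$members[[i]]]
        parents <- parents[at$element[parents] == "C"]
        if (!length(parents)) return(character())
        paste(ne$label[i], orbitOf[parents])
    })))
    length(pairs)
}

#' Count theoretical HMBC cross-peaks
#'
#' Feature 14: the number of distinct (carbon orbit, non-exchanging proton
#' class) pairs connected by a two- or three-bond carbon-to-proton path.
#' Cross-peaks between pseudo-equivalent groups (the methyls of
#' trimethylamine) are real and count once per orbit pair; the one-bond
#' (HSQC) pairing itself does not count.
#'
#' @inheritParams countShiftsAndMultiplicities
#' @return integer count.
#' @export
countHmbc <- function(topology) {
    ne <- .requireClasses(topology)
    if (!nrow(ne) || !length(topology@carbonOrbits)) return(0L)
    D <- .bondDistances(topology)
    n <- 0L
    for (orb in topology@carbonOrbits) {
        for (i in seq_len(nrow(ne))) {
            d <- D[orb, ne$members[[i]], drop = FALSE]
            if (any(d == 2L | d == 3L)) n <- n + 1L
        }
    }
    n
}

.featureCounts <- function(nShifts, nMultiplicities, nCouplings,
                           secondOrderFlag, nCosy, nHsqc, nHmbc,
                           provenance, notes = character()) {
    new("SpectralFeatureCounts",
        nShifts = as.integer(nShifts),
        nMultiplicities = as.integer(nMultiplicities),
        nCouplings = as.integer(nCouplings),
        secondOrderFlag = as.integer(secondOrderFlag),
        nCosy = as.integer(nCosy), nHsqc = as.integer(nHsqc),
        nHmbc = as.integer(nHmbc), provenance = provenance, notes = notes)
}

# all seven counted features for one structural form
.formCounts <- function(topology) {
    sm <- countShiftsAndMultiplicities(topology)
    nc <- countCouplings(topology)
    .featureCounts(sm[1], sm[2], nc, secondOrderFlag(topology),
                   nCosy = nc, nHsqc = countHsqc(topology),
                   nHmbc = countHmbc(topology),
                   provenance = "theoretical",
                   notes = if (sm[1] == 0L) "NMR-invisible" else character())
}

#' Theoretical spectroscopic feature profile of a metabolite
#'
#' Computes features 8-14 for every structural form of the record and sums
#' them (for sugars both anomers contribute, the second-order flag is OR-ed).
#' The theoretical COSY count equals the coupling count by construction.  A
#' curated override on the record, when present, replaces the algorithmic
#' result.
#'
#' @param record a \linkS4class{MetaboliteRecord}.
#' @return a \linkS4class{SpectralFeatureCounts} with provenance
#'   \code{"theoretical"}.
#' @export
theoreticalProfile <- function(record) {
    stopifnot(is(record, "MetaboliteRecord"))
    if (!is.null(record@overrides)) {
        ov <- record@overrides
        ov@provenance <- "theoretical"
        validObject(ov)
        return(ov)
    }
    topos <- lapply(record@forms, .topologyOf, withClasses = TRUE)
    formulas <- lapply(topos, function(t) table(t@atoms$element))
    if (length(topos) > 1L &&
        !all(vapply(formulas[-1], identical, logical(1), formulas[[1]])))
        stop(sprintf("forms of %s have different molecular formulas",
                     record@id), call. = FALSE)
    counts <- lapply(topos, .formCounts)
    tot <- function(slot) sum(vapply(counts, methods::slot, integer(1), slot))
    .featureCounts(tot("nShifts"), tot("nMultiplicities"), tot("nCouplings"),
                   max(vapply(counts, methods::slot, integer(1),
                              "secondOrderFlag")),
                   nCosy = tot("nCosy"), nHsqc = tot("nHsqc"),
                   nHmbc = tot("nHmbc"), provenance = "theoretical",
                   notes = unique(unlist(lapply(counts, methods::slot,
                                                "notes"))))
}

#' Cumulative identification bits at the four NMR evidence levels
#'
#' Sums the counted features into the four nested totals: 1D 1H (shifts +
#' multiplicities + couplings + second-order flag), plus COSY, plus HSQC,
#' plus HMBC.
#'
#' @param counts a \linkS4class{SpectralFeatureCounts}.
#' @return a \linkS4class{LevelBits}.
#' @export
levelBits <- function(counts) {
    stopifnot(is(counts, "SpectralFeatureCounts"))
    b <- counts@nShifts + counts@nMultiplicities + counts@nCouplings +
        counts@secondOrderFlag
    csy <- b + counts@nCosy
    hq <- csy + counts@nHsqc
    new("LevelBits", bits1d = b, bitsCosy = csy, bitsHsqc = hq,
        bitsHmbc = hq + counts@nHmbc)
}

#' @describeIn levelBits the four totals as a named integer vector.
#' @param x a \linkS4class{LevelBits}.
#' @export
bitsVector <- function(x) {
    stopifnot(is(x, "LevelBits"))
    c(`1D` = x@bits1d, `1D+COSY` = x@bitsCosy, `1D+COSY+HSQC` = x@bitsHsqc,
      `1D+COSY+HSQC+HMBC` = x@bitsHmbc)
}

.levelNames <- c("1D", "1D+COSY", "1D+COSY+HSQC", "1D+COSY+HSQC+HMBC")
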