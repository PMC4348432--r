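# Exchangeability classification and proton topicity.
#
# Equivalence classes merge homotopic and enantiotopic hydrogens and split
# diastereotopic ones.  The classifier is a literal substitution test: each
# candidate hydrogen is replaced by a fluorine label, definite configurations
# are assigned at every centre that becomes stereogenic, and two hydrogens
# are equivalent iff the labelled molecules have identical canonical SMILES
# or are mirror images of each other.

.topoCache <- new.env(parent = emptyenv())

# Parsed-and-classified topology for a SMILES, cached: the substitution test
# costs a few dozen Open Babel calls per molecule and cohort work touches
# each structure many times.
.topologyOf <- function(smiles, withClasses = FALSE) {
    key <- paste0(if (withClasses) "c:" else "p:", smiles)
    hit <- .topoCache[[key]]
    if (!is.null(hit)) return(hit)
    topo <- if (withClasses) {
        protonEquivalenceClasses(classifyExchangeable(.topologyOf(smiles)))
    } else {
        parseStructure(smiles)
    }
    assign(key, topo, envir = .topoCache)
    topo
}

.isAmideNitrogen <- function(topology, nIdx) {
    at <- topology@atoms
    bd <- topology@bonds
    carbonyl <- function(cIdx) {
        # carbon double-bonded to O (or S)
        k <- which((bd$a1 == cIdx | bd$a2 == cIdx) & bd$order == 2L)
        any(at$element[setdiff(c(bd$a1[k], bd$a2[k]), cIdx)] %in% c("O", "S"))
    }
    nb <- .neighbours(topology, nIdx)
    cnb <- nb[at$element[nb] == "C"]
    cb <- cnb[vapply(cnb, carbonyl, logical(1))]
    # exactly one carbonyl neighbour, and that carbonyl carries no second
    # nitrogen (which would make it a faster-exchanging urea/guanidine-like
    # N-H); two carbonyl neighbours are an imide, also excluded
    if (length(cb) != 1L) return(FALSE)
    cnb <- setdiff(.neighbours(topology, cb), nIdx)
    !any(at$element[cnb] == "N")
}

#' Classify hydrogen exchangeability
#'
#' Marks every hydrogen as exchangeable or non-exchanging on the NMR
#' timescale in aqueous solution.  Hydroxyl, thiol, amine, guanidino,
#' imidazole/indole, urea and imide protons are exchangeable; carbon-bound
#' protons and secondary amide N-H (a nitrogen bound to exactly one carbonyl
#' carbon that carries no further nitrogen) are non-exchanging.  Only
#' non-exchanging protons contribute identification information bits.
#'
#' @param topology a \linkS4class{MolecularTopology}.
#' @param overrides optional named logical vector keyed by atom index
#'   (as character) forcing the flag for individual hydrogens; curated
#'   fixtures may use this where the structural rule is wrong.
#' @return the topology with the \code{exchangeable} atom column filled.
#' @examples
#' topo <- classifyExchangeable(parseStructure("CC(=O)NCC(O)=O"))
#' # the amide N-H of N-acetylglycine counts, the acid O-H does not
#' @export
classifyExchangeable <- function(topology, overrides = NULL) {
    stopifnot(is(topology, "MolecularTopology"))
    at <- topology@atoms
    ex <- rep(NA, nrow(at))
    for (h in which(at$isH)) {
        p <- at$parent[h]
        if (is.na(p)) { ex[h] <- TRUE; next }   # lone/bridging H: ignore
        ex[h] <- switch(at$element[p],
            C = FALSE,
            N = !.isAmideNitrogen(topology, p),
            TRUE)
    }
    if (!is.null(overrides)) {
        idx <- as.integer(names(overrides))
        stopifnot(all(at$isH[idx]))
        ex[idx] <- as.logical(overrides)
    }
    topology@atoms$exchangeable <- ex
    topology
}

# --- substitution-test internals ---------------------------------------

.flipTag <- function(tag) {
    if (tag == "@") "@@" else if (tag == "@@") "@" else tag
}

.mirrorSmiles <- function(s) {
    s <- gsub("@@", "\001", s, fixed = TRUE)
    s <- gsub("@", "@@", s, fixed = TRUE)
    gsub("\001", "@", s, fixed = TRUE)
}

.atomTokenText <- function(element, tag, nH, charge) {
    if (tag == "" && charge == 0L && is.na(nH)) return(element)
    chg <- if (charge == 0L) "" else if (charge == 1L) "+"
           else if (charge == -1L) "-"
           else sprintf("%+d", charge)
    htxt <- if (is.na(nH) || nH == 0L) ""
            else if (nH == 1L) "H" else paste0("H", nH)
    paste0("[", element, tag, htxt, chg, "]")
}

# Number of hydrogens attached to each heavy atom, in token (input) order.
.heavyHydrogenCounts <- function(topology) {
    at <- topology@atoms
    heavy <- which(!at$isH)
    vapply(heavy, function(v) sum(at$parent[at$isH] == v, na.rm = TRUE),
           integer(1))
}

# Rewrite the SMILES with (i) one hydrogen of atom `labelAtom` (heavy-atom
# token index) replaced by a fluorine branch, carrying tag `labelTag` if the
# atom is stereogenic in the labelled molecule, and (ii) "@" assigned at
# every other atom of `newStereo` that carries no descriptor yet.
.labelledSmiles <- function(topology, labelAtom, labelTag, newStereo) {
    tok <- topology@tokens
    s <- topology@smiles
    nH <- .heavyHydrogenCounts(topology)
    pieces <- character()
    pos <- 1L
    for (k in seq_len(nrow(tok))) {
        pieces <- c(pieces, substr(s, pos, tok$start[k] - 1L))
        tag <- tok$tag[k]
        text <- substr(s, tok$start[k], tok$end[k])
        ringTxt <- substr(s, tok$end[k] + 1L, tok$ringEnd[k])
        if (k == labelAtom) {
            newTag <- if (!is.na(labelTag)) labelTag
                else if (tag != "") {
                    # the in-bracket H moves past the ring-bond digits to
                    # become a branch: odd crossings flip the descriptor
                    if (tok$nRing[k] %% 2L == 1L) .flipTag(tag) else tag
                } else ""
            pieces <- c(pieces,
                .atomTokenText(tok$element[k], newTag, nH[k] - 1L,
                               tok$charge[k]),
                ringTxt, "(F)")
        } else if (k %in% newStereo && tag == "") {
            pieces <- c(pieces,
                .atomTokenText(tok$element[k], "@", nH[k], tok$charge[k]),
                ringTxt)
        } else {
            pieces <- c(pieces, text, ringTxt)
        }
        pos <- tok$ringEnd[k] + 1L
    }
    paste0(paste(pieces, collapse = ""), substr(s, pos, nchar(s)))
}

# Equivalence key of one labelled variant: the lexicographically smaller of
# the canonical SMILES of the labelled molecule and of its mirror image, so
# that homotopic and enantiotopic labellings share a key while diastereotopic
# labellings do not.
.variantKey <- function(topology, labelAtom, labelTag, newStereo) {
    s <- .labelledSmiles(topology, labelAtom, labelTag, newStereo)
    can <- .obCanonical(s)
    mir <- .obCanonical(.mirrorSmiles(s))
    min(can, mir)
}

#' Group hydrogens into proton equivalence classes
#'
#' Partitions the hydrogens of a structure into NMR equivalence classes:
#' homotopic and enantiotopic hydrogens share a class, diastereotopic
#' hydrogens (methylene protons near a stereocentre, geminal methyls of a
#' prochiral isopropyl group in a chiral molecule, and the like) are split.
#' The decision is a substitution test: a hydrogen is replaced by a test
#' label, every centre that becomes stereogenic receives a definite
#' configuration, and two labelled structures are equivalent iff their
#' canonical forms are identical or enantiomeric.  Exchangeable hydrogens are
#' grouped by constitutional symmetry orbit only.
#'
#' @param topology a \linkS4class{MolecularTopology} whose exchangeability
#'   has been classified (\code{\link{classifyExchangeable}}).
#' @return the topology with \code{protonClasses} (one row per class, listed
#'   in atom-rank order) and \code{carbonOrbits} filled.
#' @examples
#' topo <- protonEquivalenceClasses(
#'     classifyExchangeable(parseStructure("OC(=O)CCC(O)=O")))
#' protonClasses(topo)   # succinic acid: one class of four protons
#' @export
protonEquivalenceClasses <- function(topology) {
    stopifnot(is(topology, "MolecularTopology"))
    at <- topology@atoms
    if (all(is.na(at$exchangeable[at$isH])) && any(at$isH))
        stop("classify exchangeability before deriving proton classes")
    orbits <- .autOrbits(topology)
    heavy <- which(!at$isH)
    classes <- list()
    addClass <- function(members, exch, partnerWith = NA_integer_) {
        classes[[length(classes) + 1L]] <<- list(
            members = members, exchangeable = exch, partner = partnerWith)
    }

    # exchangeable hydrogens: constitutional orbits are enough
    exH <- which(at$isH & at$exchangeable %in% TRUE)
    if (length(exH))
        for (grp in split(exH, orbits[exH])) addClass(grp, TRUE)

    # non-exchanging hydrogens: substitution test per (atom, variant)
    neH <- which(at$isH & at$exchangeable %in% FALSE)
    keys <- character(); units <- list()
    for (p in heavy) {
        hs <- neH[at$parent[neH] == p]
        if (!length(hs)) next
        pTok <- match(p, heavy)
        labelled <- topology
        labelled@atoms$element[hs[1]] <- "F"
        labelled@atoms$isH[hs[1]] <- FALSE
        stereo2 <- .perceiveStereocenters(labelled)
        remote <- match(setdiff(stereo2, p), heavy)
        pStereo <- p %in% stereo2
        pTagged <- nzchar(topology@tokens$tag[pTok])
        if (length(hs) == 2L && pStereo) {
            for (slot in 1:2) {
                keys <- c(keys, .variantKey(topology, pTok,
                                            c("@", "@@")[slot], remote))
                units[[length(units) + 1L]] <- hs[slot]
            }
        } else {
            # an already-tagged atom keeps its real descriptor (NA lets the
            # writer carry it over); an untagged atom that becomes
            # stereogenic gets the "@" convention
            keys <- c(keys, .variantKey(topology, pTok,
                                        if (pStereo && !pTagged) "@" else NA,
                                        remote))
            units[[length(units) + 1L]] <- hs
        }
    }
    if (length(keys)) {
        for (grp in split(seq_along(keys), keys)) {
            addClass(sort(unlist(units[grp])), FALSE)
        }
    }

    # deterministic ordering and labels
    ord <- order(vapply(classes, function(cl) min(cl$members), integer(1)))
    classes <- classes[ord]
    labels <- paste0("H", seq_along(classes))
    boundEl <- vapply(classes, function(cl)
        at$element[at$parent[cl$members[1]]], character(1))
    attachedC <- vapply(classes, function(cl) {
        p <- at$parent[cl$members[1]]
        if (at$element[p] == "C") p else NA_integer_
    }, integer(1))
    # geminal diastereotopic partners: two singleton classes sharing a parent
    partner <- rep(NA_character_, length(classes))
    parents <- lapply(classes, function(cl) unique(at$parent[cl$members]))
    for (i in seq_along(classes)) {
        if (length(classes[[i]]$members) != 1L) next
        j <- which(vapply(seq_along(classes), function(j) {
            j != i && length(classes[[j]]$members) == 1L &&
                identical(parents[[j]], parents[[i]])
        }, logical(1)))
        if (length(j) == 1L) partner[i] <- labels[j]
    }
    df <- data.frame(label = labels,
                     size = vapply(classes, function(cl)
                         length(cl$members), integer(1)),
                     exchangeable = vapply(classes, `[[`, logical(1),
                                           "exchangeable"),
                     boundElement = boundEl,
                     attachedCarbon = attachedC,
                     partner = partner,
                     stringsAsFactors = FALSE)
    df$members <- lapply(classes, `[[`, "members")

    # carbon orbits, refined so that carbons whose attached protons fall in
    # different classes are kept apart (diastereotopically distinct carbons)
    carbons <- which(at$element == "C" & !at$isH)
    hClassOf <- rep(NA_character_, nrow(at))
    for (i in seq_len(nrow(df))) hClassOf[df$members[[i]]] <- df$label[i]
    cKey <- vapply(carbons, function(v) {
        hs <- which(at$isH & at$parent == v)
        paste(orbits[v],
              paste(sort(hClassOf[hs]), collapse = "+"), sep = "|")
    }, character(1))
    topology@carbonOrbits <- unname(split(carbons, cKey))
    topology@protonClasses <- df
    topology
}

#' Accessor for the proton equivalence classes of a topology
#'
#' @param topology a \linkS4class{MolecularTopology} processed by
#'   \code{\link{protonEquivalenceClasses}}.
#' @return data.frame with one row per class: label, size, exchangeability,
#'   bound element, attached carbon, diastereotopic partner and member atom
#'   indices.
#' @export
protonClasses <- function(topology) {
    stopifnot(is(topology, "MolecularTopology"))
    topology@protonClasses
}
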