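# Graph machinery: coloured molecular graphs, automorphism orbits and
# constitutional stereocentre perception.  Bond orders are encoded by
# subdividing every bond with a dummy vertex coloured by the order, since the
# BLISS backend only supports vertex colours.

.elementCode <- function(element) {
    match(element, names(.monoisotopicMass))
}

# Bonds of alternating six-membered carbocycles (benzene rings in Kekule
# notation).  Their written single/double alternation is an artefact that
# would otherwise break the ring symmetry in the orbit computation, so these
# bonds receive one common colour.
.aromaticBonds <- function(topology) {
    bd <- topology@bonds
    at <- topology@atoms
    m <- nrow(bd)
    arom <- logical(m)
    if (!m) return(arom)
    carbons <- which(at$element == "C")
    keep <- bd$a1 %in% carbons & bd$a2 %in% carbons
    if (!any(keep)) return(arom)
    adj <- lapply(seq_len(nrow(at)), function(v)
        c(bd$a2[keep & bd$a1 == v], bd$a1[keep & bd$a2 == v]))
    bondIdx <- function(u, v) which((bd$a1 == u & bd$a2 == v) |
                                    (bd$a1 == v & bd$a2 == u))[1]
    # all six-membered cycles, found by depth-first search anchored at the
    # smallest vertex of each cycle
    cyc <- list()
    walk <- function(path) {
        v <- path[length(path)]
        for (w in adj[[v]]) {
            if (length(path) == 6L) {
                if (w == path[1] && path[2] < path[6])
                    cyc[[length(cyc) + 1L]] <<- path
            } else if (!w %in% path && w > path[1]) {
                walk(c(path, w))
            }
        }
    }
    for (s in carbons) walk(s)
    for (ring in cyc) {
        orders <- vapply(seq_along(ring), function(i) {
            bd$order[bondIdx(ring[i], ring[i %% 6L + 1L])]
        }, integer(1))
        if (all(sort(unique(orders)) == c(1L, 2L)) &&
            all(abs(diff(orders)) == 1L)) {
            for (i in seq_along(ring))
                arom[bondIdx(ring[i], ring[i %% 6L + 1L])] <- TRUE
        }
    }
    arom
}

# Coloured graph for symmetry work.  Vertices 1..n are atoms; vertex n+k
# subdivides bond k.  `recolor` optionally overrides atom colours
# (named/indexed integer vector).
.colouredGraph <- function(topology, recolor = NULL) {
    at <- topology@atoms
    bd <- topology@bonds
    n <- nrow(at)
    m <- nrow(bd)
    colours <- .elementCode(at$element) * 16L + (at$charge + 8L)
    if (!is.null(recolor)) colours[as.integer(names(recolor))] <- recolor
    bondColour <- 10000L + bd$order
    bondColour[.aromaticBonds(topology)] <- 10004L
    edges <- rbind(cbind(bd$a1, n + seq_len(m)), cbind(bd$a2, n + seq_len(m)))
    g <- igraph::make_empty_graph(n = n + m, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    list(graph = g, colours = c(colours, bondColour), nAtoms = n)
}

# Orbits of the automorphism group (atoms only), as an integer vector of
# orbit ids.
.orbitsFromGenerators <- function(gens, n) {
    parent <- seq_len(n)
    find <- function(x) {
        while (parent[x] != x) {
            parent[x] <<- parent[parent[x]]
            x <- parent[x]
        }
        x
    }
    for (p in gens) {
        for (v in seq_len(n)) {
            a <- find(v); b <- find(p[v])
            if (a != b) parent[a] <- b
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    match(roots, unique(roots))
}

.autOrbits <- function(topology, recolor = NULL) {
    cg <- .colouredGraph(topology, recolor)
    gens <- igraph::automorphism_group(cg$graph, colors = cg$colours)
    gens <- lapply(gens, function(p) as.integer(p)[seq_len(cg$nAtoms)])
    .orbitsFromGenerators(gens, cg$nAtoms)
}

.neighbours <- function(topology, v) {
    bd <- topology@bonds
    c(bd$a2[bd$a1 == v], bd$a1[bd$a2 == v])
}

# Constitutional tetrahedral stereocentre perception: a C or N with four
# single bonds whose four neighbours are pairwise non-equivalent under the
# automorphisms fixing the atom.  Cheap pre-filters (two hydrogens, global
# orbit separation) avoid most stabiliser computations.
.perceiveStereocenters <- function(topology, globalOrbits = NULL) {
    at <- topology@atoms
    bd <- topology@bonds
    out <- integer()
    cand <- which(at$element %in% c("C", "N") & !at$isH)
    if (!length(cand)) return(out)
    degree <- tabulate(c(bd$a1, bd$a2), nbins = nrow(at))
    maxOrder <- vapply(seq_len(nrow(at)), function(v) {
        o <- bd$order[bd$a1 == v | bd$a2 == v]
        if (length(o)) max(o) else 0L
    }, integer(1))
    cand <- cand[degree[cand] == 4L & maxOrder[cand] == 1L]
    if (!length(cand)) return(out)
    if (is.null(globalOrbits)) globalOrbits <- .autOrbits(topology)
    for (v in cand) {
        nb <- .neighbours(topology, v)
        if (sum(at$isH[nb]) >= 2L) next
        orb <- globalOrbits[nb]
        if (!anyDuplicated(orb)) {
            out <- c(out, v)
            next
        }
        stab <- .autOrbits(topology,
                           recolor = stats::setNames(9000L, as.character(v)))
        if (!anyDuplicated(stab[nb])) out <- c(out, v)
    }
    out
}

# Bond-path lengths between all atoms (number of bonds on the shortest path).
.bondDistances <- function(topology) {
    bd <- topology@bonds
    g <- igraph::make_empty_graph(n = nrow(topology@atoms), directed = FALSE)
    g <- igraph::add_edges(g, t(cbind(bd$a1, bd$a2)))
    igraph::distances(g)
}

#' Count tetrahedral stereocentres of a parsed structure
#'
#' Counts the tetrahedral stereocentres (feature 7, chiral centres) of a
#' single structural form: carbons or nitrogens with four single bonds whose
#' four substituent branches are pairwise non-equivalent under the molecular
#' graph automorphisms.  Perception is constitutional, so stereocentres count
#' whether or not the input SMILES carries a descriptor; double-bond
#' stereochemistry never counts.  For metabolites recorded as several
#' anomeric forms use \code{\link{stereocenterCount}} on the record, which
#' excludes the anomeric carbon.
#'
#' @param topology a \linkS4class{MolecularTopology}.
#' @return integer count.
#' @examples
#' countStereocenters(parseStructure("CCO"))                     # 0
#' countStereocenters(parseStructure("C[C@@H](O)C(O)=O"))        # 1 (lactic)
#' @export
countStereocenters <- function(topology) {
    stopifnot(is(topology, "MolecularTopology"))
    length(.perceiveStereocenters(topology))
}

# Anomeric carbons: sp3 carbons bonded to one hydroxyl oxygen and one ether
# oxygen.  Used to exclude the centre that differs between anomeric forms.
.anomericCarbons <- function(topology) {
    at <- topology@atoms
    which(vapply(seq_len(nrow(at)), function(v) {
        if (at$element[v] != "C" || at$isH[v]) return(FALSE)
        nb <- .neighbours(topology, v)
        ox <- nb[at$element[nb] == "O"]
        if (length(ox) != 2L) return(FALSE)
        hasH <- vapply(ox, function(o) any(at$isH[.neighbours(topology, o)]),
                       logical(1))
        isEther <- vapply(ox, function(o) {
            onb <- .neighbours(topology, o)
            sum(!at$isH[onb]) == 2L
        }, logical(1))
        any(hasH) && any(isEther & !hasH)
    }, logical(1)))
}

#' Stereocentre count of a metabolite record
#'
#' Feature 7 for a whole \linkS4class{MetaboliteRecord}.  For single-form
#' records this is \code{\link{countStereocenters}} of the structure; for
#' records carrying several anomeric forms the anomeric carbon, whose
#' configuration differs between the forms, is excluded from the count.
#'
#' @param record a \linkS4class{MetaboliteRecord}.
#' @return integer count.
#' @export
stereocenterCount <- function(record) {
    stopifnot(is(record, "MetaboliteRecord"))
    topo <- .topologyOf(record@forms[1])
    centres <- .perceiveStereocenters(topo)
    if (length(record@forms) > 1L)
        centres <- setdiff(centres, .anomericCarbons(topo))
    length(centres)
}
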