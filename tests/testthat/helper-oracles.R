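# Independent brute-force oracles, deliberately built on different machinery
# than the implementation they check.

# Bond-path distances by plain breadth-first search over an adjacency list
# (no igraph).
bfsDistances <- function(topo) {
    bd <- topo@bonds
    n <- nrow(topo@atoms)
    adj <- lapply(seq_len(n), function(v) c(bd$a2[bd$a1 == v],
                                            bd$a1[bd$a2 == v]))
    D <- matrix(Inf, n, n)
    for (s in seq_len(n)) {
        D[s, s] <- 0
        frontier <- s
        d <- 0
        while (length(frontier)) {
            d <- d + 1
            nxt <- unique(unlist(adj[frontier]))
            nxt <- nxt[!is.finite(D[s, nxt])]
            D[s, nxt] <- d
            frontier <- nxt
        }
    }
    D
}

# Constitutional substitution-test oracle: relabel each hydrogen in turn and
# compare canonical graph certificates.  Two hydrogens are constitutionally
# equivalent iff the relabelled graphs are isomorphic.  Returns an integer
# group id per hydrogen atom index.
constitutionalHOrbits <- function(topo) {
    at <- topo@atoms
    bd <- topo@bonds
    hIdx <- which(at$isH)
    base <- match(at$element, c("H", "C", "N", "O", "S", "F", "P"))
    # benzene rings written in Kekule notation: treat their bonds uniformly
    # (own detection: walk all closed 6-paths over C-C bonds)
    bondOrder <- bd$order
    ccBond <- at$element[bd$a1] == "C" & at$element[bd$a2] == "C"
    adj <- lapply(seq_len(nrow(at)), function(v)
        c(bd$a2[ccBond & bd$a1 == v], bd$a1[ccBond & bd$a2 == v]))
    bIdx <- function(u, v) which((bd$a1 == u & bd$a2 == v) |
                                 (bd$a1 == v & bd$a2 == u))[1]
    sixRings <- list()
    grow <- function(path) {
        for (w in adj[[path[length(path)]]]) {
            if (length(path) == 6L) {
                if (w == path[1] && path[2] < path[6])
                    sixRings[[length(sixRings) + 1L]] <<- path
            } else if (w > path[1] && !w %in% path) grow(c(path, w))
        }
    }
    for (s in which(at$element == "C")) grow(s)
    for (ring in sixRings) {
        e <- vapply(1:6, function(i) bIdx(ring[i], ring[i %% 6L + 1L]),
                    integer(1))
        o <- bd$order[e]
        if (setequal(o, 1:2) && all(abs(diff(o)) == 1L)) bondOrder[e] <- 4L
    }
    certificate <- function(h) {
        cols <- base
        cols[h] <- 99L
        g <- igraph::make_empty_graph(n = nrow(at) + nrow(bd),
                                      directed = FALSE)
        g <- igraph::add_edges(g, t(rbind(
            cbind(bd$a1, nrow(at) + seq_len(nrow(bd))),
            cbind(bd$a2, nrow(at) + seq_len(nrow(bd))))))
        cols <- c(cols, 200L + bondOrder)
        perm <- igraph::canonical_permutation(g, colors = cols)$labeling
        gp <- igraph::permute(g, perm)
        el <- igraph::as_edgelist(gp)
        paste(paste(sort(paste(pmin(el[, 1], el[, 2]),
                               pmax(el[, 1], el[, 2]), sep = "-")),
                    collapse = ";"),
              paste(cols[order(perm)], collapse = ","), sep = "|")
    }
    certs <- vapply(hIdx, certificate, character(1))
    setNames(match(certs, unique(certs)), hIdx)
}

# Exhaustive HMBC oracle: every (carbon, hydrogen) atom pair at bond
# distance 2 or 3, deduplicated by (carbon orbit, proton class).
hmbcOracle <- function(topo) {
    D <- bfsDistances(topo)
    pc <- protonClasses(topo)
    pc <- pc[!pc$exchangeable, , drop = FALSE]
    classOf <- rep(NA_character_, nrow(topo@atoms))
    for (i in seq_len(nrow(pc))) classOf[pc$members[[i]]] <- pc$label[i]
    orbitOf <- rep(NA_integer_, nrow(topo@atoms))
    for (k in seq_along(topo@carbonOrbits))
        orbitOf[topo@carbonOrbits[[k]]] <- k
    pairs <- character()
    for (cA in which(topo@atoms$element == "C")) {
        for (h in which(topo@atoms$isH)) {
            if (is.na(classOf[h])) next
            if (D[cA, h] %in% c(2, 3))
                pairs <- c(pairs, paste(orbitOf[cA], classOf[h]))
        }
    }
    length(unique(pairs))
}
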