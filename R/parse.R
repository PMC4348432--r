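# Structure parsing: SMILES/InChI -> MolecularTopology.
# Open Babel (via ChemmineOB) does the format work; the tokeniser keeps a
# map from input atoms to their SMILES tokens so that the substitution test
# can rewrite individual atoms later.

.monoisotopicMass <- c(H = 1L, B = 11L, C = 12L, N = 14L, O = 16L, F = 19L,
                       P = 31L, S = 32L, Cl = 35L, Br = 79L, I = 127L)

.organicSubset <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I",
                    "b", "c", "n", "o", "p", "s")

.parseError <- function(input, token, what) {
    stop(sprintf("cannot parse structure %s: %s near '%s'",
                 sQuote(input), what, token), call. = FALSE)
}

# Tokenise a SMILES string into atom tokens.  Returns a data.frame with one
# row per atom in written order: character offsets of the token, bracket
# fields (tag, explicit H count, charge) and the offset after any ring-bond
# digits that directly follow the token (insertion point for branches).
.tokenizeSmiles <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(chars)
    rows <- list()
    i <- 1L
    while (i <= n) {
        ch <- chars[i]
        if (ch == "[") {
            j <- i
            while (j <= n && chars[j] != "]") j <- j + 1L
            if (j > n) .parseError(s, "[", "unbalanced bracket")
            body <- substr(s, i + 1L, j - 1L)
            if (grepl("^[0-9]", body))
                .parseError(s, body, "isotope-labelled species are unsupported")
            if (grepl("\\.$|^\\.|\\*", body))
                .parseError(s, body, "wildcard atom")
            m <- regmatches(body, regexec(
                "^([A-Za-z][a-z]?)(@{1,2})?(H([0-9]*))?([+-][0-9]*|\\++|-+)?$",
                body))[[1]]
            if (!length(m)) .parseError(s, body, "unrecognised bracket atom")
            el <- m[2]
            tag <- m[3]
            hasH <- nzchar(m[4])
            nHexp <- if (!hasH) 0L else if (nzchar(m[5])) as.integer(m[5]) else 1L
            chg <- m[6]
            charge <- if (!nzchar(chg)) 0L
                else if (chg %in% c("+", "-")) ifelse(chg == "+", 1L, -1L)
                else if (grepl("^[+-][0-9]+$", chg))
                    as.integer(chg)
                else nchar(chg) * ifelse(substr(chg, 1L, 1L) == "+", 1L, -1L)
            rows[[length(rows) + 1L]] <- list(start = i, end = j, element = el,
                bracket = TRUE, tag = tag, nHexp = nHexp, charge = charge)
            i <- j + 1L
        } else if (i < n && substr(s, i, i + 1L) %in% c("Cl", "Br")) {
            rows[[length(rows) + 1L]] <- list(start = i, end = i + 1L,
                element = substr(s, i, i + 1L), bracket = FALSE, tag = "",
                nHexp = NA_integer_, charge = 0L)
            i <- i + 2L
        } else if (ch %in% .organicSubset) {
            rows[[length(rows) + 1L]] <- list(start = i, end = i,
                element = ch, bracket = FALSE, tag = "",
                nHexp = NA_integer_, charge = 0L)
            i <- i + 1L
        } else if (ch %in% c("(", ")", "-", "=", "#", ":", "/", "\\", ".")) {
            i <- i + 1L
        } else if (ch == "%") {
            i <- i + 3L
        } else if (ch %in% as.character(0:9)) {
            i <- i + 1L
        } else {
            .parseError(s, ch, "unexpected character")
        }
    }
    tok <- do.call(rbind, lapply(rows, as.data.frame))
    if (is.null(tok) || !nrow(tok)) .parseError(s, s, "no atoms found")
    # ring-bond digits (with optional preceding bond symbol) directly after
    # each atom token; branches inserted later must go after them
    tok$ringEnd <- tok$end
    tok$nRing <- 0L
    for (k in seq_len(nrow(tok))) {
        p <- tok$end[k] + 1L
        while (p <= n) {
            ch <- chars[p]
            if (ch %in% as.character(0:9)) {
                tok$ringEnd[k] <- p; tok$nRing[k] <- tok$nRing[k] + 1L
                p <- p + 1L
            } else if (ch == "%") {
                tok$ringEnd[k] <- p + 2L; tok$nRing[k] <- tok$nRing[k] + 1L
                p <- p + 3L
            } else if (ch %in% c("-", "=", "#", "/", "\\") && p < n &&
                       (chars[p + 1L] %in% as.character(0:9) ||
                        chars[p + 1L] == "%")) {
                p <- p + 1L
            } else break
        }
    }
    tok
}

.obConvert <- function(from, to, text) {
    out <- tryCatch(
        suppressWarnings(ChemmineOB::convertFormat(from, to, text)),
        error = function(e) "")
    if (!is.character(out) || !nzchar(out)) {
        .parseError(text, text, sprintf("Open Babel %s conversion failed", from))
    }
    out
}

# Canonical (stereo-aware) SMILES; used as the comparator of the
# substitution test.
.obCanonical <- function(smiles) {
    out <- .obConvert("SMI", "CAN", paste0(smiles, "\n"))
    sub("\\s.*$", "", trimws(out))
}

.parseV2000 <- function(sdf, input) {
    lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
    hdr <- grep("V2000", lines, fixed = TRUE)
    if (!length(hdr)) .parseError(input, input, "no structure block produced")
    h <- lines[hdr[1]]
    na <- as.integer(substr(h, 1L, 3L))
    nb <- as.integer(substr(h, 4L, 6L))
    atomLines <- lines[(hdr[1] + 1L):(hdr[1] + na)]
    bondLines <- if (nb > 0L) lines[(hdr[1] + na + 1L):(hdr[1] + na + nb)]
                 else character()
    element <- trimws(substr(atomLines, 32L, 34L))
    bonds <- data.frame(
        a1 = as.integer(substr(bondLines, 1L, 3L)),
        a2 = as.integer(substr(bondLines, 4L, 6L)),
        order = as.integer(substr(bondLines, 7L, 9L)))
    charge <- integer(na)
    for (cl in grep("^M  CHG", lines, value = TRUE)) {
        f <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "\\s+")[[1]])
        k <- f[1]
        for (q in seq_len(k)) charge[f[2L * q]] <- f[2L * q + 1L]
    }
    list(element = element, bonds = bonds, charge = charge)
}

#' Parse a structure line notation into a molecular topology
#'
#' Parses a SMILES (or InChI, converted on the fly) into a
#' \linkS4class{MolecularTopology} with explicit hydrogens, elemental counts,
#' nominal (most-abundant isotope) mass and perceived tetrahedral
#' stereocentres.
#'
#' @param lineNotation a single SMILES string, or an InChI string
#'   (\code{"InChI="} prefix).
#' @return a \linkS4class{MolecularTopology}.
#' @examples
#' topo <- parseStructure("CN")          # methylamine
#' nominalMass(topo)                     # 31 Da
#' @export
parseStructure <- function(lineNotation) {
    stopifnot(is.character(lineNotation), length(lineNotation) == 1L)
    smiles <- trimws(lineNotation)
    if (startsWith(smiles, "InChI=")) {
        smiles <- sub("\\s.*$", "",
                      trimws(.obConvert("INCHI", "SMI", paste0(smiles, "\n"))))
    }
    tokens <- .tokenizeSmiles(smiles)
    sdf <- .obConvert("SMI", "SDF", paste0(smiles, "\n"))
    # request explicit hydrogens
    sdfH <- tryCatch(
        suppressWarnings(ChemmineOB::convertFormat(
            "SMI", "SDF", paste0(smiles, "\n"),
            options = data.frame(names = "h", args = ""))),
        error = function(e) "")
    if (!nzchar(sdfH)) sdfH <- sdf
    mol <- .parseV2000(sdfH, smiles)
    heavy <- which(mol$element != "H")
    if (length(heavy) != nrow(tokens) ||
        !all(toupper(tokens$element) == toupper(mol$element[heavy])))
        .parseError(smiles, smiles, "atom order mismatch between parser passes")
    unknown <- setdiff(unique(mol$element), names(.monoisotopicMass))
    if (length(unknown))
        .parseError(smiles, unknown[1], "unsupported element")
    n <- length(mol$element)
    isH <- mol$element == "H"
    parent <- rep(NA_integer_, n)
    for (k in seq_len(nrow(mol$bonds))) {
        a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
        if (isH[a1] && !isH[a2]) parent[a1] <- a2
        if (isH[a2] && !isH[a1]) parent[a2] <- a1
    }
    atoms <- data.frame(element = mol$element, charge = mol$charge,
                        isH = isH, parent = parent,
                        exchangeable = NA)
    topo <- new("MolecularTopology", smiles = smiles, atoms = atoms,
                bonds = mol$bonds, tokens = tokens)
    topo@nStereocenters <- length(.perceiveStereocenters(topo))
    topo
}

#' @describeIn parseStructure number of hydrogen atoms (feature 1).
#' @param topology a \linkS4class{MolecularTopology}.
#' @export
hydrogenCount <- function(topology) sum(topology@atoms$isH)

#' @describeIn parseStructure number of carbon atoms (feature 2).
#' @export
carbonCount <- function(topology) sum(topology@atoms$element == "C")

#' @describeIn parseStructure number of heavy (non-hydrogen) atoms.
#' @export
heavyAtomCount <- function(topology) sum(!topology@atoms$isH)

#' @describeIn parseStructure counts of H, C, N, O and S atoms.
#' @export
elementCounts <- function(topology) {
    el <- topology@atoms$element
    c(nH = sum(el == "H"), nC = sum(el == "C"), nN = sum(el == "N"),
      nO = sum(el == "O"), nS = sum(el == "S"))
}

#' @describeIn parseStructure nominal mass in Da (most abundant isotopes).
#' @export
nominalMass <- function(topology) {
    sum(.monoisotopicMass[topology@atoms$element])
}
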