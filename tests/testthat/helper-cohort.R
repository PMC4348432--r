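# Shared fixtures: the cohort and its derived tables are computed once per
# test run (structure parsing and the substitution test dominate the cost).

.testCache <- new.env(parent = emptyenv())

cachedFixture <- function() {
    if (is.null(.testCache$records))
        .testCache$records <- loadFixture()
    .testCache$records
}

cachedProfileTable <- function() {
    if (is.null(.testCache$profile))
        .testCache$profile <- cohortProfileTable(cachedFixture())
    .testCache$profile
}

cachedTheoreticals <- function() {
    if (is.null(.testCache$theo))
        .testCache$theo <- lapply(cachedFixture(), theoreticalProfile)
    .testCache$theo
}

cachedObservations <- function() {
    if (is.null(.testCache$obs))
        .testCache$obs <- loadCohortObservations(cachedFixture())
    .testCache$obs
}

makeRecord <- function(id, forms, ...) {
    new("MetaboliteRecord", id = id, commonName = id, iupacName = "",
        hmdbAccession = "", classLabel = "", forms = forms, ...)
}

topoOf <- function(smiles) {
    protonEquivalenceClasses(classifyExchangeable(parseStructure(smiles)))
}

nonExchClasses <- function(smiles) {
    pc <- protonClasses(topoOf(smiles))
    pc[!pc$exchangeable, , drop = FALSE]
}
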