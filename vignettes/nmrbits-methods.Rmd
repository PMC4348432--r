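---
title: "Counting metabolite identification information in NMR spectra"
author: "nmrbits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting metabolite identification information in NMR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrbits)
```

## The problem

Untargeted NMR metabolomics routinely annotates dozens of urinary
metabolites by comparing 1D ^1^H and 2D COSY/HSQC/HMBC spectra with public
databases such as the HMDB, yet the standard annotation vocabulary offers
only a coarse split between "identified" (compared with an authentic
standard) and "putatively annotated" (everything else).  That split ignores
how much spectroscopic evidence was actually collected.  `nmrbits`
implements a quantitative alternative: count the *identification
information bits* a metabolite can theoretically display in ^1^H-detected
NMR, count the bits actually observed, and normalise by molecular size.

An information bit is one countable spectral feature: a ^1^H chemical
shift, a multiplet, a 2- or 3-bond H,H coupling constant, a second-order
flag, or a COSY/HSQC/HMBC cross-peak.  Bits accumulate over four nested
acquisition strategies: 1D ^1^H alone; plus COSY; plus HSQC; plus HMBC.
Three indices summarise them:

* **MIE** (metabolite identification efficiency) = bits / heavy atoms,
* **MICE** (metabolite identification carbon efficiency) = bits / carbons,
* **MIHF** (metabolite identification hydrogen fraction) =
  observed bits / theoretical bits.

MIE mirrors the ligand-efficiency idea from drug discovery; MICE is often
preferable because carbons carry nearly all non-exchanging protons.

## Theoretical counting rules

The theoretical counter applies these rules to a parsed structure:

1. Only non-exchanging protons count.  Carbon-bound protons and secondary
   amide N-H count; hydroxyl, thiol, amine, guanidino, aromatic-azole,
   urea and imide N-H protons exchange too fast in aqueous biofluids.
   The urea/imide refinement (an N-H is retained only when its single
   carbonyl neighbour binds no second nitrogen) goes slightly beyond the
   plain "amide" rule; it is what makes allantoin a single-singlet
   metabolite whose observed bits equal its theoretical maximum, and it
   keeps cytosine's ring N-H out of the count, both in line with what is
   seen in urine at pH 7.4.
2. One shift per proton equivalence class, and one multiplicity per
   resonance however complex the pattern (a triplet of septets is one
   multiplet); hence theoretical multiplicities equal theoretical shifts.
3. Couplings are unordered pairs of distinct classes joined by a 2-bond
   (geminal) or 3-bond (vicinal) path; the path may cross any heavy atom
   (amide H-N-C-H counts), but 4-bond and longer couplings never count
   theoretically.  COSY cross-peaks are counted once per coupled pair, so
   theoretical COSY equals theoretical couplings.
4. HSQC peaks are distinct (proton class, attached carbon orbit) pairs:
   diastereotopic methylene protons give two peaks, symmetry-equivalent
   carbons give one.
5. HMBC peaks are distinct (carbon orbit, proton class) pairs joined by a
   2- or 3-bond C-H path, through heteroatoms and quaternary carbons as
   well; cross-peaks between pseudo-equivalent groups (the methyls of
   trimethylamine) are real and count.
6. The second-order flag is set when chemically equivalent protons are
   magnetically non-equivalent -- detected topologically: some member of a
   class sits 2-3 bonds from an outside proton while another member does
   not (the AA'BB' pattern of para-disubstituted benzenes or putrescine).
   Second-order behaviour caused by accidental shift proximity needs
   actual shift values and is out of scope.
7. For reducing sugars both anomers are present in solution and both are
   counted: features are summed over the forms (the flag is OR-ed), while
   the MIE/MICE denominators always come from a single form.

## Proton topicity by substitution test

The scientific crux is deciding which protons share a chemical shift.
Homotopic and enantiotopic protons are isochronous; diastereotopic protons
are not.  `protonEquivalenceClasses()` implements the textbook
substitution test literally: replace a candidate hydrogen with a test
label (fluorine), give every centre that thereby becomes stereogenic a
definite configuration, and compare canonical stereo SMILES: two labelled
structures that are identical or enantiomeric mean equivalent protons;
diastereomeric structures mean split classes.  Constitutional symmetry is
handled by graph automorphism orbits (BLISS, via igraph) with bond orders
encoded as coloured subdivision vertices; benzene rings written in Kekulé
notation are detected and symmetrised so the alternation artefact cannot
break ring symmetry.

Two conventions matter:

* For a geminal pair the two labelled molecules are written with opposite
  descriptors at the labelled carbon -- they are exactly the two epimers.
* A remote centre that becomes stereogenic receives the same fixed
  descriptor in every variant, which reproduces the geometric fact that
  the remote arrangement is unchanged by the choice of geminal proton.

This machinery reproduces the delicate cases: tartrate's C~2~-symmetric
methines merge (one singlet) while glucarate's pseudo-palindromic methines
split four ways; mannitol keeps two methylene classes of two protons;
citrate's prochiral methylenes split even though the molecule is achiral
(the well-known AB quartet); isopropyl methyls split in chiral
2-isopropylmalate but not in achiral ketoleucine; a trimethylammonium
group never splits.  Because the test needs definite configurations, the
shipped structures carry full stereo descriptors; where the source data
print none (methylsuccinic, isocitric, acetoin, allantoin) one enantiomer
was fixed -- every counted quantity is invariant under global mirror
symmetry, so the choice is immaterial.

Stereocentres themselves (the chirality feature used to partition the
cohort) are perceived constitutionally: a tetrahedral C or N whose four
branches are pairwise non-equivalent under automorphisms fixing the atom.
For multi-anomer records the anomeric carbon -- whose configuration is the
thing that differs between the forms -- is excluded from the count, which
gives fucose four rather than five chiral centres and a cohort range of
0-5.

Known limitations: pseudo-asymmetric arrangements and meso cases beyond
those in the cohort are handled only as far as the descriptor conventions
above are valid; per-atom exchangeability and full feature-count overrides
exist for curation when the structural rules are wrong for an unusual
molecule.

## Observed bits, matching and the confidence call

Experimental evidence enters as peak lists with assignment labels.  The
tally counts one bit per distinct assigned resonance, per read
multiplicity, per measured J, and per deduplicated 2D cross-peak.
Long-range (≥4-bond) COSY connectivities and heteronuclear couplings
(e.g. choline's ^2^J(^14^N,^1^H) of about 0.6 Hz) are stored as *evidence
items*: they never add bits but can be diagnostic.

Matching against reference data pairs values by assignment label, never by
numeric proximity (crowded regions make nearest-value pairing unsafe), and
applies the guideline tolerances ±0.03 ppm (^1^H), ±0.5 ppm (^13^C) and
±0.2 Hz (J); boundary values pass.  Coverage requires every annotated
molecular fragment to carry at least one observed bit -- l-carnitine, with
all of its observed information on the trimethylammonium side, fails the
carboxylate fragment and stays putative no matter how good its peaks are.

The confidence call at the 1D+COSY+HSQC reference level is:

> confident ⇔ match acceptable ∧ coverage complete ∧
> (MICE ≥ 1 ∨ MIE > 0.5 ∨ any HSQC/HMBC peak ∨ diagnostic evidence).

The thresholds are configurable arguments, not constants.  The guideline
phrase "MICE ideally ≥ 1 and/or MIE > 0.5" leaves open whether either
clause suffices on its own without orthogonal data; the OR-combination
used here is the one consistent with all the low-score adjudications in
the study data (three putative calls: methylsuccinate, l-carnitine,
N-propionylglycine) and is therefore the default, documented rather than
asserted as the only reading.

```{r example}
records <- loadFixture()
obs <- loadCohortObservations(records)
keto <- scoreMetabolite(records[["ketoleucine"]], obs[["ketoleucine"]])
keto$scores$mice <- reportRound(keto$scores$mice)
keto$scores[, c("level", "bits", "mice")]
keto$call@label
```

## The cohort fixture and the synthetic generator

The shipped table holds the 75 urinary metabolites of the study cohort
with curated SMILES (both anomers for xylose, fucose, glucose and
glucuronic acid), compound classes and well-established HMDB accessions.
One naming conflict was resolved during curation: the isovaleric acid row
is 3-methylbutanoic acid, as its common name and the isovalerylglycine
acyl group imply.  On this fixture the implementation reproduces the
published cohort closely -- mean nominal mass 126.7 ± 46.6 Da, carbons
1-13 (mean 4.9), 24 chiral vs 51 achiral members, theoretical 1D bits
ranging 2-42 with mean ≈ 9.2, and exactly five metabolites with
theoretical MIE < 0.5 of which guanidoacetate alone keeps MICE = 1.0.
Cohort bit totals land within ~3% of the published 688/849/1099/1824;
the residual differences trace to manual judgements the published
aggregate does not specify (which N-H were counted, HMBC paths through
ring oxygens, second-order flags), and `cohortDiffReport()` prints the
per-metabolite listing for inspection rather than asserting equality.

The observation fixture mixes the peak lists printed for the worked
examples and the thirteen low-score metabolites with
reconstructed-from-theory sets for the remaining metabolites (labelled
`reconstructed_from_theory`); the reconstruction gives those metabolites
their full 1D/COSY/HSQC complement, consistent with the study's report
that only thirteen members fall below the score thresholds.

`simulateObservations()` emulates the loss of information in real
biofluid spectra: every theoretical bit is retained independently with a
per-family probability, default 0.68 (shifts and multiplicities, the
second-order flag riding with the shifts), 0.58 (couplings and COSY),
0.52 (HSQC) and 0.113 (HMBC) -- the cohort-level observed/theoretical
ratios.  A multiplicity may survive without its shift bit, as multiplets
were read from 2D J-resolved spectra in practice; making multiplicities
conditional on shifts would depress the 1D totals well below the observed
467 bits.  Bits are independent: chemical-shift crowding, which correlates
losses within spectral regions, is deliberately not modelled, so the
simulator validates counting arithmetic and cohort-scale retention, not
peak-overlap behaviour in real spectra.  Simulations are reproducible: the
per-metabolite stream is seeded by the model seed plus a stable hash of
the metabolite id.

## Numerical conventions and problem sizes

Reported MIE/MICE round half away from zero to one decimal (0.75 → 0.8,
25/6 → 4.2); raw values are kept internally and the ratio identity
MICE/MIE = heavy atoms/carbons holds to machine precision.  Matching
comparisons add a 10^-9^ guard so decimal tolerances behave exactly at
their boundaries.  Zero-variance group comparisons return p = 1 by
convention; group tests report both Welch and pooled t statistics because
the original spreadsheet provenance leaves the variant ambiguous (the
chirality contrasts are significant under both).  The test suite runs the
whole 75-metabolite cohort (cached after the first pass), the brute-force
substitution oracle on all fixture molecules with at most 14 heavy atoms,
and 20 seeds of the cohort-scale simulator -- sizes chosen so the full
suite completes in about a minute on one core while still exercising
every molecule in the cohort.
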