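---
title: "Designing and evaluating species-diagnostic PCR primers from DNA barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating species-diagnostic PCR primers from DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagprimer)
```

## The problem

Identifying a small insect — a 1-mm egg parasitoid, say — by morphology
requires expert training. A species-diagnostic PCR sidesteps this: primers
are designed so that they amplify a product only from the target species'
DNA, and presence/absence of a band on a gel becomes the identification.
The standard substrate is the 5' "barcode" region of the mitochondrial
cytochrome c oxidase subunit 1 (CO1) gene, which diverges quickly enough
between species to carry fixed differences, and slowly enough within
species that the assay generalizes across populations.

`diagprimer` implements the computational side of building such an assay:

1. find **diagnostic sites** — alignment columns where every target
   sequence carries one base and the confounder species carry another;
2. design primer candidates whose **3' terminus sits on a diagnostic
   site**, because a primer/template mismatch at or near the extension end
   is what actually blocks amplification;
3. screen candidate pairs by **mismatch-tolerant in-silico PCR** against a
   panel of confounders;
4. catalogue the **haplotypes** of the target species and predict, per
   haplotype and geographic region, whether the assay will amplify them.

The canonical worked example shipped with the package is the published
*Trissolcus japonicus* (samurai wasp) pair TJ234F/TJ460R, whose names
encode the sense-strand 5' coordinates 234 and 460 on the partial CO1
barcode, giving the theoretical 227-bp product
(460 &minus; 234 + 1 = 227).

## Coordinates and anchoring

All coordinates are 1-based, inclusive, on the sense strand of a
designated ungapped reference. A reverse primer is reported at the
sense-strand coordinate of its 5' end (the larger coordinate of its
footprint), which is the convention that makes primer names like "460R"
and the product arithmetic line up.

Primer binding sites are found by exhaustive ungapped sliding-window
search on both strands, minimizing mismatches; ties break by proximity to
an expected coordinate, then smallest start, then sense before antisense.
The CO1 barcode is protein-coding and effectively indel-free across the
taxa this package targets, which is why gapped (indel-tolerant) binding is
deliberately out of scope. Partial records are allowed to overhang the
footprint: uncovered positions are flagged *missing*, counted toward the
total mismatch count (a partial footprint is not evidence of binding) but
excluded from the 3'-window count, so a truncated GenBank record can never
fabricate 3'-terminal evidence. A template IUPAC ambiguity code that
includes the primer base anchors as a match but is flagged *ambiguous*; it
blocks a PERFECT call without counting as a mismatch — conservative in
both directions.

## Mismatch weighting at the 3' terminus

Not all terminal mismatches inhibit equally. Following the
mismatch-inhibition literature, doublets are written X/Y = (primer 3'
base, template base read 3'&rarr;5' opposite it). The default table ranks
G/A and C/C as the strongest extension inhibitors (weight 1.0), then T/C,
T/G, T/T, G/G, C/A (0.6), then the remaining non-complementary doublets
(0.3); Watson–Crick matches are 0. The *ordering* is the scientific
content; the magnitudes are explicit, config-overridable knobs — the
source literature provides a ranking, not calibrated values.

Pairs are ranked by the sum over confounders of the *minimum* of the two
primers' terminal weights: a pair is only as discriminating as its weaker
terminus against that confounder, so this score prefers designs where
*both* primers discriminate, rather than designs relying on a single
strong terminus. Ties break by smaller Tm difference, shorter product,
then coordinates, giving a deterministic total order.

## Melting temperature

Two estimators are provided. The Wallace rule, 2(A+T) + 4(G+C), is kept
for transparency on long AT-rich primers. The default is unified
nearest-neighbor thermodynamics with the entropic monovalent-salt
correction 0.368 (N&minus;1) ln[Na+] and a C~T~/4 duplex-formation term,
under default conditions of 50 mM Na+ and 0.25 µM oligo. Implementation
was verified against an independent unified-NN implementation to within
0.01 °C on AT-rich and mixed-composition oligos; the tests assert 0.5 °C.

Diagnostic regions of AT-rich barcodes force a design trade-off: to reach
a workable annealing temperature the primers must be long. Candidate
enumeration therefore grows each primer 5'-ward from the minimum length
until its Tm *enters* the constraint window (overshooting the window stops
the search, since further extension only warms the duplex). The default Tm
window is 48–62 °C: under the package's NN conditions the published
30/31-nt AT-rich diagnostic primers estimate near 50 °C, and bench
optimization of such assays typically sweeps annealing gradients of
48–60 °C, so a 55 °C floor would paradoxically exclude the very primers
the workflow is modeled on. The suggested annealing temperature,
min(pair Tm) &minus; 5 °C, is reported but never enforced — the bench
gradient remains the authority.

Default primer lengths are 18–34 nt (enveloping the published 30/31-nt
primers), amplicons 100–500 nt, pair ΔTm ≤ 5 °C.

## Amplification calls

Each template receives one of four categories:

* **PERFECT** — zero mismatches and zero ambiguities over both
  footprints. This is what "the primers match" means in the regional
  summaries; nothing weaker is counted as matched.
* **PROBABLE** — mismatches exist but none within the 3'-terminal window
  of either primer (e.g. a single internal mismatch 6 nt from the reverse
  3' end); amplification is plausible but unvalidated.
* **UNLIKELY** — at least one 3'-window mismatch; such templates risk
  false negatives.
* **NON_TARGET** — either primer shows ≥ 4 total mismatches with ≥ 2 in
  its 3' window (the rejection rule of Primer-BLAST-style specificity
  screening), or the two binding sites are orientation-inconsistent. The
  rule is applied per primer because amplification requires both primers
  to extend.

The 3' window is 5 nt by default (the convention of the specificity
screening tools this mirrors; the literature says "at the 3' end" without
committing to a width) and is configurable, as are both rejection
thresholds. Categories are monotone: adding a mismatch to a footprint can
never move a call toward PERFECT — this is asserted property-style in the
test suite over randomized perturbations.

## Haplotype catalogue

Records are first trimmed to the intersection of their coverage intervals
on the reference (public barcode submissions differ in length; comparing
haplotypes requires comparing the same stretch). Haplotypes are exact
deduplicates of the trimmed sequences; records containing ambiguity codes
are reported as unassignable rather than forced into a bin. Known
haplotype names are assigned only on a full match of that name's marker
set, supplied as a user TSV — published marker tables live in
supplementary material and are deliberately not hard-coded; a haplotype
matching two marker sets is treated as an invalid table, and novel
haplotypes continue the numbering in order of first observation.

The haplotype network is a minimum spanning tree over pairwise Hamming
distances (Kruskal's algorithm; edges sorted by weight, then
lexicographic node names, a documented deterministic tie-break). A
median-joining network, the usual choice of GUI tools, is a non-goal: at
typical intraspecific distances of one to a few substitutions the MST
reproduces the same topology class while being exactly testable — the
suite checks its total weight against a brute-force enumeration of all
spanning trees at small n and against an independent graph library.

## The synthetic-panel generator

Real panels cannot ship with the package, so all end-to-end validation
runs on simulated panels with planted truth. The generator emulates the
structure of a design panel for an AT-rich barcode:

* a 658-nt reference at GC 0.25 (the barcode amplicon length and the
  AT-richness typical of the diagnostic region);
* three target haplotypes of 5/3/2 records differing at two or three
  internal sites — mimicking a target species with a dominant haplotype
  plus minor variants;
* eight confounder species, two records each, at 0.10 substitutions/site
  from the reference (typical congeneric CO1 divergence), with a small
  within-species rate (0.002) so species show more than one mismatch
  pattern, as real panels do;
* two planted diagnostic sites, positioned so that a forward primer
  ending on the first meets every confounder with a G/A doublet and a
  reverse primer ending on the second with a C/C doublet — the planted
  sites sit inside candidate primer windows, as they must for the design
  step to find them.

One explicit seed governs every draw; the same seed gives byte-identical
panels. The generator writes a truth table (planted sites, haplotype
memberships, and expected amplification calls computed by direct
character comparison at the known footprint coordinates — a code path
independent of the sliding-window search it validates).

What the simulator does *not* emulate: codon structure and
transition/transversion bias, indels, sequencing error, length
heterogeneity of database submissions (exercised separately via explicit
truncation in tests), and phylogenetic correlation among confounders
(each species is drawn independently from the reference). Passing tests
on simulated panels therefore demonstrate the correctness of the
machinery under the stated generative model, not the field performance of
any particular assay.

## Numerical and degenerate-input choices

* Anchoring requires a minimum primer/template overlap of 10 nt;
  anything shorter is not a meaningful binding-site hypothesis.
* Raw panels must be ungapped; gaps are only accepted in alignment
  context, and a gap under a footprint counts as a mismatch of its own
  category ("gap"), displayed as a dash.
* 'U' on input maps to 'T' (RNA-typed submissions occur in public
  databases); any other non-IUPAC character is a parse error with the
  offending line.
* Empty candidate lists and empty pair rankings are results with a
  diagnostics note, not errors — a panel with no diagnostic sites is a
  legitimate scientific outcome.
* Tm estimation is restricted to 8–60 nt, the validity envelope of the
  parameterization.
* Problem sizes in the test suite were chosen for exactness: brute-force
  oracles cover all offsets (anchoring), all columns (diagnostic sites),
  and all spanning trees (n ≤ 7); the simulated panels are 26 records of
  658 nt.

## Known limitations

* No hairpin/self-dimer screening and no divalent-cation Tm correction;
  candidates passing the in-silico screen still need bench validation.
* The rejection rule predicts *non*-amplification conservatively; between
  PERFECT and NON_TARGET the PROBABLE/UNLIKELY bands are qualitative.
* Ungapped anchoring will mis-place footprints on templates with genuine
  indels inside the binding site (not expected for CO1 across close
  relatives, but possible for distant taxa).
* Degenerate-base primers are never generated; the modeled workflow uses
  unambiguous primers.
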