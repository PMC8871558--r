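---
title: "Detecting conserved signature indels in protein alignments"
author: "CSIscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved signature indels in protein alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CSIscan)
```

## The marker and the model

A conserved signature indel (CSI) is a fixed-length insertion or deletion
inside a conserved region of a protein that is shared by (essentially) all
members of a monophyletic group and absent outside it. Because even a one
amino-acid indel requires an in-frame three-base-pair genetic change at a
specific position, such events are rare and discrete: when one is found at
the same position in a phylogenetically coherent set of species, the most
parsimonious explanation is a single event in their common ancestor,
inherited vertically. CSIs therefore behave as molecular synapomorphies, and
— unlike tree topologies — they are largely insensitive to alignment and
model choices outside the signature region. Comparing the indel state of
outgroup species polarizes the event: if outgroups carry residues where the
clade has a gap, the clade suffered a deletion; in the mirrored case, an
insertion.

CSIscan turns the screening protocol used in comparative-genomic surveys of
this kind into an explicit, testable computation. The pipeline
(`detectCsis()`) runs five stages:

1. **Candidate enumeration** (`findIndelCandidates()`). Every maximal run of
   alignment columns with one constant, nonempty, proper set of gapped taxa
   is a candidate. Ragged patterns — where the gap set changes inside the
   run — split into several candidates and are never merged.
2. **Crisp-boundary filter.** A fixed-length shared indel requires all
   gapped taxa to resume residues immediately outside the interval. A
   candidate adjacent to further gaps in its own gap-side taxa is a fragment
   of a length-variable (ragged) pattern: length variation among carriers
   means the events are not homologous, so the candidate is discarded. This
   is the operational form of the fixed-length/shared-boundary requirement;
   without it, the clade-covering core of a ragged pattern would survive the
   remaining filters.
3. **Flank conservation** (`assessFlanks()`). Both sides must show at least
   `minConservedFlank` (default 5) conserved columns within `flankWindow`
   (default 45) columns of the indel. Indels outside conserved neighborhoods
   do not make reliable markers, because their alignment is itself
   uncertain.
4. **Specificity classification** (`classifySpecificity()`). Both sides of
   the candidate (gapped taxa; residue-bearing taxa) are tested against
   every candidate clade: the side must contain all clade members present up
   to `maxExceptions` (default 1), carry at most `maxForeign` (default 0)
   non-clade, non-outgroup taxa, and reach the clade's carrier minimum
   (default 3 — markers present in only one or two isolated species are not
   pursued). A side containing the (near-)unanimous outgroups is rejected
   outright: its taxa share the ancestral state, and shared ancestral states
   are plesiomorphies, not signatures. Among passing (side, clade) pairs the
   smallest clade wins; a tie between distinct clades of equal size is
   ambiguous and rejected with a log message.
5. **Polarity and coordinates** (`inferPolarity()`,
   `mapToReferenceCoords()`, `extractQueryRegion()`). Polarity is read off
   the outgroup states when at least `outgroupUnanimity` (default 0.9) of
   the outgroups present agree; mixed outgroups leave it undetermined
   rather than majority-voted, since shared indels in unrelated taxa can
   arise from homoplasy. Coordinates are reported on a reference sequence in
   1-based ungapped residue positions covering the displayed region (the
   indel plus the required conserved flank columns on each side), and an
   ungapped query region (indel ± 60 residues by default, within the
   conventional 50–100 range) is exported for external homology searches —
   the package performs no network searches itself.

### What "conserved" means here

The surveys that motivate this package treat flank conservation visually and
never quantify it. CSIscan declares a column conserved when at least 80% of
its non-gap, non-X rows share the majority residue and at most 10% of all
rows are gapped; both thresholds are parameters (`detectionParams()`). The
figures accompanying published CSIs show near-identity flanks, which these
defaults reproduce; identity-based conservation (no similarity matrices) is
deliberate, matching how the signature figures are read. The flank rule's
"4–5 conserved in the adjacent 40–50" is implemented per side (the stronger
reading of "flanked on both sides"), with the defaults at the upper ends
(5 of 45).

Two small conventions worth knowing: `X` counts as a mismatch to every
residue and is excluded from conservation majorities; and per-clade carrier
minima can be lowered for small clades — `gliresDetectionParams()` ships the
profile used throughout this package, which lowers the minimum to 2 for
Castorimorpha, a suborder with only two sequenced members.

## The signature figure

`renderSignature()` reproduces the classic signature-file layout: the
reference residues on the top line, every other row showing `-` where it
matches the top line, the residue letter where it differs, and a blank where
it is gapped; rows grouped into clade blocks (carriers first, then the other
in-group clades, then outgroups) with the indel columns highlighted. The
encoding is lossless — `signatureSlice()` reconstructs the alignment slice
byte-for-byte — and a strict-ASCII mode uses `.` for identity to avoid any
dash/en-dash ambiguity in plain text.

## The supermatrix tree stage

`supermatrixTree()` provides the companion phylogeny at desk scale:
per-protein alignments are concatenated with gap fill for missing taxa
(`concatenateAlignments()`), poorly conserved blocks are removed by a
simplified three-rule trimmer in the Gblocks tradition (`trimBlocks()`:
majority fraction above 0.5 = conserved, 0.85 = highly conserved;
nonconserved runs longer than 8 removed; residual blocks trimmed to highly
conserved ends and kept at length ≥ 10; gap-containing columns nonconserved
by default), columns under 95% site coverage are dropped
(`filterSiteCoverage()`, applied after trimming), and a neighbor-joining
tree is built on Poisson-corrected distances
(d = −ln(1 − p) over pairwise-ungapped columns, `poissonDistance()`) with
column-bootstrap support (`bootstrapSupport()`) and outgroup rooting at the
midpoint of the subtending edge (`rootTree()`). Neighbor joining on
corrected distances is an explicit desk-scale stand-in for maximum
likelihood: it is consistent on additive matrices (the tests verify exact
recovery), runs in seconds, and reproduces clade structure well at these
divergences, but its topologies and supports are not claimed to reproduce
any published ML tree. Negative NJ branch lengths are clamped to zero with a
log entry. The whole stage is deterministic: one seed gives a byte-identical
newick string.

## The synthetic scenario: what it emulates and what it does not

`generateScenario()` builds a fixed 35-taxon species tree shaped like the
Glires surveys: 30 in-group taxa — the four Rodentia suborders (Myomorpha
13, with Muridae/Cricetidae/Spalacidae nested in Muroidea plus a lone
Dipodoidea lineage, *Jaculus jaculus*; Sciuromorpha 6; Hystricomorpha 5;
Castorimorpha 2) and Lagomorpha 4 — plus five Euarchonta outgroups. Families
are 300 residues long; each carries 0–2 clade-ancestral planted indels
(lengths 1–5, biased short), substitutions are applied per branch at
probability 0.05 per site (the upper end of what the screening conditions
tolerate), and half the sites are constrained (never substituted), which
guarantees conserved flanks the way real single-copy conserved proteins do.
Decoys appear at 15% frequency each: ragged decoys (carrier lengths differ
by one) that a correct detector must split and discard, and homoplastic
decoys (the same indel planted independently on one non-clade terminal
branch) that specificity must reject. One planted event in ten carries a
secondarily lacking lineage — the *Jaculus jaculus* pattern — which must
surface as a named exception.

The simulator emits the true alignment directly: there is no realignment
step, which isolates detection behavior from aligner artifacts (degap the
FASTA output and realign externally if aligner robustness is the question).
Substitutions are uniform over the 19 alternative residues with a constant
per-branch probability — no exchangeability matrix, no rate heterogeneity,
no branch-length proportionality — because identity-based conservation only
needs to be stressed, not modeled realistically. Consequently, perfect
precision and recall on this scenario show that the screening logic is
implemented correctly under its own assumptions; they say nothing about
alignment error, rate variation, or paralogy in real data, which the
published protocol handles upstream (alignment construction, paralog
curation) and downstream (homology searches over the query regions).

Two constructed ambiguities are deliberately excluded from planted truth,
because no detector could resolve them: an event whose carrier set, after a
loss, coincides exactly with a different candidate clade (on this taxonomy,
Myomorpha minus its sole Dipodoidea lineage *is* Muroidea), and a
homoplastic decoy whose extra carrier completes another candidate clade.
The smallest-consistent-clade rule makes the package's choice in such cases
explicit and logged, but the generator does not score it.

Problem sizes in the shipped tests were chosen to keep the default suite
fast while exercising every rule: oracle-equivalence checks run on ≥ 50
random instances per operation (alignments up to 8 × 120, matrices 6 × 200),
planted-event recovery on 50-family (acceptance) and 200-family (property)
scenarios, NJ consistency on 100 random 5–8 leaf trees, and rendering
losslessness on 50 planted fixtures.

## Numerical and degenerate-input choices

* Majority-residue ties in a column profile break alphabetically
  (deterministic output).
* Columns with no informative rows (all gap or `X`) get majority fraction 0
  and are never conserved.
* Flank windows are clipped at alignment edges; a terminal gap run can never
  pass the flank rule on its open side.
* The reference taxon for coordinates defaults to the first alignment row —
  carriers preferred — with residues throughout the displayed flanks; a
  reference gapped across the whole displayed region is an error.
* `scoreDetection()` reports precision 1.0 with a zero-denominator flag when
  there are no calls at all (documented convention).
* Bootstrap supports annotate internal-node labels; trivial splits get empty
  labels. Rooting preserves supports by re-matching unrooted bipartitions,
  which rooting cannot change.
* All user-facing coordinates are 1-based inclusive; internal column
  arithmetic is 0-based half-open.

## The packaged catalog

`loadCatalog()` ships the 41 published rodent/Glires CSIs (7 for
Glires/Rodentia/Lagomorpha-level clades, 24 for Rodentia suborders, 10 for
Myomorpha families) transcribed verbatim, keyed by (accession, location).
Known internal inconsistencies of the source are preserved and flagged, not
corrected: the Rodentia signature is stored with the tabulated size of 28 aa
and a note that the running text calls it 29 aa, and one location printed as
"1326-28" is kept as printed. Composite specificities ("Myomorpha and
Castorimorpha", "Muridae and Cricetidae", "Glires and Scandentia") are
single labels and are never double-counted into their components —
`tallySummary()` therefore always conserves the grand total.

## Known limitations

* Specificity semantics depend on the candidate-clade list: clades not
  declared in the partition cannot be assigned (there is, for example, no
  combined "Myomorpha and Castorimorpha" candidate in the shipped config).
* The outgroup-state rule needs outgroups in the alignment; without them,
  polarity is undetermined and plesiomorphic sides cannot be screened out.
* The trimmer is a three-rule simplification, not a Gblocks reimplementation
  bug-for-bug; its report makes every kept interval auditable instead.
* Distances are Poisson-corrected identity distances; for deep divergences
  where saturation matters, build the tree elsewhere and use this stage only
  for the screening pipeline's bookkeeping.
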