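---
title: "Desk-scale characterization of a vertebrate mitogenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale characterization of a vertebrate mitogenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mitoray` implements, as one reusable pipeline, the set of analyses that
make up a typical complete-mitogenome description of a vertebrate — here
modelled on the mitogenome of the Xingu River freshwater stingray
*Potamotrygon leopoldi* (GenBank OR896919, 17,504 bp): annotation
validation, base composition and strand skews, codon usage, control-region
tandem repeats, gene-order comparison, a pairwise dN/dS screen, and a
distance-based phylogeny with a monophyly test. A synthetic-genome
generator and a tree-guided sequence evolver provide ground truth for
every stage, so the whole pipeline runs and is tested without downloading
a single record. This vignette explains the models behind each stage, the
parameters that matter, and the choices made where the design was open.

## Coordinates and annotation validation

All coordinates are 1-based inclusive on the heavy strand, end to end;
converters to 0-based half-open conventions exist only at format
boundaries (GenBank/FASTA I/O). Records are circular; a feature may wrap
the origin, which is flagged by `stop < start`.

`validate_annotation()` treats the coordinates as the single source of
truth: each feature's length is recomputed as `stop - start + 1`, the
spacer to the next feature as `start(next) - stop - 1` (negative values
are overlaps), and every row whose *printed* length or spacer disagrees
with this arithmetic is flagged — never corrected. This matters for the
packaged *P. leopoldi* table, which is internally inconsistent in ways a
reader should see rather than have papered over:

* five rows print a length that contradicts their own coordinates
  (ATP6 683 vs 684; tRNA-Ser 72 vs 67; tRNA-Glu 69 vs 79; tRNA-Pro 70 vs
  43; D-loop 1810 vs 1811);
* five rows print an intergenic spacer that contradicts the coordinates
  (tRNA-Asn, tRNA-Ser, ND6, tRNA-Thr, tRNA-Pro);
* three PCG totals circulate: the coordinate-computed 11,435 bp, the
  printed length column's 11,434 bp, and the running text's 11,444 bp.
  The validator reports the first two and downstream statistics use only
  coordinate-computed values.

The coordinate arithmetic also fixes the complete-codon count at 3,811
(the sum of `floor(length/3)` over the 13 PCGs), which happens to equal
the figure the source text reports.

## Composition and strand skews

For any region, `composition_profile()` counts A/C/G/T (N is tallied
separately and excluded from every denominator) and computes

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C}.$$

Skews are stored at full precision; two-decimal rendering (round half to
even) happens only in display code. `composition_from_percent()` applies
the same formulas to printed percentage tables, which is how the package
audits published values: the *P. leopoldi* whole-genome percentages give
AT content 56.73% and AT skew 0.1394, but the same numbers give GC skew
+0.406 while the source reports −0.40 and describes a cytosine excess —
an internal sign inconsistency (consistent with a C/G column swap) that
the package flags (`gc_sign_consistent = FALSE`) and deliberately does
not resolve. The control-region percentages (C 24.30 > G 12.24) do give a
negative skew.

## Codon usage: translation table 2, RSCU, ENc

The organisms force NCBI translation table 2 (vertebrate mitochondrial):
ATA = Met, TGA = Trp, AGA/AGG = stop. Under this code there are 60 sense
codons in 12 two-fold, 6 four-fold (Val, Pro, Thr, Ala, Arg, Gly) and 2
six-fold (Leu, Ser) families — no single-codon amino acid and no
three-fold family (isoleucine, three-fold under the standard code, is
two-fold here).

Codon extraction reverse-complements light-strand genes, splits on
complete codons, and records a trailing 1–2 nt as an incomplete stop in
the customary `T(AA)` / `TA(A)` notation; incomplete stops are excluded
from all counts. Start codons are counted as ordinary codons (a GTG start
lands in the Val family) while being tabulated separately; stop codons
are excluded from RSCU/ENc input.

RSCU is the codon count divided by its family's mean count, so values sum
to the family degeneracy. ENc follows Wright's estimator: per family with
total usage $n \ge 2$, homozygosity $F = (n\sum p_i^2 - 1)/(n-1)$; ENc is
the sum over degeneracy classes of (families in class) / (mean class
$F$). Families with undefined $F$ are imputed their class mean; an empty
class falls back to the overall mean $F$; and a guard replaces a
non-positive class mean (possible on tiny balanced counts) by the uniform
value $1/k$. One consequence of the code's family structure deserves
emphasis: **the uniform-usage ceiling of ENc under translation table 2 is
60**, not the familiar 61 of the standard code, because the two standard
single-codon amino acids do not exist here; the one-codon-per-family
floor remains 20 (= 12 + 6 + 2 families). Reported values are clamped at
61 so the conventional [20, 61] band always contains them.

## Tandem repeats in the control region

`find_tandem_repeats()` is a seed-and-extend detector. Candidate
(period, locus) pairs come from the spacing of recurring 5-mers (k = 5
detects both a 20 bp and a 128 bp class at desk scale; spurious
single-spacing candidates are discarded unless the period is short).
Extension aligns the neighborhood, without gaps, against a period-phased
column-majority consensus seeded from the two copies at the anchor; the
reported span is the maximal-scoring subarray, refined twice by refitting
the consensus on the current span. Scoring uses the customary weights
match +2, mismatch −7, and the published minimum reporting score of 30 is
the default threshold. Consensus ties break alphabetically and copy
numbers are fractional (span / period), so output is deterministic.
Overlapping hits of one locus reduce to a single period, with one
refinement: a fundamental period beats its own harmonic (a period-60 call
over a 20 bp array) whenever it scores at least 70% of the harmonic's
score, since a true harmonic's fundamental explains nearly the same span
while a spurious sub-period of a genuine long repeat scores far below it.
The detector is gapless — the generator plants substitutions, not indels,
and the exhaustive test oracle is likewise (period, phase)-exhaustive;
reproducing the probabilistic indel model of the published
tandem-repeat tool is out of scope.

## Gene order and breakpoints

`gene_order()` canonicalizes labels (COXI → COX1, 12S rRNA → RRNS, …),
disambiguates the duplicated Leu/Ser tRNAs by coordinate rank, drops the
CR, and rotation-normalizes the circle to start at tRNA-Phe.
`compare_orders()` counts breakpoints as unordered circular adjacencies
present in one order but not the other, restricted to the shared gene
set; strand changes are tallied separately, so a gene flipped in place is
0 breakpoints + 1 strand disagreement. Two orders are `identical` only
when labels and strands all agree after rotation. Excising a gene and
reinserting it elsewhere costs 3 breakpoints; swapping two neighbours
costs 2; inversion distances (Hannenhalli–Pevzner) are out of scope.

## Selection screen

The published positive-selection analysis names no method, no dataset and
no threshold, so its per-gene site counts are not a reproduction target.
Instead the package implements two fully specified, transparent
procedures:

* `ng86_pair()` — classic Nei–Gojobori (1986) counting with equal pathway
  weighting under translation table 2. Synonymous site fractions count
  only single-base changes that do not create a stop; multi-difference
  codons average over all minimal pathways, excluding pathways through
  stops (falling back to all pathways if every one is blocked). The
  Jukes–Cantor correction $d = -\tfrac34\ln(1 - \tfrac43 p)$ applies
  below saturation ($p < 3/4$); beyond it distances are reported absent.
  One subtlety the tests document: because pathway averaging ascribes
  fractional nonsynonymous steps to multi-position synonymous
  differences (e.g. TTA vs CTC within leucine), $N_d$ need not be zero
  even when the protein sequences are identical — but the rate ratio
  collapses, which is what matters.
* `sitewise_screen()` — a codon is flaggable when the background taxa are
  monomorphic at the amino-acid level; it is flagged when the foreground
  carries a different amino acid there. Per gene, a one-sided binomial
  test compares the flag count against a baseline rate (by default the
  pooled rate over all genes supplied), so the neutral false-positive
  rate is controlled at the nominal level by construction and measured at
  well under 5% in simulation.

## Phylogeny

Distances are hand-computed p or K2P with pairwise deletion of gap/N
columns (the K2P closed form is cross-checked against an independent
implementation in the tests); saturated K2P pairs are an error rather
than a silent NA. Tree building wraps the standard Q-criterion
neighbor-joining agglomeration — exact on additive matrices, which the
tests verify against random generating trees — with taxa fed in label
order for deterministic tie-breaking and negative branch lengths clamped
to zero, the deficit moved to the adjacent branch. Support values are
nonparametric bootstrap proportions over alignment columns, clearly
labelled as such to avoid confusion with the Bayesian posteriors of the
study this mirrors; Bayesian inference and divergence-time estimation are
out of scope. Monophyly is assessed after outgroup rooting (the study
roots on *Callorhinchus milii*); the sequence alignment itself is an
input — a multiple aligner is not re-implemented, and synthetic families
evolve without indels so their true alignment is trivial.

## The synthetic generator as study control

`generate_genome()` emits the canonical vertebrate mitogenome layout —
the packaged feature template's order, strands and coordinate-computed
lengths, including the 9 light-strand genes and the two incomplete-stop
PCGs — with class-specific composition targets set to the published
profiles (whole-genome A 32.32 / C 12.84 / G 30.42 / T 24.41; rRNA and CR
their own printed profiles; tRNA reuses the genome-wide one, which the
source does not print). The control region is 1,811 bp (the
coordinate-computed D-loop length) and plants a 128 bp × 4 and a
20 bp × 6 repeat array at 5% per-copy mutation, mirroring the two
reported repeat classes; copy numbers beyond "more than one" are not
published, so 4 and 6 are fixed, field-plausible choices. Generated
records always validate cleanly — the generator is the clean-room control
against the deliberately flawed printed table.

`evolve_family()` evolves protein-coding genes at codon level
(proposal–acceptance: stop-creating proposals rejected, nonsynonymous
proposals accepted with probability ω) and everything else under a
K2P-style nucleotide model, along a Newick guide tree whose branch
lengths are expected proposals per site. The default
transition/transversion ratio is 1: the evolver's first job is
calibrating counting estimators (NG86 assumes no transition bias), so its
default proposal process matches those assumptions; κ is a parameter for
realism studies. There is no indel process by default. What passing tests
therefore do **not** show: robustness to alignment error, indels,
among-site rate variation, or the compositional heterogeneity of real
elasmobranch mitogenomes — the generator emulates the statistical
structure each estimator assumes, not the full messiness of GenBank
records.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations for a
desk run: repeat recovery uses 40–100 seeded control regions; ω recovery
uses 500-codon genes, two-taxon contrasts at 0.08 proposals/site and
10–20 replicates per ω ∈ {0.2, 1.0} (tolerance ±0.15); the neutral
screen uses 4-gene, 4-taxon families; monophyly recovery uses six taxa at
10,000 sites, 10–20 replicates. Ties everywhere break deterministically
(alphabetical consensus ties, label-order NJ input), and a single integer
seed threads through every sampler, so identical inputs give
byte-identical report bundles.

## Known limitations

The GenBank reader handles single, circular, minimally annotated records
(the dialect its own writer emits and the common subset of real flat
files), not the full format. The repeat detector's gapless model will
fragment arrays with indel-divergent copies. ENc on very short genes is
noisy and per-gene values are reported as NA when no family reaches
usage 2. The published "average ENc" of 57.65 is not averaged over a
stated unit, so the package reports both pooled and per-gene ENc rather
than asserting equality with it.
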