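---
title: "Calling non-reference retrotransposon insertions from capture sequencing"
author: "rcseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling non-reference retrotransposon insertions from capture sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the data

Retrotransposon capture sequencing (RC-seq) enriches a sonicated DNA library
for fragments containing the 5' or 3' termini of recently active human
mobile elements (LINE-1, Alu, SVA) and sequences them as overlapping
paired-end reads. With an insert size of ~220 nt and 2 x 150 nt reads, each
pair can be assembled into a single contig spanning a complete insertion
junction: a non-retrotransposon (genomic) section on one side and a
retrotransposon terminus on the other. Mapping the genomic section to the
reference pinpoints non-reference insertion sites at single-nucleotide
resolution. Across a cohort of matched tumor/nontumor (T/NT) sample pairs,
the calls are then classified as known polymorphisms, shared germline,
private germline, tumor-specific candidates, or nontumor-only events, and
both-end calls are characterized for the sequence hallmarks of
target-primed reverse transcription (TPRT): a target-site duplication
(TSD), a 3' poly-A tail, an L1-endonuclease motif (canonically `TT/AAAA`),
and, for twin-primed insertions, a 5' inversion.

`rcseq` implements this pipeline end to end, together with a seeded
capture-read simulator that provides complete ground truth, a bisulphite
clone scorer for the 20-CpG L1 promoter island, and a paired-motif
permutation test for the probability that a random insertion bisects a
palindromic enhancer motif.

## Pipeline stages and their parameters

Every stage threshold defaults to the published analysis value; all are
overridable via `rcseq_params()`.

* **Trimming** (`trim_low_quality`): bases with phred quality < 10 are
  removed from read ends only; interior bases are untouched.
* **Pair assembly** (`merge_pairs`): read 2 is reverse-complemented and the
  overlap maximizing matched bases is chosen, requiring at least 10 nt of
  overlap and a mismatch rate of at most 0.1 (ties go to the longer
  overlap). In the overlap the higher-quality base wins. Unmerged pairs are
  dropped from calling: single-nucleotide junction resolution requires the
  full insert, and the library geometry makes merging the overwhelmingly
  common case.
* **Linker screen** (`screen_linker`): contigs reaching a local-alignment
  score of 22 against any ligation-mediated PCR primer or adapter stem are
  removed as ligation artifacts. The scoring scheme is BLASTN-like (match
  +1, mismatch -3, gap open -5, extend -2), so a score of 22 corresponds to
  a ~22 nt near-exact match.
* **Terminus matching** (`annotate_te_contigs`): the best local alignment
  against any consensus-library entry (both strands; match +2, mismatch -3,
  gap -5/-2) is retained when identity >= 0.95 over >= 33 alignment columns,
  the TE span abuts a contig terminus (within 2 nt, tolerating terminal
  sequencing error), and a >= 33 nt non-TE section remains. Contigs matching
  entries at both termini are fully TE-internal fragments and are set
  aside. Retained contigs are normalized so the genomic section precedes
  the TE section.
* **Genome anchoring** (`build_junction_evidence`): exact 15-mer seeds from
  the junction-proximal end, middle, and far end of the genomic section
  locate candidate loci; ungapped extension scores them (+2/-3; the
  substitution-only error model makes gapped anchoring unnecessary).
  Anchors must be >= 90 percent identical; uniqueness requires the best
  locus to beat the second best by >= 5 score points, with multi-chromosome
  ties treated as ambiguous. Contigs aligning end-to-end to the reference
  (>= 95 percent identity over >= 95 percent of their length) detect
  reference-resident elements and are routed out of novel-insertion
  calling. The molecular-chimera screen removes contigs whose reference
  alignment continues through the first 10 nt of the TE side (at most one
  mismatch): such "junctions" continue the local reference and indicate a
  reference-resident element or a ligation chimera.
* **Clustering and reporting** (`call_insertions`): evidence sharing
  sample, family, junction side, strand and chromosome clusters by single
  linkage within 10 nt; the cluster breakpoint is the modal member value
  (ties to the smallest coordinate), which restores exactness under read
  error. Supporting fragments count as unique amplicons only when their
  genomic fragmentation starts differ by >= 5 nt -- the PCR-duplicate key
  for capture libraries. Opposing 5'/3' clusters with the same implied
  element orientation join when separated by <= 100 nt. A call is reported
  only when at least one side has >= 2 unique amplicons; the rule is applied
  per side because the two junctions are separate detection events.
* **Classification** (`classify_calls`): per-sample calls merge into cohort
  loci (single linkage, 25 nt); presence per sample uses raw
  unique-anchored evidence within 50 nt, not the reporting rule, so
  sub-threshold nontumor evidence can veto a tumor-specific label -- the
  conservative choice given that validation in the original analysis found
  some sequencing-called tumor-specific events in nontumor tissue. Label
  priority: known polymorphism (database entry of the same family within
  50 nt) > shared germline (>= 2 donors) > private germline (one donor, both
  tissues) > tumor-specific candidate (tumor only) > nontumor-only.
* **Hallmarks** (`characterize_calls`): the TSD is pure coordinate
  arithmetic on the two junction breakpoints (overlap = TSD, gap = junction
  deletion, separations beyond 50 nt flagged unresolved rather than forced
  into either class); the poly-A length is a tolerant run (at most one
  non-A per 10 nt); the endonuclease motif is the 6 nt spanning the
  first-strand nick, written 5'->3' on the nicked strand with `/` at the
  scissile position so the canonical site reads `TT/AAAA`; twin-priming
  inversions are recognized as two adjacent blocks aligning to the
  consensus in opposite orientations, the genome-proximal block inverted;
  insertion length is the consensus length minus the 5'-junction consensus
  start (the junction-visible extent -- an inverted block does not extend
  it), with full length meaning >= 99.9 percent of the consensus.

## The junction coordinate convention

A poly-A tail abutting an A-rich target site, and element bases that
coincide with the reference continuation, make the exact junction base
ambiguous: several coordinate choices describe the same molecule. `rcseq`
resolves this deterministically by **maximal genomic extension**: after
anchoring, the reference claims every junction-adjacent base it can
explain, bounded by the delimited tail on 3'-end junctions and by 25 nt
into the TE span on 5'-end junctions. The simulator records its truth
coordinates under the same canonical convention (including the element's
own 3'-terminal adenosines, which are junction-indistinguishable from the
tail), so "breakpoint-exact" comparisons are well defined. This is the
junction-calling analogue of variant left-alignment in small-variant
calling.

## What the simulator emulates -- and what it does not

`sim_dataset()` draws a seeded uniform-random genome (default 1 Mb, GC
0.41) with five reference-resident decoy element copies (12 percent
interior divergence, exact terminal 10-mers, as recently fixed elements
have), implants 40 insertions (15 shared germline, 15 private germline, 10
tumor-specific; family mix 14/82/4 percent L1/Alu/SVA as in the cohort the
method was developed on, with tumor-specific insertions L1 as observed
somatically), and generates matched T/NT reads at 50x junction depth with
0.2 percent substitution error. Allele structure follows TPRT: TSD length
~ discretized Gamma(2, 4) capped at 30 nt; poly-A ~ 10 + Geometric(mean
30); L1s 5'-truncate with probability 0.65 (uniform offset over the
consensus, >= 500 nt retained) while Alu/SVA insert full length; 8 percent
of L1 TPRT events twin-prime with an inverted 5' block of 30-150 nt; 8
percent of insertions use the deletion-without-TSD route (1-30 nt deleted,
no TSD). Insertion sites prefer canonical `TT/AAAA` endonuclease positions
with probability 0.8. Ligation chimeras (2 percent of pairs) splice a
genomic flank onto a consensus 5' segment at a decoy boundary -- exactly
the artifact class the 10 nt rule removes. Capture enrichment is modeled
directly: fragments are drawn to overlap junctions, plus a thin uniform
background.

The simulator deliberately does **not** model indel sequencing errors,
PCR chemistry beyond fragmentation-start reuse, capture-probe
thermodynamics, chromosomal gain/loss, 3'/5' transductions, or nested/
overlapping insertions. Consensus sequences and the L1 promoter fixture
are synthetic constructions (mutually dissimilar random sequences of
realistic lengths), not database accessions: passing tests demonstrate the
pipeline's internal correctness under the stated error model, not
performance on real genomes, where repeat context makes anchoring much
harder.

Two capture blind spots are inherent and shared with the real assay: a 5'
junction whose truncation point lies outside the probe-targeted terminus
region produces no 5'-side evidence (the insertion is then detected at its
3' end only), and twin-priming is only measurable when the inverted block
falls inside the 5' entry region. Sensitivity figures for inversion
detection therefore refer to junction-visible blocks.

## Methylation scoring and the motif permutation test

The bisulphite module mock-converts the promoter reference (non-CpG C ->
T; CpG C ambiguous), globally aligns each clone, and reads each of the 20
CpG sites as methylated (`CG`), unmethylated (`TG`) or mutated (anything
else, excluded from denominators). Clones below 90 percent identity to the
converted reference are rejected; group comparisons pool clones and use
the closed-form 2x2 chi-square without continuity correction (group counts
are large; the correction is switchable). Conversion efficiency is not
modeled in scoring: retained non-CpG cytosines count as mismatches, not as
methylation.

The motif module scans for two 8 nt units, each within one mismatch of a
fixed pattern (unit 2 against the reverse complement in the palindromic
arrangement), separated by a gap of 0-11 nt. An insertion *bisects* an
occurrence when it falls strictly between the units; insertions inside a
unit do not count. The null model is iid uniform ACGT with both units
constrained to near-match the fixed pattern -- an unconstrained
pair-matching null produces common occurrences and cannot yield a rare
event, whereas the anchored null matches the biological question (a motif
resembling a known enhancer element). Under this null the per-unit
near-match probability is q = 25/65536 and the expected number of
bisecting occurrences at a random position is q^2 * sum over gaps of
(gap + 1) ~ 1.1e-5, far below 1/1000; the Monte-Carlo estimate (1e5 seeded
trials) agrees with this closed form within sampling error. Only the
window within reach of the insertion point can influence a trial, and the
implementation exploits that; a dinucleotide-shuffle null was considered
and not implemented, as the uniform null is the stated model.

## Numerical choices and degenerate inputs

* Alignment tie-breaks: equal-scoring family matches prefer higher
  identity, then the lexicographically first family, and are flagged
  ambiguous. Equal-scoring anchor loci within 5 score points are
  ambiguous, never assigned arbitrarily.
* Cluster ties: modal breakpoint ties resolve to the smallest coordinate;
  cluster joining prefers the nearest partner, then the smaller
  coordinate.
* Empty inputs: zero calls write a header-only report; an all-mutated CpG
  column is reported missing; a fully trimmed read becomes an empty record
  and is dropped at assembly.
* All randomness flows from explicit seeds; simulator outputs are
  byte-identical across runs with the same configuration.

## Problem sizes used by the test-suite and acceptance runs

The default simulated cohort is 1 Mb of genome, 3 donors (6 samples), 40
insertions and 50x junction depth -- about 30,000 read pairs -- which
exercises every pipeline stage in a few minutes while leaving every
per-insertion metric measurable. The twin-priming sensitivity check uses a
dedicated all-L1 cohort with forced inversions on a 200 kb genome. The
motif permutation uses 1e5 trials; methylation recovery uses 100 clones
per group at the two group methylation levels the scorer is meant to
distinguish. These sizes are the package's standard study conditions, and
the acceptance script re-runs them from scratch at a caller-supplied seed.

## Known limitations

* Unmerged pairs are discarded rather than used as split paired evidence.
* Anchoring is ungapped; reference indels near a junction would shift
  breakpoints (consistent with the substitution-only simulator, but a real
  limitation on real data).
* Twin-priming 5' junctions whose contigs show only the inverted block
  yield a lower bound on the inversion length.
* Classification at low nontumor coverage fails only in the documented
  direction (germline events can masquerade as tumor-specific when the
  nontumor sample is undersampled) -- the reason the original analysis
  required PCR confirmation of tumor-specific candidates.
* The known-polymorphism database window (50 nt) and the presence window
  are design choices; published sources report heterogeneous coordinates.
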