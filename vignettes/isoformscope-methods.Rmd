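---
title: "Reference-free isoform analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free isoform analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoformscope)
```

# The problem

Full-length cDNA sequencing (PacBio Iso-Seq and kin) reads entire transcripts
in one pass, so isoform structure — which exons a transcript contains — is
directly observable without assembly. For species without a reference genome,
however, the usual splice-aware toolchain is unavailable: there is nothing to
map to. `isoformscope` implements the reference-free alternative: cluster
full-length reads into unigenes, and recognise isoforms of one gene by the
*sequence they share at their ends*, calling exon skipping as a large internal
indel between end-anchored transcripts.

# Read model and classification

A long read is modelled as

```
5'adapter + transcript + polyA + 3'adapter
```

with a per-read predicted accuracy in [0, 1] (a published minimum "read
quality of 75" is read as 0.75 mean per-base accuracy, the long-read consensus
convention; the threshold is `min_read_quality`, configurable, because the
scale of that score is not fully specified in the literature). Classification
is by adapter content: both adapters exactly once and in order makes a read
full-length non-chimeric (FLNC); more than one copy of either adapter, or the
3' adapter upstream of the 5', is chimeric; reads under the accuracy floor are
low-quality; everything else is non-full-length. The chimera rule is our
stated operationalisation — published pipelines say only "non-chimeric" — and
the adapter mismatch tolerance (`adapter_max_mismatch = 2` for 20-mers) is a
convention, since real adapter sequences and tolerances are
platform-specific. Insert trimming removes the bases between the adapters and
one maximal terminal run of ≥ `polya_min_run = 10` A's; internal A-runs are
never touched.

Orientation: adapters orient transcripts 5'→3' during classification, so all
downstream stages consider the forward strand only. Coordinates are 0-based
half-open internally; report files are 1-based closed.

# Pairwise alignment

One alignment primitive serves clustering and indel calling:
ends-free (semi-global) global alignment with affine gaps — match +2,
mismatch −3, gap open −5, gap extension −1 per base, terminal gaps free
(values are conventions fixed in configuration; published sources do not
state a scheme). The dynamic programming is `Biostrings::pairwiseAlignment()`
with `type = "overlap"`; a gap of length L costs `open + L·ext`.

Two derived quantities have deliberate definitions:

* **identity** = matched columns / columns of the *aligned core* (between the
  first and last column where both rows have a base). Internal gap columns
  count against identity; terminal overhangs do not. Counting terminal-gap
  columns would make a nested identical fragment score `short/long` and turn
  the identity threshold into a covert length filter, which is what the
  separate *coverage* threshold (aligned fraction of the shorter sequence,
  ≥ 0.90) is for.
* **gap-excluded identity** (used by the reciprocal screen in AS detection)
  = matched columns / length of the shorter sequence. A genuine skipped exon
  sits in a gap run and costs nothing, but a decoy that shares anchors while
  diverging internally cannot hide: bases the optimal aligner pushes into gap
  runs remain unmatched in the numerator. (The naive "identity over non-gap
  columns" is sidestepped by the aligner itself, which will happily gap out
  an entire divergent interior and score ~1.0 on the few columns left.)

# Clustering into unigenes

Greedy, CD-HIT-style: sequences sorted by decreasing length (ties by id);
each joins the first cluster whose representative it matches at identity
≥ `cluster_identity = 0.99` and coverage ≥ `cluster_coverage = 0.90`, else
founds a cluster. Canonical processing order makes the result independent of
input order. Published pipelines apply an isoform-level cluster step and a
CD-HIT pass at 0.99; whether the 90% coverage belongs to the first or second
is ambiguous in the sources, so both thresholds act in this single pass (each
configurable). An optional shared 12-mer containment prefilter
(`kmer_filter`) skips alignments that cannot reach 99% identity (at 99%
identity and 90% coverage the expected containment is ≥ 0.75; the filter
cuts at 0.3); tests assert the output is identical with the filter off.

Polishing replaces signal-level consensus (Quiver/Arrow), which needs raw
instrument data: members are aligned to the representative, merged by
center-star, and each column takes the majority character, ties resolved
toward the representative; a majority gap deletes a column and insertions
survive only with majority support. This is the only desk-scale analogue and
is a stated limitation — it corrects random errors, not systematic ones.

# ORF annotation

All maximal ORFs in the three forward frames are enumerated — COMPLETE
(ATG…stop, stop included in the CDS), PARTIAL5 (frame-open 5' end to first
stop), PARTIAL3 (ATG running off the 3' end), INTERNAL (open both ends) —
keeping candidates ≥ `min_orf_len = 100` codons (TransDecoder convention).
Open-ended candidates nested inside another candidate's span are redundant
and pruned. The published selection interposes a trained gene-model scorer
between enumeration and choice; with no training data at desk scale the
score here is CDS length plus a 30-nt completeness bonus (one codon beyond
ten: a complete ORF is preferred unless an incomplete one is substantially
longer), ties broken by smaller start then lower frame. Reverse-strand ORFs
are not searched because classification already oriented the inserts; a
caller with unoriented FASTA can scan both strands by reverse-complementing.

# Exon-skipping detection

The core procedure, reference-free throughout:

1. **Anchor grouping.** Each transcript contributes an anchor pair: its first
   and last `anchor_len = 100` bases. Transcripts are grouped by *exact*
   equality of both anchors; singleton groups are discarded. Exactness is the
   point — it is what makes the procedure specific without a genome — and the
   simulator shows a single substitution inside an anchor removes the pair.
2. **Reciprocal screen.** Every pair in a group is aligned in both
   orientations; members below gap-excluded identity 0.99 against all others
   are dropped (the threshold reuses `cluster_identity`; the sources name no
   value for this step).
3. **Indel calling.** Each member is aligned to the group's reference (the
   longest member, ties by id — this keeps event lists non-redundant and
   order-invariant). Every maximal gap run strictly between the anchor
   regions is one event; runs are never merged across matching columns.
4. **Size filter.** A group is an alternative-splicing cluster iff it has an
   event **strictly longer** than `min_indel = 100` bases. The strictness
   matters: a real 78-base skipped exon is the canonical observed-but-not-
   called case, and the boundary tests plant 78/100/101 to pin the rule.
   Groups differing only by substitutions or short indels are thereby
   excluded as ambiguous near-identical forms — the sources give no other
   criterion, so "no qualifying event" *is* the exclusion rule here.
5. **MSA validation.** Each reported cluster is re-aligned by deterministic
   center-star MSA (replacing an external CLUSTALW call; no external binary,
   reproducible) and is flagged validated iff every qualifying pairwise event
   reappears as a gap block of identical length. Inconsistent clusters are
   flagged, not dropped.

**Where are the anchors taken?** The published wording ("the 100 bases at the
5' and 3' ends within their complete open reading frames") supports two
readings: ends of the CDS, or ends of the transcript gated on having a
complete ORF. Both are implemented (`anchor_mode`). The default is
`"unigene"` (transcript ends, no ORF gate) for a structural reason: a skipped
exon whose length is not a multiple of 3 shifts the reading frame, the
alternative isoform's complete ORF then terminates at an early stop, and its
*CDS* ends no longer match the full isoform — CDS anchors would make every
frame-disrupting skip undetectable, defeating the purpose of a
nucleotide-level method. On transcripts without UTRs (as simulated) the two
modes coincide for in-frame isoforms. With real UTR-bearing transcripts,
unigene-end anchors additionally require isoforms to share transcript ends;
`"cds"` mode is the choice when UTR heterogeneity is expected and only
in-frame events are of interest.

Detection is bounded away from transcript ends by construction (events must
lie strictly between the anchors), so terminal alternative splicing is out of
scope, as is intron-retention typing — both need a genome.

# SSR profiling

Maximal perfect tandem repeats with unit length 1–6, minimum repeat counts
per MISA convention (mono 10, di 6, tri 5, tetra 5, penta 4, hexa 4; the
published scan names a finder but not its thresholds). Each locus is reported
once, under its minimal unit, leftmost phase, trimmed to whole units; a
region whose unit is itself periodic is reported only at the shorter period.
Only perfect repeats are called — no compound or interrupted SSRs — the
simplest rule consistent with published motif-frequency reporting. Classes
are canonical over rotations and reverse complements (GA, CT, TC → AG;
the six rotations/RCs of AAG → AAG), and hits are localized against the best
ORF: entirely upstream → UTR5, entirely downstream → UTR3, any CDS overlap →
ORF, no ORF → NOORF.

# The simulator: what it emulates, and what it does not

The generator is first-class, tested code; every downstream guarantee is
stated against its planted truth.

* **Gene models**: 3–12 exons of 80–600 bp (multi-kilobase transcripts, in
  line with size-selected full-length cDNA libraries spanning 1 to > 6 kb).
  Each full isoform is a clean CDS: starts ATG, ends with a stop, length
  ≡ 0 mod 3, no internal in-frame stop. The terminal stop is fixed to TAG so
  the designed poly(A) tail is cleanly separable by terminal-A trimming; a
  TAA/TGA stop would donate A's to the tail and make byte-exact insert
  recovery ill-posed, which real A-rich transcript ends indeed are — a noted
  simplification.
* **Skipping**: a configurable fraction of genes (default 0.3) carries one
  skipped *internal* exon built to an exact length from
  {78, 120, 183, 250, 350} bp — bracketing the canonical 78- and 183-base
  exemplar events and the 100–400 bp range where most such indels fall.
  Skip lengths are deliberately not restricted to multiples of 3 (183 is,
  78 is, 250/350 are not): frame disruption downstream is intentional.
  First/last exons are extended when needed so that ≥ `anchor_margin = 120`
  bases flank the skipped exon on both sides — anchors must lie in shared
  sequence for an event to be detectable at all, and the generator
  guarantees it rather than leaving it to chance.
* **Reads**: adapter5 + isoform + 30-base poly(A) + adapter3, independent
  per-base substitutions at `error_rate` (default 0.002, the scale of
  circular-consensus residual error), per-read quality 1 − error_rate. An
  optional short-indel error rate exists (default 0) so planted skips remain
  the only gap sources. A `truncation_fraction` (default 0.3) of reads lose a
  uniform 5' prefix covering the 5' adapter and up to half the insert —
  modelling 5' degradation / incomplete reverse transcription, the standard
  asymmetry of full-length cDNA artefacts. Chimera simulation beyond this is
  out of scope.
* **SSRs**: half the genes carry one embedded repeat (AG or AAG class,
  6–12 units), motifs restricted to T-free alphabets so no stop codon can
  arise inside a planted run; placements are re-drawn if a junction codon
  would create one.
* **Determinism**: one integer seed; gene models and reads draw from offset
  seed streams; identical seeds give byte-identical FASTQ bundles.

What passing on this simulator does **not** show: robustness to realistic
long-read error profiles (indel-dominated, not substitution-dominated), to
UTR heterogeneity between isoforms (transcripts here are pure CDS), to
inter-genic sequence similarity (gene bodies are independent random
sequences, so clustering faces no paralogy), or to coverage imbalance.

# Study-condition scales and numerical choices

The validation suite exercises the pipeline at fixed desk scales: a 60-gene
bundle with 20 planted skips from {120, 183, 250, 350} (error-free; exact
recovery, zero false positives, all clusters MSA-validated), the
78/100/101-bp boundary triplet, 1,000 reads at 30% truncation for
classification, and 50 genes × 10 reads at 0.2% substitution error for
clustering and polishing. At that error rate, two reads of one transcript
differ by ~0.4% in expectation — inside the 1% clustering margin, though for
transcripts under ~1 kb the binomial tail can graze the 99% threshold, which
is the boundary the thresholds themselves define, not an implementation
artefact.

Numerical conventions: identity/coverage comparisons use `>=` on doubles
computed from integer counts; greedy order and all tie-breaks (cluster
joining, ORF selection, AS reference choice, consensus ties) are
deterministic and documented at each function; gap placement within a
repeated boundary context follows the aligner's convention, so event *starts*
may slide by a few bases while event *lengths* are exact; empty inputs error
early (`length_stats`) or return typed empty tibbles (scanners). Fold changes
are per replicate, summarised as mean ± standard error.

# Known limitations

* Column-majority polishing cannot fix systematic or strand-correlated
  errors; it is a stand-in for signal-level consensus by design.
* Exact anchors make AS detection conservative on error-bearing unigenes: a
  single consensus error inside either anchor hides the gene. With polished,
  low-error unigenes this is the intended specificity/sensitivity trade.
* O(n²) alignment in clustering limits inputs to a few thousand sequences;
  the k-mer prefilter extends the practical range but the design target is
  desk-scale validation, not production assembly.
* Assembly-completeness assessment, database annotation, repeat/TE
  screening, and cross-species comparisons are deliberately outside the
  package's scope.
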