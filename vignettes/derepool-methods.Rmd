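---
title: "Consolidating contaminated transcriptome collections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating contaminated transcriptome collections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Large public transcriptome collections of unicellular eukaryotes are
taxonomically redundant (many samples per genus) and contaminated, both
by material from unrelated organisms and by *cross-contamination*:
sequences leaking between samples that shared library preparation or
sequencing runs. Both defects distort downstream phylogenomics, where a
contaminant sequence is easily mistaken for a horizontally transferred
gene. `derepool` implements a consolidation protocol that removes the
most contaminated samples rather than attempting to repair them, pools
closely related samples into per-taxon transcriptomes, and collapses
near-identical sequences, yielding a smaller, cleaner, more balanced
collection.

The pipeline stages, in order:

1. **Size filter** — samples with fewer than `min_seqs` (default 5000,
   strictly "less than") transcripts are discarded, as are samples with
   unreadable files or missing phylum/genus labels. Every discard is
   recorded with a reason code; nothing is silently dropped.
2. **Marker screen (pass 1)** — each transcript is translated in six
   frames and aligned (local Smith–Waterman, BLOSUM62, affine gaps
   11/1) against a ribosomal protein marker database whose references
   carry taxonomic labels. A sample's contamination estimate is the
   fraction of its retained marker hits whose best reference belongs to
   a foreign phylum.
3. **Phylum-wise outlier discard** — contamination baselines differ
   radically between phyla (ciliates are notoriously "contaminated" as
   a feature of the clade), so no global threshold is meaningful.
   Within each phylum with at least `min_group` (default 4) scorable
   units, units above the Tukey fence `Q3 + 1.5·IQR` are discarded.
4. **Cross-contamination quantification** — all transcripts are pooled
   into a pan-assembly indexed by canonical k-mers (k = 21). Every
   sample's reads are re-attributed: each read votes for the
   transcript(s) sharing the most k-mers (ties split 1/m). Counts are
   length-normalized to a TPM-like unit per read-sample. A transcript
   owned by sample S whose expression under some other sample's reads
   is at least `R` (default 2) times its expression under S's own reads
   is a cross-contaminant with that donor; `cc(A→B)` is the percentage
   of B's transcripts called cross-contaminants with donor A.
5. **Pooling** — within each multi-sample genus, samples joined by a
   combined cross-contamination value ≥ 10% (either direction by
   default) are pooled transitively (connected components); a high
   cross-contamination value between same-genus samples is read as
   close relatedness rather than contamination. Unique-genus samples
   and unrelated same-genus samples stay as singletons.
6. **Dereplication** — each consolidated transcriptome is collapsed
   with greedy incremental clustering: longest sequence first, each
   sequence joins the first representative with nucleotide identity
   ≥ 95% (matches of the best local alignment divided by the shorter
   sequence's length — the CD-HIT convention), else founds a cluster.
7. **Second screen and outlier discard** — the marker screen and the
   cross-contamination analysis are repeated on the consolidated
   transcriptomes; the union of the two flagged sets is discarded.
8. **Completeness** — a marker-recovery score: a marker family is
   *complete* if its best hit covers ≥ `frag_frac` (default 0.7) of the
   reference, *fragmented* if hit but shorter, *missing* otherwise.

A conservation invariant is asserted at the end of every run: each
input sample is traceable to exactly one output transcriptome or one
discard-log entry.

# Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `min_seqs` | 5000 | transcripts | minimum sample size; strict `<` |
| `min_score`, `min_identity` | 50, 30% | score, % | marker-hit retention |
| `k`, `min_share` | 21, 2 | bases, k-mers | read attribution |
| `R` | 2 | ratio | expression ratio calling a cross-contaminant |
| `min_expr` | 0.5 | TPM-like | expression floor below which transcripts are ignored |
| `cc_threshold` | 10 | % | pooling relatedness threshold |
| `derep_identity` | 95 | % | dereplication operating point |
| `fence_k`, `min_group` | 1.5, 4 | –, units | phylum outlier fence |
| `frag_frac` | 0.7 | fraction | completeness cutoff |

`R` and `min_expr` deserve comment: the per-transcript decision rule
behind the cross-contamination value is not uniquely determined by the
protocol this package reconstructs, so both constants are exposed and
the value is defined as a transcript fraction (not a read fraction).
The combined edge rule for pooling (`max`, `min` or `mean` of the two
directed values) is likewise configurable; `max` — an edge as soon as
either direction passes — is the default, as the most inclusive reading
of "sharing" a cross-contamination value.

# The synthetic-data generator

Real collections of this kind are hundreds of gigabytes, so validation
runs on generated collections with planted, fully recorded structure:

* **Cross-contamination** — a stated fraction of a recipient's
  transcripts are verbatim copies of donor transcripts whose
  recipient-side read depth is reduced by `depth_mult` (default
  scenarios use 10×), reproducing the read-support asymmetry that the
  attribution stage detects.
* **Foreign markers** — a stated fraction of a sample's marker-derived
  transcripts are reverse-translated copies of a *foreign* phylum's
  reference.
* **Near-duplicates** — extra copies of background transcripts at a
  stated identity (default 96%), for the dereplication stage.

Marker references are random amino-acid roots (120–250 residues)
mutated per phylum at a stated rate (default 0.3). Reverse translation
uses the alphabetically first codon per amino acid — deterministic, no
codon-usage model — because downstream analysis re-translates.

Two generator guarantees make planted structure the *only* signal:
marker families are rejection-sampled until no six-frame translation of
any reverse-translated reference reaches the screening score floor
against another family, and (when the dataset carries marker content)
background and near-duplicate transcripts are held to the same ceiling.
Without this, random 300–800 nt transcripts occasionally reach raw
local-alignment scores of 50–60 against 120–250 aa references, and a
"clean" sample would not measure exactly 0% contamination.

What the generator does **not** emulate: isoforms, GC bias, coverage
gradients, sequencing error (available as an option, off by default),
paired-end structure, and the extreme gene-family amplification of
dinoflagellates. Passing tests therefore demonstrate that the machinery
recovers planted structure under idealized read models, not that the
thresholds are optimal for any particular real collection.

# Numerical and degenerate-case choices

* **Alignment.** Local Smith–Waterman with Gotoh affine gaps; a gap of
  length L costs `gap_open + L·gap_ext`. Identity is computed over
  aligned columns excluding gaps; dereplication identity divides
  matches by the *shorter* sequence's length. `N` participates in no
  k-mer and scores as a mismatch against everything, including itself.
  A best score of 0 is "no hit".
* **Ties.** Marker hits tie-break by higher identity, then
  lexicographically smaller reference id. Read attribution splits an
  m-way tie as 1/m. Dereplication orders by length descending, then
  lexicographic id (C-locale), and joins the *first* acceptable
  representative. Pool components are numbered by their
  lexicographically smallest member. Every tie rule is deterministic,
  so reports are byte-identical across runs and across serial/parallel
  execution.
* **Word prefilter.** Dereplication screens candidate pairs by shared
  8-mer count before running the DP. The required count is a provable
  lower bound for a pair at the identity threshold (each unmatched
  position of the shorter sequence destroys at most `word` words, plus
  one word of rounding slack), so the filter can only reject pairs the
  DP would also reject.
* **Quartiles.** Linear interpolation (`type = 7`). With an all-equal
  group the IQR is 0 and the fence equals Q3; flagging requires being
  *strictly* above the fence, so uniform groups produce no flags. The
  flip side is accepted: when a phylum's baseline is exactly zero, any
  positive noise value exceeds the degenerate fence. Real collections
  have continuous contamination values where this does not arise.
* **Unscorable units.** A sample with zero marker hits has no defined
  contamination percentage; it is excluded from fencing and never
  flagged by the marker detector.
* **Parallelism.** Worker processes are used only where per-unit
  results are provably independent (attribution, screening, per-pool
  dereplication); outputs are bit-identical to serial runs.

# Known limitations

* Transcripts that are *identical across samples* (deeply conserved
  genes; in synthetic data, marker transcripts shared by same-phylum
  samples) receive tied read votes from every carrier. Their expression
  ratio then hovers around 1 and is classified "dubious" — unless
  coverage is shallow (≲ 30 reads per transcript), where sampling noise
  can push the ratio past `R` and produce spurious cross-contamination
  calls. The same effect exists in read-mapping-based implementations
  of this protocol; deeper coverage or a larger `R` suppresses it.
* Pooling is genus-level; species/strain resolution within a pooled
  genus is lost by construction.
* The completeness score is marker recovery against the screening
  database, not a full lineage-aware completeness assessment; it ranks
  units relative to each other rather than certifying absolute
  completeness.
* The cross-contamination stage reports per-transcript verdicts but
  does not excise cross-contaminant transcripts from pool members;
  removal happens at whole-unit granularity in the outlier passes.

# Problem sizes used in the packaged checks

The packaged tests and the acceptance script validate on: two-sample
collections of 1,000 transcripts × 50,000 reads (cross-contamination
recovery, ten seeds), 400 × 20,000 (pooling threshold, four planted
fractions × five seeds), 40-sequence dereplication sets with planted
96%/90% pairs against a brute-force oracle, 60-marker-transcript
samples for contamination exactness, and a 12-sample / 4-genus / 2-phylum
end-to-end run (80 transcripts and 2,500 reads per sample) with planted
duplicates, cross-contamination and one over-contaminated sample. These
sizes were chosen so the complete validation suite runs on a laptop in
minutes while keeping ≥ 30× nominal read coverage per transcript, the
regime in which expression-ratio classification is stable.
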