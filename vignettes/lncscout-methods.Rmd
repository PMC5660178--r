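---
title: "Discovering long non-coding RNAs from assembled transcriptomes with lncscout"
author: "lncscout authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering long non-coding RNAs from assembled transcriptomes with lncscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncscout)
```

## The problem

Long non-coding RNAs (lncRNAs) are transcripts of at least 200 nt with no
protein-coding capacity. Reference annotations lag behind what deep RNA-seq
actually detects, so a recurring analysis task is: given per-sample
transcript models produced by a genome-guided assembler (StringTie-style
GTFs with expression attributes), decide which assembled transcripts are
credible *novel* lncRNAs, consolidate them across samples, and quantify
them together with the already-annotated lncRNAs so that known and novel
loci can be analyzed in one expression matrix.

`lncscout` implements this discovery pipeline from the assembled-GTF
boundary onward. Read alignment and transcript assembly are explicitly out
of scope: the assembler's output is the input contract.

## Classification: the two routes

Every assembled transcript is compared against the reference annotation
and placed in exactly one class:

* **KNOWN** — it matches an annotated transcript. Matching is structural,
  not by identifier: assembler ids are arbitrary, so a multi-exon
  transcript is known when its intron chain (the ordered intron
  coordinates, same chromosome and strand) is identical to an annotated
  transcript's, and a single-exon transcript when its span lies inside an
  annotated single-exon transcript's span on the same strand. Known
  transcripts are kept intact — discovery must not fragment the existing
  annotation — and their observed expression calibrates the
  sample-specific filters below.
* **LINCRNA** — no overlap with any known transcript on either strand: a
  long intergenic non-coding RNA candidate.
* **OVERLAP_ANTISENSE** — overlaps known transcripts, but every overlap is
  on the opposite strand. Callable only from stranded libraries.
* **REJECTED_SENSE_OVERLAP** — any same-strand overlap (likely pre-mRNA or
  a fragment of the host gene). In unstranded mode *any* overlap rejects
  the transcript, because antisense transcription cannot be separated from
  its host without strand information; only lincRNAs are callable there.

"Overlap" defaults to transcript-span overlap of at least 1 bp. This is
the conservative reading: a same-strand candidate contained in an intron
is rejected rather than called novel. An exon-level mode
(`overlap_level = "exon"`) is available for the opposite trade-off.

## The filter cascade

Candidates then pass through three filters in a fixed order, and a
candidate is attributed to the *first* filter it fails, which makes the
funnel accounting conserve exactly
(`input = survivors + sum(per-filter failures)`):

1. **Length** (`min_length_bp = 200`, strict `<`): transcripts shorter
   than 200 nt do not meet the lncRNA definition. Single-exon candidates
   longer than `max_single_exon_length_bp = 10000` (strict `>`) are also
   removed — unspliced models of that size are usually genomic background
   or run-through transcription.
2. **Repeat overlap** (single-exon only): a single-exon candidate whose
   exonic bases overlap the repeat/low-complexity track (UCSC
   simpleRepeat-style BED) by more than `repeat_overlap_max_fraction =
   0.5` is removed. The fraction is configurable down to 0 ("any overlap
   fails"); the spliced structure of multi-exon candidates is itself
   evidence against a repeat artifact, so they are exempt.
3. **Expression**: cutoffs are *derived per sample* from the expression of
   the known transcripts actually observed in that sample's assembly,
   separately for single- and multi-exon reference classes (restricted to
   values > 0). Single-exon candidates must fall inside the
   `(0.05, 0.95)` quantile band of the known single-exon distribution —
   both tails are noise-prone for unspliced models. Multi-exon candidates
   only need to reach the `0.05` quantile of the known multi-exon
   distribution: a very low value suggests an incompletely constructed
   model, while there is no reason to cap high expression of a spliced
   transcript. Because the cutoffs are quantiles of what each sample
   observed, lower-depth samples automatically get lower absolute cutoffs.

The expression rule deserves a note. The original formulation relies on a
third-party tool's internal statistical models, whose exact form is not
published in a reproducible way; `lncscout` replaces it with the empirical
quantile bounds above. This keeps the stated intent — dynamic,
sample-specific cutoffs referenced to known single-/multi-exon
transcripts — in a form that is transparent, configurable and testable.
Quantiles are fixed to the linear-interpolation (type-7) convention so the
cutoffs are reproducible across implementations. When a reference class
has fewer than `min_reference_n = 20` expressed members the quantiles fall
back to the pooled expressed reference set; with no expressed reference at
all the function refuses and asks for absolute cutoffs — silently
inventing bounds would be worse than stopping.

Which StringTie attribute feeds these comparisons is configurable
(`FPKM` > `TPM` > `cov` by default); the filters only require that the
same measure is used for candidates and references within a sample.

## Coding potential: two scorers, union or intersection

The final discovery step removes candidates that look protein-coding.
`lncscout` uses two independent logistic scorers that both output
P(noncoding):

* **Scorer A** (ORF-centric): longest forward-frame ORF length (log
  scale), ORF coverage, the Fickett position/composition statistic, and
  hexamer usage bias — the mean log-ratio of coding vs noncoding in-frame
  hexamer frequencies over the longest ORF.
* **Scorer B** (composition-centric, disjoint features): Fickett
  statistic, GC content, and stop-codon density across the three forward
  frames.

Their calls are combined at a threshold (default 0.9, strict `>`):
**union** — noncoding if either scorer exceeds the threshold (higher
sensitivity) — or **intersection** — both must exceed it (higher
specificity). The threshold can be lowered to 0.5 for maximum
sensitivity. Missing scores count as a failed scorer and are logged.
ORFs are searched on the three forward frames of the sense-strand spliced
sequence, since assembled transcripts are stranded; unstranded candidates
are scored in both orientations and the minimum noncoding probability per
scorer is used, the conservative choice (a strong ORF on either strand
counts against the candidate).

The scorers are trained in-package on synthetic sequences (codon-biased
planted ORFs vs their mononucleotide shuffles; `synth_training_sequences()`),
deterministically per seed. The shuffle preserves base composition, so the
scorers must learn positional signal rather than GC content. Training AUC
is reported on the scorer object. For production use on real genomes the
same `train_scorer()` interface accepts any coding/noncoding training
sets, e.g. annotated CDSs and shuffled controls.

## Consolidation, quantification, annotation

Candidates that pass everything are merged across samples into one
unified novel annotation: multi-exon candidates with identical intron
chains merge into one transcript spanning the union of member spans
(boundary-only differences merge; there is no fuzzy intron matching);
single-exon candidates on the same strand cluster by transitive overlap
of at least 1 bp and merge to the union span. Merged ids
(`NOVEL.<gene>.<tx>`) are assigned after coordinate sorting, so the result
is independent of sample order, and a provenance table maps every merged
transcript back to its per-sample members. With a single sample the merge
is a pass-through. Merging a merged annotation is a fixed point.

Quantification counts fragments over gene-level exon unions
(featureCounts-default semantics): a fragment is assigned on >= 1 bp
overlap with exactly one gene's exon union (strand-matched in stranded
mode); fragments hitting two or more genes are discarded as ambiguous;
`assigned + ambiguous + unassigned = library size` per sample. RPKM is
`count / ((length/1000) * (library_size/1e6))`. The known-lncRNA universe
is `lincRNA` only in unstranded mode and all lncRNA biotypes in stranded
mode, where opposite-strand transcription is separable — which roughly
doubles the quantified known set.

Every known and novel lncRNA is annotated with its nearest protein-coding
gene. The distance is anchored TSS-to-TSS by default (the transcription
start site being the 5' end on the coding strand), signed as
`gene TSS - lncRNA TSS`, and 0 exactly when the genomic spans overlap; a
span-gap mode is available behind `nearest_method = "span_gap"` since
either convention is defensible. Ties break toward the lexicographically
smaller gene id, for determinism.

## Withhold-and-recover validation

Absolute accuracy cannot be measured — the true lncRNA complement of any
real sample is unknown. The pipeline therefore validates itself by
*withholding*: a seeded uniform third (configurable) of the known
lincRNAs is removed from the reference, the pipeline re-predicts against
the reduced annotation, and every withheld transcript is followed through
the funnel

> withheld → covered (any fragment coverage) → assembled (present in the
> assembly input) → recovered / filtered (with the first failing filter)

Recovery defaults to a passed candidate covering at least 50% of the
withheld transcript's exonic bases on the same strand; an exact
intron-chain mode is available. The recall is
`100 * recovered / assembled`, reported to one decimal. Only eligible
lincRNAs enter the draw — those passing the pipeline's own length, repeat,
coding-potential and no-overlap criteria — since an ineligible transcript
could never be re-predicted, and only transcripts with read coverage
count toward the assembled denominator.

## The synthetic-data generator

`synth_generate()` builds a fully self-contained test universe with known
ground truth: a two-chromosome random genome; multi-exon protein-coding
genes whose exons carry codon-biased ORFs (painted strand-aware into the
genome so the scorers have real signal to find); known lincRNAs (multi-
and single-exon) and antisense lncRNAs inside coding introns; a repeat
track; and planted novels covering every branch of the pipeline — clean
intergenic multi- and single-exon novels, antisense novels in coding
introns, and one decoy family per filter (too-short, over-10-kb
single-exon, repeat-buried, below- and above-cutoff expression, and
strong-ORF coding decoys). Every feature is placed in its own genomic
slot, so no unintended overlaps arise, and the generator re-verifies each
planted transcript's intended class against the classifier before
returning. Sequence under noncoding features is re-randomized until no
chance ORF longer than 150 nt remains (skipped for decoys that fail
before coding potential is consulted, such as the 10.4 kb length decoy,
where chance ORFs are unavoidable and irrelevant).

Per-sample expression is log-normal (`meanlog = 1.5`, `sdlog = 0.8`)
scaled by per-sample depth factors (`1, 0.5, 2` by default), emulating
variable sequencing depth: shallow samples observe lower absolute known
expression and hence derive lower cutoffs, and known transcripts below a
detection floor (0.3) drop out of that sample's assembly. Expression
decoys are pinned per sample at 0.25x the single-exon 5% quantile and 4x
the 95% quantile, so they fail in every sample; clean novels sit at the
per-sample median, so they pass in every sample. A degenerate
`expression_model = "constant"` puts every transcript at the same level,
which collapses the quantile band and switches expression filtering off —
the control used to demonstrate that the pipeline introduces no losses
beyond its stated filters (recall is then exactly 100%). Fragments are
drawn per feature as Poisson with mean proportional to expression x
exonic length (150 bp, placed within single exons), which reproduces the
expected count-vs-abundance proportionality at large n.

What the generator deliberately does *not* emulate: sequencing errors,
splice-site motifs, fuzzy assembly boundaries, multi-mapping, and
biologically realistic hexamer composition. Passing the planted-truth
tests therefore demonstrates that the pipeline's logic is correct under
its own contracts, not that any particular recall will be achieved on
real tissue data.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere internally (GTF native);
  BED is converted at the boundary (`start+1, end`), a bijection.
* Chromosome names are taken verbatim; a validation pass warns when two
  inputs share zero chromosome names instead of silently renaming.
* Quantile type is fixed (type 7); ties in nearest-gene distance break on
  gene id; merged ids are assigned after coordinate sorting — all for
  bit-for-bit reproducibility given a seed.
* Transcripts with a `transcript` GTF line but no exons are dropped with
  a warning (annotation dialects differ); exons of one transcript on two
  strands are an error.
* An all-unstranded assembly presented in stranded mode is refused at
  validation, as it indicates a mis-set aligner/assembler option.
* ORFs require an in-frame stop codon; open-ended reading frames are not
  counted.

## Problem sizes used in the shipped tests

The test suite runs the full pipeline on bundles of 120-420 kb genomes
with 30-80 known transcripts, ~40 planted novels and decoys, and 2-20 k
fragments per sample; the funnel-conservation property is checked over 20
seeded evaluation runs on reduced bundles, and the count-proportionality
property on a ~60 k fragment bundle. These sizes were chosen so every
code path (including every decoy family) is exercised while each property
stays attributable to a single cause; all are the package's own defaults
or explicit test parameters and scale linearly if increased.

## Known limitations

* The two shipped scorers are trained on synthetic codon bias; on real
  genomes users should retrain with species-appropriate CDS/noncoding
  sets. The union/intersection combination semantics are independent of
  the training source.
* Merging has no intron-fuzz window; assemblers that wobble splice sites
  by a few bases will yield duplicate merged models rather than one.
* The fragment model is single-interval; spliced fragments spanning
  introns are not simulated, though the counter handles them (exon-union
  overlap).
* Specificity against unknown truth is not estimated — only recovery of
  withheld known transcripts, which is the validation the design admits.
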