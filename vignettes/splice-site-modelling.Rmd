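---
title: "Splice-site modelling with spliceworks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-site modelling with spliceworks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceworks)
```

## The problem

Splicing removes introns from pre-mRNA at donor (exon→intron, canonically
GT) and acceptor (intron→exon, canonically AG) sites. Predicting these
sites directly from genomic sequence supports gene annotation, the study
of alternative isoforms, and the interpretation of variants that create
or destroy splice signals — including cryptic sites activated deep inside
introns. spliceworks implements the full tool chain for this task:
dataset construction from a genome and its annotation, a deep
convolutional scorer, training and transfer learning, probability
calibration, genome-scale prediction, variant delta-score annotation, and
in-silico mutagenesis (ISM) analysis, together with a synthetic-genome
fixture generator that makes every stage testable on a laptop.

## From annotation to training tensors

`create_dataset()` reads a FASTA genome and GFF3/GTF annotation and
produces train/test archives of per-gene examples:

* **Gene selection.** Features of type `gene` are retained; by default
  only `protein_coding` biotypes. Pseudogenes are dropped, matching on
  the feature type `pseudogene` or the biotypes `pseudogene`,
  `transcribed_pseudogene`, `processed_pseudogene`.
* **Canonical transcript.** The longest transcript of each gene (by
  genomic span) is used for labeling; ties break to the
  lexicographically smallest transcript id so runs are reproducible.
* **Labels.** Over the sense-strand gene sequence, each intron labels
  the last exonic base of its upstream exon as *donor* and the first
  exonic base of its downstream exon as *acceptor*; everything else is
  *none*. The indexed base is a convention the annotation formats leave
  open; this package places labels on the exon-boundary bases and records
  the convention in archive metadata so it is auditable. With
  `canonical_only = TRUE`, introns whose terminal dinucleotides fall
  outside GT–AG / GC–AG / AT–AC are skipped: curated annotations still
  contain misannotated sites, and this switch trades recall of unusual
  introns for label precision. Minus-strand genes are
  reverse-complemented so the model always sees the sense strand;
  predictions are mapped back to plus-strand coordinates on output.
* **Encoding.** A/C/G/T(U) are one-hot unit vectors; any other symbol is
  the zero row, which also serves as the padding encoding. Soft-masked
  lowercase sequence is uppercased first — masking state carries no
  information the model should use.
* **Segmentation.** Each gene is tiled into `ceil(L/5000)` disjoint
  5,000-nt label cores, each wrapped in a 15,000-nt feature window
  (5,000 nt of context per side); deficits are padded (zero feature
  rows, all-zero label rows). A 22,000-nt gene therefore yields feature
  tensors of shape (5, 15000, 4) and label tensors of (5, 5000, 3), the
  fifth core holding 2,000 real positions.
* **Splitting.** The human split holds out chromosomes 1, 3, 5, 7, 9 for
  testing and trains on the rest; the random split shuffles chromosomes
  under a seed (default 10, the first ensemble seed) and accumulates
  them by length until the training fraction (default 0.8) is reached.
* **Paralog removal.** Test genes whose DNA aligns to any training gene
  with more than 80% identity *and* 80% query coverage are excluded to
  prevent leakage of near-duplicate sites. The aligner is an interface —
  identity is matching bases over the alignment block, coverage the
  aligned query span over the query length — with a local-alignment
  backend (`pairwise_aligner()`) suited to gene-scale sequences; a
  minimizer-based long-sequence aligner can be injected behind the same
  contract for genome-scale corpora. Similarity is computed on gene-span
  DNA (not spliced transcripts), which is the conservative choice for
  leakage control.
* **Archives.** Examples are packed into batch groups of up to 100 genes
  with metadata (flanking size, encoding version, split, label
  convention) and serialized; the roundtrip is lossless.

## The scorer

The model is a dilated residual convolutional network mapping one-hot
sequence to a per-position probability simplex over {none, acceptor,
donor}. An initial 1×1 convolution lifts 4 channels to `L` feature
channels (default 32; tests use 8). The trunk is a sequence of residual
units — each is batch norm → LeakyReLU(α = 0.1) → dilated convolution,
applied twice, added back to its input — whose kernel widths `W` and
dilation rates `AR` grow with depth. Every fourth unit feeds a skip path
through a 1×1 convolution; the skip sum passes through a final crop and a
1×1 convolution to 3 channels and a position-wise softmax.

Because all convolutions are padded, the valid output is narrower than
the input by the **cropping length** `CL = 2 * sum(AR * (W - 1))`,
removed as `CL/2` per side. The four named configurations (flanking 80,
400, 2,000 and 10,000 nt) are constructed so that `CL` equals the
flanking size; `compute_cropping()` exposes the law. Any input longer
than `CL` can be scored in one pass — the network is applied
convolutionally, so a window of 15,000 nt yields 5,000 predictions with
the 10,000-nt configuration.

Each residual unit applies its `W`/`AR` entry to both of its
convolutions (the architecture vectors list one entry per unit).
Normalization layers use running statistics at inference, so `forward()`
is deterministic; training-mode batch statistics are a recognized source
of run-to-run variation. Checkpoints store parameters together with the
full configuration and seed, and refuse to load into a mismatched
configuration.

## Training

`train_loop()` optimizes with AdamW (learning rate 1e-3, decoupled weight
decay 0.01) under either loss:

* cross-entropy: mean over non-pad positions of `-log P[true class]`;
* focal: `-(1 - P)^γ log P` with γ = 2 by default, down-weighting
  well-classified background so the rare site classes contribute more.
  At γ = 0 the focal loss reduces exactly to cross-entropy, and for
  γ > 0 it is pointwise no larger.

The loss is averaged over non-pad positions (the sum/mean choice is open
in the formulation; the mean keeps magnitudes comparable across batch
sizes), probabilities are clamped at 1e-10 inside the log, and pad rows
contribute nothing. Two schedulers are provided: *multistep* (1e-3,
halved from epoch 6 onward) and *cosine warm restarts* (period 5,
floor 1e-5). Training splits genes 90:10 into train/validation under a
seed, runs up to 10 epochs by default, stops early after `patience = 2`
epochs without any validation-loss improvement (equal loss counts as no
improvement), and retains the best-validation parameters.
`transfer_init()` starts from a checkpoint and either unfreezes all
parameter groups or only the last *k* in forward order (`k = 1` trains
only the final 3-channel convolution); frozen groups — including their
normalization statistics — are bit-identical after training.

## Calibration

Class-wise temperature scaling divides each logit column by its own
temperature `T = [T0, T1, T2]` before the softmax; `T > 1` softens,
`T < 1` sharpens. `fit_temperature()` minimizes validation NLL by
full-batch Adam (initial rate 0.01), reducing the rate by 0.1 on a
two-iteration plateau and stopping once improvements fall below 1e-6,
with `T` initialized at 1 and clamped to [0.05, 5]. Diagnostics follow
the standard calibration toolkit: NLL, expected calibration error over
30 uniform right-closed confidence bins (empty bins contribute zero),
and per-class reliability curves with normal-approximation 95% intervals
(`SE = sqrt(p(1-p)/n)`, z = 1.96, bounds clamped to [0, 1]).

One subtlety deserves the exact statement: dividing a class's logits by
a positive constant preserves the ordering of positions on that class's
*logit* scale, so any ranking computed on logits — and the resulting
top-k sets — is invariant. On the *probability* scale the softmax couples
classes, so when temperatures differ between classes, cross-position
ranks (and the argmax) can change slightly; `calibrate_scorer()` reports
the argmax-change count, which is small in practice for near-uniform
fitted temperatures.

## Prediction and variant annotation

`predict_track()` tiles a target with disjoint 5,000-nt cores, each
scored inside a window carrying `flank/2` real context per side (N-padded
only beyond the sequence ends), so every position is reported exactly
once. Sequences longer than `split_threshold` (default 1.5 Mb) are
planned into chunks whose context spans overlap neighbouring chunks by
`flank/2`; since windows read real sequence across junctions, chunking is
purely a memory plan and chunked equals unchunked prediction exactly.
Ensembles of scorers sharing a cropping length are averaged
arithmetically, and results are independent of the batch size. BED output
(one file each for donors and acceptors) contains positions whose class
probability strictly exceeds the threshold (default 0.5), in 0-based
half-open coordinates, strand-resolved back to the plus strand when an
annotation is supplied.

`annotate_vcf()` applies the exclusion rules (outside annotated genes,
within `flank` of a chromosome end, deletions longer than `2*distance`,
REF mismatches — each skip carries a machine-readable reason and the
record passes through unannotated), then scores reference and alternate
haplotypes over the variant ± `distance` window (101 positions at the
default 50) and reports four delta scores with their positions:

* acceptor gain `max(a_alt - a_ref)`, acceptor loss `max(a_ref - a_alt)`,
* donor gain `max(d_alt - d_ref)`, donor loss `max(d_ref - d_alt)`.

Gains and losses are symmetric under swapping ref and alt. Reported
scores are clipped to [0, 1] (the signed maxima are kept in a debug
field); delta positions break ties toward the smallest absolute offset,
then upstream. For indels the alternate score track is realigned to
reference offsets: positions inside a deletion are masked out of the
maxima, and scores over inserted bases collapse onto the variant offset
by maximum.

## Evaluation and ISM

Top-k accuracy extracts, per class, the `k * n_true` highest-scoring
positions (ties break by position index; pad positions are never
candidates) and reports the fraction that are true sites — with 10 true
sites per class, k = 1 examines 20 predictions in total, k = 2 examines
40. Thresholded metrics use the standard confusion definitions
(precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, accuracy `(TP+TN)/total`,
F1 the harmonic mean). AUPRC is the step-wise average-precision
area over all distinct thresholds and is verified against a brute-force
threshold sweep. Zero-denominator metrics report 0 with a warning rather
than NaN.

ISM substitutes every non-reference base at every position in a window
around a site, rescores the site, and summarizes the *importance* of a
position as `S_ref` minus the mean substituted score. Two averaging
conventions are in circulation — over the three non-reference
substitutions, or over all four bases including the reference (which
simply scales importance by 3/4); the three-base mean is the default
because it makes "no effect" exactly zero, and `average = "four"` gives
the other. Profiles aggregate linearly
into position-by-substitution mean-decrease matrices for logo rendering,
and profile concordance between scorers is summarized by Pearson
correlation (undefined for zero-variance profiles, reported as missing).

## The fixture generator and what it does (not) show

`generate_genome()` plants multi-exon genes on both strands of
uniform-random chromosomes. Donors carry the strong consensus
`CAG|GTAAGT` and acceptors a C/T-enriched polypyrimidine tract followed
by `TTTTTCAG|G`; the intron-terminal dinucleotides follow a configurable
motif mix (GT–AG by default, optionally GC–AG, AT–AC or noncanonical).
Each gene's first long intron also hides a one-mismatch donor decoy
(`CAGGTCAGT`) whose repair is the canonical donor-gain variant fixture.
Optional pseudogene decoys and mutated paralog copies (consensus windows
exempt from mutation, so planted labels stay truthful) exercise the
filtering steps. `make_mock_scorer()` scores by consensus match count
through a softmax — above 0.9 at a full match, below 0.1 otherwise — and
satisfies the same forward contract as a trained scorer, so prediction,
variant and ISM machinery can be tested without training.

Synthetic background is i.i.d. uniform over ACGT. Real genomes differ in
base composition, repeats, intron length distributions, and in having
weak, context-dependent splice signals; passing fixture tests therefore
demonstrates the *correctness of the machinery* (coordinates, strand
handling, tiling, deltas, metrics) and the *trainability of the
architecture on clean signal*, not field accuracy on real genomes.

## Study conditions for the desk-scale learnability check

The learnability smoke test trains the smallest configuration (flanking
80 nt, 8 channels) on 30 genes across 5 chromosomes, split 80:20 by
chromosome and 90:10 into train/validation. Genes are sized to fill the
5,000-nt label core (9–12 exons of 220–320 nt, introns of 120–200 nt),
so segments are signal-dense rather than pad-dominated — roughly ten
donor sites per segment. Training runs 30 epochs of AdamW under the
cosine warm-restart scheduler with one segment per optimization step;
on a single CPU this gives the optimizer on the order of 800 steps in a
few minutes, after which validation top-1 accuracy for donors exceeds
0.9. These sizes are the package's chosen study conditions for a
desk-scale demonstration; they are reused by `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Probabilities are clamped at 1e-10 inside logarithms.
* Softmax subtracts the row maximum before exponentiation; all-N (zero)
  input still yields finite simplex rows.
* Forward on an input of length ≤ CL raises an error naming the minimum
  valid length.
* Batch norm uses ε = 1e-5 and running-statistic momentum 0.1.
* Weight initialization is He-style scaled Gaussian under a recorded
  seed; seeds 10–14 are the ensemble convention.
* Empty reliability bins are omitted; empty BED files are legal output;
  an empty VCF body round-trips to a header-only annotated VCF.
* Canonical-transcript ties, delta-position ties and equal-score top-k
  ties all have documented deterministic resolutions.

## Known limitations

* Training here is CPU-bound and desk-scale; reproducing published
  accuracies on real genomes requires hardware and data volumes outside
  this package's scope.
* The dataset archive uses R's native serialization rather than HDF5;
  the batch-group structure, metadata and lossless roundtrip are
  preserved, but the files are not interchangeable with HDF5 tooling.
* The default paralog-aligner backend is quadratic-time local alignment,
  appropriate for fixtures and small genomes; inject a minimizer-based
  backend for large corpora.
* Only the canonical (longest) transcript is labeled; alternative
  isoforms and intergenic training regions are out of scope.
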