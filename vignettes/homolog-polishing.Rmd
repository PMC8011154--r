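---
title: "Homolog-guided polishing of draft microbial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homolog-guided polishing of draft microbial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homologpolish)
```

## The problem

Nanopore-only assemblies of microbial genomes carry *systematic* errors:
basecalling mistakes shared by most reads at a locus, overwhelmingly
single-base insertions or deletions inside homopolymer runs. Because the
error is in the reads themselves, no amount of read-consensus polishing can
remove it. Within coding sequence such indels shift the reading frame, so a
handful of them inflates apparent pseudogene counts and depresses assembly
quality from roughly Q30 to useless for annotation.

The remedy implemented here uses a different source of evidence: *homologs*.
Closely related genomes are highly conserved at the sequence level, and a
position where nearly **all** related genomes agree against the draft is far
more likely to be a sequencing artifact than a true difference. The
complication is that related genomes also differ from the draft genuinely —
strain variation, including true indels that inactivate genes (pseudogenes).
Those must be *retained*. Distinguishing the two cases is a supervised
classification problem, and the pipeline is:

1. **Screen**: reduce every candidate related genome to a MinHash sketch
   (the `s` smallest 53-bit hashes over canonical k-mers, default
   `s = 1000`); estimate identity against the draft from the containment
   index; keep genomes with identity at least `p` (default 95%) and take the
   top `t` (default 20).
2. **Pile up**: align the selected homologs onto the draft genome-to-genome
   (minimap2 `asm5` by default, or precomputed PAF/SAM) and stack the
   alignments into per-position columns.
3. **Featurize**: each candidate indel locus (any position where at least
   one homolog implies an insertion or deletion) becomes twelve features
   over 21 numeric dimensions.
4. **Classify**: a seven-class RBF-kernel SVM decides, per locus, between
   *insertion of A/T/C/G*, *deletion*, *no insertion*, and *no deletion*.
5. **Edit**: only predicted systematic errors are corrected; retain classes
   leave the draft untouched.

## The feature encoding

The twelve features span 21 dimensions:

| feature group | dims | content |
|---|---|---|
| matched allele counts | 4 | homologs matching A/T/C/G at the locus |
| inserted allele counts | 4 | homologs inserting A/T/C/G before the anchor |
| deletion allele count | 1 | homologs deleting the draft base |
| homologous coverage | 1 | homologs whose alignment spans the locus |
| homopolymer length | 10 | one-hot over categories {1, 2, ..., 9, >=10} |
| paired-ambiguity code | 1 | 0 unpaired / 1 major allele / 2 minor allele |

The first ten dimensions are raw counts min-max normalized into [0, 1]. The
scaler is fitted on the training set, serialized inside the model bundle,
and clamps unseen values at prediction time; this makes prediction
deterministic and independent of the composition of the genome being
polished (per-locus normalization by coverage was the alternative reading;
the global scaler was chosen for that determinism, and coverage itself is a
feature, so the SVM can learn the interaction).

The homopolymer length is the run of the affected base adjacent to the
locus: for an insertion of base X anchored before position *p*, the longer
of the X-runs ending at *p − 1* and starting at *p* (1 if neither neighbour
is X); for a deletion, the run containing the draft base. It is *one-hot*
encoded, not numeric: basecallers overfit particular run lengths, so the
error rate is not monotone in length and a categorical encoding
discriminates better. Lengths of ten and above share one bucket because the
run-length distribution is strongly right-skewed — most runs are shorter
than three and almost none exceed ten.

The ambiguity code handles a subtle failure mode: when the major and minor
alleles of a variation both differ from the draft by one indel at nearby
anchors, their flanking similarity against the draft is identical, and
counts alone mislead. Such loci occur in close pairs whose supporter sets
are mutually exclusive. The detector scans same-contig candidate pairs
within a window (default 100 bp, "proximity" being otherwise unquantified),
requires disjoint supporter sets jointly explaining at least 80% of the
homologs covering both loci, and pairs greedily leftmost-first with the
nearest qualifying partner. The majority locus is coded 1, the minority 2,
everything else 0. The code is fed to the SVM as an ordinal value in
{0, 1, 2} rather than one-hot, since it is three-valued and ordered by
allele rank.

## The classifier

A single seven-class SVM (RBF kernel, `C = 1.0`, one-vs-one multiclass) is
trained on loci labeled against a truth genome. Three choices the method
description leaves open are resolved as follows and recorded in the model
bundle:

* **gamma** follows the "scale" policy, `1 / (n_dims * var(X))` over the
  scaled training matrix — a standard default that adapts to feature
  variance.
* **Class imbalance** is handled only by deduplicating exact-duplicate
  no-deletion vectors (that class dominates raw training data by orders of
  magnitude); no class weights are applied.
* **Prediction is kind-masked**: an insertion candidate can only receive an
  insertion-side class (INS_A/T/C/G or NO_INSERTION) and a deletion
  candidate only DELETION or NO_DELETION. One model is trained over all
  seven classes, but candidates are intrinsically one-sided; masking selects
  the best-scoring admissible class from the pairwise decision values.

Data are split 9:1 into train and test, stratified per class for classes
with at least 10 members (smaller classes contribute `floor(n/10)` test
rows, so none is silently emptied from training). Default split seed 17.
Reported metrics are per-class precision/recall/F1 with macro averages and
the 7x7 confusion matrix.

At prediction time the genome is chopped into 10-kbp segments so that
classification can run in parallel; features are computed genome-wide
*before* chopping, so segment boundaries never truncate pileup context, and
results are identical for any thread count.

## Sketching details

The k-mer length is not dictated by the method description; `k = 21` is the
common choice for bacterial-scale MinHash screening and is configurable.
Hashing is FNV-1a with a splitmix64 finalizer over the canonical k-mer (the
lexicographic minimum of the k-mer and its reverse complement), seeded
(default 42) and masked to 53 bits so hash values are exactly representable
as R doubles on every platform. Identity is estimated from containment,
`identity = 1 + ln(c)/k` (clamped at 0), the first-order form of the Poisson
k-mer-survival model — containment semantics fit the screening direction
(sketch against the draft's full k-mer set). A symmetric Mash-distance
estimator over the merged bottom-s Jaccard index is provided for
sketch-vs-sketch comparison. Genomes with fewer than `s` distinct canonical
k-mers keep short sketches, and the containment denominator is the actual
sketch length, which makes sketch containment *exact* for such genomes.

## What the synthetic worlds emulate

All tests run against seeded fixture worlds built by `make_fixture_bundle()`:

* a **truth genome** (default 200 kb, GC 0.5) drawn i.i.d. except that each
  base repeats its predecessor with probability 0.15, producing the
  right-skewed homopolymer run-length distribution of real microbial
  genomes (most runs < 3, almost none > 10);
* **20 strains** around 99% identity: SNP events placed to hit the identity
  target and shared by uniform random subsets of strains, plus 300 true
  indel events shared by small geometric subsets (mostly 1–2 carriers) —
  true indels segregate at low frequency under frameshift-purifying
  selection, and this is what gives the retain classes their signal;
* a **draft** derived from the truth by 500 systematic errors, 70%
  deletions-of-a-base (requiring INS_X fixes) and 30% duplications
  (requiring DELETION fixes), sampled with weight `run_length^2` so they
  concentrate in homopolymers;
* **exact alignments**: every edit is recorded, so strain-vs-draft and
  truth-vs-draft CIGARs are composed algebraically rather than estimated by
  an aligner, and label closure holds exactly (applying the labeled edits to
  the draft reproduces the truth byte-for-byte).

Event positions are kept at least 10 bp apart so edits never interact; this
makes correction and retention unambiguously scoreable and lets residual
error counts be computed by exact bookkeeping instead of re-alignment.

The generator deliberately does **not** emulate: alignment ambiguity inside
homopolymers (the paired-ambiguity signal therefore stays near zero on
fixtures and that feature is exercised by targeted unit cases instead),
phylogenetic structure among strains (sharing is star-like random),
misassemblies, structural variation, mismatch-error spectra of specific
basecallers, or read-level artifacts. Passing the fixture suite therefore
demonstrates that the machinery — screening, pileup, featurization,
classification, editing, evaluation — is correct and that the class
structure is learnable from homolog counts; it does not certify error rates
on real flow-cell data.

## Evaluation conventions

Assembly quality is reported as `Q = -10 log10(errors / aligned_bases)`
computed from assembly-vs-reference alignments with `=`/`X` CIGARs:
mismatches are X bases, insertions and deletions are counted in bases (not
events). Zero observed errors are reported as Q90, the conventional ceiling
for an error-free alignment. `avg_q` pools counts across contigs;
`median_q` is the median of per-contig Q values (the aggregation unit is
otherwise unspecified; per-contig is this package's concrete choice).
Correction ratios `100 (before − after) / before` are rounded half-up to
two decimals, matching how such percentages are conventionally printed.
Error loci intersecting any interval of a BED annotation count as coding.

## Problem sizes and determinism

The default fixture (200 kb, 20 strains, 500 errors) builds in a few
seconds and the full train-and-polish cycle runs in well under a minute on
one CPU; the test suite uses a 20-kb world for unit tests and the default
world for the end-to-end recovery checks. Every stochastic step — truth
genome, error placement, strain simulation, train/test split, SVM training
— is seeded, and a fixed seed yields byte-identical fixtures, predictions
and polished FASTA output.

## Known limitations

* Only indel errors are corrected; mismatches are left alone by design,
  since substitutions frequently reflect strain variation and are less
  destructive in coding regions.
* Polishing quality degrades when no sufficiently close relatives exist;
  the pipeline aborts with guidance when nothing passes the identity
  threshold rather than polishing against distant homologs.
* Multi-base insertions are recovered one base per polishing round (the
  candidate encoding names a single inserted base); iterative rounds
  converge on longer insertions.
* Eukaryote-scale genomes are out of scope; repeat structure and genome
  size break both the screening assumptions and the alignment contract.
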