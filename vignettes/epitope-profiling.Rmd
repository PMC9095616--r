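---
title: "Epitope profiling of phage-display immunoprofiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epitope profiling of phage-display immunoprofiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette describes the models and procedures implemented in
`epitopescan`, the assumptions behind them, the parameters that matter, and
the design choices made where the method left genuine freedom.

## The data model

Mimotope variation analysis (MVA) profiles a serum sample by panning a
random 12-mer phage-display peptide library against the sample's IgG,
deep-sequencing the captured phage, and counting peptides. The package's
unit of data is the **peptide repertoire**: a map from 12-mer amino-acid
sequence to read count, with a sample identifier and a normalization flag.

Cleaning removes what cannot be a library peptide: sequences whose length
is not 12, sequences containing non-canonical letters (stop `*`, ambiguous
`X`, anything outside the 20 canonical residues), and any peptide on a
user-supplied artefact list. The artefact list is deliberately an input
(default empty): upstream error profiles differ between sequencing setups,
and an explicit list plus the removal report keeps the cleaning auditable.
No library-bias correction is applied.

Normalization scales every count by `target / total` so that each sample
sums to 3 × 10⁶ reads, the package-wide depth standard. Counts become
real-valued and are never re-rounded: downstream abundance sums and ratios
are real-valued, and rounding would break the conservation of relative
composition (checked to a relative tolerance of 1e-9 in the tests).

## Epitope patterns and the discovery search

An **epitope** here is a motif of fixed amino-acid positions separated by
single-position wildcards, written as a string over the residue alphabet
plus `.` — for example `YKDWH.R`. The grammar is deliberately minimal:
ends fixed, span at most 12 (one peptide window), no variable-length gaps
and no residue-group symbols. This is the smallest grammar consistent with
the fixed-residue alignment rule used downstream; richer grammars would
change what "every fixed residue matches" means.

Discovery compares a **query** repertoire with a **reference**:

* *discriminative* mode — the reference is the paired pre-treatment sample
  of the same subject; minimum fold enrichment 2;
* *vs-random* mode — the reference is a randomly generated peptide set;
  minimum fold enrichment 10.

For a pattern with matching abundance $k_q$ (of total $n_q$) in the query
and $k_r$ (of $n_r$) in the reference,

$$\mathrm{fold} = \frac{k_q / n_q}{(k_r + 1) / n_r},$$

with a +1 pseudocount on the reference only: a pattern absent from the
reference gets a large but finite fold, which is the conservative
direction. Significance is a hypergeometric upper tail on **distinct
peptides**: $N$ distinct peptides in query plus reference, $K$ of them
matching, $n$ in the query, $k$ matching in the query, $p = P(X \ge k)$.
The urn is counted in unique peptides regardless of the abundance units
because the hypergeometric model needs exchangeable discrete units, and
normalized read counts are not integers. Abundances and fold default to
normalized reads (`count_mode = "reads"`), since an epitope's abundance is
the number of IgG-bound peptide observations carrying it; a
`unique_peptides` mode is available.

The search enumerates patterns breadth-first by appending one symbol (a
residue or a wildcard; wildcards are never terminal) and carries each
pattern's match list — the (peptide, offset) positions where it occurs —
in both repertoires. Appending a symbol filters the parent's list, so
distinct-peptide support is monotone non-increasing, and pruning on
minimum support (`min_support`, default 10) is the only pruning rule: the
enumeration is exhaustive within the span bound. The default of 10 distinct
query peptides reflects that the 10⁻⁸ p-value cutoff is unreachable at
lower support for realistic set sizes, so lower-support branches cannot
produce reportable patterns. The inner loop is C++ (via Rcpp); the test
suite checks the whole search against a brute-force enumeration oracle on
randomized small instances, where every candidate pattern is evaluated
directly.

Reported patterns require ≥ 4 fixed residues. No multiple-testing
correction is applied in discovery: the fixed 10⁻⁸ cutoff is the device
that controls false discoveries, and reported p-values are explicitly
unadjusted.

**Core reduction.** Discovery output is redundant (a strong motif appears
together with its sub-patterns and extensions). `reduce_to_core()` removes
any pattern whose query match set is a subset of a retained pattern's match
set with smaller-or-equal p-value; among equal-p patterns with identical
match sets the one with more fixed positions, then the lexicographically
smallest, is kept. The notion of a "core epitope" is not otherwise pinned
down by the method; match-set containment is this package's declared rule,
chosen because it is order-independent and verifiable against an $O(m^2)$
pairwise oracle.

## Antigen mapping

Patterns are aligned to linear database epitopes and to full antigen
sequences under one rule: a hit is an offset at which **every fixed residue
is identical**; wildcards are unconstrained; overlapping hits are all
reported; coordinates are 1-based inclusive. Only pattern-inside-epitope
containment is considered when matching database epitopes (the reverse —
a database epitope occurring inside a longer pattern — is not implemented,
as patterns are at most 12 residues and database epitopes typically
longer). Antigens with sequence identity to at least one epitope from each
of two pattern sets (e.g. treatment-specific and disease-specific) are
recruited by accession intersection.

The antigen-level response score is the mean, over distinct patterns
hitting the antigen, of each pattern's abundance in the sample, reported
raw and as log10(mean + 1). The +1 offset keeps zero-abundance antigens
defined and is recorded in the score matrix metadata. One sequence per
accession is assumed; isoforms are not expanded.

## Profile metrics

**Cosine similarity (CSI).** Samples are compared on their top-2500
peptide profiles. The axes are the union of the two samples' top lists; a
sample contributes its abundance only for peptides in its own top list and
0 elsewhere, tying both magnitude and membership to the top profile. The
alternative (full-repertoire values on union axes) is available behind
`mask_to_top = FALSE`. CSI is symmetric, lies in [0, 1], equals 1 for
self-comparison and is invariant to rescaling a sample's counts.

**Immunodominance and Z-score maps.** The top 50 epitopes are ranked by
abundance in a designated sample (ties lexicographic). Per-patient Z-score
maps standardize the patient's epitope-by-sample abundance sub-matrix with
**one global mean and one sample standard deviation (n−1 denominator)**
over all entries. The per-epitope alternative (standardizing each epitope
across its two samples) is unusable at two samples per patient — every row
would collapse to ±0.707 — and was rejected. Values above the patient's
97.5th percentile of the z-scores are capped at that percentile; the cap
is one-sided (upper only), with a symmetric option behind a flag. The n−1
denominator follows the statistical-environment default; the choice is not
forced by the method description.

**Ratios.** The pre/post response change of an epitope is
`log10((post + 1)/(pre + 1))`; 0 means unchanged. Competition experiments
(serum pre-blocked with cell lysate) are summarized as
`competed / uncompeted` abundance; values well below 1 localize the
response to lysate antigens.

## Biomarker statistics

Group differences per epitope use the Wilcoxon rank-sum test with
continuity correction (the base R implementation with `exact = FALSE`,
`correct = TRUE` — midranks for ties, tie-corrected normal approximation).
ROC analysis evaluates every distinct score plus +∞ as thresholds with the
positive call `score ≥ threshold` (higher abundance calls the cancer
class); the operating point maximizes Youden's J = sensitivity +
specificity − 1, with ties broken by higher specificity then lower
threshold. Markers must exceed sensitivity 0.72 and specificity 0.67
(strict), are ranked by J (ties by rank-sum p, then pattern), and the top
15 are kept. How the original ranking of thousands of antigen-associated
epitopes down to exactly 15 was performed is not fully documented; the
Youden-rank-plus-floors rule here is a declared reconstruction.

Combined models are maximum-likelihood logistic regressions (IRLS,
log-likelihood tolerance 1e-8, 100 iterations) on log10(x+1)-transformed
abundances — abundances span orders of magnitude, and the original
software's input scale is unstated; a raw-scale option exists. Constant
and duplicated columns are dropped with a warning. With an 11-vs-90-style
design near-complete separation is plausible; on separation the fit stops
at the iteration cap, is flagged `converged = FALSE`, and AUC, sensitivity
and specificity are still reported because the rank-based ROC summary is
separation-robust — no penalization is applied. `best_subset()` fits every
non-empty subset up to size 3 and keeps the highest AUC (ties prefer the
smaller subset, then lexicographic order). **No cross-validation is
performed**: reported performance is apparent performance, and the model
report says so.

## The synthetic cohort generator

Real MVA sequencing data are not public, so validation runs on synthetic
cohorts whose defaults are fixed once:

* 3 × 10⁵ reads over 5 × 10⁴ unique peptides per sample — a deliberate
  ~10% scale model of real sequencing depth (~3 × 10⁶ reads, ~6 × 10⁵
  unique), keeping whole-cohort analyses desk-sized while preserving the
  top-N selection and abundance-sum behaviour;
* uniform background residue frequencies (the library's actual codon-level
  bias is out of scope, and the frequency vector is a parameter);
* counts from a discrete power law (Pareto tail, dispersion 1.5), matching
  the heavy-tailed look of deep phage-display count data;
* three planted motifs (baseline matching read fractions 10⁻³, 10⁻³,
  5 × 10⁻⁴; folds 10, 10, 8) targeting the treated groups, spanning the
  vs-random threshold regime;
* a study design of 2 vaccinated subjects (paired pre/post samples), 2
  checkpoint-inhibitor subjects (single samples), and 4 + 2 controls —
  12 samples, a desk-scale miniature of a real cohort's group structure;
* competition samples off by default; when enabled, motif-matching reads
  are binomially thinned with retention 0.1, so the realized relative
  abundance is the depletion factor up to binomial noise.

Motif planting rewrites existing background peptides (imposing the fixed
residues at a random admissible offset) rather than appending new ones,
so the unique-peptide count stays a clean configuration knob; peptides are
selected greedily from the small-count pool until the motif's matching
read fraction reaches its target, which keeps the overshoot small. The
random reference set for vs-random discovery defaults to the query's
number of unique peptides (a balanced urn), each with count 1; the
original reference-set size is not documented, so it is exposed as a
parameter rather than asserted.

The generator returns cleaned raw integer repertoires; normalization is
applied at load time (the on-disk interchange format is an integer-count
TSV, and keeping generation and normalization separate lets the loader be
exercised on exactly what it will read in practice).

**What the generator does not emulate.** Phage selection rounds,
amplification bias and codon usage are not modelled; counts are
independent across peptides; and different samples — including a subject's
pre and post samples — draw independent backgrounds, so the within-subject
profile similarity seen in real longitudinal data (paired CSI well above
between-subject CSI) is absent. Passing recovery tests therefore show that
the analysis finds planted enrichment structure of realistic effect size
under realistic count noise; they do not show robustness to correlated
backgrounds, batch effects or selection artefacts of real panning data.

## Numerical choices and degenerate inputs

* Hypergeometric tails come from the upper-tail hypergeometric
  distribution function computed in log space, verified against exact
  combinatorial summation (relative tolerance 1e-12) on all small urns.
* Ties in every ranking are broken deterministically (documented above),
  and string ordering is byte-lexicographic (C locale) everywhere, so all
  outputs are reproducible across platforms and locales.
* Degenerate inputs error explicitly: empty repertoires cannot be
  normalized or compared; constant matrices cannot be z-scored;
  single-class label vectors cannot be ROC-analyzed; a zero uncompeted
  abundance cannot normalize a competition value. All-identical samples in
  the rank-sum test return p = 1.
* Every stochastic component takes an explicit seed; the pipeline derives
  a named sub-stream per stage from one master seed (hash of the stage
  label), so stages are reproducible in isolation and two runs with the
  same configuration are byte-identical.

## Problem sizes used in the shipped tests

The test suite validates discovery exhaustively against brute force on
instances of up to 30 unique peptides (span ≤ 6), planted-motif recovery
at 10⁵ reads over 2 × 10⁴ unique peptides across 5 seeds, and the full
pipeline at the default 3 × 10⁵-read, 12-sample cohort. These sizes are
the package's chosen validation scale: large enough that the heavy-tailed
count structure and the threshold regime are realistic, small enough that
exhaustive oracles remain computable.

## Known limitations

* The pattern grammar excludes variable-length gaps and residue classes;
  epitopes whose conservation pattern needs either will be found only via
  their fixed-residue sub-patterns.
* Marker selection reports apparent (resubstitution) performance; with
  few cases, Youden-optimal cutoffs are optimistically biased.
* The core-epitope reduction and the 15-marker ranking rule are declared
  reconstructions of under-specified steps, not re-implementations.
* Antigen recruitment depends entirely on the supplied linear-epitope
  table and antigen FASTA; no live database retrieval is performed.
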