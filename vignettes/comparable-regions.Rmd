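---
title: "Comparable regions for cross-species RNA-seq: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparable regions for cross-species RNA-seq: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Between-species expression comparisons inherit two biases that within-species
designs do not have: the two genomes' annotations of a 1:1 ortholog pair
usually delimit different sequence, and read coverage along the pair can
disagree between species for purely technical reasons (annotation errors,
unannotated isoform differences, mapping artifacts in diverged regions). Both
make per-gene counts incommensurable.

`orthowindow` addresses this by quantifying only *comparable regions*. The
unit of comparability is a fixed-length window of the pairwise transcript
alignment of each ortholog pair. The pipeline assumes:

* each gene contributes one designated transcript per species (multi-isoform
  reconciliation is out of scope);
* replicate coverage profiles within a species are highly correlated, and a
  truly comparable gene's profiles across species are related linearly —
  the same window-to-window shape, scaled by the expression ratio;
* orthologous transcripts can be globally aligned (the alignments may be
  produced externally, e.g. with MAFFT, and supplied as 2-record aligned
  FASTA files).

Stages, with the objects they produce:

1. **Windowing** (`window_alignment`): alignment columns are tiled into
   disjoint windows of `window_len` columns; a terminal partial window is
   dropped so all windows share one denominator and identities are
   comparable across windows.
2. **Window filter** (`passes_window_filter`): identity strictly above
   `min_identity` and strictly fewer than `max_gap_cols` gap columns. A
   column is a gap column if either row holds a gap; identity is
   `n_match / window_len`, so gaps penalize identity. Both inequalities are
   strict, matching the ">70% identity, <3 bp gaps" reading literally.
3. **Coordinate mapping** (`transcript_to_genomic`): each retained window's
   transcript interval in each species is mapped through that species' exon
   chain (5'→3'; on the minus strand the chain is walked in descending
   genomic order). A window spanning a junction yields one genomic segment
   per exon touched. Serialized as one GTF per species (1-based inclusive,
   feature `exon`, `window_id` attribute), window ids identical across
   species.
4. **Coverage concordance** (`classify_gene`): per gene, the two species'
   per-window mean depths (each sample scaled to per-million depth mass,
   then averaged over replicates) are compared. Genes with Pearson
   `r < min_r` are excluded *unless* a two-sided exact sign test on the
   per-window comparison is significant at `sign_alpha` — coverage
   consistently higher in one species is exactly what a real expression
   difference looks like, so those genes are rescued, not excluded.
5. **Outlier windows** (`robust_line_fit`, `flag_outliers`): for retained,
   non-rescued genes, profile a is regressed on profile b with a Huber
   M-estimator (`MASS::rlm`, tuning constant 1.345, ≤ 50 IRLS iterations);
   windows with |residual| > `outlier_z` MAD-scaled units are dropped from
   both species. Rescued genes skip outlier removal: their profiles are
   *expected* to sit off the shared line, and the rescue clause exempts
   them.
6. **Quantification** (`count_fragments`, `tmm_factors`, `cpm`, `fpkm`):
   union-mode fragment counting (≥ 1 bp overlap with retained windows of
   exactly one gene; multi-gene fragments are ambiguous and discarded),
   TMM normalization, CPM, and FPKM over each species' own comparable
   length. Because comparable lengths differ between species by at most the
   gap allowance per window, cross-species testing should use counts/CPM;
   FPKM is provided for display. Differential-expression *testing* itself
   is deliberately external: adjusted p-values from any standard engine are
   accepted and thresholded (`de_threshold_filter`, strict
   `adj_p < alpha`, `|log2FC| > cutoff`).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window_len` | 25 | alignment columns | small enough to localize misalignment, large enough for a meaningful identity fraction |
| `min_identity` | 0.70 (strict >) | fraction of window | tolerates rodent-scale neutral divergence while rejecting misaligned blocks |
| `max_gap_cols` | 3 (strict <) | columns | ≤ 2 gap columns pass; keeps window lengths nearly equal across species |
| `min_r` | 0.4 | Pearson r | below this, window profiles carry no shared shape signal |
| `sign_alpha` | 0.001 | p-value | per-gene exact test; intentionally conservative, no FDR across genes |
| `outlier_z` | 2.5 | MAD-scaled residuals | conventional robust-outlier cutoff |
| `min_windows` | 4 | windows | a correlation over fewer points is meaningless; genes below are excluded outright |
| `pseudocount` | 0.5 | CPM | stabilizes log2 fold changes of zero-count genes |

Windows are measured in alignment columns (not ungapped bp of one species),
and the identity denominator includes gap columns; both choices are
configurable readings of an ambiguous convention and are encoded in
`filter_config` so they can be revisited without touching code.

## Numerical and design choices

* **Aligner.** The built-in global aligner (Rcpp) uses affine gaps with the
  convention that a gap run of length L costs `gap_open + (L-1)*gap_extend`
  (defaults 2/−3/−5/−2), tie-broken diagonal > up > left, so results are
  deterministic. It exists for fixtures and small inputs; precomputed
  alignments are the recommended path at genome scale. `N` matches nothing;
  `.` is normalized to `-`; bases are case-folded.
* **Sign test.** Implemented via `stats::binom.test` at p = ½ (for the
  symmetric null the two-sided p equals the doubled smaller tail, capped at
  1); exact ties in normalized depth are dropped, standard sign-test
  practice. The gene screen is two-sided; cross-method validation
  (`method_concordance`) is one-sided (greater), the natural direction for
  "does the orthogonal assay corroborate more often than chance".
* **Robust fit.** Species b (the second column of the pair list) is x,
  species a is y; behavior under swapping is covered by tests rather than
  assumed. The residual scale is `mad(residuals)` (constant 1.4826); when
  MAD is zero with nonzero residuals the standard deviation is the
  fallback, and residuals below ~1e-8 of the response scale are treated as
  exact zeros so floating-point noise from a perfect fit is never amplified
  into fake outliers. Zero x-variance is a degenerate fit and excludes the
  gene (`excluded_degenerate`) rather than crashing.
* **Coverage normalization.** The source procedure is silent on whether
  coverage was normalized before comparison. Pearson r is scale-invariant,
  but the sign test is not, so each sample is scaled to per-million depth
  mass before the replicate mean; this makes the sign test well defined
  across library sizes. Mean per-base depth (not read count) is the window
  statistic because it is robust to junction-split window lengths.
* **Welch's t.** `stats::t.test(var.equal = FALSE)`; zero variance in both
  groups raises an error (documented convention) rather than returning a
  degenerate statistic.
* **TMM.** Authored in the package following the trimmed weighted-mean
  construction (30%/5% double trim, inverse approximate-variance weights,
  reference = sample with upper-quartile rate closest to the mean); factors
  are reference-relative (the reference's factor is exactly 1), and the test
  suite cross-checks against `edgeR::calcNormFactors` after matching
  edgeR's geometric-mean rescaling. No gene-length term enters, because the
  compared regions have near-equal lengths by construction.

## The synthetic-data generator

`sim_config()` / `make_fixture_dataset()` emulate the data regime the method
assumes: an ancestor transcript is mutated independently per species
(substitutions at rate d, indels with geometric lengths) with the true
column-level alignment recorded; exon models are drawn per species (min exon
30 bp, each gene in its own genomic slot); coverage follows a latent
lognormal window-weight profile shared across species for concordant genes
(scaled by 2^log2FC in species a) and drawn independently for discordant
genes, with multiplicative lognormal replicate noise; a configurable
fraction of windows is distorted 5× in one species to exercise the outlier
screen; fragments are Poisson in number and placed uniformly within windows.
Every draw uses an RNG stream derived from (seed, gene index, stage), so
per-gene output is byte-stable under changes of `n_genes`, and identical
configs produce byte-identical fixture directories.

Defaults encode the validation conditions: 300 genes, one third discordant,
log2FC ∈ {−2, 0, +2}, 3 replicates per species, noise σ_log = 0.2, window
profile σ_log = 1, 5% bias windows at 5×.

What the generator does **not** emulate: read-level sequencing error, splice
junction reads, GC/positional bias along transcripts,
transition/transversion asymmetry, and multi-isoform structure. Passing
tests therefore demonstrate that the pipeline's logic recovers truth under
its own model assumptions — not that those assumptions hold for any given
real dataset.

One property of the method worth knowing, visible in the synthetic runs:
when the two libraries differ strongly in composition (here, the asymmetric
arithmetic mean of 2^log2FC makes species a's depth mass ~1.7× species b's),
per-million scaling shifts *all* of species a's profiles down, and a
minority of genuinely discordant genes can acquire a "consistently lower in
one species" signature and be rescued by the sign test. This is inherent to
the rescue rule — it cannot distinguish a real global shift from a
compositional one at the single-gene level — and is the main reason the
discordant-gene exclusion rate sits below 1 in the end-to-end runs while
profile-level exclusion (no composition shift) is near-perfect.

## Problem sizes in the test suite

The suite validates primitives against independent oracles (exhaustive
binomial enumeration for every k at n ≤ 20; an exhaustive alignment
enumeration and an independently written plain-R DP for the aligner,
exhaustive over a two-letter alphabet at short lengths and randomized up to
length 8 including N; textbook formulas for Pearson and Welch on 100 random
vector pairs; per-base summation for window coverage), checks the
transcript↔genome round trip on 1,000 random intervals over random
multi-exon models on both strands, and runs the full pipeline end-to-end at
the default 300-gene conditions, asserting ≥ 0.90 gene-classification
accuracy, ≤ 0.3 median |log2FC error| over retained concordant genes, and
≥ 80% recall of distorted windows. `scripts/acceptance.R` re-runs the same
computations against the installed package and writes the numbers as JSON.

## Known limitations

* One transcript per gene; genes whose dominant isoforms differ between
  species will lose the non-shared exons to the identity filter, which is
  the intended behavior but reduces power.
* The sign-test rescue interacts with library composition (above); strongly
  asymmetric designs should interpret `retain_rescued` genes with care.
* Outlier removal is not iterated (no re-screen after dropping windows),
  and sign tests are per-gene at a fixed α, not FDR-controlled — both match
  the source procedure.
* The built-in aligner is quadratic in sequence length and memory-capped;
  it refuses inputs beyond ~20M DP cells and is not a substitute for a
  production aligner.
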