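---
title: "Methods: exon-intron split analysis in eisapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exon-intron split analysis in eisapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the tunable parameters and their defaults,
and the limits of what the synthetic-data tests demonstrate.

## The model

Total-RNA sequencing libraries contain reads from mature, spliced mRNA
(mapping to exons) and from nascent pre-mRNA (mapping to introns). Intronic
coverage is a proxy for transcriptional activity; exonic coverage reflects
transcription plus everything that happens to the mature transcript
afterwards. Between two conditions (labelled `young` and `expanded`
throughout, after the leaf-ontogeny designs this package targets), the
per-gene contrasts

$$\Delta \mathrm{Exon} = \overline{\log_2 E}_{\mathrm{expanded}} -
  \overline{\log_2 E}_{\mathrm{young}}, \qquad
  \Delta \mathrm{Intron} = \overline{\log_2 I}_{\mathrm{expanded}} -
  \overline{\log_2 I}_{\mathrm{young}}$$

are computed on normalized log2 expression averaged across replicates
within condition (averaging on the log scale; the alternative — averaging
counts before the log — differs only at low counts and is not exposed).
$\Delta\mathrm{Exon} - \Delta\mathrm{Intron}$ estimates the log2
post-transcriptional effect on mature-mRNA abundance: zero for purely
transcriptional regulation, negative when mature transcripts are
preferentially destabilized in the second condition.

## Region model

Reads are counted against a flattened, conservative gene model:

* **Exons** are the union over all transcripts: a base is exonic if it is
  exonic in *any* isoform. No isoform-level quantification is attempted.
* **Gene body**: the span from the first to the last CDS base. Counting only
  inside the CDS-bounded body implements the "no UTRs" rule without
  requiring UTR annotation; genes lacking CDS records cannot be trimmed and
  are excluded by default (`trim_mode = "none"` falls back to the full exon
  span when UTR contamination is acceptable).
* **Introns** are the maximal gaps between consecutive merged exons inside
  the body, so every intron has exon sequence on both sides ("enclosed"
  introns). Single-exon genes carry no intronic signal and are excluded.
* **Overlapping genes** are excluded pairwise — a read in a shared region
  cannot be attributed. The overlap test ignores strand by default because
  library strandedness is generally unknown for the data this targets; with
  stranded protocols `stranded = TRUE` restricts exclusion to same-strand
  overlaps. Overlap is tested between trimmed bodies (the regions actually
  counted), one of the two readings of the rule; both behaviours are
  documented rather than asserted as the original intent.

All internal coordinates are 0-based half-open; GFF3/GTF input is converted
at the parsing boundary, which keeps the interval algebra free of off-by-one
cases (verified against a per-base boolean-array oracle in the tests).

## Counting rules

* Only uniquely mapped records are used: `NH == 1` when the tag is present,
  otherwise MAPQ at or above `min_mapq` (default 30).
* A read is attributable to a gene only when **all** of its aligned blocks
  (CIGAR split at `N`) lie inside the gene body. Bodies are disjoint after
  the overlap filter, so the attribution is unique (asserted at run time).
* Classification is exon-over-intron: any overlap (≥ 1 bp) with exon
  sequence makes the read exonic — a boundary-spanning read certainly comes
  from a transcript containing that exon, and junction reads are the
  strongest mature-mRNA evidence. Otherwise any overlap with an intron
  (optionally shrunk by `intron_margin`, default 0) makes it intronic.
* Paired-end mates count as independent records by default; `fragment =
  TRUE` collapses mates by read name. Each counting unit increments at most
  one gene × compartment cell.
* The minimum-coverage filter keeps a gene only when both compartments have
  at least `min_reads = 2` in **every** sample — the strictest reading of a
  per-feature coverage requirement stated at gene level. A literal
  per-feature mode (every individual exon and intron ≥ 2 reads, requiring
  `counting_params(per_feature = TRUE)`) is provided; neither mode is
  asserted to be the original authors' computation.

## Normalization and the pseudocount

Each compartment is normalized separately by total library count: sample
counts are rescaled to the mean library total of their compartment and
log2-transformed after adding a pseudocount (default 8). The mean-library
target is an arbitrary positive constant — all deltas are invariant to it —
chosen so values read as counts at average depth. The pseudocount bounds the
variance of low-count log-ratios; 8 is the long-standing default of the
method family and is exposed as a parameter.

Two consequences worth knowing:

* At counts comparable to the pseudocount, deltas are shrunk toward zero
  (the intronic compartment, typically ~8-fold below the exonic one, is
  affected first). The significance test works on raw counts with offsets
  and is not shrunk.
* **Library-composition bias**: total-count normalization assumes the
  compartment composition is stable between conditions. If a noticeable
  fraction of genes carries a large exon-only effect, the exonic library
  totals themselves shift — by convexity even sign-balanced effects inflate
  them ($\mathbb{E}[2^p] > 1$) — and the normalization transfers a common
  offset of $-\log_2 f$ into every gene's $\Delta\mathrm{Exon}$. Under a
  mixture with 10% of genes at $|p| = 2$ this term is about $-0.15$ to
  $-0.25$ log2 units. The tests therefore measure estimator recovery on a
  2% spike-in (composition stable) and separately bound the mixture bias;
  analyses of datasets where pervasive large post-transcriptional shifts
  are plausible should treat absolute effect sizes with this caveat.

## The interaction test

For each gene, the $2 \times 2 \times$ replicates counts (compartment ×
condition) are modelled as negative binomial with log link and
compartment-specific log library totals as offsets:

$$\log \mu = \beta_0 + \beta_1 [\mathrm{intron}] + \beta_2
[\mathrm{expanded}] + \beta_3 [\mathrm{intron} \times \mathrm{expanded}] +
\mathrm{offset}$$

$\beta_3$ is the change of the intron/exon ratio between conditions — the
post-transcriptional signal with its sign flipped relative to
$\Delta\mathrm{Exon} - \Delta\mathrm{Intron}$ (the result table reports the
coefficient on the log2 scale). Significance is a likelihood-ratio test of
the full against the additive model, referred to $\chi^2(1)$. The LRT was
chosen over a quasi-likelihood F-test because it estimates fewer quantities
and admits a direct independent oracle (Nelder–Mead maximization of the NB
likelihood), at the price of mild anti-conservatism for very few
replicates; the null-calibration test bounds this empirically.

Exonic and intronic observations from the same biological sample are
treated as independent NB observations — the assumption the method family
makes, shared here and stated as a limitation (within-sample correlation
between compartments would make p-values optimistic).

**Dispersion** (variance $= \mu + \phi \mu^2$) is estimated across genes by
Cox–Reid adjusted profile likelihood of the full model: `common` (default)
maximizes the summed APL over one $\phi$ (a deterministic subsample of up
to 200 genes is used — the estimate is an across-gene consensus and
stabilizes long before that); `tagwise` maximizes each gene's APL plus
`prior_weight = 10` gene-equivalents of the average APL curve, shrinking
low-information genes toward the consensus. Genes whose IRLS fit fails get
$p = 1$ and a convergence flag, never an error.

## Empirical-Bayes differential expression

DE between conditions is called from exonic counts only (the mature-mRNA
proxy). The model is a two-pattern beta-negative-binomial mixture chosen
for its closed-form marginals: per gene, counts are NB with per-sample size
$r_g s_j$ (sizes from a pooled within-condition method-of-moments fit on
size-factor-normalized counts, median-of-ratios size factors) and a
probability parameter $q$ drawn from a conjugate $\mathrm{Beta}(\alpha,
\beta)$ prior — one shared $q$ under equal expression, independent $q$ per
condition under DE. $\alpha$, $\beta$ and the mixture weight $P(DE)$ are
fitted by EM over all genes (weight update exact; hyperparameter update a
bounded quasi-Newton step on the expected complete-data log-likelihood, a
generalized EM that keeps the observed log-likelihood non-decreasing — the
trace is stored and asserted in tests). PPDE is the posterior probability
of the DE pattern; EM runs to relative tolerance $10^{-6}$ or 500
iterations, with a warning flag on non-convergence.

The fold-change filter uses size-factor-normalized condition means with
pseudocount 0.5 (no division by zero); calls require PPDE ≥ 0.95 **and**
fold change ≥ 2, directions reported as up in young / up in expanded. Any
calibrated EB posterior satisfies the package's invariants (relabelling
invariance, monotone thresholding, mixture-weight recovery); this specific
model is the package's own, not a wrapper around an external package.

## Over-representation analysis

Categories with at least 5 members in the universe are tested with
hypergeometric tails; the smaller of the over/under tails is reported with
its direction, over-representation only by default, BH-adjusted across
tested categories. The universe is the **EISA-tested** gene set, not the
genome: a category whose genes could never pass the coverage filter must
not look enriched merely because the filter is correlated with it. The
universe is configurable for users who want genome-wide conditioning.

## The synthetic-data generator

`simulate_counts()` emulates the statistical structure the method assumes:
per gene a baseline $\log_2$ mean $b_i \sim N(\log_2 100,\, 1)$, intron
means offset by `exon_intron_ratio` $= -3$ (introns ~8-fold lower, matching
the exon-dominated read composition of real total-RNA libraries), NB noise
with dispersion 0.05, 3 replicates per condition, and log2 effects added in
the expanded condition: transcriptional $t_i$ (both compartments; 30% of
genes at $|t| = 1$) and post-transcriptional $p_i$ (exons only; 10% of
genes at $|p| = 2$), signs randomized, drawn independently so a small
"both" class exists. The truth table records class and effects per gene.
`simulate_annotation()` writes byte-stable GFF3 with known flattening,
trimming and exclusion truth; `simulate_alignments()` realizes target
counts as uniquely mapped SAM records placed wholly within chosen features,
plus NH=2 multimapper and intergenic decoys that must never be counted.

What the generator does **not** model: sequencing error, GC and positional
bias, isoform mixtures, intron retention, UMI structure, within-sample
correlation between exonic and intronic counts, or batch effects. Passing
tests therefore demonstrate correctness of the algorithms under the
method's own assumptions, not robustness to every artefact of real
libraries.

## Numerical choices and degenerate inputs

* Per-gene GLM fits: IRLS at fixed $\phi$ (up to 100 iterations); LRT
  statistics clipped at 0; dispersion search on $\log \phi \in
  [\log 10^{-4}, \log 4]$.
* EM: log-sum-exp for the posterior; hyperparameters bounded in
  $[10^{-3}, 10^3] \times [10^{-2}, 10^9]$; mixture weight clipped to
  $[10^{-6}, 1 - 10^{-6}]$.
* Ties and ordering: genes sorted by (chromosome, body start, gene id)
  everywhere; enrichment sorted by adjusted p then category id; all TSV/JSON
  output written with fixed significant digits so repeated runs are
  byte-identical.
* Degenerate inputs fail loudly and early: zero library totals, p-values
  outside $[0,1]$, gene sets outside the universe, missing files at
  configuration time; all-zero genes yield $p = 1$ with a flag.

## Problem sizes in the test suite

The statistical properties are verified at sizes chosen to make the checks
sharp yet quick to re-run: null calibration on 2,000 genes (KS distance of
p-values from uniform, false-call fraction), FDR/power on 25 seeds × 800
genes per effect size, estimator recovery on 2,000 genes at mean count
1,000, EB-DE recovery on 2,000 genes, exact-oracle equivalence on 100
random counting fixtures and 100 random gene structures, and exhaustive
hypergeometric checks to $N = 60$. `scripts/acceptance.R` re-measures the
same quantities from scratch under any seed.

## Known limitations

* Two conditions only; no batch covariates, paired designs or >2-group
  contrasts.
* Compartment independence assumption (above).
* Total-count normalization's composition sensitivity (above).
* No multimapper rescue; genes in repetitive regions lose coverage.
* The coverage filter conditions the tested universe on expression and
  intron coverage; enrichment results are conditional on that universe.
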