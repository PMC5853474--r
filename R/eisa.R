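# EISA core: compartment-wise normalization, delta-exon / delta-intron, and
# the post-transcriptional call.
#
# Exonic reads measure mature mRNA, intronic reads the nascent pre-mRNA, so
# a transcriptional change moves both compartments together while a
# post-transcriptional change (e.g. differential mRNA stability) moves only
# the exonic signal. The per-gene contrast
#   delta_diff = delta_exon - delta_intron
# is therefore the log2 post-transcriptional effect, and its significance is
# assessed with the NB interaction test in fit_interaction_test().

#' Normalize exon and intron counts to log2 expression
#'
#' Library-size normalization performed separately for the exonic and
#' intronic compartments: each sample's counts are rescaled to the mean
#' library total of its compartment, then log2-transformed after adding a
#' pseudocount. The scaling target (mean library size) is an arbitrary
#' positive constant — deltas are unaffected by it — chosen so values read as
#' log2 counts at average depth.
#'
#' @param table A `CountTable` with positive library totals in every sample
#'   and compartment.
#' @param pseudocount Added before the log (default 8, damping the variance
#'   of low counts).
#' @return A `NormalizedMatrix`: list with `log2_exon`, `log2_intron`
#'   (gene x sample matrices), `scale_exon`, `scale_intron` (per-sample
#'   factors applied), `pseudocount`.
#' @export
normalize_counts <- function(table, pseudocount = 8) {
  stopifnot(inherits(table, "CountTable"), pseudocount > 0)
  for (comp in c("exon", "intron")) {
    tot <- table[[paste0("lib_", comp)]]
    if (any(tot <= 0)) {
      stop(sprintf("zero %s library total in sample(s): %s", comp,
                   paste(table$samples[tot <= 0], collapse = ", ")))
    }
  }
  norm_one <- function(counts, totals) {
    scale <- mean(totals) / totals
    list(mat = log2(sweep(counts, 2L, scale, `*`) + pseudocount),
         scale = scale)
  }
  ex <- norm_one(table$exon, table$lib_exon)
  inr <- norm_one(table$intron, table$lib_intron)
  structure(
    list(log2_exon = ex$mat, log2_intron = inr$mat,
         scale_exon = ex$scale, scale_intron = inr$scale,
         pseudocount = pseudocount,
         samples = table$samples, condition = table$condition,
         genes = table$genes),
    class = "NormalizedMatrix"
  )
}

#' Per-gene delta-exon, delta-intron and their difference
#'
#' Each delta is the difference of mean log2 normalized expression,
#' expanded minus young, in the respective compartment; `delta_diff` is
#' `delta_exon - delta_intron`, the log2 post-transcriptional effect
#' estimate.
#'
#' @param norm A `NormalizedMatrix` from [normalize_counts()].
#' @return Data frame with `gene_id`, `delta_exon`, `delta_intron`,
#'   `delta_diff`.
#' @export
compute_deltas <- function(norm) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  young <- norm$condition == "young"
  expanded <- norm$condition == "expanded"
  if (!any(young) || !any(expanded)) {
    stop("both conditions (young, expanded) must be present")
  }
  d_exon <- rowMeans(norm$log2_exon[, expanded, drop = FALSE]) -
    rowMeans(norm$log2_exon[, young, drop = FALSE])
  d_intron <- rowMeans(norm$log2_intron[, expanded, drop = FALSE]) -
    rowMeans(norm$log2_intron[, young, drop = FALSE])
  data.frame(gene_id = norm$genes,
             delta_exon = unname(d_exon),
             delta_intron = unname(d_intron),
             delta_diff = unname(d_exon - d_intron),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validating wrapper around
#' the standard procedure.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Run the full EISA stage on a filtered count table
#'
#' Normalizes, computes deltas, runs the interaction test and adjusts for
#' multiple testing.
#'
#' @param table A filtered `CountTable` (>= 2 replicates per condition).
#' @param pseudocount Pseudocount for [normalize_counts()].
#' @param dispersion_mode,dispersion,prior_weight Passed to
#'   [fit_interaction_test()].
#' @param fdr_threshold Threshold for the post-transcriptional call.
#' @return An `EisaResult` data frame: `gene_id`, `delta_exon`,
#'   `delta_intron`, `delta_diff`, `p_value`, `fdr`, `call`
#'   (`"post_transcriptional"` / `"not_called"`), `direction`
#'   (sign of `delta_diff`: `"up"`, `"down"`, `"none"`).
#' @export
run_eisa <- function(table, pseudocount = 8,
                     dispersion_mode = "common", dispersion = NULL,
                     prior_weight = 10, fdr_threshold = 0.05) {
  deltas <- compute_deltas(normalize_counts(table, pseudocount))
  test <- fit_interaction_test(table, dispersion_mode = dispersion_mode,
                               dispersion = dispersion,
                               prior_weight = prior_weight)
  stopifnot(identical(deltas$gene_id, test$gene_id))
  res <- data.frame(
    gene_id = deltas$gene_id,
    delta_exon = deltas$delta_exon,
    delta_intron = deltas$delta_intron,
    delta_diff = deltas$delta_diff,
    p_value = test$p_value,
    fdr = adjust_fdr(test$p_value),
    stringsAsFactors = FALSE
  )
  res <- call_post_transcriptional(res, fdr_threshold = fdr_threshold)$results
  attr(res, "dispersion") <- attr(test, "dispersion")
  class(res) <- c("EisaResult", "data.frame")
  res
}

#' Call post-transcriptionally regulated genes
#'
#' A gene is called when its interaction-test FDR is at or below the
#' threshold; the direction is the sign of `delta_diff` (positive: exonic
#' change exceeds intronic, i.e. post-transcriptional up-regulation of the
#' mature mRNA in expanded leaves).
#'
#' @param results Data frame with at least `gene_id`, `delta_diff`, `fdr`.
#' @param fdr_threshold FDR cut-off (default 0.05).
#' @return List with `results` (input plus `call`, `direction` columns),
#'   `called` (the called subset) and `summary`
#'   (`n_tested`, `n_called`, `pct_called`).
#' @export
call_post_transcriptional <- function(results, fdr_threshold = 0.05) {
  stopifnot(all(c("gene_id", "delta_diff", "fdr") %in% names(results)))
  called <- results$fdr <= fdr_threshold
  results$call <- ifelse(called, "post_transcriptional", "not_called")
  results$direction <- ifelse(results$delta_diff > 0, "up",
                              ifelse(results$delta_diff < 0, "down", "none"))
  n_tested <- nrow(results)
  n_called <- sum(called)
  list(results = results,
       called = results[called, , drop = FALSE],
       summary = list(n_tested = n_tested, n_called = n_called,
                      pct_called = .pct(n_called, n_tested)))
}

# Percentage rounded to one decimal; recomputable exactly from (num, den).
.pct <- function(num, den) {
  if (den == 0) return(0)
  round(100 * num / den, 1)
}
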