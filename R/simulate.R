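# Synthetic-data generation: annotation, truth-labelled count matrices and
# SAM alignments with the statistical structure the split analysis assumes.
#
# The count model mirrors the biology the method exploits: intronic reads
# come from nascent pre-mRNA and therefore track transcription only, exonic
# reads come mostly from mature mRNA and additionally carry any
# post-transcriptional effect. For gene i in condition c:
#   exon mean   = 2^(b_i + t_i*[c=expanded] + p_i*[c=expanded])
#   intron mean = 2^(b_i + exon_intron_ratio + t_i*[c=expanded])
# with NB noise (variance mu + phi*mu^2). t_i is the transcriptional and p_i
# the post-transcriptional log2 effect; the truth table records both.

#' Simulation configuration
#'
#' Defaults describe a bulk RNA-seq contrast of two leaf stages: 2,000 genes,
#' 3 replicates per condition, baseline exonic means log-normal around 100
#' reads, introns ~8-fold lower (most reads map to exons), NB dispersion
#' 0.05, 10% of genes with a 4-fold post-transcriptional effect and 30% with
#' a 2-fold transcriptional effect (random signs, drawn independently, so a
#' small "both" class arises).
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per condition (>= 2).
#' @param baseline_mean_log2,baseline_sd_log2 Mean and sd of the per-gene
#'   baseline log2 exonic mean count.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param fraction_pt Fraction of genes with a post-transcriptional effect.
#' @param pt_effect Magnitude of the post-transcriptional log2 effect `p_i`
#'   (sign randomized per gene).
#' @param fraction_t,t_effect Same for the transcriptional effect `t_i`.
#' @param exon_intron_ratio Log2 offset of the intron baseline relative to
#'   the exon baseline (default -3).
#' @param seed RNG seed.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 2000L, n_replicates = 3L,
                              baseline_mean_log2 = log2(100),
                              baseline_sd_log2 = 1,
                              nb_dispersion = 0.05,
                              fraction_pt = 0.1, pt_effect = 2,
                              fraction_t = 0.3, t_effect = 1,
                              exon_intron_ratio = -3,
                              seed = 1L) {
  stopifnot(n_genes >= 1L, n_replicates >= 2L, nb_dispersion > 0,
            fraction_pt >= 0, fraction_pt <= 1,
            fraction_t >= 0, fraction_t <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 baseline_mean_log2 = baseline_mean_log2,
                 baseline_sd_log2 = baseline_sd_log2,
                 nb_dispersion = nb_dispersion,
                 fraction_pt = fraction_pt, pt_effect = pt_effect,
                 fraction_t = fraction_t, t_effect = t_effect,
                 exon_intron_ratio = exon_intron_ratio,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate exon/intron count matrices with known truth
#'
#' @param config A [simulation_config()].
#' @return List with `table` (a `CountTable`), `truth` (data frame
#'   `gene_id`, `class` in
#'   {`transcriptional`, `post_transcriptional`, `both`, `null`}, `t_i`,
#'   `p_i`) and `design`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  nr <- config$n_replicates
  gene_ids <- sprintf("g%04d", seq_len(n))
  samples <- c(sprintf("young_%d", seq_len(nr)),
               sprintf("expanded_%d", seq_len(nr)))
  cond <- rep(c("young", "expanded"), each = nr)
  design <- data.frame(sample = samples, condition = cond,
                       stringsAsFactors = FALSE)

  b <- stats::rnorm(n, config$baseline_mean_log2, config$baseline_sd_log2)
  is_pt <- seq_len(n) %in% sample.int(n, round(config$fraction_pt * n))
  is_t <- seq_len(n) %in% sample.int(n, round(config$fraction_t * n))
  p_i <- ifelse(is_pt, config$pt_effect * sample(c(-1, 1), n, replace = TRUE), 0)
  t_i <- ifelse(is_t, config$t_effect * sample(c(-1, 1), n, replace = TRUE), 0)

  size <- 1 / config$nb_dispersion
  exon <- matrix(0L, n, 2L * nr, dimnames = list(gene_ids, samples))
  intron <- exon
  for (j in seq_len(2L * nr)) {
    ex_mu <- 2^(b + (t_i + p_i) * (cond[j] == "expanded"))
    in_mu <- 2^(b + config$exon_intron_ratio + t_i * (cond[j] == "expanded"))
    exon[, j] <- stats::rnbinom(n, size = size, mu = ex_mu)
    intron[, j] <- stats::rnbinom(n, size = size, mu = in_mu)
  }
  cls <- ifelse(is_pt & is_t, "both",
                ifelse(is_pt, "post_transcriptional",
                       ifelse(is_t, "transcriptional", "null")))
  truth <- data.frame(gene_id = gene_ids, class = cls, t_i = t_i, p_i = p_i,
                      stringsAsFactors = FALSE)
  list(table = count_table(exon, intron, design), truth = truth,
       design = design)
}

#' Simulate a GFF3 annotation with known region-model truth
#'
#' Genes have 1-10 exons with a CDS strictly inside the first and last exon,
#' separated by intergenic gaps; a configurable fraction of genes is placed
#' overlapping its predecessor (both members of such a pair must later be
#' excluded), and a configurable fraction is single-exon (excluded for lack
#' of introns). Byte-identical output for a fixed seed.
#'
#' @param n_genes Number of genes.
#' @param seed RNG seed.
#' @param path Output GFF3 path (default: temp file).
#' @param overlap_fraction Fraction of genes deliberately overlapping the
#'   previous gene.
#' @param single_exon_fraction Fraction of single-exon genes.
#' @param genes_per_chrom Genes per chromosome.
#' @return List with `gff` (path), `models` (expected finalized
#'   `GeneModel` truth, sorted), and `truth` (data frame `gene_id`,
#'   `excluded`, `reason`).
#' @export
simulate_annotation <- function(n_genes, seed = 1L, path = tempfile(fileext = ".gff3"),
                                overlap_fraction = 0, single_exon_fraction = 0.1,
                                genes_per_chrom = 20L) {
  stopifnot(n_genes >= 1L)
  set.seed(seed)
  lines <- c("##gff-version 3")
  models <- list()
  truth_reason <- character(n_genes)
  cursor <- 0L
  chrom_i <- 1L
  prev <- NULL  # previous gene's layout, for overlap placement
  overlaps_prev <- logical(n_genes)

  for (i in seq_len(n_genes)) {
    if ((i - 1L) %% genes_per_chrom == 0L && i > 1L) {
      chrom_i <- chrom_i + 1L
      cursor <- 0L
      prev <- NULL
    }
    chrom <- paste0("chr", chrom_i)
    gid <- sprintf("gene%04d", i)
    single <- stats::runif(1) < single_exon_fraction
    n_ex <- if (single) 1L else sample(2:10, 1L)
    ex_len <- sample(100:300, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) sample(60:500, n_ex - 1L, replace = TRUE) else integer(0)

    overlap_here <- !is.null(prev) && stats::runif(1) < overlap_fraction
    start <- if (overlap_here) prev$body_start + 20L else cursor + sample(200:2000, 1L)

    ex_start <- integer(n_ex)
    ex_end <- integer(n_ex)
    pos <- start
    for (e in seq_len(n_ex)) {
      ex_start[e] <- pos
      ex_end[e] <- pos + ex_len[e]
      pos <- ex_end[e] + if (e < n_ex) in_len[e] else 0L
    }
    cds_start <- ex_start[1L] + sample(5:20, 1L)
    cds_end <- ex_end[n_ex] - sample(5:20, 1L)
    strand <- sample(c("+", "-"), 1L)
    gene_end <- ex_end[n_ex]

    # GFF3 is 1-based inclusive
    lines <- c(lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom, start + 1L,
              gene_end, strand, gid),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s", chrom,
              start + 1L, gene_end, strand, gid, gid),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
              chrom, ex_start + 1L, ex_end, strand, gid, seq_len(n_ex), gid))
    # CDS segments: clip exons to the CDS span
    cds_seg_s <- pmax(ex_start, cds_start)
    cds_seg_e <- pmin(ex_end, cds_end)
    keep <- cds_seg_s < cds_seg_e
    lines <- c(lines,
      sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s.t1",
              chrom, cds_seg_s[keep] + 1L, cds_seg_e[keep], strand, gid,
              seq_len(sum(keep)), gid))

    # expected finalized model
    body <- c(cds_start, cds_end)
    exp_ex <- interval_matrix(pmax(ex_start, cds_start)[keep],
                              pmin(ex_end, cds_end)[keep])
    exp_in <- gaps_between(exp_ex)
    excluded <- FALSE
    reason <- NA_character_
    if (nrow(exp_in) == 0L) {
      excluded <- TRUE
      reason <- "no_intron"
    }
    models[[i]] <- gene_model(gid, chrom, strand, exons = exp_ex,
                              cds = interval_matrix(cds_seg_s[keep], cds_seg_e[keep]),
                              body = as.integer(body), introns = exp_in,
                              excluded = excluded, reason = reason)
    overlaps_prev[i] <- overlap_here
    truth_reason[i] <- reason

    cursor <- max(cursor, gene_end)
    prev <- list(body_start = body[1L], body_end = body[2L], chrom = chrom)
  }

  # overlap truth: both members of each deliberately overlapping pair
  for (i in which(overlaps_prev)) {
    for (j in c(i - 1L, i)) {
      if (is.na(truth_reason[j])) {
        truth_reason[j] <- "overlapping"
        models[[j]]$excluded <- TRUE
        models[[j]]$reason <- "overlapping"
      }
    }
  }

  writeLines(lines, path)
  truth <- data.frame(
    gene_id = vapply(models, `[[`, "", "gene_id"),
    excluded = !is.na(truth_reason),
    reason = truth_reason,
    stringsAsFactors = FALSE
  )
  list(gff = path, models = sort_gene_models(models), truth = truth)
}

#' Simulate uniquely mapped alignments realizing target counts
#'
#' Writes a SAM file whose unique reads lie wholly within designated exons or
#' introns of each gene so that [count_sample()] recovers the targets
#' exactly; decoy multimappers (NH=2, placed inside genes) and intergenic
#' unique reads are added and must not be counted.
#'
#' @param gene_models List of finalized `GeneModel` (retained genes are
#'   targets).
#' @param target_counts Data frame `gene_id`, `exon`, `intron` for one
#'   sample.
#' @param read_length Read length in bases (default 50).
#' @param seed RNG seed.
#' @param path Output SAM path (default: temp file).
#' @param n_decoy_multimap,n_decoy_outside Number of decoy reads of each
#'   kind.
#' @param spliced Emit exon reads as two-block junction reads (spanning two
#'   consecutive exons) where the gene has >= 2 exons.
#' @return The SAM path.
#' @export
simulate_alignments <- function(gene_models, target_counts, read_length = 50L,
                                seed = 1L, path = tempfile(fileext = ".sam"),
                                n_decoy_multimap = 5L, n_decoy_outside = 5L,
                                spliced = FALSE) {
  set.seed(seed)
  kept <- retained_genes(gene_models)
  ids <- vapply(kept, `[[`, "", "gene_id")
  stopifnot(all(target_counts$gene_id %in% ids))

  chrom_len <- list()
  note_len <- function(chrom, end) {
    cur <- chrom_len[[chrom]]
    chrom_len[[chrom]] <<- max(if (is.null(cur)) 0L else cur, end)
  }
  for (g in gene_models) {
    end <- max(g$exons[, "end"], if (!is.null(g$body)) g$body[2] else 0L)
    note_len(g$chrom, end)
  }

  recs <- character(0)
  rid <- 0L
  emit <- function(chrom, pos0, cigar, mapq, nh) {
    rid <<- rid + 1L
    recs <<- c(recs, sprintf("r%06d\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tNH:i:%d",
                             rid, chrom, pos0 + 1L, mapq, cigar, nh))
  }

  place_in <- function(feat, n_reads, chrom) {
    # reads wholly inside one feature interval of width >= read_length
    ok <- which(feat[, "end"] - feat[, "start"] >= read_length)
    if (!length(ok) && n_reads > 0L) {
      stop("no feature long enough for read length ", read_length)
    }
    for (r in seq_len(n_reads)) {
      f <- feat[ok[sample.int(length(ok), 1L)], , drop = FALSE]
      pos <- f[1, "start"] + sample.int(f[1, "end"] - f[1, "start"] - read_length + 1L, 1L) - 1L
      emit(chrom, pos, paste0(read_length, "M"), 60L, 1L)
    }
  }

  for (row in seq_len(nrow(target_counts))) {
    g <- kept[[match(target_counts$gene_id[row], ids)]]
    n_ex_reads <- target_counts$exon[row]
    if (spliced && nrow(g$exons) >= 2L && n_ex_reads > 0L) {
      # junction reads: half in exon e, gap over the intron, half in exon e+1
      half <- read_length %/% 2L
      for (r in seq_len(n_ex_reads)) {
        e <- sample.int(nrow(g$exons) - 1L, 1L)
        left_end <- g$exons[e, "end"]
        right_start <- g$exons[e + 1L, "start"]
        if (left_end - g$exons[e, "start"] < half ||
            g$exons[e + 1L, "end"] - right_start < read_length - half) {
          place_in(g$exons, 1L, g$chrom)
          next
        }
        pos <- left_end - half
        gap <- right_start - left_end
        emit(g$chrom, pos,
             sprintf("%dM%dN%dM", half, gap, read_length - half), 60L, 1L)
      }
    } else {
      place_in(g$exons, n_ex_reads, g$chrom)
    }
    place_in(g$introns, target_counts$intron[row], g$chrom)
  }

  # decoys: NH=2 multimappers inside gene bodies; unique reads past all genes
  if (length(kept)) {
    for (d in seq_len(n_decoy_multimap)) {
      g <- kept[[sample.int(length(kept), 1L)]]
      ok <- which(g$exons[, "end"] - g$exons[, "start"] >= read_length)
      if (!length(ok)) next
      f <- g$exons[ok[1L], , drop = FALSE]
      emit(g$chrom, f[1, "start"], paste0(read_length, "M"), 0L, 2L)
    }
  }
  for (d in seq_len(n_decoy_outside)) {
    chrom <- names(chrom_len)[1L]
    pos <- chrom_len[[chrom]] + 500L + d * (read_length + 10L)
    note_len(chrom, pos + read_length + 1000L)
    emit(chrom, pos, paste0(read_length, "M"), 60L, 1L)
  }

  header <- c("@HD\tVN:1.6\tSO:unknown",
              vapply(sort(names(chrom_len)), function(ch) {
                sprintf("@SQ\tSN:%s\tLN:%d", ch, chrom_len[[ch]] + 2000L)
              }, ""))
  writeLines(c(header, recs), path)
  path
}
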