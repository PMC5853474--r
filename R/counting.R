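# Counting uniquely mapped reads in exonic and intronic compartments.
#
# A read is attributed to a gene only when all of its aligned blocks fall
# inside that gene's (UTR-trimmed) body; because overlapping genes are
# excluded upstream, gene bodies are disjoint and the attribution is unique.
# Within a gene, any overlap with exon sequence classifies the read as exonic
# (boundary-spanning reads certainly derive from a transcript containing the
# exon; junction reads are the strongest mature-mRNA evidence); otherwise an
# overlap with an intron (optionally shrunk by a margin) makes it intronic.

#' Counting parameters
#'
#' @param min_mapq Minimum MAPQ for reads lacking an NH tag; reads with an NH
#'   tag are kept only when `NH == 1` (unique mappers).
#' @param intron_margin Bases trimmed from each intron end before intron
#'   assignment (default 0).
#' @param per_feature Also record per-exon / per-intron read counts (needed by
#'   the per-feature minimum-count filter).
#' @param fragment Count paired-end fragments once (mates merged by read name)
#'   instead of counting mates independently.
#' @return A list of class `counting_params`.
#' @export
counting_params <- function(min_mapq = 30L, intron_margin = 0L,
                            per_feature = FALSE, fragment = FALSE) {
  stopifnot(min_mapq >= 0L, intron_margin >= 0L)
  structure(list(min_mapq = as.integer(min_mapq),
                 intron_margin = as.integer(intron_margin),
                 per_feature = isTRUE(per_feature),
                 fragment = isTRUE(fragment)),
            class = "counting_params")
}

# Prepare a coordinate-sorted, indexed BAM. SAM input is converted (sorted and
# indexed) in a scratch directory; BAM input must already have an index.
.prepare_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
    return(bam)
  }
  bai <- paste0(path, ".bai")
  bai2 <- sub("\\.bam$", ".bai", path)
  if (!file.exists(bai) && !file.exists(bai2)) {
    stop("BAM file must be coordinate-sorted and indexed (.bai not found): ", path)
  }
  path
}

#' Count exonic and intronic reads for one sample
#'
#' Streams uniquely mapped reads from a SAM/BAM file and counts them against
#' the retained gene models, one increment per read in at most one
#' gene-by-compartment cell. Spliced alignments are split into blocks at `N`
#' CIGAR operations. Chromosomes present in the alignments but absent from
#' the annotation produce a warning and their reads are skipped.
#'
#' @param alignments Path to a SAM file (converted, sorted and indexed
#'   internally) or a coordinate-sorted, indexed BAM file.
#' @param genes List of finalized `GeneModel`; only retained genes are
#'   counted.
#' @param params A [counting_params()] object.
#' @return A list with `exon` and `intron` (named integer vectors over
#'   retained gene ids), `n_unique` (unique-mapping records processed),
#'   `n_assigned`, and, when `params$per_feature`, `exon_features` /
#'   `intron_features` (lists of per-feature count vectors per gene).
#' @export
count_sample <- function(alignments, genes, params = counting_params()) {
  stopifnot(inherits(params, "counting_params"))
  kept <- retained_genes(genes)
  gene_ids <- vapply(kept, `[[`, "", "gene_id")
  exon_counts <- stats::setNames(integer(length(kept)), gene_ids)
  intron_counts <- exon_counts
  feat_exon <- feat_intron <- NULL
  if (params$per_feature) {
    feat_exon <- lapply(kept, function(g) integer(nrow(g$exons)))
    feat_intron <- lapply(kept, function(g) integer(nrow(g$introns)))
    names(feat_exon) <- names(feat_intron) <- gene_ids
  }

  bam <- .prepare_bam(alignments)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "mapq", "flag"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  n_records <- length(gal)
  if (n_records == 0L) {
    return(list(exon = exon_counts, intron = intron_counts,
                n_unique = 0L, n_assigned = 0L,
                exon_features = feat_exon, intron_features = feat_intron))
  }

  nh <- S4Vectors::mcols(gal)$NH
  mapq <- S4Vectors::mcols(gal)$mapq
  unique_ok <- ifelse(!is.na(nh), nh == 1L, !is.na(mapq) & mapq >= params$min_mapq)
  gal <- gal[unique_ok]
  n_unique <- length(gal)

  ann_chroms <- unique(vapply(kept, `[[`, "", "chrom"))
  aln_chroms <- unique(as.character(GenomicAlignments::seqnames(gal)))
  missing_chroms <- setdiff(aln_chroms, ann_chroms)
  if (length(missing_chroms)) {
    warning("alignments on chromosome(s) absent from annotation, skipped: ",
            paste(missing_chroms, collapse = ", "))
  }

  # Blocks (0-based half-open) per record, plus a per-record grouping key:
  # record index, or read name when counting fragments.
  blocks <- GenomicAlignments::grglist(gal)
  flat <- unlist(blocks, use.names = FALSE)
  rec_of_block <- rep(seq_along(gal), lengths(blocks))
  b_chrom <- as.character(GenomicRanges::seqnames(flat))
  b_start <- GenomicRanges::start(flat) - 1L
  b_end <- GenomicRanges::end(flat)
  if (params$fragment) {
    key <- paste0(as.character(GenomicAlignments::seqnames(gal)), "\r",
                  S4Vectors::mcols(gal)$qname)
    unit_of_block <- match(key, unique(key))[rec_of_block]
    n_units_total <- length(unique(key))
  } else {
    unit_of_block <- rec_of_block
    n_units_total <- length(gal)
  }

  n_assigned <- 0L
  for (chrom in intersect(aln_chroms, ann_chroms)) {
    g_idx <- which(vapply(kept, `[[`, "", "chrom") == chrom)
    if (!length(g_idx)) next
    sel <- b_chrom == chrom
    if (!any(sel)) next
    u_ids <- unique(unit_of_block[sel])
    u_map <- match(unit_of_block[sel], u_ids)
    # Span of each counting unit (read or fragment) on this chromosome.
    span_start <- tapply(b_start[sel], u_map, min)
    span_end <- tapply(b_end[sel], u_map, max)
    ord <- as.integer(names(span_start))
    span_start <- as.integer(span_start)[order(ord)]
    span_end <- as.integer(span_end)[order(ord)]

    bodies <- IRanges::IRanges(
      start = vapply(kept[g_idx], function(g) g$body[1], 0L) + 1L,
      end = vapply(kept[g_idx], function(g) g$body[2], 0L)
    )
    spans <- IRanges::IRanges(start = span_start + 1L, end = span_end)
    hit <- IRanges::findOverlaps(spans, bodies, type = "within", select = "first")
    # Bodies are disjoint (overlapping genes excluded), so 'first' is unique;
    # assert that no unit fits inside two bodies.
    hit_all <- IRanges::findOverlaps(spans, bodies, type = "within")
    if (any(duplicated(S4Vectors::queryHits(hit_all)))) {
      stop("internal error: read contained in two gene bodies; overlapping genes must be excluded upstream")
    }

    bs <- b_start[sel]; be <- b_end[sel]
    for (u in which(!is.na(hit))) {
      gi <- g_idx[hit[u]]
      g <- kept[[gi]]
      ub <- which(u_map == u)
      us <- bs[ub]; ue <- be[ub]
      ex <- g$exons
      ov_exon <- FALSE
      ex_hit <- logical(nrow(ex))
      for (j in seq_len(nrow(ex))) {
        o <- any(us < ex[j, "end"] & ue > ex[j, "start"])
        ex_hit[j] <- o
        ov_exon <- ov_exon || o
      }
      if (ov_exon) {
        exon_counts[gi] <- exon_counts[gi] + 1L
        n_assigned <- n_assigned + 1L
        if (params$per_feature) {
          feat_exon[[gi]][ex_hit] <- feat_exon[[gi]][ex_hit] + 1L
        }
      } else {
        inr <- g$introns
        if (nrow(inr)) {
          s <- inr[, "start"] + params$intron_margin
          e <- inr[, "end"] - params$intron_margin
          ok <- s < e
          in_hit <- logical(nrow(inr))
          for (j in which(ok)) {
            in_hit[j] <- any(us < e[j] & ue > s[j])
          }
          if (any(in_hit)) {
            intron_counts[gi] <- intron_counts[gi] + 1L
            n_assigned <- n_assigned + 1L
            if (params$per_feature) {
              feat_intron[[gi]][in_hit] <- feat_intron[[gi]][in_hit] + 1L
            }
          }
        }
      }
    }
  }

  list(exon = exon_counts, intron = intron_counts,
       n_unique = if (params$fragment) n_units_total else n_unique,
       n_assigned = n_assigned,
       exon_features = feat_exon, intron_features = feat_intron)
}

#' Assemble per-sample counts into a count table
#'
#' @param sample_counts Named list of [count_sample()] results (names are
#'   sample ids).
#' @param design Data frame with columns `sample` and `condition`
#'   (`"young"` / `"expanded"`), one row per sample.
#' @return A `CountTable`: list with `genes`, `samples`, `condition`,
#'   `exon` and `intron` (gene x sample integer matrices), `lib_exon` /
#'   `lib_intron` (per-sample column totals), and per-feature counts when
#'   present.
#' @export
build_count_table <- function(sample_counts, design) {
  stopifnot(is.list(sample_counts), length(sample_counts) >= 1L,
            all(c("sample", "condition") %in% names(design)))
  samples <- design$sample
  if (!all(samples %in% names(sample_counts))) {
    stop("design lists samples with no counts: ",
         paste(setdiff(samples, names(sample_counts)), collapse = ", "))
  }
  gene_sets <- lapply(sample_counts[samples], function(x) names(x$exon))
  ref <- gene_sets[[1L]]
  for (i in seq_along(gene_sets)) {
    if (!identical(gene_sets[[i]], ref)) {
      stop("gene sets differ across samples (sample ", samples[i], ")")
    }
  }
  exon <- vapply(sample_counts[samples], function(x) x$exon,
                 integer(length(ref)))
  intron <- vapply(sample_counts[samples], function(x) x$intron,
                   integer(length(ref)))
  exon <- matrix(exon, nrow = length(ref), dimnames = list(ref, samples))
  intron <- matrix(intron, nrow = length(ref), dimnames = list(ref, samples))
  has_feat <- all(vapply(sample_counts[samples],
                         function(x) !is.null(x$exon_features), TRUE))
  count_table(exon, intron, design,
              exon_features = if (has_feat) {
                lapply(sample_counts[samples], `[[`, "exon_features")
              },
              intron_features = if (has_feat) {
                lapply(sample_counts[samples], `[[`, "intron_features")
              })
}

#' Construct a count table from matrices
#'
#' @param exon,intron Gene x sample integer matrices with identical dimnames.
#' @param design Data frame with columns `sample`, `condition`.
#' @param exon_features,intron_features Optional per-feature counts
#'   (per-sample lists as returned by [count_sample()]).
#' @return A `CountTable` object.
#' @export
count_table <- function(exon, intron, design,
                        exon_features = NULL, intron_features = NULL) {
  stopifnot(identical(dim(exon), dim(intron)),
            identical(rownames(exon), rownames(intron)),
            identical(colnames(exon), colnames(intron)))
  if (any(exon < 0) || any(intron < 0)) stop("counts must be non-negative")
  samples <- colnames(exon)
  cond <- design$condition[match(samples, design$sample)]
  if (anyNA(cond)) stop("design missing condition for some samples")
  bad <- setdiff(unique(cond), c("young", "expanded"))
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  structure(
    list(genes = rownames(exon), samples = samples,
         condition = as.character(cond),
         exon = exon, intron = intron,
         lib_exon = colSums(exon), lib_intron = colSums(intron),
         exon_features = exon_features, intron_features = intron_features),
    class = "CountTable"
  )
}

#' @export
print.CountTable <- function(x, ...) {
  cat(sprintf("CountTable: %d genes x %d samples (%s)\n",
              length(x$genes), length(x$samples),
              paste(table(x$condition), collapse = "+")))
  invisible(x)
}

#' Apply the minimum-count filter
#'
#' Genes with too little intronic (or exonic) coverage cannot support a split
#' analysis. The default `gene_total` mode keeps a gene only when its summed
#' exonic and its summed intronic counts each reach `min_reads` in every
#' sample; `per_feature` mode applies the same test to every individual exon
#' and intron (requires per-feature counts from [count_sample()]).
#'
#' @param table A `CountTable`.
#' @param mode `"gene_total"` (default) or `"per_feature"`.
#' @param min_reads Minimum read count (default 2).
#' @return A list with `table` (the filtered `CountTable`) and `report`
#'   (data frame `gene_id`, `reason` for removed genes).
#' @export
apply_min_count_filter <- function(table, mode = c("gene_total", "per_feature"),
                                   min_reads = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "CountTable"))
  if (min_reads < 0) stop("min_reads must be >= 0")
  if (mode == "gene_total") {
    ok_exon <- apply(table$exon >= min_reads, 1L, all)
    ok_intron <- apply(table$intron >= min_reads, 1L, all)
  } else {
    if (is.null(table$exon_features) || is.null(table$intron_features)) {
      stop("per_feature mode requires per-feature counts (counting_params(per_feature = TRUE))")
    }
    ok_feat <- function(feats) {
      # feats: per-sample list of per-gene lists of feature count vectors
      vapply(table$genes, function(g) {
        all(vapply(feats, function(s) {
          v <- s[[g]]
          length(v) == 0L || all(v >= min_reads)
        }, TRUE))
      }, TRUE)
    }
    ok_exon <- ok_feat(table$exon_features)
    ok_intron <- ok_feat(table$intron_features)
  }
  keep <- ok_exon & ok_intron
  reason <- ifelse(!ok_exon & !ok_intron, "low_exon_and_intron",
                   ifelse(!ok_exon, "low_exon", "low_intron"))
  report <- data.frame(gene_id = table$genes[!keep],
                       reason = reason[!keep], stringsAsFactors = FALSE)
  rownames(report) <- NULL
  design <- data.frame(sample = table$samples, condition = table$condition,
                       stringsAsFactors = FALSE)
  filtered <- count_table(table$exon[keep, , drop = FALSE],
                          table$intron[keep, , drop = FALSE], design)
  # Library totals describe the sequencing depth of the whole compartment, so
  # they are kept from the unfiltered table for normalization purposes.
  filtered$lib_exon <- table$lib_exon
  filtered$lib_intron <- table$lib_intron
  list(table = filtered, report = report)
}

#' Write and read count matrices as TSV
#'
#' @param table A `CountTable`.
#' @param exon_path,intron_path Output TSV paths (rows gene_id, columns
#'   sample ids).
#' @return Invisibly the paths.
#' @export
write_count_table <- function(table, exon_path, intron_path) {
  wr <- function(m, path) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(table$exon, exon_path)
  wr(table$intron, intron_path)
  invisible(list(exon = exon_path, intron = intron_path))
}

#' @rdname write_count_table
#' @param design Data frame with columns `sample`, `condition`.
#' @export
read_count_table <- function(exon_path, intron_path, design) {
  rd <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "integer"
    m
  }
  count_table(rd(exon_path), rd(intron_path), design)
}
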