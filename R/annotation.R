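# Annotation parsing and the exon/intron region model.
#
# A "gene model" is the flattened, per-gene structure EISA counts against:
# the union of all transcript exons, the maximal gaps between consecutive
# merged exons (the "enclosed" introns: every one has exon sequence on both
# sides), and a CDS-bounded gene body so that UTR reads are never counted.
# Genes without usable structure carry an exclusion reason instead.

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @param exons Interval matrix of exons (0-based half-open).
#' @param cds Interval matrix of CDS segments, or `NULL` if unannotated.
#' @param body Length-2 integer vector `c(start, end)` or `NULL` before
#'   trimming.
#' @param introns Interval matrix of enclosed introns.
#' @param excluded Logical; is the gene excluded from counting?
#' @param reason Exclusion reason: one of `"overlapping"`, `"no_intron"`,
#'   `"no_cds"`, or `NA` when retained.
#' @return An object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, chrom, strand = ".",
                       exons = interval_matrix(),
                       cds = NULL, body = NULL,
                       introns = interval_matrix(),
                       excluded = FALSE, reason = NA_character_) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-", ".")) stop("strand must be one of +, -, .")
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, cds = cds, body = body, introns = introns,
         excluded = isTRUE(excluded), reason = reason),
    class = "GeneModel"
  )
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s%s) %d exon(s), %d intron(s)%s\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), nrow(x$introns),
              if (x$excluded) paste0(" [excluded: ", x$reason, "]") else ""))
  invisible(x)
}

# Light syntactic validation so malformed annotation fails with a line number
# rather than an opaque parser error.
.check_annotation_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    nfield <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nfield < 8L) {
      stop(sprintf("malformed annotation line %d in %s: expected >= 8 tab-separated fields, got %d",
                   i, path, nfield))
    }
  }
  invisible(length(body))
}

.detect_annotation_format <- function(path) {
  if (grepl("\\.(gtf)(\\.gz)?$", path, ignore.case = TRUE)) return("gtf")
  if (grepl("\\.(gff3?|gff)(\\.gz)?$", path, ignore.case = TRUE)) return("gff3")
  # Sniff: GTF attributes look like 'key "value";', GFF3 like 'key=value'.
  lines <- readLines(path, n = 200L, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return("gff3")
  attrs <- vapply(strsplit(lines, "\t", fixed = TRUE), function(x) x[min(9L, length(x))], "")
  if (any(grepl("\\w+ \"", attrs))) "gtf" else "gff3"
}

#' Load genome annotation into raw gene models
#'
#' Parses a GFF3 or GTF file (dialect autodetected) and assembles one raw
#' gene model per gene: the collection of all transcript exons (not yet
#' flattened) plus any CDS records, with 1-based inclusive coordinates
#' converted to the internal 0-based half-open convention. Exons are linked to
#' genes either directly (`gene_id` attribute, GTF) or through their parent
#' transcript (`Parent` attribute, GFF3).
#'
#' @param annotation_file Path to a GFF3 or GTF file.
#' @return A list of `GeneModel` objects, ordered by
#'   `(chrom, min exon start, gene_id)`. Exons are unflattened; `body` and
#'   `introns` are unset until [flatten_and_trim()].
#' @seealso [flatten_and_trim()], [filter_overlapping_genes()]
#' @export
load_annotation <- function(annotation_file) {
  if (!file.exists(annotation_file)) {
    stop("annotation file not found: ", annotation_file)
  }
  n_body <- .check_annotation_lines(annotation_file)
  if (n_body == 0L) return(list())
  fmt <- .detect_annotation_format(annotation_file)
  gr <- rtracklayer::import(annotation_file, format = fmt)
  type <- as.character(gr$type)
  meta <- S4Vectors::mcols(gr)

  # Transcript -> gene map (GFF3); GTF rows carry gene_id directly.
  tx2gene <- character(0)
  if (fmt == "gff3") {
    is_tx <- type %in% c("mRNA", "transcript", "tRNA", "rRNA", "ncRNA",
                         "snoRNA", "snRNA", "miRNA", "lnc_RNA", "pseudogenic_transcript")
    if (any(is_tx)) {
      tx_id <- as.character(meta$ID[is_tx])
      tx_parent <- vapply(as.list(meta$Parent[is_tx]), function(p) {
        if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
      }, "")
      tx2gene <- stats::setNames(tx_parent, tx_id)
    }
  }
  gene_ids_declared <- if ("ID" %in% colnames(meta)) {
    as.character(meta$ID[type == "gene"])
  } else character(0)

  resolve_gene <- function(idx) {
    if (fmt == "gtf") {
      if (!"gene_id" %in% colnames(meta)) return(rep(NA_character_, length(idx)))
      gid <- as.character(meta$gene_id[idx])
      gid[is.na(gid) | !nzchar(gid)] <- NA_character_
      return(gid)
    }
    if (!"Parent" %in% colnames(meta)) return(rep(NA_character_, length(idx)))
    parents <- as.list(meta$Parent[idx])
    vapply(parents, function(p) {
      if (length(p) == 0L) return(NA_character_)
      p <- as.character(p[[1L]])
      if (p %in% names(tx2gene)) tx2gene[[p]]
      else if (p %in% gene_ids_declared || !length(gene_ids_declared)) p
      else p
    }, "")
  }

  collect <- function(sel_type) {
    idx <- which(type == sel_type)
    if (!length(idx)) {
      return(data.frame(gene = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0)))
    }
    gid <- resolve_gene(idx)
    if (anyNA(gid)) {
      stop(sprintf("%s record without resolvable gene parent (e.g. %s:%d-%d)",
                   sel_type,
                   as.character(GenomicRanges::seqnames(gr))[idx[which(is.na(gid))[1]]],
                   GenomicRanges::start(gr)[idx[which(is.na(gid))[1]]],
                   GenomicRanges::end(gr)[idx[which(is.na(gid))[1]]]))
    }
    data.frame(
      gene = gid,
      chrom = as.character(GenomicRanges::seqnames(gr))[idx],
      start = GenomicRanges::start(gr)[idx] - 1L,  # to 0-based half-open
      end = GenomicRanges::end(gr)[idx],
      strand = as.character(GenomicRanges::strand(gr))[idx],
      stringsAsFactors = FALSE
    )
  }

  exons <- collect("exon")
  cds <- collect("CDS")
  if (nrow(exons) == 0L) return(list())

  models <- lapply(split(seq_len(nrow(exons)), exons$gene), function(rows) {
    chroms <- unique(exons$chrom[rows])
    if (length(chroms) > 1L) {
      stop("gene ", exons$gene[rows[1]], " has exons on multiple chromosomes")
    }
    strand <- unique(exons$strand[rows])
    strand <- if (length(strand) == 1L && strand[1] %in% c("+", "-")) strand[1] else "."
    gid <- exons$gene[rows[1]]
    cds_rows <- which(cds$gene == gid & cds$chrom == chroms)
    gene_model(
      gene_id = gid, chrom = chroms, strand = strand,
      exons = interval_matrix(exons$start[rows], exons$end[rows]),
      cds = if (length(cds_rows)) {
        interval_matrix(cds$start[cds_rows], cds$end[cds_rows])
      } else NULL
    )
  })
  sort_gene_models(unname(models))
}

#' Sort gene models deterministically
#'
#' Orders by `(chrom, start, gene_id)` where start is the body start if set,
#' otherwise the first exon start. Used everywhere a gene list is produced so
#' outputs are reproducible.
#'
#' @param genes List of `GeneModel`.
#' @return The sorted list.
#' @export
sort_gene_models <- function(genes) {
  if (!length(genes)) return(genes)
  chrom <- vapply(genes, `[[`, "", "chrom")
  start <- vapply(genes, function(g) {
    if (!is.null(g$body)) g$body[1] else g$exons[1, "start"]
  }, 0L)
  id <- vapply(genes, `[[`, "", "gene_id")
  genes[order(chrom, start, id)]
}

#' Flatten transcript exons and trim the gene body to the CDS span
#'
#' Merges exons across transcripts into their union (a base is exonic if it is
#' exonic in any transcript), optionally trims the gene body to the CDS span
#' so UTR bases are dropped, and derives introns as the maximal gaps between
#' consecutive merged exons — by construction every intron is enclosed by
#' exons on both sides. Genes with no remaining intron are flagged
#' `excluded(no_intron)`; with `trim_mode = "cds"` genes lacking CDS records
#' are flagged `excluded(no_cds)` (no body can be defined without UTR
#' knowledge).
#'
#' @param gene A raw `GeneModel` from [load_annotation()].
#' @param trim_mode `"cds"` (default): body is `[min CDS start, max CDS end)`
#'   and exons are clipped to it; `"none"`: body is the full exon span.
#' @return The finalized `GeneModel` (idempotent: re-applying is a no-op).
#' @export
flatten_and_trim <- function(gene, trim_mode = c("cds", "none")) {
  trim_mode <- match.arg(trim_mode)
  stopifnot(inherits(gene, "GeneModel"))
  if (nrow(gene$exons) == 0L) stop("gene ", gene$gene_id, " has no exons")
  exons <- merge_intervals(gene$exons)
  if (trim_mode == "cds") {
    if (is.null(gene$cds) || nrow(gene$cds) == 0L) {
      gene$excluded <- TRUE
      gene$reason <- "no_cds"
      gene$exons <- exons
      gene$body <- NULL
      gene$introns <- interval_matrix()
      return(gene)
    }
    body <- c(min(gene$cds[, "start"]), max(gene$cds[, "end"]))
    exons <- clip_intervals(exons, body[1], body[2])
  } else {
    body <- c(min(exons[, "start"]), max(exons[, "end"]))
  }
  introns <- gaps_between(exons)
  gene$exons <- exons
  gene$body <- as.integer(body)
  gene$introns <- introns
  if (nrow(introns) == 0L) {
    gene$excluded <- TRUE
    gene$reason <- "no_intron"
  } else if (identical(gene$reason, "no_intron") || identical(gene$reason, "no_cds")) {
    gene$excluded <- FALSE
    gene$reason <- NA_character_
  }
  gene
}

#' Exclude genes with overlapping bodies
#'
#' Reads falling in a region shared by two genes cannot be attributed to
#' either, so both members of every overlapping pair are excluded. Overlap is
#' tested between finalized gene bodies on the same chromosome; by default
#' strand is ignored (library strandedness unknown), optionally restricted to
#' same-strand overlaps.
#'
#' @param genes List of finalized `GeneModel` (after [flatten_and_trim()]).
#' @param stranded If `TRUE`, only same-strand overlaps cause exclusion.
#' @return The gene list with overlapping genes flagged
#'   `excluded(overlapping)`; already-excluded genes keep their original
#'   reason. Order-independent: permuting the input yields the same exclusion
#'   set.
#' @export
filter_overlapping_genes <- function(genes, stranded = FALSE) {
  has_body <- vapply(genes, function(g) !is.null(g$body), TRUE)
  idx <- which(has_body)
  if (length(idx) >= 2L) {
    chrom <- vapply(genes[idx], `[[`, "", "chrom")
    strand <- vapply(genes[idx], `[[`, "", "strand")
    starts <- vapply(genes[idx], function(g) g$body[1], 0L)
    ends <- vapply(genes[idx], function(g) g$body[2], 0L)
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = starts + 1L, end = ends),
      strand = if (stranded) strand else "*"
    )
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        ignore.strand = !stranded)
    bad <- unique(S4Vectors::queryHits(hits))
    for (i in idx[bad]) {
      if (!genes[[i]]$excluded) {
        genes[[i]]$excluded <- TRUE
        genes[[i]]$reason <- "overlapping"
      }
    }
  }
  genes
}

#' Retained (countable) gene models
#'
#' @param genes List of `GeneModel`.
#' @return The sublist with `excluded = FALSE`.
#' @export
retained_genes <- function(genes) {
  genes[!vapply(genes, `[[`, TRUE, "excluded")]
}

#' Write retained exon and intron regions as BED6
#'
#' One BED record per exon/intron of every retained gene
#' (name = gene id, score = 0). BED is 0-based half-open, matching the
#' internal convention, so coordinates pass through unchanged.
#'
#' @param genes List of finalized `GeneModel`.
#' @param exon_path,intron_path Output BED file paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_regions_bed <- function(genes, exon_path, intron_path) {
  kept <- retained_genes(genes)
  fmt_bed <- function(slot) {
    rows <- lapply(kept, function(g) {
      m <- g[[slot]]
      if (nrow(m) == 0L) return(NULL)
      sprintf("%s\t%d\t%d\t%s\t0\t%s",
              g$chrom, m[, "start"], m[, "end"], g$gene_id, g$strand)
    })
    unlist(rows, use.names = FALSE)
  }
  writeLines(fmt_bed("exons"), exon_path)
  writeLines(fmt_bed("introns"), intron_path)
  invisible(list(exons = exon_path, introns = intron_path))
}

#' Tabulate gene exclusions
#'
#' @param genes List of finalized `GeneModel`.
#' @param path Optional TSV output path (`gene_id`, `reason`).
#' @return A data frame of excluded genes and reasons.
#' @export
exclusion_report <- function(genes, path = NULL) {
  excl <- genes[vapply(genes, `[[`, TRUE, "excluded")]
  df <- data.frame(
    gene_id = vapply(excl, `[[`, "", "gene_id"),
    reason = vapply(excl, `[[`, "", "reason"),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}

#' Build the full region model from an annotation file
#'
#' Convenience wrapper: [load_annotation()], [flatten_and_trim()] on every
#' gene, then [filter_overlapping_genes()].
#'
#' @inheritParams load_annotation
#' @inheritParams flatten_and_trim
#' @inheritParams filter_overlapping_genes
#' @return Sorted list of finalized `GeneModel`.
#' @export
build_region_model <- function(annotation_file, trim_mode = "cds",
                               stranded = FALSE) {
  genes <- load_annotation(annotation_file)
  genes <- lapply(genes, flatten_and_trim, trim_mode = trim_mode)
  sort_gene_models(filter_overlapping_genes(genes, stranded = stranded))
}
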