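# Pipeline orchestration: annotation -> counting -> EISA -> DE -> overlaps ->
# enrichment, with deterministic TSV/JSON reports.

# Deterministic numeric formatting for text outputs: fixed significant
# digits so re-runs are byte-identical.
.fmt_num <- function(x, digits = 8L) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15, sprintf("%d", as.integer(x)),
                sprintf(paste0("%.", digits, "g"), x)))
}

#' Write a data frame as a deterministic TSV
#'
#' Numeric columns are formatted to a fixed number of significant digits so
#' that repeated runs produce byte-identical files.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns.
#' @return Invisibly `path`.
#' @export
write_tsv_deterministic <- function(df, path, digits = 8L) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- .fmt_num(out[[j]], digits)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Input paths plus every threshold of the analysis. Either `alignments`
#' (+ `annotation`) or precomputed `exon_counts` / `intron_counts` TSVs must
#' be given.
#'
#' @param design Data frame with `sample`, `condition` columns.
#' @param annotation Path to GFF3/GTF (required for the alignment entry
#'   point).
#' @param alignments Named character vector of SAM/BAM paths (names =
#'   sample ids).
#' @param exon_counts,intron_counts Paths to count-matrix TSVs (count-matrix
#'   entry point).
#' @param ortholog_map Optional two-column TSV path for cross-species
#'   overlap; requires `foreign_calls`.
#' @param foreign_calls Optional character vector of called gene ids in the
#'   other species.
#' @param category_map Optional TSV path (`gene_id`, `category_id`,
#'   `category_name`) for enrichment.
#' @param min_reads,fdr,ppde_min,fc_min,pseudocount Analysis thresholds
#'   (defaults 2, 0.05, 0.95, 2, 8).
#' @param trim_mode,stranded,dispersion_mode Region-model and test options.
#' @param seed Seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @param outdir Output directory.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(design, annotation = NULL, alignments = NULL,
                            exon_counts = NULL, intron_counts = NULL,
                            ortholog_map = NULL, foreign_calls = NULL,
                            category_map = NULL,
                            min_reads = 2L, fdr = 0.05, ppde_min = 0.95,
                            fc_min = 2, pseudocount = 8,
                            trim_mode = "cds", stranded = FALSE,
                            dispersion_mode = "common",
                            seed = 1L, outdir = tempfile("eisa_run_")) {
  stopifnot(fdr > 0, fdr <= 1, ppde_min >= 0, ppde_min <= 1,
            fc_min >= 1, pseudocount > 0, min_reads >= 0)
  cfg <- structure(
    list(design = design, annotation = annotation, alignments = alignments,
         exon_counts = exon_counts, intron_counts = intron_counts,
         ortholog_map = ortholog_map, foreign_calls = foreign_calls,
         category_map = category_map,
         min_reads = min_reads, fdr = fdr, ppde_min = ppde_min,
         fc_min = fc_min, pseudocount = pseudocount,
         trim_mode = trim_mode, stranded = stranded,
         dispersion_mode = dispersion_mode,
         seed = as.integer(seed), outdir = outdir),
    class = "PipelineConfig")
  has_counts <- !is.null(exon_counts) && !is.null(intron_counts)
  has_bam <- !is.null(alignments) && !is.null(annotation)
  if (!has_counts && !has_bam) {
    stop("provide either annotation+alignments or exon_counts+intron_counts")
  }
  for (p in c(annotation, alignments, exon_counts, intron_counts,
              ortholog_map, category_map)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  cfg
}

#' Run the full EISA pipeline
#'
#' Executes every stage and writes `eisa_results.tsv`, `de_results.tsv`,
#' `scatter_table.tsv`, `enrichment.tsv` (when a category map is given),
#' `summary.json` and `run_log.txt` into the output directory. Outputs are
#' deterministic: re-running on identical inputs yields byte-identical
#' files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the `CountTable`, filter report,
#'   `EisaResult`, `DEResult`, call summaries, overlap reports, enrichment
#'   table, and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  design <- config$design

  if (!is.null(config$exon_counts)) {
    table <- read_count_table(config$exon_counts, config$intron_counts, design)
    genes <- NULL
  } else {
    genes <- build_region_model(config$annotation, trim_mode = config$trim_mode,
                                stranded = config$stranded)
    samples <- lapply(config$alignments, count_sample, genes = genes)
    names(samples) <- names(config$alignments)
    table <- build_count_table(samples, design)
    write_regions_bed(genes,
                      file.path(config$outdir, "exons.bed"),
                      file.path(config$outdir, "introns.bed"))
    exclusion_report(genes, file.path(config$outdir, "exclusions.tsv"))
  }
  n_total <- length(table$genes)

  filt <- apply_min_count_filter(table, min_reads = config$min_reads)
  write_tsv_deterministic(filt$report, file.path(config$outdir, "filter_report.tsv"))
  n_selected <- length(filt$table$genes)

  eisa <- run_eisa(filt$table, pseudocount = config$pseudocount,
                   dispersion_mode = config$dispersion_mode,
                   fdr_threshold = config$fdr)
  eisa_calls <- call_post_transcriptional(eisa, fdr_threshold = config$fdr)
  write_tsv_deterministic(eisa_calls$results,
                          file.path(config$outdir, "eisa_results.tsv"))
  write_tsv_deterministic(make_scatter_table(eisa_calls$results),
                          file.path(config$outdir, "scatter_table.tsv"))

  de <- fit_eb_model(filt$table$exon, design)
  de_calls <- call_de(de, ppde_min = config$ppde_min, fc_min = config$fc_min)
  write_tsv_deterministic(de_calls$results,
                          file.path(config$outdir, "de_results.tsv"))

  overlap <- overlap_eisa_de(eisa_calls$called, de_calls$called)

  cross <- NULL
  if (!is.null(config$ortholog_map) && !is.null(config$foreign_calls)) {
    cross <- cross_species_overlap(eisa_calls$called$gene_id,
                                   config$foreign_calls, config$ortholog_map)
  }

  enrich <- NULL
  if (!is.null(config$category_map)) {
    cats <- utils::read.table(config$category_map, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    enrich <- if (nrow(eisa_calls$called)) {
      run_ora(eisa_calls$called$gene_id, eisa$gene_id, cats)
    } else {
      # no called genes: nothing to test, write a header-only table
      run_ora(eisa$gene_id[1], eisa$gene_id, cats[0, , drop = FALSE])
    }
    write_tsv_deterministic(enrich, file.path(config$outdir, "enrichment.tsv"))
  }

  summary <- list(
    genes_total = n_total,
    genes_selected = n_selected,
    pct_selected = .pct(n_selected, n_total),
    eisa = eisa_calls$summary,
    de = de_calls$summary,
    overlap_eisa_de = overlap
  )
  if (!is.null(cross)) summary$cross_species <- cross
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, file.path(config$outdir, "summary.json"))

  log_lines <- c(
    paste0("eisapipe ", as.character(utils::packageVersion("eisapipe"))),
    paste0("seed: ", config$seed),
    sprintf("thresholds: min_reads=%d fdr=%g ppde_min=%g fc_min=%g pseudocount=%g",
            config$min_reads, config$fdr, config$ppde_min, config$fc_min,
            config$pseudocount),
    paste0("dispersion_mode: ", config$dispersion_mode),
    paste0("entry: ", if (is.null(config$exon_counts)) "alignments" else "count matrices")
  )
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))

  invisible(list(table = table, filtered = filt$table,
                 filter_report = filt$report, genes = genes,
                 eisa = eisa_calls$results, eisa_summary = eisa_calls$summary,
                 de = de_calls$results, de_summary = de_calls$summary,
                 overlap = overlap, cross_species = cross,
                 enrichment = enrich, summary = summary,
                 outdir = config$outdir))
}

#' Scatter table of per-gene deltas
#'
#' One row per tested gene with `delta_intron`, `delta_exon` and the call —
#' the data behind the classic delta-exon vs delta-intron scatter in which
#' transcriptionally regulated genes hug the diagonal and
#' post-transcriptionally regulated genes depart from it.
#'
#' @param eisa_results An `EisaResult` data frame (with `call` column).
#' @return Data frame `gene_id`, `delta_intron`, `delta_exon`, `call`.
#' @export
make_scatter_table <- function(eisa_results) {
  stopifnot(all(c("gene_id", "delta_intron", "delta_exon", "call") %in%
                  names(eisa_results)))
  data.frame(gene_id = eisa_results$gene_id,
             delta_intron = eisa_results$delta_intron,
             delta_exon = eisa_results$delta_exon,
             call = eisa_results$call,
             stringsAsFactors = FALSE)
}
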