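# Generates the packaged 30-gene demonstration fixture under inst/extdata/
# and the golden pipeline outputs the regression test compares against.
# Run from the repository root after installing the package:
#   Rscript tools/make_fixture.R
library(eisapipe)

outdir <- "inst/extdata"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(n_genes = 30, n_replicates = 3, seed = 101,
                         fraction_pt = 0.2, pt_effect = 3,
                         fraction_t = 0.3, t_effect = 1.5)
sim <- simulate_counts(cfg)

write_count_table(sim$table,
                  file.path(outdir, "fixture_exon_counts.tsv"),
                  file.path(outdir, "fixture_intron_counts.tsv"))
write.table(sim$design, file.path(outdir, "fixture_design.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(outdir, "fixture_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# category map: one category enriched in the true post-transcriptional genes,
# one spread across the rest
set.seed(7)
pt_genes <- sim$truth$gene_id[sim$truth$p_i != 0]
other <- setdiff(sim$truth$gene_id, pt_genes)
cats <- rbind(
  data.frame(gene_id = c(pt_genes, sample(other, 2)),
             category_id = "CAT:PT", category_name = "mRNA stability pathway"),
  data.frame(gene_id = sample(other, 15),
             category_id = "CAT:BG", category_name = "background process")
)
write.table(cats, file.path(outdir, "fixture_categories.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# orthologue map to a fictitious second species plus its call set
map <- data.frame(a = sim$truth$gene_id,
                  b = sprintf("sp2_%s", sim$truth$gene_id))
write.table(map, file.path(outdir, "fixture_orthologs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
foreign <- sprintf("sp2_%s", sort(c(pt_genes[1:3], other[1:2])))
writeLines(foreign, file.path(outdir, "fixture_foreign_calls.txt"))

# golden run
golden_dir <- file.path(outdir, "golden")
dir.create(golden_dir, showWarnings = FALSE)
pcfg <- pipeline_config(
  design = sim$design,
  exon_counts = file.path(outdir, "fixture_exon_counts.tsv"),
  intron_counts = file.path(outdir, "fixture_intron_counts.tsv"),
  ortholog_map = file.path(outdir, "fixture_orthologs.tsv"),
  foreign_calls = foreign,
  category_map = file.path(outdir, "fixture_categories.tsv"),
  outdir = tempfile("golden_run_")
)
res <- run_pipeline(pcfg)
for (f in c("summary.json", "eisa_results.tsv", "de_results.tsv",
            "scatter_table.tsv", "enrichment.tsv")) {
  file.copy(file.path(pcfg$outdir, f), file.path(golden_dir, f),
            overwrite = TRUE)
}
cat("golden summary:\n")
cat(readLines(file.path(golden_dir, "summary.json")), sep = "\n")
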