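# Region model: coordinate conventions, exon flattening, CDS trimming,
# enclosed introns, and exclusion of overlapping genes.

write_gff <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("GFF3 1-based inclusive coordinates convert to 0-based half-open", {
  p <- write_gff(c(
    "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tID=e1;Parent=gA.t1",
    "chr1\tsrc\texon\t300\t400\t.\t+\t.\tID=e2;Parent=gA.t1"
  ))
  genes <- load_annotation(p)
  expect_length(genes, 1L)
  expect_equal(unname(genes[[1]]$exons[, "start"]), c(99L, 299L))
  expect_equal(unname(genes[[1]]$exons[, "end"]), c(200L, 400L))
})

test_that("exons from multiple transcripts flatten to their interval union", {
  p <- write_gff(c(
    "chr1\tsrc\tgene\t101\t250\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=e1;Parent=gA.t1",
    "chr1\tsrc\tmRNA\t151\t250\t.\t+\t.\tID=gA.t2;Parent=gA",
    "chr1\tsrc\texon\t151\t250\t.\t+\t.\tID=e2;Parent=gA.t2"
  ))
  g <- flatten_and_trim(load_annotation(p)[[1]], trim_mode = "none")
  expect_equal(nrow(g$exons), 1L)
  expect_equal(unname(g$exons[1, ]), c(100L, 250L))
})

test_that("empty and malformed annotation files are handled", {
  empty <- write_gff(character(0))
  expect_identical(load_annotation(empty), list())
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\tonly three\tfields"), bad)
  expect_error(load_annotation(bad), "line 2")
  orphan <- write_gff("chr1\tsrc\texon\t10\t90\t.\t+\t.\tID=e1")
  expect_error(load_annotation(orphan), "parent")
})

test_that("CDS trimming clips exons to the body and derives enclosed introns", {
  g <- gene_model("g1", "chr1", "+",
                  exons = interval_matrix(c(0, 200), c(100, 300)),
                  cds = interval_matrix(50, 250))
  out <- flatten_and_trim(g, trim_mode = "cds")
  expect_equal(unname(out$body), c(50L, 250L))
  expect_equal(unname(out$exons), matrix(c(50L, 200L, 100L, 250L), 2),
               ignore_attr = TRUE)
  expect_equal(unname(out$introns), matrix(c(100L, 200L), 1),
               ignore_attr = TRUE)
  expect_false(out$excluded)
  # idempotence
  again <- flatten_and_trim(out, trim_mode = "cds")
  expect_equal(again[c("body", "exons", "introns", "excluded")],
               out[c("body", "exons", "introns", "excluded")])
})

test_that("genes without introns or without CDS are excluded with a reason", {
  single <- flatten_and_trim(
    gene_model("g1", "chr1", exons = interval_matrix(0, 100),
               cds = interval_matrix(10, 90)))
  expect_true(single$excluded)
  expect_identical(single$reason, "no_intron")

  abutting <- flatten_and_trim(
    gene_model("g2", "chr1", exons = interval_matrix(c(0, 100), c(100, 200)),
               cds = interval_matrix(10, 190)))
  expect_equal(nrow(abutting$exons), 1L)
  expect_identical(abutting$reason, "no_intron")

  nocds <- flatten_and_trim(
    gene_model("g3", "chr1", exons = interval_matrix(c(0, 200), c(100, 300))))
  expect_true(nocds$excluded)
  expect_identical(nocds$reason, "no_cds")
  # trim_mode = none keeps it
  kept <- flatten_and_trim(
    gene_model("g3", "chr1", exons = interval_matrix(c(0, 200), c(100, 300))),
    trim_mode = "none")
  expect_false(kept$excluded)
  expect_equal(unname(kept$body), c(0L, 300L))
})

test_that("overlapping bodies exclude both genes; abutting bodies neither", {
  mk <- function(id, s, e, chrom = "chr1", strand = "+") {
    g <- gene_model(id, chrom, strand,
                    exons = interval_matrix(c(s, e - 50), c(s + 40, e)),
                    cds = interval_matrix(s, e))
    flatten_and_trim(g)
  }
  a <- mk("A", 0, 100); b <- mk("B", 50, 150); c <- mk("C", 300, 400)
  out <- filter_overlapping_genes(list(a, b, c))
  expect_identical(vapply(out, `[[`, "", "reason")[1:2],
                   c("overlapping", "overlapping"))
  expect_false(out[[3]]$excluded)

  d <- mk("D", 100, 200)  # abuts A at 100 (half-open)
  out2 <- filter_overlapping_genes(list(a, d))
  expect_false(out2[[1]]$excluded)
  expect_false(out2[[2]]$excluded)

  # strand-aware mode ignores opposite-strand overlap
  b_minus <- mk("B", 50, 150, strand = "-")
  out3 <- filter_overlapping_genes(list(a, b_minus), stranded = TRUE)
  expect_false(out3[[1]]$excluded)
})

test_that("overlap exclusion is invariant to input order", {
  set.seed(5)
  mk <- function(id, s, e) {
    flatten_and_trim(gene_model(id, "chr1",
                                exons = interval_matrix(c(s, e - 30), c(s + 20, e)),
                                cds = interval_matrix(s, e)))
  }
  starts <- sample(0:2000, 20)
  genes <- lapply(seq_along(starts), function(i) {
    mk(sprintf("g%02d", i), starts[i], starts[i] + sample(60:300, 1))
  })
  excl_set <- function(gs) {
    out <- filter_overlapping_genes(gs)
    sort(vapply(out[vapply(out, `[[`, TRUE, "excluded")], `[[`, "", "gene_id"))
  }
  expect_identical(excl_set(genes), excl_set(rev(genes)))
  expect_identical(excl_set(genes), excl_set(genes[sample(20)]))
})

test_that("introns match the per-base complement oracle and tile the body", {
  set.seed(11)
  for (rep in 1:30) {
    n_ex <- sample(1:8, 1)
    lens <- sample(30:200, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1) sample(20:150, n_ex - 1, replace = TRUE) else integer(0)
    pos <- cumsum(c(sample(0:50, 1), rbind(lens, c(gaps, 0))))
    starts <- pos[seq(1, length(pos) - 1, by = 2)]
    ends <- starts + lens
    cds <- c(starts[1] + 5, ends[n_ex] - 5)
    g <- flatten_and_trim(gene_model("g", "chr1",
                                     exons = interval_matrix(starts, ends),
                                     cds = interval_matrix(cds[1], cds[2])))
    expect_equal(g$introns, oracle_introns(g$exons, g$body))
    if (!g$excluded) {
      # exons and introns tile the body exactly
      expect_equal(interval_width(g$exons) + interval_width(g$introns),
                   g$body[2] - g$body[1])
      expect_equal(nrow(merge_intervals(rbind(g$exons, g$introns))), 1L)
    }
  }
})

test_that("BED export writes retained regions with gene ids", {
  ann <- simulate_annotation(12, seed = 3, overlap_fraction = 0.2)
  genes <- build_region_model(ann$gff)
  eb <- tempfile(fileext = ".bed"); ib <- tempfile(fileext = ".bed")
  write_regions_bed(genes, eb, ib)
  ex <- read.table(eb, sep = "\t")
  expect_true(all(ex$V5 == 0))
  kept_ids <- vapply(retained_genes(genes), `[[`, "", "gene_id")
  expect_setequal(unique(ex$V4), kept_ids)
  expect_true(all(ex$V2 < ex$V3))
  rep <- exclusion_report(genes)
  expect_setequal(rep$gene_id, ann$truth$gene_id[ann$truth$excluded])
})
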