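# Read counting: uniqueness filter, body containment, exon-over-intron
# priority, spliced reads, table assembly and the minimum-count filter.

# One gene chr1:[100,400) body, exons [100,200)+[300,400), intron [200,300).
simple_gene <- function() {
  flatten_and_trim(gene_model("gX", "chr1",
                              exons = interval_matrix(c(100, 300), c(200, 400)),
                              cds = interval_matrix(100, 400)))
}

write_sam <- function(recs, path = tempfile(fileext = ".sam"), ln = 10000L) {
  writeLines(c("@HD\tVN:1.6", sprintf("@SQ\tSN:chr1\tLN:%d", ln), recs), path)
  path
}

rec <- function(pos0, cigar, nh = 1L, mapq = 60L, chrom = "chr1", id = "r1") {
  sprintf("%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tNH:i:%d",
          id, chrom, pos0 + 1L, mapq, cigar, nh)
}

test_that("reads are classified exonic/intronic by the containment rules", {
  g <- list(simple_gene())
  sam <- write_sam(c(
    rec(120, "50M", id = "exonic"),          # inside exon
    rec(220, "50M", id = "intronic"),        # inside intron
    rec(150, "100M", id = "boundary"),       # spans exon/intron boundary -> exon
    rec(95, "50M", id = "outside_body"),     # pokes out of body -> unassigned
    rec(3000, "50M", id = "intergenic"),     # not in any gene
    rec(120, "50M", nh = 2L, id = "multi"),  # multimapper, dropped
    rec(150, "50M50N50M", id = "spliced")    # split read; first block in exon -> exonic
  ))
  out <- count_sample(sam, g)
  expect_equal(unname(out$exon["gX"]), 3L)   # exonic + boundary + spliced
  expect_equal(unname(out$intron["gX"]), 1L)
  expect_equal(out$n_unique, 6L)
  expect_equal(out$n_assigned, 4L)
})

test_that("reads without NH tag fall back to the MAPQ threshold", {
  g <- list(simple_gene())
  norec <- function(pos0, mapq, id) {
    sprintf("%s\t0\tchr1\t%d\t%d\t50M\t*\t0\t0\t*\t*", id, pos0 + 1L, mapq)
  }
  sam <- write_sam(c(norec(120, 60, "hi"), norec(120, 5, "lo")))
  out <- count_sample(sam, g)
  expect_equal(unname(out$exon["gX"]), 1L)
  out2 <- count_sample(sam, g, counting_params(min_mapq = 0L))
  expect_equal(unname(out2$exon["gX"]), 2L)
})

test_that("intron margin shrinks the intronic assignment window", {
  g <- list(simple_gene())
  sam <- write_sam(rec(210, "20M"))  # within [200,300) but near the 5' edge
  expect_equal(unname(count_sample(sam, g)$intron["gX"]), 1L)
  out <- count_sample(sam, g, counting_params(intron_margin = 40L))
  expect_equal(unname(out$intron["gX"]), 0L)
})

test_that("chromosomes absent from the annotation warn and are skipped", {
  g <- list(simple_gene())
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:10000", "@SQ\tSN:chr9\tLN:10000",
               rec(120, "50M"), rec(120, "50M", chrom = "chr9", id = "r2")),
             path)
  expect_warning(out <- count_sample(path, g), "chr9")
  expect_equal(unname(out$exon["gX"]), 1L)
})

test_that("unindexed BAM input errors", {
  g <- list(simple_gene())
  sam <- write_sam(rec(120, "50M"))
  bam <- Rsamtools::asBam(sam, tempfile(), indexDestination = FALSE)
  expect_error(count_sample(bam, g), "index")
})

test_that("count tables assemble deterministically and totals match", {
  g <- list(simple_gene())
  sams <- list(
    s1 = write_sam(c(rec(110, "50M"), rec(130, "50M", id = "r2"),
                     rec(150, "50M", id = "r3"), rec(220, "40M", id = "r4"))),
    s2 = write_sam(c(rec(110, "50M"), rec(130, "50M", id = "r2"),
                     rec(220, "40M", id = "r3"), rec(230, "40M", id = "r4"),
                     rec(120, "50M", id = "r5")))
  )
  design <- data.frame(sample = c("s1", "s2"),
                       condition = c("young", "expanded"))
  counts <- lapply(sams, count_sample, genes = g)
  tab <- build_count_table(counts, design)
  expect_equal(unname(tab$exon["gX", ]), c(3L, 3L))
  expect_equal(unname(tab$intron["gX", ]), c(1L, 2L))
  expect_equal(unname(tab$lib_exon), c(3L, 3L))
  # conservation: assigned <= unique reads
  expect_true(all(vapply(counts, function(x) x$n_assigned <= x$n_unique, TRUE)))
  # determinism: recount yields the identical table
  counts2 <- lapply(sams, count_sample, genes = g)
  expect_identical(build_count_table(counts2, design), tab)
  # mismatched gene universes error
  counts2$s2$exon <- counts2$s2$exon[0]
  counts2$s2$intron <- counts2$s2$intron[0]
  expect_error(build_count_table(counts2, design), "gene sets differ")
})

test_that("fragment mode counts a read pair once", {
  g <- list(simple_gene())
  sam <- write_sam(c(rec(110, "40M", id = "pair1"), rec(150, "40M", id = "pair1")))
  expect_equal(unname(count_sample(sam, g)$exon["gX"]), 2L)
  out <- count_sample(sam, g, counting_params(fragment = TRUE))
  expect_equal(unname(out$exon["gX"]), 1L)
})

test_that("minimum-count filter removes low-coverage genes and is monotone", {
  design <- data.frame(sample = c("s1", "s2"), condition = c("young", "expanded"))
  exon <- matrix(c(5L, 9L, 4L, 7L), 2, 2,
                 dimnames = list(c("gA", "gB"), c("s1", "s2")))
  intron <- matrix(c(3L, 1L, 2L, 6L), 2, 2,
                   dimnames = list(c("gA", "gB"), c("s1", "s2")))
  tab <- count_table(exon, intron, design)
  out <- apply_min_count_filter(tab, min_reads = 2L)
  expect_identical(out$table$genes, "gA")  # gB has an intron count of 1
  expect_identical(out$report$gene_id, "gB")
  expect_identical(out$report$reason, "low_intron")
  # vacuous filter
  expect_identical(apply_min_count_filter(tab, min_reads = 0L)$table$genes,
                   c("gA", "gB"))
  expect_error(apply_min_count_filter(tab, min_reads = -1), "min_reads")
  # monotone: raising min_reads never enlarges the retained set
  set.seed(2)
  tab2 <- random_count_table(n_genes = 40, mean_count = 6)
  prev <- tab2$genes
  for (mr in 0:6) {
    cur <- apply_min_count_filter(tab2, min_reads = mr)$table$genes
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # library totals are preserved from the unfiltered table
  filt <- apply_min_count_filter(tab2, min_reads = 4L)$table
  expect_identical(filt$lib_exon, tab2$lib_exon)
})

test_that("per-feature filter needs and uses per-feature counts", {
  g <- list(simple_gene())
  # exon 1 gets 2 reads, exon 2 gets none, intron gets 2
  sam <- write_sam(c(rec(110, "50M"), rec(120, "50M", id = "r2"),
                     rec(220, "40M", id = "r3"), rec(230, "40M", id = "r4")))
  design <- data.frame(sample = "s1", condition = "young")
  plain <- build_count_table(list(s1 = count_sample(sam, g)), design)
  expect_error(apply_min_count_filter(plain, mode = "per_feature"),
               "per-feature")
  cnt <- count_sample(sam, g, counting_params(per_feature = TRUE))
  expect_equal(cnt$exon_features$gX, c(2L, 0L))
  tab <- build_count_table(list(s1 = cnt), design)
  out <- apply_min_count_filter(tab, mode = "per_feature", min_reads = 2L)
  expect_length(out$table$genes, 0L)  # exon 2 has < 2 reads
  gt <- apply_min_count_filter(tab, mode = "gene_total", min_reads = 2L)
  expect_identical(gt$table$genes, "gX")
})

test_that("counts match the per-base SAM oracle on random fixtures", {
  set.seed(21)
  for (rep in 1:10) {
    ann <- simulate_annotation(sample(3:8, 1), seed = 100 + rep,
                               overlap_fraction = 0.1)
    genes <- build_region_model(ann$gff)
    kept <- retained_genes(genes)
    if (!length(kept)) next
    tc <- data.frame(gene_id = vapply(kept, `[[`, "", "gene_id"),
                     exon = sample(0:6, length(kept), replace = TRUE),
                     intron = sample(0:4, length(kept), replace = TRUE))
    sam <- simulate_alignments(genes, tc, seed = 200 + rep,
                               spliced = rep %% 2 == 0)
    got <- count_sample(sam, genes)
    want <- oracle_count_sam(sam, genes)
    expect_identical(got$exon, want$exon)
    expect_identical(got$intron, want$intron)
  }
})
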