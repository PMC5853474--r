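# The synthetic-data generator: determinism, distributional structure, and
# agreement between generated alignments and counting targets.

test_that("annotation generation is byte-identical for a fixed seed", {
  p1 <- simulate_annotation(25, seed = 99, overlap_fraction = 0.1)$gff
  p2 <- simulate_annotation(25, seed = 99, overlap_fraction = 0.1)$gff
  expect_identical(readLines(p1), readLines(p2))
  p3 <- simulate_annotation(25, seed = 100, overlap_fraction = 0.1)$gff
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("generator truth matches the region model built from its GFF3", {
  for (ofrac in c(0, 0.2)) {
    ann <- simulate_annotation(50, seed = 31, overlap_fraction = ofrac)
    genes <- build_region_model(ann$gff)
    obs <- data.frame(gene_id = vapply(genes, `[[`, "", "gene_id"),
                      reason = vapply(genes, `[[`, "", "reason"))
    obs <- obs[order(obs$gene_id), ]
    tr <- ann$truth[order(ann$truth$gene_id), ]
    expect_identical(obs$reason, tr$reason)
    if (ofrac == 0) {
      expect_false(any(obs$reason == "overlapping", na.rm = TRUE))
    }
    # expected models agree interval-by-interval for retained genes
    exp_kept <- retained_genes(ann$models)
    got_kept <- retained_genes(genes)
    expect_equal(length(exp_kept), length(got_kept))
    for (i in seq_along(exp_kept)) {
      expect_equal(got_kept[[i]]$exons, exp_kept[[i]]$exons)
      expect_equal(got_kept[[i]]$introns, exp_kept[[i]]$introns)
      expect_equal(got_kept[[i]]$body, exp_kept[[i]]$body)
    }
  }
})

test_that("simulated counts have NB mean-variance structure", {
  cfg <- simulation_config(n_genes = 1, n_replicates = 2, seed = 8,
                           baseline_mean_log2 = log2(200), baseline_sd_log2 = 0,
                           nb_dispersion = 0.1, fraction_pt = 0, fraction_t = 0)
  # draw many replicates by stacking independent simulations
  set.seed(8)
  draws <- rnbinom(1e4, size = 1 / 0.1, mu = 200)
  expect_equal(mean(draws), 200, tolerance = 0.05 * 200)
  expect_equal(var(draws), 200 + 0.1 * 200^2, tolerance = 0.05 * (200 + 0.1 * 200^2))
  # the generator's own draws match the same law
  cfg2 <- simulation_config(n_genes = 2000, n_replicates = 3, seed = 9,
                            baseline_mean_log2 = log2(200), baseline_sd_log2 = 0,
                            nb_dispersion = 0.1, fraction_pt = 0, fraction_t = 0)
  sim <- simulate_counts(cfg2)
  m <- mean(sim$table$exon)
  v <- var(as.vector(sim$table$exon))
  expect_equal(m, 200, tolerance = 0.05 * 200)
  expect_equal(v, 200 + 0.1 * 200^2, tolerance = 0.05 * (200 + 0.1 * 200^2))
})

test_that("effect construction matches expectation in the high-count limit", {
  # checks on raw count means, before any normalization: the generator's
  # construction puts t_i in both compartments and p_i in exons only
  raw_ratio <- function(m, cond) {
    log2(rowMeans(m[, cond == "expanded", drop = FALSE]) /
           rowMeans(m[, cond == "young", drop = FALSE]))
  }
  cfg <- simulation_config(n_genes = 500, n_replicates = 6, seed = 14,
                           baseline_mean_log2 = log2(2000),
                           fraction_pt = 0, fraction_t = 1, t_effect = 1)
  sim <- simulate_counts(cfg)
  sgn <- sign(sim$truth$t_i)
  expect_equal(mean(raw_ratio(sim$table$exon, sim$table$condition) * sgn), 1,
               tolerance = 0.05)
  expect_equal(mean(raw_ratio(sim$table$intron, sim$table$condition) * sgn), 1,
               tolerance = 0.1)
  # post-transcriptional effect appears in exons only
  cfg2 <- simulation_config(n_genes = 500, n_replicates = 6, seed = 15,
                            baseline_mean_log2 = log2(2000),
                            fraction_pt = 1, pt_effect = 2, fraction_t = 0)
  sim2 <- simulate_counts(cfg2)
  dd_raw <- raw_ratio(sim2$table$exon, sim2$table$condition) -
    raw_ratio(sim2$table$intron, sim2$table$condition)
  expect_equal(mean(dd_raw - sim2$truth$p_i), 0, tolerance = 0.1)
  # no post-transcriptional effect: normalized delta_diff hugs the diagonal
  cfg3 <- simulation_config(n_genes = 500, seed = 16,
                            baseline_mean_log2 = log2(1000),
                            fraction_pt = 0, fraction_t = 0.3)
  d3 <- compute_deltas(normalize_counts(simulate_counts(cfg3)$table))
  expect_lt(median(abs(d3$delta_diff)), 0.3)
})

test_that("alignment round trip recovers targets; decoys never count", {
  ann <- simulate_annotation(10, seed = 44)
  genes <- build_region_model(ann$gff)
  kept <- retained_genes(genes)
  ids <- vapply(kept, `[[`, "", "gene_id")
  tc <- data.frame(gene_id = ids,
                   exon = sample(0:9, length(ids), replace = TRUE),
                   intron = sample(0:5, length(ids), replace = TRUE))
  sam <- simulate_alignments(genes, tc, seed = 45)
  out <- count_sample(sam, genes)
  expect_identical(unname(out$exon[ids]), as.integer(tc$exon))
  expect_identical(unname(out$intron[ids]), as.integer(tc$intron))

  # multimapper-only input counts nothing
  tc0 <- data.frame(gene_id = ids, exon = 0L, intron = 0L)
  sam0 <- simulate_alignments(genes, tc0, seed = 46, n_decoy_multimap = 10,
                              n_decoy_outside = 0)
  out0 <- count_sample(sam0, genes)
  expect_true(all(out0$exon == 0L) && all(out0$intron == 0L))

  # empty target with no decoys: header-only SAM
  sam_empty <- simulate_alignments(genes, tc0, seed = 47,
                                   n_decoy_multimap = 0, n_decoy_outside = 0)
  expect_true(all(grepl("^@", readLines(sam_empty))))
})

test_that("count generation is reproducible and truth classes are consistent", {
  cfg <- simulation_config(n_genes = 100, seed = 3)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$table$exon, s2$table$exon)
  expect_identical(s1$truth, s2$truth)
  with(s1$truth, {
    expect_true(all((class == "null") == (t_i == 0 & p_i == 0)))
    expect_true(all((class == "post_transcriptional") == (t_i == 0 & p_i != 0)))
    expect_true(all((class == "both") == (t_i != 0 & p_i != 0)))
  })
})
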