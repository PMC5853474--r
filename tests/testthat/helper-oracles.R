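# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: per-base boolean arrays for region and
# counting checks, a hand-written SAM parser, direct likelihood optimization
# for the NB GLM, and direct binomial-coefficient summation for the
# hypergeometric tail.

# Introns as the per-base complement of exon bases within the body.
oracle_introns <- function(exons, body) {
  n <- body[2] - body[1]
  if (n <= 0) return(interval_matrix())
  covered <- logical(n)
  for (i in seq_len(nrow(exons))) {
    s <- max(exons[i, "start"], body[1]) - body[1]
    e <- min(exons[i, "end"], body[2]) - body[1]
    if (s < e) covered[(s + 1):e] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  gap <- !r$values
  # leading/trailing uncovered runs are not introns (not enclosed by exons)
  if (length(gap) && gap[1]) gap[1] <- FALSE
  if (length(gap) && gap[length(gap)]) gap[length(gap)] <- FALSE
  if (!any(gap)) return(interval_matrix())
  interval_matrix(body[1] + starts[gap], body[1] + ends[gap])
}

# All-pairs body overlap: returns logical vector, TRUE = overlapping.
oracle_overlapping <- function(chrom, start, end) {
  n <- length(chrom)
  bad <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && chrom[i] == chrom[j] &&
          start[i] < end[j] && start[j] < end[i]) {
        bad[i] <- TRUE
      }
    }
  }
  bad
}

# Minimal independent SAM parser: returns one row per record with the read's
# aligned blocks (0-based half-open) after CIGAR splitting, plus NH and MAPQ.
oracle_parse_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^@", lines)]
  recs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    pos0 <- as.integer(f[4]) - 1L
    cigar <- f[6]
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    blocks <- NULL
    cur <- pos0
    bs <- cur
    open <- FALSE
    starts <- integer(0); ends <- integer(0)
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^\\d+", "", op)
      if (type %in% c("M", "=", "X")) {
        if (!open) { bs <- cur; open <- TRUE }
        cur <- cur + len
      } else if (type %in% c("D")) {
        cur <- cur + len  # deletion stays within the block
      } else if (type == "N") {
        if (open) { starts <- c(starts, bs); ends <- c(ends, cur); open <- FALSE }
        cur <- cur + len
      }
      # I, S, H, P consume no reference
    }
    if (open) { starts <- c(starts, bs); ends <- c(ends, cur) }
    nh <- NA_integer_
    m <- grep("^NH:i:", f[-(1:11)], value = TRUE)
    if (length(m)) nh <- as.integer(sub("^NH:i:", "", m[1]))
    list(qname = f[1], chrom = f[3], mapq = as.integer(f[5]),
         nh = nh, starts = starts, ends = ends)
  })
  recs
}

# Per-base counting oracle: classify every unique-mapping record against the
# retained gene models, exonic-over-intronic priority, whole-read-in-body
# rule. Returns named exon/intron count vectors.
oracle_count_sam <- function(path, genes, min_mapq = 30L) {
  kept <- retained_genes(genes)
  ids <- vapply(kept, `[[`, "", "gene_id")
  exon <- stats::setNames(integer(length(kept)), ids)
  intron <- exon
  recs <- oracle_parse_sam(path)
  for (r in recs) {
    unique_ok <- if (!is.na(r$nh)) r$nh == 1L else r$mapq >= min_mapq
    if (!unique_ok) next
    span <- c(min(r$starts), max(r$ends))
    for (gi in seq_along(kept)) {
      g <- kept[[gi]]
      if (g$chrom != r$chrom) next
      if (!(g$body[1] <= span[1] && span[2] <= g$body[2])) next
      hit_exon <- FALSE
      for (b in seq_along(r$starts)) {
        for (e in seq_len(nrow(g$exons))) {
          if (r$starts[b] < g$exons[e, "end"] && g$exons[e, "start"] < r$ends[b]) {
            hit_exon <- TRUE
          }
        }
      }
      if (hit_exon) {
        exon[gi] <- exon[gi] + 1L
      } else {
        hit_intron <- FALSE
        for (b in seq_along(r$starts)) {
          for (e in seq_len(nrow(g$introns))) {
            if (r$starts[b] < g$introns[e, "end"] &&
                g$introns[e, "start"] < r$ends[b]) {
              hit_intron <- TRUE
            }
          }
        }
        if (hit_intron) intron[gi] <- intron[gi] + 1L
      }
      break  # bodies are disjoint
    }
  }
  list(exon = exon, intron = intron)
}

# Direct NB likelihood maximization over the GLM coefficients (Nelder-Mead),
# independent of IRLS. Returns the maximized log-likelihood.
oracle_nb_maxloglik <- function(y, X, offset, phi) {
  nll <- function(beta) {
    mu <- exp(offset + drop(X %*% beta))
    -sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
  start <- rep(0, ncol(X))
  start[1] <- log(mean(y) + 0.5) - mean(offset)
  best <- optim(start, nll, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-12))
  best <- optim(best$par, nll, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-12))
  -best$value
}

# Benjamini-Hochberg step-up, written out directly.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, (m / i) * p[o[i]])
    adj[o[i]] <- prev
  }
  adj
}

# Upper-tail hypergeometric by direct binomial-coefficient summation.
oracle_hyper_upper <- function(k, N, K, n) {
  j <- k:min(n, K)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Rank-based AUROC of scores against binary truth.
oracle_auroc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small random count table with both compartments and a 2x2 design.
random_count_table <- function(n_genes = 5, n_rep = 3, mean_count = 50,
                               phi = 0.1) {
  samples <- c(sprintf("young_%d", seq_len(n_rep)),
               sprintf("expanded_%d", seq_len(n_rep)))
  design <- data.frame(sample = samples,
                       condition = rep(c("young", "expanded"), each = n_rep))
  gid <- sprintf("g%03d", seq_len(n_genes))
  mk <- function() {
    m <- matrix(rnbinom(n_genes * 2 * n_rep, size = 1 / phi, mu = mean_count),
                n_genes, 2 * n_rep, dimnames = list(gid, samples))
    m
  }
  count_table(mk(), mk(), design)
}
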