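# Empirical-Bayes differential expression on exonic counts, plus the overlap
# reports between EISA calls and DE calls (within and across species).
#
# The DE model is a two-pattern beta-negative-binomial mixture: each gene's
# counts are NB(r_g * s_j, q) with the probability parameter q drawn from a
# conjugate Beta(alpha, beta) prior — either one q shared by both conditions
# (equal expression, EE) or independent q per condition (DE). The conjugacy
# gives closed-form marginal likelihoods; the prior hyperparameters and the
# mixture weight P(DE) are fitted by EM over all genes, and each gene's
# posterior probability of the DE pattern is its PPDE.

#' Median-of-ratios size factors
#'
#' For each sample, the median across genes of the ratio of its count to the
#' per-gene geometric mean, computed over genes expressed in every sample;
#' factors are rescaled so their geometric mean is 1. Falls back to
#' total-count factors (same rescaling) with a warning when no gene is
#' expressed in all samples.
#'
#' @param counts Gene x sample count matrix.
#' @return Named per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- apply(counts > 0, 1L, all)
  if (!any(all_pos)) {
    warning("no gene expressed in all samples; using total-count size factors")
    sf <- colSums(counts)
    if (any(sf <= 0)) stop("sample with zero total count")
  } else {
    logc <- log(counts[all_pos, , drop = FALSE])
    loggeo <- rowMeans(logc)
    sf <- apply(logc, 2L, function(x) exp(stats::median(x - loggeo)))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

# Log marginal likelihood of counts y (sizes r) sharing one q ~ Beta(a, b):
#   sum_j log NBcoef(y_j; r_j) + log B(a + sum r, b + sum y) - log B(a, b)
.bnb_logmarg <- function(y_sum, r_sum, coef_sum, a, b) {
  coef_sum + lbeta(a + r_sum, b + y_sum) - lbeta(a, b)
}

#' Fit the empirical-Bayes DE model
#'
#' Estimates, for every gene, the posterior probability of differential
#' expression (PPDE) between the young and expanded conditions from exonic
#' counts, together with a moderated log2 fold change.
#'
#' Per-gene NB sizes `r_g` come from a pooled within-condition
#' method-of-moments fit on size-factor-normalized counts; the Beta prior
#' hyperparameters and the mixture weight are then fitted by EM (monotone in
#' the observed-data log-likelihood, tracked in the result).
#'
#' @param counts Gene x sample matrix of exonic counts.
#' @param design Data frame with `sample`, `condition` columns.
#' @param size_factors Optional per-sample factors; estimated with
#'   [estimate_size_factors()] when missing.
#' @param maxit,tol EM iteration cap (default 500) and relative log-likelihood
#'   tolerance (default 1e-6).
#' @return A `DEResult` data frame: `gene_id`, `log2_fc` (expanded vs young,
#'   pseudocount 0.5), `ppde`. Attributes: `mixture_weight` (fitted P(DE)),
#'   `hyper` (alpha, beta), `loglik_trace`, `converged`.
#' @export
fit_eb_model <- function(counts, design, size_factors = NULL,
                         maxit = 500L, tol = 1e-6) {
  counts <- as.matrix(counts)
  samples <- colnames(counts)
  cond <- design$condition[match(samples, design$sample)]
  if (anyNA(cond)) stop("design missing condition for some samples")
  young <- cond == "young"
  expanded <- cond == "expanded"
  if (sum(young) < 2L || sum(expanded) < 2L) {
    stop("the EB model needs >= 2 replicates per condition")
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  sf <- size_factors[samples]

  norm <- sweep(counts, 2L, sf, `/`)
  m <- rowMeans(norm)
  # pooled within-condition variance, so true DE does not inflate r_g
  v_within <- (apply(norm[, young, drop = FALSE], 1L, stats::var) * (sum(young) - 1L) +
               apply(norm[, expanded, drop = FALSE], 1L, stats::var) * (sum(expanded) - 1L)) /
    (ncol(norm) - 2L)
  r_g <- ifelse(v_within > m & m > 0, m^2 / (v_within - m), pmax(m, 1) * 100)
  r_g <- pmin(pmax(r_g, 1e-2), 1e6)

  r_mat <- outer(r_g, sf)            # r_gs = r_g * s_j
  coef_mat <- lgamma(counts + r_mat) - lgamma(r_mat) - lgamma(counts + 1)
  sum_grp <- function(mat, grp) rowSums(mat[, grp, drop = FALSE])
  y_all <- rowSums(counts); r_all <- rowSums(r_mat); c_all <- rowSums(coef_mat)
  y_y <- sum_grp(counts, young); r_y <- sum_grp(r_mat, young); c_y <- sum_grp(coef_mat, young)
  y_e <- sum_grp(counts, expanded); r_e <- sum_grp(r_mat, expanded); c_e <- sum_grp(coef_mat, expanded)

  log_f <- function(a, b) {
    list(ee = .bnb_logmarg(y_all, r_all, c_all, a, b),
         de = .bnb_logmarg(y_y, r_y, c_y, a, b) +
              .bnb_logmarg(y_e, r_e, c_e, a, b))
  }
  # Both patterns are proper densities over the same counts (the DE marginal
  # is the product of the two condition marginals), so they are directly
  # comparable in the mixture.

  obs_loglik <- function(f, w) {
    sum(log((1 - w) * exp(f$ee - pmax(f$ee, f$de)) +
            w * exp(f$de - pmax(f$ee, f$de))) + pmax(f$ee, f$de))
  }

  theta <- c(log_a = log(0.7), log_b = log(1000))
  w <- 0.25
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    f <- log_f(exp(theta[1]), exp(theta[2]))
    ll <- obs_loglik(f, w)
    trace <- c(trace, ll)
    if (it > 1L && abs(ll - trace[it - 1L]) <= tol * (abs(trace[it - 1L]) + 1)) {
      converged <- TRUE
      break
    }
    # E-step
    z <- 1 / (1 + exp(log1p(-w) - log(w) + f$ee - f$de))
    # M-step: weight update is exact; hyperparameters improved by a bounded
    # quasi-Newton step on the expected complete-data log-likelihood
    # (generalized EM — any improvement keeps the observed log-likelihood
    # non-decreasing).
    w <- mean(z)
    w <- min(max(w, 1e-6), 1 - 1e-6)
    Q <- function(th) {
      fq <- log_f(exp(th[1]), exp(th[2]))
      -sum((1 - z) * fq$ee + z * fq$de)
    }
    opt <- tryCatch(
      stats::optim(theta, Q, method = "L-BFGS-B",
                   lower = c(log(1e-3), log(1e-2)),
                   upper = c(log(1e3), log(1e9)),
                   control = list(maxit = 25L)),
      error = function(e) NULL
    )
    if (!is.null(opt) && opt$value <= Q(theta)) theta <- opt$par
  }
  if (!converged) warning("EB model EM did not converge in ", maxit, " iterations")

  f <- log_f(exp(theta[1]), exp(theta[2]))
  ppde <- 1 / (1 + exp(log1p(-w) - log(w) + f$ee - f$de))
  mean_y <- rowMeans(norm[, young, drop = FALSE])
  mean_e <- rowMeans(norm[, expanded, drop = FALSE])
  out <- data.frame(
    gene_id = rownames(counts),
    log2_fc = log2((mean_e + 0.5) / (mean_y + 0.5)),
    ppde = unname(ppde),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "mixture_weight") <- unname(w)
  attr(out, "hyper") <- c(alpha = unname(exp(theta[1])), beta = unname(exp(theta[2])))
  attr(out, "loglik_trace") <- trace
  attr(out, "converged") <- converged
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Call differentially expressed genes
#'
#' A gene is DE when its PPDE reaches `ppde_min` and its fold change (larger
#' condition mean over smaller, on normalized means with pseudocount 0.5)
#' reaches `fc_min`; the direction is the condition with the higher mean.
#'
#' @param results A `DEResult` data frame.
#' @param ppde_min Minimum posterior probability of DE (default 0.95).
#' @param fc_min Minimum fold change (default 2).
#' @return List with `results` (plus `call` column), `called`, and `summary`
#'   (`n_genes`, `n_de`, `pct_de`, `up_in_young`, `up_in_expanded`).
#' @export
call_de <- function(results, ppde_min = 0.95, fc_min = 2) {
  stopifnot(all(c("gene_id", "log2_fc", "ppde") %in% names(results)))
  passes <- results$ppde >= ppde_min & abs(results$log2_fc) >= log2(fc_min)
  results$call <- ifelse(!passes, "not_de",
                         ifelse(results$log2_fc > 0, "up_in_expanded", "up_in_young"))
  n <- nrow(results)
  n_de <- sum(passes)
  list(results = results,
       called = results[passes, , drop = FALSE],
       summary = list(n_genes = n, n_de = n_de, pct_de = .pct(n_de, n),
                      up_in_young = sum(results$call == "up_in_young"),
                      up_in_expanded = sum(results$call == "up_in_expanded")))
}

#' Overlap between EISA-positive and DE gene sets
#'
#' @param eisa_calls Character vector of EISA-positive gene ids, or the
#'   `called` data frame from [call_post_transcriptional()].
#' @param de_calls Character vector of DE gene ids, or the `called` data
#'   frame from [call_de()] (direction breakdown reported when available).
#' @return An overlap report list: set sizes, intersection size, and the
#'   fraction of EISA-positive genes that are DE (percent), with a
#'   by-direction breakdown when directions are supplied.
#' @export
overlap_eisa_de <- function(eisa_calls, de_calls) {
  eisa_ids <- if (is.data.frame(eisa_calls)) eisa_calls$gene_id else eisa_calls
  if (is.data.frame(de_calls)) {
    de_ids <- de_calls$gene_id
    dir <- de_calls$call[match(de_ids, de_calls$gene_id)]
  } else {
    de_ids <- de_calls
    dir <- NULL
  }
  eisa_ids <- unique(eisa_ids)
  de_ids <- unique(de_ids)
  inter <- intersect(eisa_ids, de_ids)
  rep <- list(n_eisa = length(eisa_ids), n_de = length(de_ids),
              n_overlap = length(inter),
              pct_eisa_also_de = .pct(length(inter), length(eisa_ids)))
  if (!is.null(dir)) {
    rep$overlap_up_in_young <- sum(dir[match(inter, de_ids)] == "up_in_young")
    rep$overlap_up_in_expanded <- sum(dir[match(inter, de_ids)] == "up_in_expanded")
  }
  rep
}

#' Cross-species overlap of call sets through an orthologue map
#'
#' Counts orthologue pairs whose members are called in both species.
#' One-to-many mappings are collapsed to unique A-side genes, so the overlap
#' is the number of distinct species-A genes with at least one called
#' orthologue in species B.
#'
#' @param calls_a,calls_b Character vectors of called gene ids in each
#'   species.
#' @param ortholog_map Two-column data frame (gene_a, gene_b) or path to a
#'   headerless two-column TSV. Duplicated rows are deduplicated with a
#'   warning.
#' @return Overlap report list: per-species call-set sizes, number of map
#'   pairs, shared pairs, and the collapsed count of shared A-side genes.
#' @export
cross_species_overlap <- function(calls_a, calls_b, ortholog_map) {
  if (is.character(ortholog_map) && length(ortholog_map) == 1L) {
    ortholog_map <- utils::read.table(ortholog_map, sep = "\t", header = FALSE,
                                      stringsAsFactors = FALSE,
                                      col.names = c("gene_a", "gene_b"))
  }
  stopifnot(ncol(ortholog_map) >= 2L)
  map <- data.frame(gene_a = as.character(ortholog_map[[1L]]),
                    gene_b = as.character(ortholog_map[[2L]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map)) {
    warning("duplicate orthologue rows deduplicated")
    map <- unique(map)
  }
  shared <- map$gene_a %in% calls_a & map$gene_b %in% calls_b
  list(n_called_a = length(unique(calls_a)),
       n_called_b = length(unique(calls_b)),
       n_pairs = nrow(map),
       n_shared_pairs = sum(shared),
       n_shared_genes_a = length(unique(map$gene_a[shared])))
}
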