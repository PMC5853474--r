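# Negative-binomial GLM machinery for the compartment-by-condition
# interaction test. Per-gene fits use IRLS (stats::glm.fit with the
# fixed-theta NB family) at a given dispersion phi (variance = mu + phi*mu^2);
# the dispersion itself is estimated across genes by maximizing the Cox-Reid
# adjusted profile likelihood, either as one common value or per gene with
# shrinkage toward the common curve.

# Log-likelihood of counts y at means mu for NB with dispersion phi.
nb_loglik <- function(y, mu, phi) {
  sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# Fit one NB GLM with log link at fixed dispersion. Returns coefficients,
# fitted means, log-likelihood and the Cox-Reid adjustment term.
nb_glm_fit <- function(y, X, offset, phi) {
  fam <- MASS::negative.binomial(theta = 1 / phi, link = "log")
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(x = X, y = y, family = fam, offset = offset,
                                    control = stats::glm.control(maxit = 100))),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
    return(list(ok = FALSE, loglik = NA_real_, coef = rep(NA_real_, ncol(X)),
                mu = NULL, cr_adj = NA_real_))
  }
  mu <- fit$fitted.values
  # Working weights for the CR adjustment: w_i = mu_i / (1 + phi mu_i).
  w <- mu / (1 + phi * mu)
  XtWX <- crossprod(X * sqrt(w))
  ld <- determinant(XtWX, logarithm = TRUE)
  cr <- if (ld$sign > 0) 0.5 * as.numeric(ld$modulus) else NA_real_
  list(ok = TRUE, loglik = nb_loglik(y, mu, phi), coef = fit$coefficients,
       mu = mu, cr_adj = cr)
}

# Cox-Reid adjusted profile log-likelihood of one gene at dispersion phi.
nb_apl <- function(y, X, offset, phi) {
  fit <- nb_glm_fit(y, X, offset, phi)
  if (!fit$ok || is.na(fit$cr_adj)) return(NA_real_)
  fit$loglik - fit$cr_adj
}

# Build the per-gene response/design for the interaction model:
# observations are (sample x compartment) counts; offsets are the log library
# totals of the matching compartment and sample.
.interaction_design <- function(table) {
  cond <- factor(table$condition, levels = c("young", "expanded"))
  compartment <- factor(rep(c("exon", "intron"), each = length(table$samples)),
                        levels = c("exon", "intron"))
  condition <- factor(rep(as.character(cond), 2L),
                      levels = c("young", "expanded"))
  X_full <- stats::model.matrix(~ compartment + condition + compartment:condition)
  X_red <- stats::model.matrix(~ compartment + condition)
  offset <- log(c(table$lib_exon, table$lib_intron))
  list(X_full = X_full, X_red = X_red, offset = offset)
}

.gene_counts <- function(table, i) {
  as.numeric(c(table$exon[i, ], table$intron[i, ]))
}

#' Estimate a common NB dispersion across genes
#'
#' Maximizes the summed Cox-Reid adjusted profile likelihood of the full
#' interaction model over a single dispersion shared by all genes. For large
#' tables a deterministic subsample of genes is used; the estimate is an
#' across-gene consensus, so a few hundred genes determine it accurately.
#'
#' @param table A filtered `CountTable`.
#' @param max_genes Maximum number of genes entering the profile (evenly
#'   spaced subsample when exceeded).
#' @param interval Search interval for the dispersion.
#' @return The common dispersion (scalar).
#' @export
estimate_common_dispersion <- function(table, max_genes = 200L,
                                       interval = c(1e-4, 4)) {
  des <- .interaction_design(table)
  n <- length(table$genes)
  idx <- if (n > max_genes) {
    unique(round(seq(1L, n, length.out = max_genes)))
  } else seq_len(n)
  ys <- lapply(idx, function(i) .gene_counts(table, i))
  obj <- function(log_phi) {
    phi <- exp(log_phi)
    s <- vapply(ys, function(y) {
      a <- nb_apl(y, des$X_full, des$offset, phi)
      if (is.na(a)) 0 else a
    }, 0)
    -sum(s)
  }
  opt <- stats::optimize(obj, interval = log(interval))
  exp(opt$minimum)
}

#' Estimate tagwise dispersions with shrinkage toward the common value
#'
#' Per-gene dispersions maximize the gene's own adjusted profile likelihood
#' plus `prior_weight` times the across-gene average profile (which peaks at
#' the common dispersion); genes with little information are thereby pulled
#' toward the consensus.
#'
#' @param table A filtered `CountTable`.
#' @param prior_weight Weight of the common profile, in gene-equivalents
#'   (default 10).
#' @param grid_size Number of log-dispersion grid points for the common
#'   profile curve.
#' @inheritParams estimate_common_dispersion
#' @return Numeric vector of per-gene dispersions (named by gene).
#' @export
estimate_tagwise_dispersion <- function(table, prior_weight = 10,
                                        max_genes = 200L, grid_size = 21L,
                                        interval = c(1e-4, 4)) {
  des <- .interaction_design(table)
  n <- length(table$genes)
  idx <- if (n > max_genes) {
    unique(round(seq(1L, n, length.out = max_genes)))
  } else seq_len(n)
  grid <- seq(log(interval[1]), log(interval[2]), length.out = grid_size)
  common_curve <- vapply(grid, function(lp) {
    phi <- exp(lp)
    mean(vapply(idx, function(i) {
      a <- nb_apl(.gene_counts(table, i), des$X_full, des$offset, phi)
      if (is.na(a)) 0 else a
    }, 0))
  }, 0)
  common_fun <- stats::splinefun(grid, common_curve, method = "natural")
  phis <- vapply(seq_len(n), function(i) {
    y <- .gene_counts(table, i)
    obj <- function(lp) {
      a <- nb_apl(y, des$X_full, des$offset, exp(lp))
      if (is.na(a)) a <- -1e8
      -(a + prior_weight * common_fun(lp))
    }
    exp(stats::optimize(obj, interval = range(grid))$minimum)
  }, 0)
  stats::setNames(phis, table$genes)
}

#' Likelihood-ratio test for differential post-transcriptional regulation
#'
#' Models each gene's exonic and intronic counts jointly as negative binomial
#' with a log link and compartment-specific library-size offsets, under the
#' factorial model `~ compartment + condition + compartment:condition`. The
#' interaction coefficient is the change of the exon/intron ratio between
#' conditions — the post-transcriptional signal — and is tested by a
#' likelihood-ratio test against the additive model, with the statistic
#' referred to a chi-squared distribution on 1 degree of freedom.
#'
#' @param table A filtered `CountTable` with at least 2 replicates per
#'   condition.
#' @param dispersion_mode `"common"` (one dispersion for all genes, default)
#'   or `"tagwise"` (per-gene with shrinkage toward the common curve).
#' @param dispersion Optional: fix the dispersion(s) instead of estimating
#'   (scalar or per-gene vector).
#' @param prior_weight Shrinkage weight for tagwise estimation.
#' @return A data frame with `gene_id`, `p_value`, `interaction` (the
#'   interaction coefficient, log2 scale), `deviance_full`, `deviance_reduced`
#'   (-2 log-likelihoods), `converged`. Non-converging genes get `p_value = 1`
#'   and `converged = FALSE`, never an error. The dispersion used is attached
#'   as attribute `"dispersion"`.
#' @export
fit_interaction_test <- function(table, dispersion_mode = c("common", "tagwise"),
                                 dispersion = NULL, prior_weight = 10) {
  dispersion_mode <- match.arg(dispersion_mode)
  stopifnot(inherits(table, "CountTable"))
  n_young <- sum(table$condition == "young")
  n_expanded <- sum(table$condition == "expanded")
  if (n_young < 2L || n_expanded < 2L) {
    stop("the interaction test needs >= 2 replicates in each condition")
  }
  n <- length(table$genes)
  if (is.null(dispersion)) {
    phi <- if (dispersion_mode == "common") {
      rep(estimate_common_dispersion(table), n)
    } else {
      estimate_tagwise_dispersion(table, prior_weight = prior_weight)
    }
  } else {
    if (any(dispersion <= 0)) stop("dispersion must be positive")
    phi <- rep_len(dispersion, n)
  }
  des <- .interaction_design(table)
  res <- vapply(seq_len(n), function(i) {
    y <- .gene_counts(table, i)
    full <- nb_glm_fit(y, des$X_full, des$offset, phi[i])
    red <- nb_glm_fit(y, des$X_red, des$offset, phi[i])
    if (!full$ok || !red$ok) {
      return(c(p = 1, beta = NA_real_, dev_full = NA_real_,
               dev_red = NA_real_, conv = 0))
    }
    lrt <- max(0, 2 * (full$loglik - red$loglik))
    c(p = stats::pchisq(lrt, df = 1L, lower.tail = FALSE),
      beta = full$coef[ncol(des$X_full)] / log(2),
      dev_full = -2 * full$loglik, dev_red = -2 * red$loglik, conv = 1)
  }, c(p = 0, beta = 0, dev_full = 0, dev_red = 0, conv = 0))
  out <- data.frame(
    gene_id = table$genes,
    p_value = res["p", ],
    interaction = res["beta", ],
    deviance_full = res["dev_full", ],
    deviance_reduced = res["dev_red", ],
    converged = res["conv", ] == 1,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "dispersion") <- phi
  out
}
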