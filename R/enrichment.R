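# Hypergeometric over-representation analysis of gene categories.

#' Over-representation analysis of gene categories
#'
#' For every category with at least `min_category_size` members in the
#' universe, tests whether the category is over- (or under-) represented in
#' the gene set with a hypergeometric tail probability; the smaller tail is
#' reported with its direction, and Benjamini-Hochberg adjustment is applied
#' across tested categories. The universe should be the set of genes that
#' could have been called (here: the EISA-tested genes), so that detection
#' bias does not masquerade as enrichment.
#'
#' @param gene_set Character vector of called genes (must be a subset of
#'   `universe`).
#' @param universe Character vector of all testable genes.
#' @param categories Data frame with columns `gene_id`, `category_id` and
#'   optionally `category_name`; memberships outside the universe are
#'   dropped.
#' @param min_category_size Minimum in-universe category size (default 5).
#' @param direction `"over"` (default) restricts output to over-represented
#'   categories, `"both"` reports both directions.
#' @return Data frame sorted by `adj_p` then `category_id`:
#'   `category_id`, `category_name`, `k` (hits in set), `n` (set size),
#'   `K` (category size in universe), `N` (universe size), `odds_ratio`,
#'   `p_value`, `adj_p`, `direction`.
#' @export
run_ora <- function(gene_set, universe, categories, min_category_size = 5L,
                    direction = c("over", "both")) {
  direction <- match.arg(direction)
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (length(gene_set) == 0L) stop("empty gene set")
  offenders <- setdiff(gene_set, universe)
  if (length(offenders)) {
    stop("gene set members outside the universe: ",
         paste(utils::head(offenders, 5L), collapse = ", "),
         if (length(offenders) > 5L) sprintf(" (and %d more)", length(offenders) - 5L) else "")
  }
  stopifnot(all(c("gene_id", "category_id") %in% names(categories)))
  categories <- categories[categories$gene_id %in% universe, , drop = FALSE]
  categories <- unique(categories[, intersect(c("gene_id", "category_id", "category_name"),
                                              names(categories)), drop = FALSE])
  if (nrow(categories) == 0L) {
    return(data.frame(category_id = character(0), category_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0), N = integer(0),
                      odds_ratio = numeric(0), p_value = numeric(0),
                      adj_p = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  N <- length(universe)
  n <- length(gene_set)
  by_cat <- split(categories$gene_id, categories$category_id)
  names_map <- if ("category_name" %in% names(categories)) {
    tapply(categories$category_name, categories$category_id, `[`, 1L)
  } else NULL
  rows <- lapply(names(by_cat), function(cid) {
    members <- unique(by_cat[[cid]])
    K <- length(members)
    if (K < min_category_size) return(NULL)
    k <- length(intersect(members, gene_set))
    p_over <- hyper_tail(k, N, K, n, upper = TRUE)
    p_under <- hyper_tail(k, N, K, n, upper = FALSE)
    dir <- if (p_over <= p_under) "over" else "under"
    a <- k; b <- n - k; cc <- K - k; d <- N - K - (n - k)
    or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
    data.frame(category_id = cid,
               category_name = if (is.null(names_map)) cid else unname(names_map[cid]),
               k = k, n = n, K = K, N = N,
               odds_ratio = or,
               p_value = min(p_over, p_under),
               direction = dir,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame(category_id = character(0), category_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0), N = integer(0),
                      odds_ratio = numeric(0), p_value = numeric(0),
                      adj_p = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  res$adj_p <- adjust_fdr(res$p_value)
  res <- res[order(res$adj_p, res$category_id), , drop = FALSE]
  res <- res[, c("category_id", "category_name", "k", "n", "K", "N",
                 "odds_ratio", "p_value", "adj_p", "direction")]
  if (direction == "over") res <- res[res$direction == "over", , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Hypergeometric tail probability
#'
#' Upper tail: probability of observing `k` or more category members in the
#' set; lower tail: `k` or fewer. Both tails include the observed value, so
#' each lies in (0, 1].
#'
#' @param k Observed hits in the set.
#' @param N Universe size.
#' @param K Category size in the universe.
#' @param n Gene-set size.
#' @param upper Upper (over-representation) tail if `TRUE`.
#' @return The tail probability.
#' @export
hyper_tail <- function(k, N, K, n, upper = TRUE) {
  stopifnot(k >= 0, K <= N, n <= N, k <= min(n, K))
  if (upper) {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  }
}
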