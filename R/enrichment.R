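#' Hypergeometric over-representation p-value
#'
#' Upper tail `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: from a universe
#' of `N` genes of which `K` carry the term, drawing the `n` DE genes, the
#' probability of seeing `k` or more term genes.
#'
#' @param N background universe size.
#' @param K genes annotated with the term.
#' @param n DE-set size.
#' @param k DE genes annotated with the term.
#' @return the upper-tail p-value, in (0, 1].
#' @export
hypergeom_p <- function(N, K, n, k) {
  stopifnot(length(N) == 1, N >= 0, K >= 0, n >= 0, k >= 0)
  if (K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric parameters")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment of a DE gene set
#'
#' Hypergeometric over-representation of each term's annotated genes in the
#' DE set against a background universe, with Bonferroni correction over the
#' tested terms (those with at least one DE gene). Category tallies of the
#' assigned terms are reported with 1-decimal half-up percentages.
#'
#' @param de_genes character vector of DE gene ids (must be within
#'   `background`).
#' @param background character vector, the gene universe.
#' @param term_map data.frame with columns `term_id`, `term_name`,
#'   `category`, `gene_id` (one row per term-gene link).
#' @param alpha significance threshold on the corrected value (default 0.05).
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @return list of class `enrichment_result` with `table` (per tested term:
#'   `term_id`, `term_name`, `category`, `N`, `K`, `n`, `k`, `p`,
#'   `corrected`, `significant`, ordered by p), `categories` (per-category
#'   term counts and percentage shares), `m` (terms tested) and `alpha`.
#' @export
enrich <- function(de_genes, background, term_map, alpha = 0.05,
                   correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  background <- unique(background)
  if (length(background) == 0) stop("empty background universe")
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% background))
    stop("DE genes outside the background universe")
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(de_genes)
  terms <- split(tm, tm$term_id)
  rows <- lapply(terms, function(t) {
    genes <- unique(t$gene_id)
    k <- sum(genes %in% de_genes)
    if (k == 0) return(NULL)
    K <- length(genes)
    data.frame(term_id = t$term_id[1], term_name = t$term_name[1],
               category = t$category[1], N = N, K = K, n = n, k = k,
               p = hypergeom_p(N, K, n, k))
  })
  tab <- do.call(rbind, rows) %||%
    data.frame(term_id = character(0), term_name = character(0),
               category = character(0), N = integer(0), K = integer(0),
               n = integer(0), k = integer(0), p = numeric(0))
  m <- nrow(tab)
  tab$corrected <- if (m > 0) stats::p.adjust(tab$p, method =
    if (correction == "bonferroni") "bonferroni" else "BH") else numeric(0)
  tab$significant <- tab$corrected <= alpha
  tab <- tab[order(tab$p, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  cats <- category_shares(tab$category)
  structure(list(table = tab, categories = cats, m = m, alpha = alpha),
            class = "enrichment_result")
}

#' Category shares of assigned terms
#'
#' Counts terms per category and their percentage of all assigned terms at
#' 1 decimal, half-up.
#'
#' @param categories character vector, one element per assigned term.
#' @return data.frame with `category`, `terms`, `percent`.
#' @export
category_shares <- function(categories) {
  if (length(categories) == 0)
    return(data.frame(category = character(0), terms = integer(0),
                      percent = numeric(0)))
  tab <- table(categories)
  data.frame(category = names(tab), terms = as.integer(tab),
             percent = round_half_up(100 * as.integer(tab) /
                                       length(categories), 1),
             row.names = NULL)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result:", x$m, "terms tested,",
      sum(x$table$significant), "significant at corrected <=", x$alpha, "\n")
  print(utils::head(x$table, 10))
  invisible(x)
}
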