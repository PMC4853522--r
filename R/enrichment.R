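#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `x` annotated genes in a query of
#' size `n` drawn from a universe of `M` genes of which `K` carry the
#' annotation: `P(X >= x)` for `X ~ Hypergeometric(M, K, n)`. Computed
#' from log-space terms (via [stats::phyper()]) so tiny tail probabilities
#' do not underflow.
#'
#' @param M Universe size.
#' @param K Annotated genes in the universe.
#' @param n Query size.
#' @param x Overlap (annotated genes in the query).
#' @return The p-value in (0, 1]; `x = 0` gives exactly 1.
#' @export
hypergeometric_pvalue <- function(M, K, n, x) {
  stopifnot(length(M) == 1L, length(K) == 1L, length(n) == 1L,
            length(x) == 1L)
  if (any(c(M, K, n, x) < 0) || K > M || n > M || x > min(K, n))
    stop("inconsistent hypergeometric counts (need K <= M, n <= M, ",
         "x <= min(K, n))")
  if (x == 0) return(1)
  stats::phyper(x - 1, K, M - K, n, lower.tail = FALSE)
}

#' Singular enrichment analysis of a gene list
#'
#' Tests every GO term for over-representation in the query against a
#' reference background with the exact one-sided hypergeometric test,
#' adjusting p-values by Benjamini-Hochberg (or Benjamini-Yekutieli)
#' within each namespace. Query genes outside the background are dropped
#' with a message; terms are tested when they have at least
#' `min_term_size` background genes and at least one query gene.
#'
#' @param query Character vector of gene ids (e.g. a significant list).
#' @param annotation A `go_annotation` (pre-propagated gene-term pairs).
#' @param background Reference gene universe; defaults to all genes in the
#'   annotation (stand-in for a whole-array gene-model reference).
#' @param alpha_fdr Significance threshold on the adjusted FDR
#'   (default 0.05).
#' @param min_term_size Minimum background term size tested (default 2).
#' @param adjust `"BH"` (default) or `"BY"`.
#' @return An `enrichment_result` data frame sorted by p, with columns
#'   `term`, `namespace`, `label`, `x`, `n`, `K`, `M`, `ratio`
#'   (`(x/n)/(K/M)`), `p`, `fdr`, `significant`.
#' @export
run_sea <- function(query, annotation, background = NULL,
                    alpha_fdr = 0.05, min_term_size = 2L,
                    adjust = c("BH", "BY")) {
  adjust <- match.arg(adjust)
  if (!inherits(annotation, "go_annotation") || nrow(annotation) == 0L)
    stop("empty or invalid annotation")
  if (is.null(background))
    background <- unique(annotation$gene)
  background <- unique(background)
  query <- unique(query)
  dropped <- setdiff(query, background)
  if (length(dropped))
    message("dropped ", length(dropped),
            " query gene(s) outside the background")
  query <- intersect(query, background)
  if (!length(query))
    stop("empty query after background intersection")
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  M <- length(background)
  n <- length(query)
  in_query <- ann$gene %in% query
  K_all <- table(ann$term)
  x_all <- table(ann$term[in_query])
  terms <- names(K_all)[K_all >= min_term_size & names(K_all) %in%
                          names(x_all)]
  if (!length(terms)) {
    message("no term shares genes with the query; nothing to test")
    out <- data.frame(term = character(0), namespace = character(0),
                      label = character(0), x = integer(0), n = integer(0),
                      K = integer(0), M = integer(0), ratio = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  meta <- ann[!duplicated(ann$term), c("term", "namespace", "label")]
  K <- as.integer(K_all[terms])
  x <- as.integer(x_all[terms])
  p <- vapply(seq_along(terms),
              function(i) hypergeometric_pvalue(M, K[i], n, x[i]),
              numeric(1L))
  ns <- meta$namespace[match(terms, meta$term)]
  fdr <- stats::ave(p, ns, FUN = function(pp)
    stats::p.adjust(pp, method = adjust))
  out <- data.frame(term = terms, namespace = ns,
                    label = meta$label[match(terms, meta$term)],
                    x = x, n = n, K = K, M = M,
                    ratio = (x / n) / (K / M), p = p, fdr = fdr,
                    significant = fdr <= alpha_fdr,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "n_dropped") <- length(dropped)
  out
}
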