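#' Hypergeometric gene-set over-representation
#'
#' For each term, the probability of seeing at least the observed number of
#' query genes in the term's gene list, given the annotated universe: the
#' upper tail of the hypergeometric distribution with universe size `N`, term
#' size `K` and query size `n`. Query genes outside the universe are dropped
#' with a warning before testing; terms with zero overlap are reported with
#' `p = 1`. Multiple testing is corrected across all tested terms.
#'
#' @param query a [GeneSet-class] or character vector of gene symbols.
#' @param annotation a [TermAnnotation-class].
#' @param correction `"bh"` (Benjamini-Hochberg, default), `"bonferroni"`, or
#'   `"none"`.
#' @return data.frame with columns `term`, `K` (term size), `n` (query size in
#'   universe), `k` (overlap), `p`, `p_adj`, sorted by `p`; attribute
#'   `correction` records the method.
#' @examples
#' ann <- TermAnnotation(list(t1 = letters[1:4], t2 = letters[3:8]),
#'                       universe = letters[1:10])
#' hypergeomEnrich(letters[1:3], ann)
#' @export
hypergeomEnrich <- function(query, annotation,
                            correction = c("bh", "bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(is(annotation, "TermAnnotation"))
  if (!length(annotation@universe)) stop("empty annotation universe")
  q <- if (is(query, "GeneSet")) geneSymbols(query) else unique(as.character(query))
  dropped <- setdiff(q, annotation@universe)
  if (length(dropped))
    warning(sprintf("%d query gene(s) outside the annotation universe dropped",
                    length(dropped)))
  q <- intersect(q, annotation@universe)
  N <- length(annotation@universe)
  n <- length(q)
  K <- lengths(annotation@terms)
  k <- vapply(annotation@terms, function(g) length(intersect(g, q)), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p[k == 0L] <- 1
  p_adj <- stats::p.adjust(p, method = switch(correction, bh = "BH",
                                              bonferroni = "bonferroni",
                                              none = "none"))
  out <- data.frame(term = names(annotation@terms), K = unname(K),
                    n = n, k = unname(k), p = unname(p), p_adj = unname(p_adj),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "correction") <- correction
  out
}
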