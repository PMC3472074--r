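# Overrepresentation analysis: one-sided hypergeometric test with fold
# enrichment and Bonferroni correction.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ hypergeometric(N, K, n): drawing n genes without
#' replacement from a background of N genes of which K carry the term.
#' Computed stably via the log-space tail of [stats::phyper()].
#'
#' @param k observed genes carrying the term in the query set.
#' @param n query-set size.
#' @param K background genes carrying the term.
#' @param N background size.
#' @return tail probability in (0, 1].
#' @export
hypergeom_p <- function(k, n, K, N) {
  if (any(k < 0) || any(k > n) || any(n > N) || any(k > K) || any(K > N)) {
    stop("require 0 <= k <= n <= N and k <= K <= N", call. = FALSE)
  }
  # log-space evaluation avoids underflow for extreme tails
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Fold enrichment of a term in a query set
#'
#' `(k/n) / (K/N)`: the term's prevalence in the query set relative to its
#' background prevalence.
#'
#' @inheritParams hypergeom_p
#' @return non-negative real; 0 when `k = 0`.
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (any(n <= 0) || any(K <= 0) || any(N <= 0)) {
    stop("n, K and N must be positive", call. = FALSE)
  }
  (k / n) / (K / N)
}

#' Term overrepresentation analysis of a gene set
#'
#' Tests every term annotated to at least one query gene with a one-sided
#' hypergeometric test; Bonferroni m = number of terms tested. Query genes
#' absent from the background are dropped (with a message). A term is
#' flagged overrepresented when `fold > min_fold` and
#' `p_bonferroni < max_p_bonf` (strict comparisons, matching thresholds
#' quoted as "fold enrichment > 5; corrected p < 0.1").
#'
#' @param genes query gene symbols.
#' @param annotation a `TermAnnotation` from [read_annotations()].
#' @param min_fold fold-enrichment threshold; default 5.
#' @param max_p_bonf Bonferroni-corrected p-value threshold; default 0.1.
#' @param background optional background universe; default all genes in the
#'   annotation.
#' @return `data.frame` of class `TermResultTable`, sorted by `p`, with
#'   columns `term`, `k`, `n`, `K`, `N`, `fold`, `p`, `p_bonferroni`,
#'   `overrepresented`.
#' @export
enrich_set <- function(genes, annotation, min_fold = 5, max_p_bonf = 0.1,
                       background = NULL) {
  if (is.null(background)) background <- annotation$background
  background <- unique(toupper(background))
  if (length(background) == 0) stop("empty background", call. = FALSE)
  genes <- unique(toupper(genes))
  dropped <- setdiff(genes, background)
  if (length(dropped) > 0) {
    message(length(dropped), " query gene(s) outside the background dropped")
    genes <- intersect(genes, background)
  }
  n <- length(genes)
  N <- length(background)
  term_genes <- lapply(annotation$term2gene,
                       function(gs) intersect(gs, background))
  k_all <- vapply(term_genes, function(gs) length(intersect(gs, genes)),
                  integer(1))
  tested <- names(k_all)[k_all >= 1]
  m <- length(tested)
  rows <- lapply(tested, function(t) {
    k <- k_all[[t]]
    K <- length(term_genes[[t]])
    p <- hypergeom_p(k, n, K, N)
    data.frame(term = t, k = k, n = n, K = K, N = N,
               fold = fold_enrichment(k, n, K, N),
               p = p, p_bonferroni = min(1, m * p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), fold = numeric(),
                      p = numeric(), p_bonferroni = numeric())
  }
  out$overrepresented <- out$fold > min_fold & out$p_bonferroni < max_p_bonf
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  attr(out, "m_tested") <- nrow(out)
  attr(out, "background_size") <- N
  class(out) <- c("TermResultTable", "data.frame")
  out
}

#' @export
write_term_results <- function(results, path) {
  write_tsv_file(as.data.frame(results), path)
}
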