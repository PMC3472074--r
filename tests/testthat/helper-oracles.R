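# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and stats::phyper / the Lance-Williams recursion).

# two-pass mean/SD threshold oracle
oracle_threshold <- function(ratios) {
  n <- length(ratios)
  m <- sum(ratios) / n
  s <- sqrt(sum((ratios - m)^2) / (n - 1))
  m + s
}

# Pearson correlation from the raw covariance formula
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# Exhaustive agglomerative clustering oracle: cluster-to-cluster distance
# is recomputed from the original leaf distance matrix at every step
# (mean over leaf pairs = UPGMA; min = single; max = complete). Same
# tie-break rule as the implementation: lowest smallest leaf index, then
# lowest largest leaf index. Returns sorted (height, member-set) records.
oracle_agglomerate <- function(d0, linkage = "average") {
  n <- nrow(d0)
  clusters <- as.list(seq_len(n))
  records <- list()
  agg <- switch(linkage, average = mean, single = min, complete = max)
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dij <- agg(d0[clusters[[i]], clusters[[j]]])
        key <- c(dij,
                 min(clusters[[i]][1], clusters[[j]][1]),
                 max(clusters[[i]][1], clusters[[j]][1]))
        if (is.null(best) ||
            key[1] < best$key[1] - 1e-12 ||
            (abs(key[1] - best$key[1]) <= 1e-12 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    records[[length(records) + 1]] <-
      list(height = best$key[1], members = merged)
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  records
}

# canonical comparable form of a dendrogram: per-merge height + members
dendro_records <- function(dend) {
  lapply(seq_along(dend$height), function(k) {
    list(height = dend$height[k],
         members = sort(match(dend$members[[k]], dend$labels)))
  })
}

# hypergeometric upper tail as an explicit sum of choose() ratios
oracle_hyper_tail <- function(k, n, K, N) {
  x <- k:min(n, K)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# full enumeration over all C(N, n) draws (small N only)
oracle_hyper_enum <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)   # items 1..K carry the term
}

# transitive closure of child->parent relations by repeated boolean joins
oracle_closure <- function(terms, relations) {
  m <- matrix(FALSE, length(terms), length(terms),
              dimnames = list(terms, terms))
  diag(m) <- TRUE
  m[cbind(relations$child, relations$parent)] <- TRUE
  repeat {
    m2 <- (m %*% m) > 0
    if (identical(m2, m)) break
    m <- m2
  }
  m
}

# naive O(L * p) peptide scan
oracle_scan <- function(peptide, sequence) {
  L <- nchar(sequence); p <- nchar(peptide)
  hits <- integer(0)
  if (p <= L) {
    for (s in 1:(L - p + 1)) {
      if (substr(sequence, s, s + p - 1) == peptide) hits <- c(hits, s)
    }
  }
  hits
}
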