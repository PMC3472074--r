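# Hierarchical clustering of protein enrichment profiles under a Pearson
# correlation distance, with rule-based selection of clusters of interest
# and flagging of control-dominated "background" clusters.

#' Pearson correlation distance between two profiles
#'
#' `d = 1 - r`, so d lies in [0, 2]: identical profiles are at 0, perfectly
#' anti-correlated ones at 2. If either vector is constant (zero variance),
#' the correlation is undefined; it is treated as 0, i.e. distance 1, so
#' all-zero background rows need not be dropped.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return distance in [0, 2].
#' @export
pearson_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("profiles differ in length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  if (length(a) < 2) stop("profiles must have length >= 2", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(1)
  1 - stats::cor(a, b)
}

# Full pairwise Pearson-distance matrix with the constant-row rule.
pearson_distance_matrix <- function(X) {
  const <- apply(X, 1, function(r) stats::sd(r) == 0)
  C <- suppressWarnings(stats::cor(t(X)))
  C[const, ] <- 0
  C[, const] <- 0
  d <- 1 - C
  diag(d) <- 0
  d
}

#' Enrichment profiles for clustering
#'
#' One row per protein; columns are the per-cell-line bait and control mean
#' counts, `log2(x + pseudocount)` transformed (spectral counts are
#' right-skewed), in a fixed cell-line-then-condition order.
#'
#' @param enrich an `EnrichmentTable` from [compute_enrichment()].
#' @param pseudocount added before the log transform; default 1.
#' @param log2_transform logical; set `FALSE` for raw means.
#' @return numeric matrix, rownames = accessions (lexicographically sorted).
#' @export
profile_matrix <- function(enrich, pseudocount = 1, log2_transform = TRUE) {
  lines <- intersect(CELL_LINES, unique(enrich$cell_line))
  accs <- sort(unique(enrich$accession))
  cols <- as.vector(outer(c("bait_mean", "control_mean"), lines,
                          function(v, l) paste(l, sub("_mean", "", v),
                                               sep = ".")))
  X <- matrix(NA_real_, length(accs), length(cols),
              dimnames = list(accs, cols))
  for (cl in lines) {
    sub <- enrich[enrich$cell_line == cl, ]
    i <- match(sub$accession, accs)
    X[i, paste0(cl, ".bait")] <- sub$bait_mean
    X[i, paste0(cl, ".control")] <- sub$control_mean
  }
  if (any(is.na(X))) stop("enrichment table is not rectangular", call. = FALSE)
  if (log2_transform) X <- log2(X + pseudocount)
  X
}

#' Agglomerative hierarchical clustering of profiles
#'
#' Average-linkage (UPGMA) agglomeration under [pearson_distance()],
#' implemented with the Lance-Williams update. Rows are sorted
#' lexicographically by name before clustering, and ties in the minimal
#' merge distance are broken toward the pair containing the lowest original
#' leaf index, then the lowest second index — so the result is deterministic
#' and invariant to input row order.
#'
#' @param X numeric matrix of profiles (rows = proteins, named), or a
#'   precomputed symmetric distance matrix when `is_distance = TRUE`.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @param is_distance interpret `X` as a distance matrix.
#' @return list of class `apms_dendro` with hclust-compatible `merge`,
#'   `height`, `labels`, `order`, plus `members` (leaf labels per internal
#'   node) and `node_correlation` (`1 - height`).
#' @export
apms_hclust <- function(X, linkage = c("average", "single", "complete"),
                        is_distance = FALSE) {
  linkage <- match.arg(linkage)
  if (is.null(rownames(X))) {
    rownames(X) <- sprintf("P%04d", seq_len(nrow(X)))
  }
  X <- X[order(rownames(X)), , drop = FALSE]
  if (is_distance) X <- X[, order(colnames(X)), drop = FALSE]
  n <- nrow(X)
  if (n < 2) stop("need at least two profiles", call. = FALSE)
  d <- if (is_distance) as.matrix(X) else pearson_distance_matrix(X)
  diag(d) <- Inf

  labels <- rownames(X)
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  min_leaf <- seq_len(n)        # smallest original leaf index per slot
  slot_id <- -seq_len(n)        # hclust convention: leaves negative
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- vector("list", n - 1)
  leafsets <- as.list(labels)

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    dm <- d[idx, idx, drop = FALSE]
    m <- min(dm)
    cand <- which(dm == m, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on the smallest (then largest) original
    # leaf index of the two clusters involved
    key1 <- pmin(min_leaf[idx[cand[, 1]]], min_leaf[idx[cand[, 2]]])
    key2 <- pmax(min_leaf[idx[cand[, 1]]], min_leaf[idx[cand[, 2]]])
    pick <- order(key1, key2)[1]
    i <- idx[cand[pick, 1]]
    j <- idx[cand[pick, 2]]

    a <- slot_id[i]; b <- slot_id[j]
    # hclust row convention: singletons (negative) before merges, and
    # within a kind, increasing absolute index
    pair <- c(a, b)[order(c(a, b) > 0, abs(c(a, b)))]
    merge[step, ] <- pair
    height[step] <- m
    members[[step]] <- sort(c(leafsets[[i]], leafsets[[j]]))

    others <- setdiff(idx, c(i, j))
    if (length(others) > 0) {
      new_d <- switch(linkage,
        average = (size[i] * d[i, others] + size[j] * d[j, others]) /
                  (size[i] + size[j]),
        single = pmin(d[i, others], d[j, others]),
        complete = pmax(d[i, others], d[j, others]))
      d[i, others] <- new_d
      d[others, i] <- new_d
    }
    leafsets[[i]] <- c(leafsets[[i]], leafsets[[j]])
    size[i] <- size[i] + size[j]
    min_leaf[i] <- min(min_leaf[i], min_leaf[j])
    slot_id[i] <- step
    active[j] <- FALSE
    d[j, ] <- Inf
    d[, j] <- Inf
  }

  if (linkage %in% c("average", "complete") &&
      any(diff(height) < -1e-8)) {
    stop("internal error: non-monotone merge heights under ", linkage,
         " linkage", call. = FALSE)
  }

  dend <- structure(list(merge = merge, height = height, labels = labels,
                         order = dendro_leaf_order(merge),
                         members = members,
                         node_correlation = 1 - height,
                         method = linkage,
                         dist.method = "pearson"),
                    class = "apms_dendro")
  dend
}

dendro_leaf_order <- function(merge) {
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  expand(nrow(merge))
}

#' @export
as.hclust.apms_dendro <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 dist.method = x$dist.method,
                 call = match.call()),
            class = "hclust")
}

#' @export
print.apms_dendro <- function(x, ...) {
  cat("apms_dendro:", length(x$labels), "leaves,", x$method,
      "linkage, Pearson distance\n")
  cat("root height", round(x$height[length(x$height)], 4),
      "(correlation", round(1 - x$height[length(x$height)], 4), ")\n")
  invisible(x)
}

#' Write a dendrogram as Newick with node heights as branch lengths
#' @param dend an [apms_hclust()] result.
#' @param path output file.
#' @export
write_newick <- function(dend, path) {
  phy <- ape::as.phylo(stats::as.hclust(dend))
  ape::write.tree(phy, file = path)
  invisible(path)
}

# parent index of each internal node (0 for the root)
dendro_parents <- function(merge) {
  n_nodes <- nrow(merge)
  parent <- integer(n_nodes)
  for (k in seq_len(n_nodes)) {
    for (child in merge[k, ]) if (child > 0) parent[child] <- k
  }
  parent
}

# per-protein summary statistics used by the cluster-selection rules
cluster_protein_stats <- function(enrich) {
  sp <- split(enrich, enrich$accession)
  data.frame(
    accession = names(sp),
    max_control = vapply(sp, function(z) max(z$control_mean), 0),
    med_control = vapply(sp, function(z) stats::median(z$control_mean), 0),
    max_ratio = vapply(sp, function(z) max(z$ratio), 0),
    stringsAsFactors = FALSE)
}

#' Select clusters of interest from a dendrogram
#'
#' Returns the maximal dendrogram nodes (no selected node is an ancestor of
#' another) whose node correlation (`1 - merge height`) is at least
#' `min_corr` and whose members all show absence or low detection in the
#' control samples: the maximum over members of the per-protein control mean
#' (itself maximized over cell lines) must not exceed `control_cap`.
#' Both comparisons are inclusive.
#'
#' @param dend an [apms_hclust()] result.
#' @param enrich the `EnrichmentTable` the profiles came from.
#' @param min_corr minimum Pearson correlation at the node; default 0.6.
#' @param control_cap maximum tolerated mean control count; default 1
#'   spectrum per replicate.
#' @return list of class `ClusterSelection`; one element per cluster with
#'   `node`, `members`, `node_correlation`, `max_control_mean`.
#' @export
select_clusters <- function(dend, enrich, min_corr = 0.6, control_cap = 1) {
  stats_tab <- cluster_protein_stats(enrich)
  missing <- setdiff(dend$labels, stats_tab$accession)
  if (length(missing) > 0) {
    stop("dendrogram leaves absent from enrichment table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ctrl <- stats::setNames(stats_tab$max_control, stats_tab$accession)
  eligible <- vapply(seq_along(dend$members), function(k) {
    dend$node_correlation[k] >= min_corr &&
      max(ctrl[dend$members[[k]]]) <= control_cap
  }, logical(1))
  picked <- maximal_nodes(dend$merge, eligible)
  out <- lapply(picked, function(k) {
    list(node = k,
         members = dend$members[[k]],
         node_correlation = dend$node_correlation[k],
         max_control_mean = max(ctrl[dend$members[[k]]]))
  })
  structure(out, class = "ClusterSelection")
}

#' Flag putative background clusters
#'
#' Background clusters group reagent and nonspecific proteins: detection is
#' dominated by the control samples with no relative enrichment. A node is
#' flagged when the median (over members) of the per-protein median control
#' mean exceeds `control_cap` and the median (over members) of the
#' per-protein maximum enrichment ratio is below `ratio_threshold` — the
#' maximum over cell lines, so a protein enriched in even one line never
#' counts as unenriched. Every qualifying node is returned (ancestors of a
#' flagged node can qualify too when control-detected proteins dominate the
#' tree); consumers typically inspect the tightest nodes first.
#'
#' @param dend an [apms_hclust()] result.
#' @param enrich the matching `EnrichmentTable`.
#' @param control_cap control-detection floor; default 1.
#' @param ratio_threshold specificity threshold (e.g. from
#'   [specificity_threshold()]).
#' @return integer vector of flagged internal-node indices (possibly empty),
#'   with the member sets as a `members` attribute.
#' @export
flag_background_clusters <- function(dend, enrich, ratio_threshold,
                                     control_cap = 1) {
  if (inherits(ratio_threshold, "ThresholdReport")) {
    ratio_threshold <- ratio_threshold$threshold
  }
  stats_tab <- cluster_protein_stats(enrich)
  med_ctrl <- stats::setNames(stats_tab$med_control, stats_tab$accession)
  max_ratio <- stats::setNames(stats_tab$max_ratio, stats_tab$accession)
  flagged <- vapply(seq_along(dend$members), function(k) {
    mem <- dend$members[[k]]
    stats::median(med_ctrl[mem]) > control_cap &&
      stats::median(max_ratio[mem]) < ratio_threshold
  }, logical(1))
  picked <- which(flagged)
  structure(picked, members = dend$members[picked])
}

# indices of eligible nodes having no eligible ancestor
maximal_nodes <- function(merge, eligible) {
  parent <- dendro_parents(merge)
  keep <- integer(0)
  for (k in which(eligible)) {
    p <- parent[k]
    blocked <- FALSE
    while (p != 0) {
      if (eligible[p]) { blocked <- TRUE; break }
      p <- parent[p]
    }
    if (!blocked) keep <- c(keep, k)
  }
  keep
}

#' @export
write_cluster_table <- function(selection, path) {
  rows <- do.call(rbind, lapply(seq_along(selection), function(i) {
    cl <- selection[[i]]
    data.frame(cluster_id = i, node = cl$node, protein = cl$members,
               node_correlation = cl$node_correlation,
               max_control_mean = cl$max_control_mean,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(cluster_id = integer(), node = integer(),
                       protein = character(), node_correlation = numeric(),
                       max_control_mean = numeric())
  }
  write_tsv_file(rows, path)
}
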