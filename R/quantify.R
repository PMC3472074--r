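# Spectral-count quantification: replicate aggregation, bait/control
# enrichment ratios and the mean + 1 SD specificity threshold.

#' Mean spectral count per protein for one cell line and condition
#'
#' Replicates are averaged, not summed, so that cell lines run with
#' different replicate numbers remain comparable.
#'
#' @param x a [count_matrix()].
#' @param cell_line,condition which samples to aggregate.
#' @return named numeric vector, protein accession -> mean count.
#' @export
aggregate_replicates <- function(x, cell_line, condition) {
  stopifnot(inherits(x, "CountMatrix"))
  sel <- x$design$cell_line == cell_line & x$design$condition == condition
  if (!any(sel)) {
    stop("no samples for cell_line '", cell_line, "', condition '",
         condition, "'", call. = FALSE)
  }
  rowMeans(x$counts[, x$design$sample_id[sel], drop = FALSE])
}

#' Bait-over-control enrichment ratio
#'
#' `ratio = (bait_mean + pseudocount) / (control_mean + pseudocount)`.
#' The pseudocount is applied symmetrically; with `pseudocount = 0` a zero
#' control mean is an error rather than an infinite ratio.
#'
#' @param bait_mean,control_mean non-negative mean counts (vectorized).
#' @param pseudocount non-negative stabilizer, default 1.
#' @return numeric ratio(s).
#' @export
enrichment_ratio <- function(bait_mean, control_mean, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (any(bait_mean < 0) || any(control_mean < 0)) {
    stop("mean counts must be >= 0", call. = FALSE)
  }
  if (pseudocount == 0 && any(control_mean == 0)) {
    stop("control mean of 0 with pseudocount 0: ratio undefined; ",
         "use a positive pseudocount", call. = FALSE)
  }
  (bait_mean + pseudocount) / (control_mean + pseudocount)
}

#' Per-protein, per-cell-line enrichment table
#'
#' For every protein and every cell line present in the design, computes the
#' mean bait count, mean control count and their enrichment ratio. The
#' `specific` column is `NA` until [call_specific()] is applied.
#'
#' @param x a [count_matrix()].
#' @param pseudocount passed to [enrichment_ratio()].
#' @return `data.frame` of class `EnrichmentTable` with columns `accession`,
#'   `gene_symbol`, `cell_line`, `bait_mean`, `control_mean`, `ratio`,
#'   `specific`.
#' @export
compute_enrichment <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "CountMatrix"))
  lines <- intersect(CELL_LINES, unique(x$design$cell_line))
  rows <- lapply(lines, function(cl) {
    bait <- aggregate_replicates(x, cl, "BAIT")
    ctrl <- aggregate_replicates(x, cl, "CONTROL")
    data.frame(accession = x$proteins$accession,
               gene_symbol = x$proteins$gene_symbol,
               cell_line = cl,
               bait_mean = unname(bait),
               control_mean = unname(ctrl),
               ratio = unname(enrichment_ratio(bait, ctrl, pseudocount)),
               specific = NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Specific-enrichment threshold: mean + 1 sample SD of the ratios
#'
#' The cut-off for calling a protein specifically enriched is one sample
#' standard deviation (n - 1 denominator) above the mean enrichment ratio,
#' computed over the pooled ratios of all cell lines.
#'
#' @param ratios numeric vector of at least two finite enrichment ratios.
#' @return list of class `ThresholdReport` with `mean_ratio`, `sd_ratio`,
#'   `threshold` and `n_ratios`.
#' @export
specificity_threshold <- function(ratios) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 2) {
    stop("need at least two finite ratios", call. = FALSE)
  }
  m <- mean(ratios)
  s <- stats::sd(ratios)
  structure(list(mean_ratio = m, sd_ratio = s, threshold = m + s,
                 n_ratios = length(ratios)),
            class = "ThresholdReport")
}

#' @export
print.ThresholdReport <- function(x, ...) {
  cat(sprintf(
    "ThresholdReport: mean %.4g + sd %.4g = threshold %.4g (n = %d)\n",
    x$mean_ratio, x$sd_ratio, x$threshold, x$n_ratios))
  invisible(x)
}

#' Call specific enrichment at a threshold
#'
#' The comparison is inclusive: a ratio exactly at the threshold counts as
#' specific ("enriched at least threshold-fold"). Idempotent.
#'
#' @param table an `EnrichmentTable` from [compute_enrichment()].
#' @param threshold finite fold-change cut-off, or a `ThresholdReport`.
#' @return the table with its `specific` column filled in.
#' @export
call_specific <- function(table, threshold) {
  if (inherits(threshold, "ThresholdReport")) threshold <- threshold$threshold
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  table$specific <- table$ratio >= threshold
  attr(table, "threshold") <- threshold
  table
}

#' Overlap of two enriched-protein sets
#'
#' Used to compare an enriched set against a previously published dataset:
#' reports the intersection size and the fraction of the reference set B
#' recovered in A.
#'
#' @param set_a,set_b character vectors of gene symbols.
#' @return list with `n_intersection` and `fraction_of_b`.
#' @export
dataset_overlap <- function(set_a, set_b) {
  set_a <- unique(toupper(set_a))
  set_b <- unique(toupper(set_b))
  if (length(set_b) == 0) stop("reference set B is empty", call. = FALSE)
  n <- length(intersect(set_a, set_b))
  list(n_intersection = n, fraction_of_b = n / length(set_b))
}

#' Proteins called specific in a given cell line
#' @param table an `EnrichmentTable` after [call_specific()].
#' @param cell_line cell line name, or NULL for any line.
#' @return character vector of accessions.
#' @export
specific_proteins <- function(table, cell_line = NULL) {
  if (all(is.na(table$specific))) {
    stop("run call_specific() first", call. = FALSE)
  }
  keep <- table$specific %in% TRUE
  if (!is.null(cell_line)) keep <- keep & table$cell_line == cell_line
  unique(table$accession[keep])
}

#' @export
write_enrichment_table <- function(table, path) {
  write_tsv_file(as.data.frame(table), path)
}

#' @export
write_threshold_report <- function(report, path) {
  write_tsv_file(data.frame(mean_ratio = report$mean_ratio,
                            sd_ratio = report$sd_ratio,
                            threshold = report$threshold,
                            n_ratios = report$n_ratios), path)
}
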