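#' Spectral-count matrix with sample design
#'
#' A `CountMatrix` couples a proteins-by-samples matrix of spectral counts
#' with the experiment's [sample_design()] and per-protein metadata
#' (gene symbol, identification probability, number of unique peptides).
#' Counts are non-negative integers; relative protein abundance in the
#' downstream analysis is determined by these counts.
#'
#' @param counts numeric matrix, rows = proteins (rownames are accessions),
#'   columns named by `design$sample_id`.
#' @param design a [sample_design()].
#' @param proteins optional `data.frame` with columns `accession` and any of
#'   `gene_symbol`, `probability`, `n_unique_peptides`.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, design, proteins = NULL) {
  design <- validate_sample_design(as.data.frame(design))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("counts must carry protein accessions as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicate accession(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(design$sample_id, colnames(counts))
  if (length(missing) > 0) {
    stop("counts lack column(s) for design sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- counts[, design$sample_id, drop = FALSE]
  if (any(is.na(counts))) stop("counts contain NA", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop("negative or non-integer count at protein '",
         rownames(counts)[bad[1]], "', sample '", colnames(counts)[bad[2]],
         "'", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (is.null(proteins)) {
    proteins <- data.frame(accession = rownames(counts),
                           gene_symbol = rownames(counts),
                           stringsAsFactors = FALSE)
  }
  if (!"accession" %in% names(proteins)) {
    stop("proteins table needs an 'accession' column", call. = FALSE)
  }
  proteins <- proteins[match(rownames(counts), proteins$accession), ,
                       drop = FALSE]
  rownames(proteins) <- NULL
  if (any(is.na(proteins$accession))) {
    stop("proteins table does not cover all count rows", call. = FALSE)
  }
  if (is.null(proteins$gene_symbol)) proteins$gene_symbol <- proteins$accession
  proteins$gene_symbol <- toupper(proteins$gene_symbol)
  if (!is.null(proteins$probability)) {
    p <- proteins$probability
    if (any(!is.na(p) & (p < 0 | p > 1))) {
      stop("probability must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(proteins$n_unique_peptides)) {
    np <- proteins$n_unique_peptides
    if (any(!is.na(np) & (np < 0 | np != round(np)))) {
      stop("n_unique_peptides must be a non-negative integer", call. = FALSE)
    }
  }
  structure(list(counts = counts, design = design, proteins = proteins),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "proteins x", ncol(x$counts),
      "samples\n")
  tab <- table(x$design$cell_line, x$design$condition)
  print(tab)
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Read a spectral-count table
#'
#' Expects a TSV with one protein per row: an `accession` column, optional
#' `gene_symbol`, `probability` and `n_unique_peptides` columns, and one
#' count column per sample in `design`, matched by `sample_id`.
#'
#' @param path TSV path.
#' @param design a [sample_design()].
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path, design) {
  design <- validate_sample_design(as.data.frame(design))
  tab <- read_tsv_file(path)
  if (!"accession" %in% names(tab)) {
    stop("count table lacks an 'accession' column", call. = FALSE)
  }
  missing <- setdiff(design$sample_id, names(tab))
  if (length(missing) > 0) {
    stop("count table is missing sample column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$accession)) {
    dup <- unique(tab$accession[duplicated(tab$accession)])
    stop("duplicate accession(s) in count table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  counts <- as.matrix(tab[, design$sample_id, drop = FALSE])
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    bad_row <- which(apply(counts, 1, function(r) {
      any(is.na(r)) || any(r < 0) || any(r != round(r))
    }))[1]
    stop("negative, missing or non-integer count in row ", bad_row,
         " (accession '", tab$accession[bad_row], "')", call. = FALSE)
  }
  rownames(counts) <- tab$accession
  meta_cols <- intersect(c("accession", "gene_symbol", "probability",
                           "n_unique_peptides"), names(tab))
  count_matrix(counts, design, tab[, meta_cols, drop = FALSE])
}

#' Write a spectral-count table
#'
#' Inverse of [read_count_table()]: counts round-trip bit-exactly.
#'
#' @param x a [count_matrix()].
#' @param path output TSV path.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "CountMatrix"))
  out <- cbind(x$proteins,
               as.data.frame(x$counts, check.names = FALSE))
  write_tsv_file(out, path)
}
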