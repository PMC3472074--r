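# Shared TSV conventions: tab-separated, UTF-8, '#' comment lines ignored.

CELL_LINES <- c("A4", "X4C0", "A4P_A5L")
CONDITIONS <- c("BAIT", "CONTROL")

read_tsv_file <- function(path, ...) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8", ...)
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct and validate a sample design
#'
#' A sample design lists every MS run of the experiment: which cell line it
#' came from, whether the bait was the integrin ligand (`BAIT`) or the
#' non-binding control (`CONTROL`), and its replicate number.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param cell_line one of `"A4"`, `"X4C0"`, `"A4P_A5L"` per sample.
#' @param condition one of `"BAIT"`, `"CONTROL"` per sample.
#' @param replicate positive integer replicate index per sample.
#' @return A `data.frame` of class `SampleDesign`.
#' @export
sample_design <- function(sample_id, cell_line, condition, replicate) {
  design <- data.frame(sample_id = as.character(sample_id),
                       cell_line = as.character(cell_line),
                       condition = as.character(condition),
                       replicate = as.integer(replicate),
                       stringsAsFactors = FALSE)
  validate_sample_design(design)
}

validate_sample_design <- function(design) {
  required <- c("sample_id", "cell_line", "condition", "replicate")
  missing <- setdiff(required, names(design))
  if (length(missing) > 0) {
    stop("sample design lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    dup <- unique(design$sample_id[duplicated(design$sample_id)])
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_cl <- setdiff(unique(design$cell_line), CELL_LINES)
  if (length(bad_cl) > 0) {
    stop("unknown cell_line(s): ", paste(bad_cl, collapse = ", "),
         " (expected ", paste(CELL_LINES, collapse = "/"), ")", call. = FALSE)
  }
  bad_cond <- setdiff(unique(design$condition), CONDITIONS)
  if (length(bad_cond) > 0) {
    stop("unknown condition(s): ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(design$replicate)) || any(design$replicate < 1)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  if (!any(design$condition == "BAIT") || !any(design$condition == "CONTROL")) {
    stop("design needs at least one BAIT and one CONTROL sample", call. = FALSE)
  }
  class(design) <- c("SampleDesign", "data.frame")
  design
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample_id`, `cell_line`, `condition`,
#'   `replicate`.
#' @return A validated [sample_design()] data frame.
#' @export
read_sample_design <- function(path) {
  validate_sample_design(read_tsv_file(path))
}

#' @export
write_sample_design <- function(design, path) {
  write_tsv_file(as.data.frame(design), path)
}
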