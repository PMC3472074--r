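# Peptide-to-region mapping: the construct-specificity validation. Peptides
# identified from a truncated or chimeric receptor must not map into regions
# absent from that construct.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Locate peptides on a protein sequence
#'
#' Exact string matching over the 20-letter amino-acid alphabet (I and L are
#' distinct); every occurrence is reported, including overlapping ones.
#'
#' @param peptides character vector of peptide sequences.
#' @param sequence protein sequence (single string).
#' @param accession accession recorded on the hits.
#' @return `data.frame` of class `PeptideHits` with columns `peptide`,
#'   `accession`, `start`, `end` (1-based inclusive); zero rows when nothing
#'   matches.
#' @export
locate_peptides <- function(peptides, sequence, accession = NA_character_) {
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                peptides)
  if (any(bad)) {
    stop("peptide(s) with non-amino-acid characters: ",
         paste(utils::head(peptides[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  subject <- Biostrings::AAString(sequence)
  rows <- lapply(unique(peptides), function(pep) {
    m <- Biostrings::matchPattern(Biostrings::AAString(pep), subject)
    if (length(m) == 0) return(NULL)
    data.frame(peptide = pep, accession = accession,
               start = Biostrings::start(m), end = Biostrings::end(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peptide = character(), accession = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("PeptideHits", "data.frame")
  out
}

#' Region coverage of peptide hits
#'
#' A peptide counts toward a region if its match interval overlaps the
#' region by at least one residue (so a peptide spanning a boundary counts
#' toward both adjacent regions). Hits overlapping any region named in
#' `forbidden` are reported as violations.
#'
#' @param hits a `PeptideHits` table from [locate_peptides()].
#' @param region_map a `RegionMap` (one accession) from [read_region_map()].
#' @param forbidden character vector of region names declared absent from
#'   the construct.
#' @return list of class `RegionCoverageReport`: `per_region` data frame
#'   (`region_name`, `n_peptides`, `n_residues_covered`, `length`) and
#'   `violations` (subset of hits with the offending region).
#' @export
region_coverage <- function(hits, region_map, forbidden = character(0)) {
  validate_region_map(region_map)
  unknown <- setdiff(forbidden, region_map$region_name)
  if (length(unknown) > 0) {
    stop("forbidden region(s) not in region map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  per_region <- do.call(rbind, lapply(seq_len(nrow(region_map)), function(i) {
    s <- region_map$start[i]; e <- region_map$end[i]
    ov <- hits$start <= e & hits$end >= s
    covered <- integer(0)
    if (any(ov)) {
      covered <- unique(unlist(Map(seq, pmax(hits$start[ov], s),
                                   pmin(hits$end[ov], e))))
    }
    data.frame(region_name = region_map$region_name[i],
               n_peptides = sum(ov),
               n_residues_covered = length(covered),
               length = e - s + 1L,
               stringsAsFactors = FALSE)
  }))
  viol <- do.call(rbind, lapply(forbidden, function(rn) {
    i <- match(rn, region_map$region_name)
    ov <- hits$start <= region_map$end[i] & hits$end >= region_map$start[i]
    if (!any(ov)) return(NULL)
    cbind(hits[ov, , drop = FALSE], region = rn)
  }))
  if (is.null(viol)) {
    viol <- data.frame(peptide = character(), accession = character(),
                       start = integer(), end = integer(),
                       region = character(), stringsAsFactors = FALSE)
  }
  structure(list(per_region = per_region, violations = viol),
            class = "RegionCoverageReport")
}

#' Validate construct-specific peptide coverage
#'
#' For each expectation row (cell line x accession), peptides from that cell
#' line's samples are located on the construct sequence; the construct
#' passes if no peptide overlaps a forbidden region and every required
#' region harbors at least one peptide.
#'
#' @param peptides named list: cell line -> data.frame with columns
#'   `peptide`, `accession`.
#' @param sequences named character vector of construct sequences
#'   (accession -> sequence).
#' @param region_maps named list of `RegionMap`s by accession.
#' @param expectations data.frame with columns `cell_line`, `accession`,
#'   `forbidden_regions`, `required_regions` (semicolon-separated, may be
#'   empty).
#' @return `data.frame` of class `ConstructValidation` with one row per
#'   expectation: `cell_line`, `accession`, `n_peptides`, `n_violations`,
#'   `missing_required`, `pass`; plus attribute `reports` (the underlying
#'   [region_coverage()] reports) and `pass` (overall).
#' @export
validate_construct <- function(peptides, sequences, region_maps,
                               expectations) {
  split_field <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) character(0)
    else trimws(strsplit(s, ";")[[1]])
  }
  reports <- list()
  rows <- lapply(seq_len(nrow(expectations)), function(i) {
    exp_row <- expectations[i, ]
    acc <- exp_row$accession
    if (!acc %in% names(sequences)) {
      stop("expectation references unknown accession '", acc, "'",
           call. = FALSE)
    }
    rm <- region_maps[[acc]]
    if (is.null(rm)) {
      stop("no region map for accession '", acc, "'", call. = FALSE)
    }
    forb <- split_field(exp_row$forbidden_regions)
    reqd <- split_field(exp_row$required_regions)
    unknown <- setdiff(c(forb, reqd), rm$region_name)
    if (length(unknown) > 0) {
      stop("expectation references unknown region(s): ",
           paste(unknown, collapse = ", "), " for '", acc, "'",
           call. = FALSE)
    }
    pep_tab <- peptides[[exp_row$cell_line]]
    peps <- if (is.null(pep_tab)) character(0) else {
      pep_tab$peptide[pep_tab$accession == acc]
    }
    hits <- locate_peptides(unique(peps), sequences[[acc]], acc)
    rep_i <- region_coverage(hits, rm, forbidden = forb)
    reports[[paste(exp_row$cell_line, acc, sep = ":")]] <<- rep_i
    cov <- rep_i$per_region
    missing_req <- reqd[!reqd %in%
                          cov$region_name[cov$n_peptides > 0]]
    data.frame(cell_line = exp_row$cell_line, accession = acc,
               n_peptides = nrow(hits),
               n_violations = nrow(rep_i$violations),
               missing_required = paste(missing_req, collapse = ";"),
               pass = nrow(rep_i$violations) == 0 &&
                 length(missing_req) == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell_line = character(), accession = character(),
                      n_peptides = integer(), n_violations = integer(),
                      missing_required = character(), pass = logical())
  }
  attr(out, "reports") <- reports
  attr(out, "pass") <- all(out$pass)
  class(out) <- c("ConstructValidation", "data.frame")
  out
}
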