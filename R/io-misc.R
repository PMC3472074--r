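# Readers for region maps, edge lists, gene sets, term annotations and
# accession-to-symbol mappings. Coordinates are 1-based inclusive residue
# positions throughout.

#' Read a protein region map
#'
#' Regions are named residue intervals on a protein (for example the
#' N-terminal beta-propeller, leg, transmembrane and cytoplasmic domains of
#' an integrin alpha subunit). Intervals are 1-based inclusive and may not
#' overlap within one accession.
#'
#' @param path TSV with columns `accession`, `region_name`, `start`, `end`.
#' @return Named list (by accession) of `RegionMap` data frames with columns
#'   `region_name`, `start`, `end`.
#' @export
read_region_map <- function(path) {
  tab <- read_tsv_file(path)
  required <- c("accession", "region_name", "start", "end")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("region map lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  lapply(split(tab, tab$accession), function(rm) {
    acc <- rm$accession[1]
    rm <- rm[order(rm$start), c("region_name", "start", "end")]
    rownames(rm) <- NULL
    validate_region_map(rm, acc)
    attr(rm, "accession") <- acc
    class(rm) <- c("RegionMap", "data.frame")
    rm
  })
}

validate_region_map <- function(rm, accession = "?") {
  if (any(is.na(rm$start)) || any(is.na(rm$end))) {
    stop("non-numeric region coordinates", call. = FALSE)
  }
  if (any(rm$start < 1) || any(rm$start > rm$end)) {
    bad <- which(rm$start < 1 | rm$start > rm$end)[1]
    stop("invalid region interval [", rm$start[bad], ", ", rm$end[bad],
         "] for region '", rm$region_name[bad], "'", call. = FALSE)
  }
  if (anyDuplicated(rm$region_name)) {
    stop("duplicate region name(s): ",
         paste(unique(rm$region_name[duplicated(rm$region_name)]),
               collapse = ", "), call. = FALSE)
  }
  rm <- rm[order(rm$start), ]
  if (nrow(rm) > 1 && any(rm$start[-1] <= rm$end[-nrow(rm)])) {
    i <- which(rm$start[-1] <= rm$end[-nrow(rm)])[1]
    stop("overlapping regions '", rm$region_name[i], "' and '",
         rm$region_name[i + 1], "'", call. = FALSE)
  }
  invisible(rm)
}

#' Read a protein-protein interaction edge list
#'
#' Accepts either SIF lines (`A pp B`, whitespace-delimited) or a 2-3 column
#' TSV (`gene_a`, `gene_b`, optional `source`). Self-loops are dropped and
#' symbols upper-cased; endpoint order is preserved as read (canonicalization
#' happens in [merge_interactomes()]).
#'
#' @param path edge-list file.
#' @param source_tag provenance tag used when the file carries none;
#'   defaults to the file name.
#' @return `data.frame` with columns `gene_a`, `gene_b`, `source`.
#' @export
read_edge_list <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  lines <- lines[keep]
  # header line of a TSV variant is recognised and skipped
  if (length(lines) > 0 &&
      grepl("^gene_a\\t", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
    idx <- idx[-1]
  }
  edges <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(fields) == 3 && fields[2] == "pp") {
      edges[[i]] <- c(fields[1], fields[3], source_tag)        # SIF
    } else if (length(fields) == 2) {
      edges[[i]] <- c(fields[1], fields[2], source_tag)
    } else if (length(fields) == 3) {
      edges[[i]] <- fields
    } else {
      stop("malformed edge line ", idx[i], " in ", path, ": '",
           lines[i], "'", call. = FALSE)
    }
  }
  out <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  if (nrow(out) == 0) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      source = character(), stringsAsFactors = FALSE)
  }
  names(out) <- c("gene_a", "gene_b", "source")
  out$gene_a <- toupper(out$gene_a)
  out$gene_b <- toupper(out$gene_b)
  out[out$gene_a != out$gene_b, , drop = FALSE]
}

#' Read a curated gene set
#'
#' @param path plain text, one gene symbol per line ('#' comments allowed).
#' @param name gene-set name; defaults to the file name.
#' @return list of class `GeneSet` with `name` and `members` (upper-cased,
#'   unique). Empty sets are rejected.
#' @export
read_gene_set <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  members <- unique(toupper(lines[!grepl("^(#|$)", lines)]))
  if (length(members) == 0) {
    stop("gene set '", name, "' is empty", call. = FALSE)
  }
  structure(list(name = name, members = members), class = "GeneSet")
}

#' Read term annotations and term relations
#'
#' Builds a `TermAnnotation`: a gene-to-term map (GAF-like TSV with columns
#' `gene` and `term`), plus a child-to-parent relation table used for
#' ancestor rollup. The relation graph must be acyclic.
#'
#' @param gaf_path TSV with columns `gene`, `term`.
#' @param relations_path TSV with columns `child`, `parent`; may be empty
#'   (rollup is then the identity).
#' @return list of class `TermAnnotation` with elements `gene2term` (named
#'   list), `term2gene` (named list), `relations` (data.frame), `terms`
#'   (term universe) and `background` (all annotated genes).
#' @export
read_annotations <- function(gaf_path, relations_path = NULL) {
  gaf <- read_tsv_file(gaf_path)
  if (!all(c("gene", "term") %in% names(gaf))) {
    stop("annotation file needs 'gene' and 'term' columns", call. = FALSE)
  }
  gaf$gene <- toupper(gaf$gene)
  relations <- data.frame(child = character(), parent = character(),
                          stringsAsFactors = FALSE)
  if (!is.null(relations_path)) {
    rel <- read_tsv_file(relations_path)
    if (nrow(rel) > 0) {
      if (!all(c("child", "parent") %in% names(rel))) {
        stop("relations file needs 'child' and 'parent' columns",
             call. = FALSE)
      }
      relations <- rel[, c("child", "parent")]
    }
  }
  term_annotation(gaf, relations)
}

#' Construct a TermAnnotation from in-memory tables
#'
#' @param gaf data.frame with columns `gene`, `term`.
#' @param relations data.frame with columns `child`, `parent` (acyclic).
#' @return A `TermAnnotation` (see [read_annotations()]).
#' @export
term_annotation <- function(gaf, relations = NULL) {
  if (is.null(relations) || nrow(relations) == 0) {
    relations <- data.frame(child = character(), parent = character(),
                            stringsAsFactors = FALSE)
  }
  assert_acyclic_relations(relations)
  gaf <- unique(gaf[, c("gene", "term")])
  terms <- sort(unique(c(gaf$term, relations$child, relations$parent)))
  structure(list(
    gene2term = split(gaf$term, gaf$gene),
    term2gene = split(gaf$gene, gaf$term),
    relations = relations,
    terms = terms,
    background = sort(unique(gaf$gene))
  ), class = "TermAnnotation")
}

assert_acyclic_relations <- function(relations) {
  if (nrow(relations) == 0) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(relations, directed = TRUE)
  if (!igraph::is_dag(g)) {
    # surface one cycle for the error message
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1]]
    stop("term relations contain a cycle involving: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Ancestors of terms under the relation closure
#'
#' @param annotation a `TermAnnotation`.
#' @param terms character vector of term ids.
#' @return For each input term, the term itself plus all (transitive)
#'   parents, as one character vector per term (named list).
#' @export
term_ancestors <- function(annotation, terms) {
  rel <- annotation$relations
  parents <- split(rel$parent, rel$child)
  lapply(stats::setNames(terms, terms), function(t) {
    seen <- character()
    frontier <- t
    while (length(frontier) > 0) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(parents[frontier], use.names = FALSE), seen)
    }
    seen
  })
}

#' Read an accession-to-gene-symbol mapping table
#'
#' Proteins without a mapping are retained in quantification but flagged
#' unmapped for network stages.
#'
#' @param path TSV with columns `accession`, `gene_symbol`.
#' @return named character vector (accession -> upper-cased symbol).
#' @export
read_symbol_map <- function(path) {
  tab <- read_tsv_file(path)
  if (!all(c("accession", "gene_symbol") %in% names(tab))) {
    stop("mapping file needs 'accession' and 'gene_symbol' columns",
         call. = FALSE)
  }
  stats::setNames(toupper(tab$gene_symbol), tab$accession)
}

#' Read protein sequences from FASTA
#'
#' @param path amino-acid FASTA.
#' @return named character vector of sequences (names truncated at first
#'   whitespace).
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write protein sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_protein_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
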