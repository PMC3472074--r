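# Interactome assembly, mapping coverage, induced subnetworks, Venn-set
# partitioning of specific proteins across cell lines, gene-set filtering
# and localization rollup annotation.

#' Merge interaction edge lists into one interactome
#'
#' Edges are undirected; endpoint pairs are canonicalized (sorted) so that
#' (A,B) and (B,A) collapse to a single edge whose `sources` attribute
#' records every contributing database tag. Self-loops never enter (dropped
#' at read time and again here).
#'
#' @param edge_lists a list of data frames as returned by
#'   [read_edge_list()], or a single such data frame.
#' @return an igraph graph of class `Interactome` with edge attribute
#'   `sources` (semicolon-joined tags).
#' @export
merge_interactomes <- function(edge_lists) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  if (length(edge_lists) == 0) stop("need at least one edge list",
                                    call. = FALSE)
  all_edges <- do.call(rbind, edge_lists)
  if (is.null(all_edges) || nrow(all_edges) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    class(g) <- c("Interactome", class(g))
    return(g)
  }
  a <- pmin(all_edges$gene_a, all_edges$gene_b)
  b <- pmax(all_edges$gene_a, all_edges$gene_b)
  keep <- a != b
  key <- paste(a[keep], b[keep], sep = "\r")
  sources <- vapply(split(all_edges$source[keep], key), function(s) {
    paste(sort(unique(s)), collapse = ";")
  }, character(1))
  uk <- names(sources)
  parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = parts[, 1], to = parts[, 2],
               sources = unname(sources), stringsAsFactors = FALSE),
    directed = FALSE)
  class(g) <- c("Interactome", class(g))
  g
}

#' Fraction of proteins mappable onto the interactome
#'
#' @param proteins character vector of gene symbols.
#' @param interactome graph from [merge_interactomes()].
#' @return list with `mapped` (symbols found as nodes), `unmapped`, and
#'   `fraction` = |mapped| / |proteins|.
#' @export
map_coverage <- function(proteins, interactome) {
  proteins <- unique(toupper(proteins))
  if (length(proteins) == 0) stop("empty protein set", call. = FALSE)
  nodes <- igraph::V(interactome)$name
  mapped <- intersect(proteins, nodes)
  list(mapped = mapped,
       unmapped = setdiff(proteins, nodes),
       fraction = length(mapped) / length(proteins))
}

#' Subnetwork induced by a protein set
#'
#' Node set = proteins found in the interactome; edge set = interactome
#' edges with both endpoints in that node set. Isolated nodes are retained.
#'
#' @param interactome graph from [merge_interactomes()].
#' @param proteins character vector of gene symbols.
#' @return induced igraph subgraph.
#' @export
induced_subnetwork <- function(interactome, proteins) {
  proteins <- unique(toupper(proteins))
  nodes <- intersect(proteins, igraph::V(interactome)$name)
  g <- igraph::induced_subgraph(interactome, nodes)
  class(g) <- c("Interactome", class(g))
  g
}

#' Venn-set partition of specifically enriched proteins
#'
#' Each protein called specific in at least one cell line is assigned the
#' exact subset of cell lines in which it was specific; these subsets
#' partition the specific-protein universe (the seven regions of a
#' three-set Venn diagram).
#'
#' @param enrich an `EnrichmentTable` after [call_specific()], with calls
#'   for all three cell lines.
#' @return `data.frame` of class `VennPartition` with columns `accession`,
#'   `gene_symbol`, `venn_set` (e.g. `"A4+X4C0"`), and one logical column
#'   per cell line.
#' @export
venn_partition <- function(enrich) {
  if (any(is.na(enrich$specific))) {
    stop("enrichment table has missing specificity calls; ",
         "run call_specific() first", call. = FALSE)
  }
  missing_lines <- setdiff(CELL_LINES, unique(enrich$cell_line))
  if (length(missing_lines) > 0) {
    stop("specificity calls missing for cell line(s): ",
         paste(missing_lines, collapse = ", "), call. = FALSE)
  }
  wide <- lapply(split(enrich, enrich$accession), function(z) {
    spec <- CELL_LINES %in% z$cell_line[z$specific]
    data.frame(accession = z$accession[1], gene_symbol = z$gene_symbol[1],
               A4 = spec[1], X4C0 = spec[2], A4P_A5L = spec[3],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, wide)
  tab <- tab[tab$A4 | tab$X4C0 | tab$A4P_A5L, , drop = FALSE]
  tab$venn_set <- apply(tab[, CELL_LINES], 1, function(f) {
    paste(CELL_LINES[f], collapse = "+")
  })
  rownames(tab) <- NULL
  tab <- tab[, c("accession", "gene_symbol", "venn_set", CELL_LINES)]
  class(tab) <- c("VennPartition", "data.frame")
  tab
}

#' Filter proteins against a curated gene set
#'
#' Intersection by gene symbol, e.g. restricting an enriched-protein list to
#' literature-curated adhesome components. Multiple subunits or paralogs
#' mapping to one catalogue entry stay distinct proteins.
#'
#' @param proteins character vector of gene symbols.
#' @param gene_set a `GeneSet` from [read_gene_set()].
#' @return character vector (subset of `proteins`).
#' @export
geneset_filter <- function(proteins, gene_set) {
  stopifnot(inherits(gene_set, "GeneSet"))
  proteins <- unique(toupper(proteins))
  proteins[proteins %in% gene_set$members]
}

#' Default localization category roots (GO cellular component)
#'
#' extracellular: GO:0005576 (extracellular region); cell_periphery:
#' GO:0009986 (cell surface), GO:0030054 (cell junction), GO:0071944 (cell
#' periphery); transmembrane: GO:0031226 (intrinsic to plasma membrane);
#' intracellular: GO:0005622 (intracellular).
#'
#' @return named list category -> character vector of root term ids.
#' @export
localization_roots <- function() {
  list(extracellular = "GO:0005576",
       cell_periphery = c("GO:0009986", "GO:0030054", "GO:0071944"),
       transmembrane = "GO:0031226",
       intracellular = "GO:0005622")
}

#' Annotate proteins with localization categories by term rollup
#'
#' A protein belongs to a category if it is annotated with any of the
#' category's root terms or with any descendant of a root under the
#' child-to-parent relation closure. Unannotated proteins get an empty
#' category set.
#'
#' @param proteins character vector of gene symbols.
#' @param annotation a `TermAnnotation` from [read_annotations()].
#' @param category_roots named list category -> root term ids; default
#'   [localization_roots()].
#' @return named list protein -> character vector of categories.
#' @export
annotate_localization <- function(proteins, annotation,
                                  category_roots = localization_roots()) {
  roots <- unlist(category_roots, use.names = FALSE)
  unknown <- setdiff(roots, annotation$terms)
  if (length(unknown) > 0) {
    stop("unknown root term id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # ancestors of every annotated term, computed once
  anc <- term_ancestors(annotation, unique(unlist(annotation$gene2term,
                                                  use.names = FALSE)))
  proteins <- unique(toupper(proteins))
  out <- lapply(stats::setNames(proteins, proteins), function(p) {
    terms <- annotation$gene2term[[p]]
    if (is.null(terms)) return(character(0))
    reach <- unique(c(terms, unlist(anc[terms], use.names = FALSE)))
    names(category_roots)[vapply(category_roots, function(r) {
      any(r %in% reach)
    }, logical(1))]
  })
  out
}

#' Write a subnetwork as GraphML with analysis attributes
#'
#' Node attributes carried along: `venn_set`, comma-joined localization
#' categories, and per-cell-line enrichment ratios.
#'
#' @param g igraph subnetwork.
#' @param path output `.graphml` path.
#' @param venn optional `VennPartition`.
#' @param localization optional result of [annotate_localization()].
#' @param enrich optional `EnrichmentTable` (adds `ratio_<line>` columns).
#' @export
write_graphml <- function(g, path, venn = NULL, localization = NULL,
                          enrich = NULL) {
  nodes <- igraph::V(g)$name
  if (!is.null(venn)) {
    g <- igraph::set_vertex_attr(
      g, "venn_set", value = venn$venn_set[match(nodes, venn$gene_symbol)])
  }
  if (!is.null(localization)) {
    g <- igraph::set_vertex_attr(
      g, "localization", value = vapply(nodes, function(n) {
        paste(localization[[n]], collapse = ",")
      }, character(1)))
  }
  if (!is.null(enrich)) {
    for (cl in intersect(CELL_LINES, unique(enrich$cell_line))) {
      sub <- enrich[enrich$cell_line == cl, ]
      g <- igraph::set_vertex_attr(
        g, paste0("ratio_", cl),
        value = sub$ratio[match(nodes, sub$gene_symbol)])
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a graph as SIF ("A pp B" lines)
#' @param g igraph graph.
#' @param path output `.sif` path.
#' @export
write_sif <- function(g, path) {
  el <- igraph::as_edgelist(g)
  lines <- if (nrow(el) > 0) paste(el[, 1], "pp", el[, 2]) else character(0)
  isolated <- igraph::V(g)$name[igraph::degree(g) == 0]
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' @export
write_venn_table <- function(venn, path) {
  write_tsv_file(as.data.frame(venn), path)
}
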