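# End-to-end orchestration: quantify -> cluster -> network -> enrich ->
# peptide-validate, with a manifest of checksummed artifacts and a run log.

#' Build a run configuration
#'
#' @param counts,design,edges,annotations,relations,gene_set,fasta,regions,
#'   peptides,expectations input paths (`edges` and `peptides` may be
#'   vectors; `peptides` named by cell line).
#' @param out_dir output directory.
#' @param pseudocount,linkage,min_corr,control_cap,min_fold,max_p_bonf,
#'   background analysis parameters (see the stage functions).
#' @param seed integer seed recorded in the log (the pipeline itself is
#'   deterministic).
#' @return list of class `RunConfig`.
#' @export
run_config <- function(counts, design, out_dir,
                       edges = NULL, annotations = NULL, relations = NULL,
                       gene_set = NULL, fasta = NULL, regions = NULL,
                       peptides = NULL, expectations = NULL,
                       pseudocount = 1, linkage = "average",
                       min_corr = 0.6, control_cap = 1,
                       min_fold = 5, max_p_bonf = 0.1,
                       background = "annotation", seed = 1L) {
  cfg <- as.list(environment())
  required <- c(counts = counts, design = design)
  optional <- c(edges, annotations, relations, gene_set, fasta, regions,
                peptides, expectations)
  missing <- c(required, optional)[!file.exists(c(required, optional))]
  if (length(missing) > 0) {
    stop("input path(s) do not exist: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (min_corr < -1 || min_corr > 1) stop("min_corr must lie in [-1, 1]",
                                          call. = FALSE)
  if (pseudocount < 0 || control_cap < 0 || min_fold < 0 ||
      max_p_bonf <= 0 || max_p_bonf > 1) {
    stop("threshold parameter out of range", call. = FALSE)
  }
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$peptides)) y$peptides <- unlist(y$peptides)
  if (!is.null(y$edges)) y$edges <- unlist(y$edges)
  do.call(run_config, y)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: quantification (enrichment ratios + mean+1SD
#' threshold + specificity calls), clustering (profiles, dendrogram,
#' cluster selection, background flagging), network (interactome merge,
#' Venn partition, induced subnetworks, gene-set filter, localization),
#' term overrepresentation per Venn-line subnetwork, and construct peptide
#' validation. Each stage is skipped cleanly when its inputs are not
#' configured. All artifacts are checksummed into `manifest.tsv`.
#'
#' @param config a [run_config()].
#' @return list with `manifest` (data.frame file/md5), `results` (in-memory
#'   stage outputs) and `log` (path).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_path <- out("run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  artifacts <- character(0)
  results <- list()
  for (p in c("pseudocount", "linkage", "min_corr", "control_cap",
              "min_fold", "max_p_bonf", "background", "seed")) {
    log_line(con, "param ", p, " = ", paste(config[[p]], collapse = ","))
  }

  stage <- function(name, expr) {
    log_line(con, "stage ", name, " started")
    r <- tryCatch(expr, error = function(e) {
      log_line(con, "stage ", name, " FAILED: ", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_line(con, "stage ", name, " done")
    r
  }

  # quantify ----------------------------------------------------------
  results$quantify <- stage("quantify", {
    design <- read_sample_design(config$design)
    cm <- read_count_table(config$counts, design)
    enrich <- compute_enrichment(cm, pseudocount = config$pseudocount)
    thr <- specificity_threshold(enrich$ratio)
    enrich <- call_specific(enrich, thr)
    write_enrichment_table(enrich, out("enrichment.tsv"))
    write_threshold_report(thr, out("threshold.tsv"))
    artifacts <- c(artifacts, out("enrichment.tsv"), out("threshold.tsv"))
    list(matrix = cm, enrich = enrich, threshold = thr)
  })
  enrich <- results$quantify$enrich
  thr <- results$quantify$threshold

  # cluster -----------------------------------------------------------
  results$cluster <- stage("cluster", {
    X <- profile_matrix(enrich, pseudocount = config$pseudocount)
    dend <- apms_hclust(X, linkage = config$linkage)
    sel <- select_clusters(dend, enrich, min_corr = config$min_corr,
                           control_cap = config$control_cap)
    bg <- flag_background_clusters(dend, enrich, thr,
                                   control_cap = config$control_cap)
    write_newick(dend, out("dendrogram.nwk"))
    write_cluster_table(sel, out("clusters.tsv"))
    artifacts <- c(artifacts, out("dendrogram.nwk"), out("clusters.tsv"))
    list(dendrogram = dend, selection = sel, background_nodes = bg)
  })

  # network -----------------------------------------------------------
  if (!is.null(config$edges)) {
    results$network <- stage("network", {
      el <- lapply(config$edges, read_edge_list)
      net <- merge_interactomes(el)
      venn <- venn_partition(enrich)
      cov <- map_coverage(venn$gene_symbol, net)
      log_line(con, sprintf("mapped %d/%d specific proteins (%.1f%%)",
                            length(cov$mapped), nrow(venn),
                            100 * cov$fraction))
      sub <- induced_subnetwork(net, venn$gene_symbol)
      loc <- NULL
      if (!is.null(config$annotations)) {
        ann <- read_annotations(config$annotations, config$relations)
        loc <- tryCatch(
          annotate_localization(venn$gene_symbol, ann),
          error = function(e) {
            log_line(con, "localization skipped: ", conditionMessage(e))
            NULL
          })
      }
      adheso <- NULL
      if (!is.null(config$gene_set)) {
        gs <- read_gene_set(config$gene_set)
        adheso <- geneset_filter(venn$gene_symbol, gs)
        write_sif(induced_subnetwork(net, adheso), out("geneset_sub.sif"))
        artifacts <- c(artifacts, out("geneset_sub.sif"))
      }
      write_venn_table(venn, out("venn_partition.tsv"))
      write_graphml(sub, out("subnetwork.graphml"), venn = venn,
                    localization = loc, enrich = enrich)
      write_sif(sub, out("subnetwork.sif"))
      artifacts <- c(artifacts, out("venn_partition.tsv"),
                      out("subnetwork.graphml"), out("subnetwork.sif"))
      list(interactome = net, venn = venn, coverage = cov,
           subnetwork = sub, localization = loc, geneset_hits = adheso)
    })
  }

  # term enrichment ---------------------------------------------------
  if (!is.null(config$annotations)) {
    results$enrich_terms <- stage("enrich", {
      ann <- read_annotations(config$annotations, config$relations)
      background <- if (identical(config$background, "detected")) {
        unique(enrich$gene_symbol)
      } else NULL
      venn <- venn_partition(enrich)
      per_line <- lapply(stats::setNames(CELL_LINES, CELL_LINES),
                         function(cl) {
        genes <- venn$gene_symbol[venn[[cl]]]
        if (length(genes) == 0) return(NULL)
        suppressMessages(
          enrich_set(genes, ann, min_fold = config$min_fold,
                     max_p_bonf = config$max_p_bonf,
                     background = background))
      })
      tab <- do.call(rbind, lapply(names(per_line), function(cl) {
        if (is.null(per_line[[cl]])) return(NULL)
        cbind(cell_line = cl, as.data.frame(per_line[[cl]]))
      }))
      write_tsv_file(tab, out("term_enrichment.tsv"))
      artifacts <- c(artifacts, out("term_enrichment.tsv"))
      per_line
    })
  }

  # peptide validation ------------------------------------------------
  if (!is.null(config$fasta)) {
    results$peptides <- stage("validate-peptides", {
      seqs <- read_protein_fasta(config$fasta)
      rms <- read_region_map(config$regions)
      peps <- lapply(config$peptides, read_tsv_file)
      names(peps) <- names(config$peptides)
      expectations <- read_tsv_file(config$expectations)
      expectations$forbidden_regions <-
        as.character(expectations$forbidden_regions)
      expectations$required_regions <-
        as.character(expectations$required_regions)
      val <- validate_construct(peps, seqs, rms, expectations)
      write_tsv_file(as.data.frame(val), out("construct_validation.tsv"))
      artifacts <- c(artifacts, out("construct_validation.tsv"))
      log_line(con, "construct validation overall: ",
               if (attr(val, "pass")) "PASS" else "FAIL")
      val
    })
  }

  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)),
                         stringsAsFactors = FALSE)
  write_tsv_file(manifest, out("manifest.tsv"))
  log_line(con, "wrote manifest with ", nrow(manifest), " artifacts")
  list(manifest = manifest, results = results, log = log_path)
}
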