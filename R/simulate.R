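# Synthetic-data generator: emits a complete AP-MS input bundle (counts,
# design, interactome, annotations, gene set, construct sequences and
# peptides) with planted structure, so every pipeline stage is testable
# without external downloads.

VENN_REGIONS <- list("A4", "X4C0", "A4P_A5L",
                     c("A4", "X4C0"), c("A4", "A4P_A5L"),
                     c("X4C0", "A4P_A5L"), c("A4", "X4C0", "A4P_A5L"))

venn_label <- function(lines) paste(lines, collapse = "+")

# independent reproducible sub-stream per component, all below 2^31
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults emulate the scale and design of a three-cell-line integrin
#' AP-MS experiment: ~650 detected proteins, bait (ligand-coated beads) vs
#' control (non-binding mutant ligand) purifications, two biological
#' replicates (three for the wild-type line's bait), planted receptor-
#' specific proteins in all seven Venn regions at fold `fold` over a
#' ratio-1 background, control-dominated background proteins and constant
#' reagent proteins, negative-binomial counts (overdispersed across
#' replicates).
#'
#' @param seed integer master seed; all generators derive independent
#'   streams from it.
#' @param n_proteins total proteins in the count matrix.
#' @param planted_per_region planted specific proteins per Venn region.
#' @param fold planted bait fold-change in member cell lines.
#' @param mu baseline mean spectral count.
#' @param mu_control mean control count for planted/unenriched proteins.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed); ignored for `count_model = "poisson"`.
#' @param count_model `"nb"` (default) or `"poisson"`.
#' @param bait_replicates named integer vector of bait replicates per line.
#' @param control_replicates control replicates per line.
#' @param n_background control-dominated (nonspecific) proteins.
#' @param n_reagent equal-mean-everywhere reagent proteins.
#' @param background_control_mean,background_bait_mean,reagent_mean count
#'   means for the background/reagent classes.
#' @param edge_prob_background,edge_prob_module interactome edge
#'   probabilities (Erdos-Renyi background; extra within planted modules).
#' @param n_random_terms,random_term_prob,planted_term_coverage annotation
#'   structure: random terms and per-region planted terms.
#' @param region_lengths named lengths of the four construct regions.
#' @param n_peptides_per_region,peptide_length_range construct peptides.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 650L,
                              planted_per_region = 20L,
                              fold = 8,
                              mu = 10,
                              mu_control = 10,
                              dispersion = 5,
                              count_model = c("nb", "poisson"),
                              bait_replicates = c(A4 = 3L, X4C0 = 2L,
                                                  A4P_A5L = 2L),
                              control_replicates = 2L,
                              n_background = 60L,
                              n_reagent = 10L,
                              background_control_mean = 50,
                              background_bait_mean = 2,
                              reagent_mean = 30,
                              edge_prob_background = 0.01,
                              edge_prob_module = 0.35,
                              n_random_terms = 40L,
                              random_term_prob = 0.05,
                              planted_term_coverage = 0.9,
                              region_lengths = c(propeller = 440L, leg = 260L,
                                                 tm = 25L,
                                                 cytoplasmic = 35L),
                              n_peptides_per_region = 6L,
                              peptide_length_range = c(8L, 20L)) {
  count_model <- match.arg(count_model)
  cfg <- as.list(environment())
  n_planted <- length(VENN_REGIONS) * cfg$planted_per_region
  if (cfg$n_proteins < n_planted + cfg$n_background + cfg$n_reagent) {
    stop("n_proteins too small for the planted + background + reagent sets",
         call. = FALSE)
  }
  if (cfg$fold < 1) stop("fold must be >= 1 (fold = 1 is the null world)",
                         call. = FALSE)
  if (any(c(cfg$edge_prob_background, cfg$edge_prob_module,
            cfg$random_term_prob, cfg$planted_term_coverage) < 0) ||
      any(c(cfg$edge_prob_background, cfg$edge_prob_module,
            cfg$random_term_prob, cfg$planted_term_coverage) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(cfg$mu, cfg$mu_control, cfg$dispersion) <= 0)) {
    stop("mu, mu_control and dispersion must be positive", call. = FALSE)
  }
  if (!all(CELL_LINES %in% names(cfg$bait_replicates))) {
    stop("bait_replicates must name all of ",
         paste(CELL_LINES, collapse = ", "), call. = FALSE)
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

simulated_design <- function(config) {
  rows <- list()
  for (cl in CELL_LINES) {
    for (r in seq_len(config$bait_replicates[[cl]])) {
      rows[[length(rows) + 1]] <- c(paste(cl, "BAIT", r, sep = "_"),
                                    cl, "BAIT", r)
    }
    for (r in seq_len(config$control_replicates)) {
      rows[[length(rows) + 1]] <- c(paste(cl, "CONTROL", r, sep = "_"),
                                    cl, "CONTROL", r)
    }
  }
  m <- do.call(rbind, rows)
  sample_design(m[, 1], m[, 2], m[, 3], as.integer(m[, 4]))
}

#' Simulate a spectral-count matrix with planted enrichment
#'
#' Planted proteins in Venn region S have bait mean `fold * mu` in member
#' cell lines and `mu` elsewhere, with control mean `mu_control`;
#' unenriched proteins sit at ratio ~1; background proteins are dominated
#' by control detection; reagent proteins have one mean everywhere. Counts
#' are negative binomial (or Poisson). Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `matrix` (a [count_matrix()]) and `truth` (data.frame
#'   `accession`, `label` where label is a Venn region such as `"A4+X4C0"`,
#'   or `background` / `reagent` / `unenriched`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(derive_seed(config$seed, "counts"))
  design <- simulated_design(config)
  n <- config$n_proteins
  accs <- sprintf("SIMG%04d", seq_len(n))
  labels <- c(rep(vapply(VENN_REGIONS, venn_label, ""),
                  each = config$planted_per_region),
              rep("background", config$n_background),
              rep("reagent", config$n_reagent))
  labels <- c(labels, rep("unenriched", n - length(labels)))

  mean_for <- function(label, cell_line, condition) {
    if (label == "background") {
      if (condition == "BAIT") config$background_bait_mean
      else config$background_control_mean
    } else if (label == "reagent") {
      config$reagent_mean
    } else if (label == "unenriched") {
      if (condition == "BAIT") config$mu else config$mu_control
    } else {                      # planted in a Venn region
      if (condition == "CONTROL") config$mu_control
      else if (cell_line %in% strsplit(label, "+", fixed = TRUE)[[1]]) {
        config$fold * config$mu
      } else config$mu
    }
  }
  mu_mat <- sapply(seq_len(nrow(design)), function(s) {
    vapply(labels, mean_for, 0,
           cell_line = design$cell_line[s], condition = design$condition[s])
  })
  draw <- if (config$count_model == "poisson") {
    function(m) stats::rpois(length(m), lambda = m)
  } else {
    function(m) stats::rnbinom(length(m), mu = m, size = config$dispersion)
  }
  counts <- matrix(draw(mu_mat), nrow = n,
                   dimnames = list(accs, design$sample_id))
  truth <- data.frame(accession = accs, label = unname(labels),
                      stringsAsFactors = FALSE)
  list(matrix = count_matrix(counts, design), truth = truth)
}

#' Simulate an interactome with planted modules
#'
#' Erdos-Renyi background over all simulated proteins plus dense planted
#' modules aligned with the Venn-region sets; the edges are split across
#' two "source database" files (one SIF-style, one TSV-style data frame) to
#' exercise [merge_interactomes()].
#'
#' @param config a [simulation_config()].
#' @param truth truth table from [simulate_counts()].
#' @return list of two edge-list data frames (columns `gene_a`, `gene_b`,
#'   `source`).
#' @export
simulate_interactome <- function(config, truth) {
  set.seed(derive_seed(config$seed, "interactome"))
  nodes <- truth$accession
  n <- length(nodes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < config$edge_prob_background
  edges <- pairs[keep, , drop = FALSE]
  for (region in VENN_REGIONS) {
    idx <- which(truth$label == venn_label(region))
    mp <- which(upper.tri(matrix(0, length(idx), length(idx))),
                arr.ind = TRUE)
    mkeep <- stats::runif(nrow(mp)) < config$edge_prob_module
    edges <- rbind(edges, cbind(idx[mp[mkeep, 1]], idx[mp[mkeep, 2]]))
  }
  edges <- unique(edges)
  src <- sample(c("dbA", "dbB"), nrow(edges), replace = TRUE)
  el <- data.frame(gene_a = nodes[edges[, 1]], gene_b = nodes[edges[, 2]],
                   source = src, stringsAsFactors = FALSE)
  split(el, el$source)
}

#' Simulate term annotations, relations and a curated gene set
#'
#' One planted term per Venn region covering `planted_term_coverage` of the
#' region's proteins, random terms elsewhere, a rooted relation DAG that
#' includes the six localization root terms with child terms annotated to
#' genes, and an adhesome-like gene set overlapping the planted proteins.
#'
#' @param config a [simulation_config()].
#' @param truth truth table from [simulate_counts()].
#' @return list with `gaf` (gene/term data frame), `relations`
#'   (child/parent data frame), `gene_set` (character members) and
#'   `planted_terms` (named by Venn label).
#' @export
simulate_annotations <- function(config, truth) {
  set.seed(derive_seed(config$seed, "annotations"))
  genes <- truth$accession
  gaf <- list()
  planted_terms <- character(0)
  for (region in VENN_REGIONS) {
    lab <- venn_label(region)
    term <- paste0("TERM:", gsub("\\+", "_", lab))
    planted_terms[lab] <- term
    members <- truth$accession[truth$label == lab]
    covered <- members[stats::runif(length(members)) <=
                         config$planted_term_coverage]
    extra <- sample(setdiff(genes, members),
                    max(1, round(0.01 * length(genes))))
    gaf[[length(gaf) + 1]] <- data.frame(gene = c(covered, extra),
                                         term = term)
  }
  for (t in seq_len(config$n_random_terms)) {
    members <- genes[stats::runif(length(genes)) < config$random_term_prob]
    if (length(members) > 0) {
      gaf[[length(gaf) + 1]] <- data.frame(
        gene = members, term = sprintf("TERM:RAND%03d", t))
    }
  }
  # localization subtree: each root gets two children and one grandchild
  roots <- unlist(localization_roots(), use.names = FALSE)
  relations <- list()
  loc_leaves <- character(0)
  for (r in seq_along(roots)) {
    children <- sprintf("LOC:%02d_%d", r, 1:2)
    grandchild <- sprintf("LOC:%02d_3", r)
    relations[[length(relations) + 1]] <-
      data.frame(child = c(children, grandchild),
                 parent = c(roots[r], roots[r], children[1]))
    loc_leaves <- c(loc_leaves, children, grandchild)
  }
  for (leaf in loc_leaves) {
    members <- genes[stats::runif(length(genes)) < 0.08]
    if (length(members) > 0) {
      gaf[[length(gaf) + 1]] <- data.frame(gene = members, term = leaf)
    }
  }
  planted_all <- truth$accession[!truth$label %in%
                                   c("background", "reagent", "unenriched")]
  gene_set <- sort(unique(c(
    sample(planted_all, round(0.6 * length(planted_all))),
    sample(setdiff(genes, planted_all), 20))))
  list(gaf = do.call(rbind, gaf),
       relations = do.call(rbind, relations),
       gene_set = gene_set,
       planted_terms = planted_terms)
}

random_aa <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

#' Simulate construct sequences, regions and peptide identifications
#'
#' Builds a synthetic wild-type alpha-subunit sequence with propeller, leg,
#' transmembrane and cytoplasmic regions, plus a second (alpha-5-like)
#' subunit. Peptides per cell line are sampled only from the regions
#' present in that line's construct: the wild-type line covers the full
#' length, the tail-deletion line excludes the cytoplasmic region, and the
#' chimera line restricts first-subunit peptides to the propeller with
#' second-subunit peptides confined to the leg/tail side.
#'
#' @param config a [simulation_config()].
#' @param inject_violation also emit one forbidden-region peptide for the
#'   tail-deletion line (for negative tests).
#' @return list with `sequences`, `regions` (data frame), `peptides`
#'   (named list by cell line of `peptide`/`accession` data frames) and
#'   `expectations` (data frame).
#' @export
simulate_constructs <- function(config, inject_violation = FALSE) {
  set.seed(derive_seed(config$seed, "constructs"))
  rl <- config$region_lengths
  bounds <- cumsum(rl)
  starts <- c(1L, utils::head(bounds, -1) + 1L)
  regions <- data.frame(
    accession = rep(c("ITGA4_SYN", "ITGA5_SYN"), each = length(rl)),
    region_name = rep(names(rl), 2),
    start = rep(starts, 2), end = rep(bounds, 2),
    stringsAsFactors = FALSE)
  sequences <- c(ITGA4_SYN = random_aa(sum(rl)),
                 ITGA5_SYN = random_aa(sum(rl)))

  sample_peptides <- function(acc, region_names) {
    rows <- lapply(region_names, function(rn) {
      r <- regions[regions$accession == acc & regions$region_name == rn, ]
      reps <- lapply(seq_len(config$n_peptides_per_region), function(i) {
        len <- sample(seq(config$peptide_length_range[1],
                          min(config$peptide_length_range[2],
                              r$end - r$start + 1)), 1)
        s <- sample(seq(r$start, r$end - len + 1), 1)
        substr(sequences[[acc]], s, s + len - 1)
      })
      data.frame(peptide = unlist(reps), accession = acc,
                 stringsAsFactors = FALSE)
    })
    unique(do.call(rbind, rows))
  }

  peptides <- list(
    A4 = sample_peptides("ITGA4_SYN",
                         c("propeller", "leg", "tm", "cytoplasmic")),
    X4C0 = sample_peptides("ITGA4_SYN", c("propeller", "leg", "tm")),
    A4P_A5L = rbind(sample_peptides("ITGA4_SYN", "propeller"),
                    sample_peptides("ITGA5_SYN", c("leg", "tm",
                                                   "cytoplasmic"))))
  if (inject_violation) {
    r <- regions[regions$accession == "ITGA4_SYN" &
                   regions$region_name == "cytoplasmic", ]
    s <- sample(seq(r$start, r$end - 10), 1)
    peptides$X4C0 <- rbind(peptides$X4C0, data.frame(
      peptide = substr(sequences[["ITGA4_SYN"]], s, s + 9),
      accession = "ITGA4_SYN", stringsAsFactors = FALSE))
  }
  expectations <- data.frame(
    cell_line = c("A4", "X4C0", "A4P_A5L", "A4P_A5L"),
    accession = c("ITGA4_SYN", "ITGA4_SYN", "ITGA4_SYN", "ITGA5_SYN"),
    forbidden_regions = c("", "cytoplasmic", "leg;tm;cytoplasmic",
                          "propeller"),
    required_regions = c("propeller;leg;tm;cytoplasmic", "propeller",
                         "propeller", "leg"),
    stringsAsFactors = FALSE)
  list(sequences = sequences, regions = regions, peptides = peptides,
       expectations = expectations)
}

#' Write a complete simulated input bundle to a directory
#'
#' Emits every file the pipeline consumes: design and count TSVs, two
#' interactome source files (one SIF, one TSV), GAF-like annotations with a
#' relations table, a synthetic adhesome-like gene set, construct FASTA,
#' region map, per-cell-line peptide TSVs, an expectation table, the ground
#' truth and the resolved configuration (YAML).
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if absent).
#' @param inject_violation passed to [simulate_constructs()].
#' @return named list of file paths (invisibly also the ground truth as
#'   attribute `truth`).
#' @export
simulate_bundle <- function(config, dir, inject_violation = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  sim <- simulate_counts(config)
  write_sample_design(sim$matrix$design, p("design.tsv"))
  write_count_table(sim$matrix, p("counts.tsv"))
  write_tsv_file(sim$truth, p("ground_truth.tsv"))

  el <- simulate_interactome(config, sim$truth)
  writeLines(paste(el$dbA$gene_a, "pp", el$dbA$gene_b), p("edges_dbA.sif"))
  write_tsv_file(el$dbB, p("edges_dbB.tsv"))

  ann <- simulate_annotations(config, sim$truth)
  write_tsv_file(ann$gaf, p("annotations.tsv"))
  write_tsv_file(ann$relations, p("term_relations.tsv"))
  writeLines(ann$gene_set, p("geneset_adhesome_synthetic.txt"))
  write_tsv_file(data.frame(venn_set = names(ann$planted_terms),
                            term = unname(ann$planted_terms)),
                 p("planted_terms.tsv"))

  con <- simulate_constructs(config, inject_violation)
  write_protein_fasta(con$sequences, p("constructs.fasta"))
  write_tsv_file(con$regions, p("regions.tsv"))
  for (cl in names(con$peptides)) {
    write_tsv_file(con$peptides[[cl]], p(paste0("peptides_", cl, ".tsv")))
  }
  write_tsv_file(con$expectations, p("expectations.tsv"))

  cfg <- config
  cfg$bait_replicates <- as.list(cfg$bait_replicates)
  cfg$region_lengths <- as.list(cfg$region_lengths)
  yaml::write_yaml(unclass(cfg), p("sim_config.yaml"))

  paths <- list(design = p("design.tsv"), counts = p("counts.tsv"),
                truth = p("ground_truth.tsv"),
                edges = c(p("edges_dbA.sif"), p("edges_dbB.tsv")),
                annotations = p("annotations.tsv"),
                relations = p("term_relations.tsv"),
                gene_set = p("geneset_adhesome_synthetic.txt"),
                planted_terms = p("planted_terms.tsv"),
                fasta = p("constructs.fasta"), regions = p("regions.tsv"),
                peptides = stats::setNames(
                  file.path(dir, paste0("peptides_", names(con$peptides),
                                        ".tsv")),
                  names(con$peptides)),
                expectations = p("expectations.tsv"),
                config = p("sim_config.yaml"))
  attr(paths, "truth") <- sim$truth
  paths
}
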