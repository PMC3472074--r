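edge_df <- function(a, b, src = "db") {
  data.frame(gene_a = a, gene_b = b,
             source = rep(src, length.out = length(a)),
             stringsAsFactors = FALSE)
}

test_that("interactome merge canonicalizes pairs and keeps provenance", {
  g <- merge_interactomes(list(edge_df("TLN1", "ITGB1", "db1"),
                               edge_df("ITGB1", "TLN1", "db2")))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$sources, "db1;db2")
  expect_equal(igraph::ecount(merge_interactomes(list(edge_df(
    character(0), character(0))))), 0)
})

test_that("map_coverage reports the mapped fraction", {
  g <- merge_interactomes(edge_df(c("A", "B"), c("B", "C")))
  expect_equal(map_coverage(c("A", "B", "C"), g)$fraction, 1)
  expect_equal(map_coverage(c("X", "Y"), g)$fraction, 0)
  cov <- map_coverage(c("A", "B", "Z"), g)
  expect_setequal(cov$mapped, c("A", "B"))
  expect_equal(cov$unmapped, "Z")
  expect_error(map_coverage(character(0), g), "empty")
})

test_that("induced subnetworks keep isolated nodes, are idempotent and monotone", {
  g <- merge_interactomes(edge_df(c("A", "B", "A"), c("B", "C", "C")))
  tri_ab <- induced_subnetwork(g, c("A", "B"))
  expect_equal(igraph::ecount(tri_ab), 1)
  full <- induced_subnetwork(g, c("A", "B", "C"))
  expect_equal(igraph::ecount(full), 3)
  lone <- induced_subnetwork(g, c("A", "ZZZ"))
  expect_equal(igraph::vcount(lone), 1)      # isolated node retained
  expect_equal(igraph::ecount(lone), 0)

  set.seed(21)
  for (i in 1:10) {
    n <- 25
    el <- t(utils::combn(paste0("N", 1:n), 2))
    keep <- runif(nrow(el)) < 0.15
    g2 <- merge_interactomes(edge_df(el[keep, 1], el[keep, 2]))
    p_small <- sample(paste0("N", 1:n), 8)
    p_big <- union(p_small, sample(paste0("N", 1:n), 8))
    sub_small <- induced_subnetwork(g2, p_small)
    sub_big <- induced_subnetwork(g2, p_big)
    eset <- function(g) apply(igraph::as_edgelist(g), 1,
                              function(e) paste(sort(e), collapse = "-"))
    expect_true(all(eset(sub_small) %in% eset(sub_big)))     # monotone
    expect_equal(eset(induced_subnetwork(sub_small, p_small)),
                 eset(sub_small))                            # idempotent
  }
})

test_that("venn partition assigns exactly the lines where a protein is specific", {
  cm <- tiny_count_matrix()
  enr <- call_specific(compute_enrichment(cm, pseudocount = 0), 1.82)
  venn <- venn_partition(enr)
  expect_equal(venn$venn_set[venn$accession == "TLN1"], "A4+X4C0+A4P_A5L")
  expect_equal(venn$venn_set[venn$accession == "MYO18A"], "X4C0")
  expect_false("ACTB" %in% venn$accession)       # specific nowhere
  expect_false("HSPA9" %in% venn$accession)
  # partition invariant: disjoint sets whose union is the specific universe
  expect_equal(anyDuplicated(venn$accession), 0L)
  expect_setequal(venn$accession, specific_proteins(enr))

  enr_partial <- enr[enr$cell_line != "X4C0", ]
  expect_error(venn_partition(enr_partial), "X4C0")
  enr_nocall <- compute_enrichment(cm)
  expect_error(venn_partition(enr_nocall), "call_specific")
})

test_that("gene-set filtering intersects by symbol", {
  gs <- structure(list(name = "adh", members = c("TLN1", "VCL", "PXN")),
                  class = "GeneSet")
  expect_setequal(geneset_filter(c("TLN1", "MYO18A", "PXN"), gs),
                  c("TLN1", "PXN"))
  expect_length(geneset_filter(c("AAA", "BBB"), gs), 0)
})

test_that("localization rollup matches a brute-force closure oracle", {
  roots <- localization_roots()
  # direct root annotation and child rollup
  gaf <- data.frame(gene = c("G1", "G2", "G3"),
                    term = c("GO:0030054", "CHILD_IC", "TERM:OTHER"))
  rel <- data.frame(child = c("CHILD_IC", "TERM:OTHER"),
                    parent = c("GO:0005622", "UNRELATED"))
  # make all root ids known terms
  gaf <- rbind(gaf, data.frame(gene = "G0",
                               term = unlist(roots, use.names = FALSE)))
  ann <- term_annotation(gaf, rel)
  loc <- annotate_localization(c("G1", "G2", "G3", "G9"), ann)
  expect_equal(loc$G1, "cell_periphery")
  expect_equal(loc$G2, "intracellular")
  expect_length(loc$G3, 0)
  expect_length(loc$G9, 0)                       # unannotated
  expect_error(annotate_localization(
    "G1", ann, category_roots = list(x = "GO:9999999")), "unknown")

  # random DAGs of <= 50 terms against transitive-closure oracle
  set.seed(31)
  for (i in 1:20) {
    nt <- sample(10:50, 1)
    terms <- paste0("T", seq_len(nt))
    # parents only with higher index: guaranteed acyclic
    rel <- do.call(rbind, lapply(seq_len(nt - 1), function(ch) {
      np <- rbinom(1, 2, 0.4)
      if (np == 0) return(NULL)
      higher <- terms[(ch + 1):nt]   # parents above the child: acyclic
      data.frame(child = terms[ch],
                 parent = higher[sample.int(length(higher),
                                            min(np, length(higher)))])
    }))
    genes <- paste0("G", 1:30)
    gaf <- data.frame(gene = sample(genes, 60, replace = TRUE),
                      term = sample(terms, 60, replace = TRUE))
    # a dummy gene carrying every term keeps the whole term universe known
    ann <- term_annotation(rbind(gaf, data.frame(gene = "GDUMMY",
                                                 term = terms)), rel)
    n_roots <- sample(1:3, 1)
    cats <- list(catA = sample(terms, n_roots), catB = sample(terms, 2))
    got <- annotate_localization(genes, ann, category_roots = cats)
    clo <- oracle_closure(terms, ann$relations)
    for (g in genes) {
      ts <- unique(gaf$term[gaf$gene == g])
      want <- names(cats)[vapply(cats, function(r) {
        # gene has the category iff one of its terms reaches a root
        any(clo[ts, r, drop = FALSE])
      }, logical(1))]
      expect_setequal(got[[g]], want)
    }
  }
})

test_that("planted modules are denser than degree-preserving rewirings", {
  cfg <- small_sim_config(seed = 9)
  sim <- simulate_counts(cfg)
  el <- simulate_interactome(cfg, sim$truth)
  g <- merge_interactomes(el)
  planted <- sim$truth$accession[sim$truth$label == "A4+X4C0+A4P_A5L"]
  obs <- igraph::ecount(induced_subnetwork(g, planted))
  set.seed(77)
  null_counts <- replicate(100, {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 20 *
                                                     igraph::ecount(g)))
    igraph::ecount(induced_subnetwork(gr, planted))
  })
  expect_gte(mean(obs > null_counts), 0.95)
})
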