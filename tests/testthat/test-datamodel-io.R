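test_that("count tables parse, validate and round-trip bit-exactly", {
  design <- sample_design(c("s1", "s2", "s3", "s4"),
                          c("A4", "A4", "A4", "A4"),
                          c("BAIT", "BAIT", "CONTROL", "CONTROL"),
                          c(1, 2, 1, 2))
  path <- write_lines_tmp(c(
    "# comment line",
    "accession\tgene_symbol\ts1\ts2\ts3\ts4",
    "P1\ttln1\t4\t6\t1\t1",
    "P2\tACTB\t0\t0\t0\t0",
    "P3\tMSN\t9\t11\t2\t2"))
  cm <- read_count_table(path, design)
  expect_equal(dim(cm), c(3L, 4L))
  expect_equal(unname(cm$counts["P1", ]), c(4, 6, 1, 1))
  expect_equal(cm$proteins$gene_symbol[1], "TLN1")  # upper-cased on load

  out <- tempfile(fileext = ".tsv")
  write_count_table(cm, out)
  cm2 <- read_count_table(out, design)
  expect_identical(cm2$counts, cm$counts)

  # row order does not matter
  lines <- readLines(path)
  shuffled <- write_lines_tmp(lines[c(1, 2, 5, 3, 4)])
  cm3 <- read_count_table(shuffled, design)
  expect_identical(cm3$counts[rownames(cm$counts), ], cm$counts)
})

test_that("count-table contract violations fail with informative errors", {
  design <- sample_design(c("s1", "s2"), c("A4", "A4"),
                          c("BAIT", "CONTROL"), c(1, 1))
  expect_error(
    read_count_table(write_lines_tmp(c("accession\ts1", "P1\t3")), design),
    "s2")
  expect_error(
    read_count_table(write_lines_tmp(
      c("accession\ts1\ts2", "P1\t3\t1", "P1\t4\t1")), design),
    "duplicate accession.*P1")
  expect_error(
    read_count_table(write_lines_tmp(
      c("accession\ts1\ts2", "P1\t3\t1", "P2\t-2\t1")), design),
    "row 2")
  expect_error(
    read_count_table(write_lines_tmp(
      c("accession\ts1\ts2", "P1\t3.5\t1")), design),
    "non-integer")
})

test_that("sample design invariants are enforced", {
  expect_error(sample_design(c("a", "a"), c("A4", "A4"),
                             c("BAIT", "CONTROL"), c(1, 1)),
               "duplicate sample_id")
  expect_error(sample_design("a", "K562", "BAIT", 1), "unknown cell_line")
  expect_error(sample_design(c("a", "b"), c("A4", "A4"),
                             c("BAIT", "BAIT"), c(1, 2)),
               "CONTROL")
})

test_that("region maps parse and reject bad intervals", {
  rm <- read_region_map(write_lines_tmp(c(
    "accession\tregion_name\tstart\tend",
    "ITGA4\tpropeller\t1\t438",
    "ITGA4\tleg\t439\t700")))
  expect_named(rm, "ITGA4")
  expect_equal(rm$ITGA4$region_name, c("propeller", "leg"))

  expect_error(read_region_map(write_lines_tmp(c(
    "accession\tregion_name\tstart\tend", "A\tx\t10\t5"))),
    "invalid region interval")
  expect_error(read_region_map(write_lines_tmp(c(
    "accession\tregion_name\tstart\tend",
    "A\tx\t1\t10", "A\ty\t10\t20"))),
    "overlapping regions")
})

test_that("edge lists parse SIF and TSV forms, dropping self-loops", {
  sif <- read_edge_list(write_lines_tmp(c("TLN1 pp ITGB1", "A pp A")),
                        source_tag = "db1")
  expect_equal(nrow(sif), 1)
  expect_equal(sif$gene_a, "TLN1")
  expect_equal(sif$source, "db1")

  tsv <- read_edge_list(write_lines_tmp(c("itga4\titgb1\tbiogrid")))
  expect_equal(tsv$gene_a, "ITGA4")   # upper-cased
  expect_equal(tsv$source, "biogrid")

  expect_error(read_edge_list(write_lines_tmp(c("TLN1 pp ITGB1",
                                                "just_one_field"))),
               "line 2")
})

test_that("gene sets load upper-cased and non-empty", {
  gs <- read_gene_set(write_lines_tmp(c("# adhesome-like", "tln1", "VCL")),
                      name = "adh")
  expect_s3_class(gs, "GeneSet")
  expect_setequal(gs$members, c("TLN1", "VCL"))
  expect_error(read_gene_set(write_lines_tmp("# only a comment")), "empty")
})

test_that("annotations roll up through relations and reject cycles", {
  gaf <- write_lines_tmp(c("gene\tterm", "G1\tGO:0030054", "G2\tGO:0071944"))
  rel <- write_lines_tmp(c("child\tparent", "GO:0030054\tGO:0071944"))
  ann <- read_annotations(gaf, rel)
  anc <- term_ancestors(ann, "GO:0030054")[[1]]
  expect_setequal(anc, c("GO:0030054", "GO:0071944"))

  # empty relations: rollup is the identity
  ann0 <- read_annotations(gaf, write_lines_tmp("child\tparent"))
  expect_equal(term_ancestors(ann0, "GO:0030054")[[1]], "GO:0030054")

  cyc <- write_lines_tmp(c("child\tparent", "A\tB", "B\tC", "C\tA"))
  expect_error(read_annotations(gaf, cyc), "cycle")
})
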