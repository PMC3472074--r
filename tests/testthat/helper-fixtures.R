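# Small in-code fixtures shared across test files.

tiny_design <- function() {
  sample_design(
    sample_id = c("A4_B1", "A4_B2", "A4_C1", "A4_C2",
                  "X4C0_B1", "X4C0_B2", "X4C0_C1", "X4C0_C2",
                  "P_B1", "P_B2", "P_C1", "P_C2"),
    cell_line = rep(c("A4", "X4C0", "A4P_A5L"), each = 4),
    condition = rep(c("BAIT", "BAIT", "CONTROL", "CONTROL"), 3),
    replicate = rep(c(1, 2, 1, 2), 3))
}

# deterministic 4-protein count matrix over the tiny design
tiny_count_matrix <- function() {
  design <- tiny_design()
  counts <- rbind(
    TLN1  = c(17, 17, 1, 3, 8, 8, 1, 3, 4, 4, 1, 3),
    ACTB  = c(5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5),
    HSPA9 = c(1, 1, 40, 40, 2, 2, 38, 42, 1, 1, 40, 40),
    MYO18A = c(0, 0, 1, 1, 30, 34, 1, 1, 0, 2, 1, 1))
  colnames(counts) <- design$sample_id
  count_matrix(counts, design)
}

# a small config that keeps simulation-driven tests fast
small_sim_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_proteins = 90L, planted_per_region = 6L,
                    n_background = 12L, n_reagent = 4L,
                    edge_prob_background = 0.03, ...)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
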