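# Shared in-code fixtures for the test suite.  Everything is generated
# programmatically under fixed seeds; no data files are read.

# Small mapped genome: a few chromosomes, evenly spaced markers.
toy_map <- function(n_markers = 120, n_chrom = 4, len = 100) {
  uniform_map(n_markers, n_chromosomes = n_chrom, chrom_length_cM = len)
}

# One simulated DH population plus its founders and plan.
toy_population <- function(n_markers = 150, n_parents = 16, n_crosses = 8,
                           lines_per_cross = 5:6, line_type = "DH",
                           seed = 42, id = "pop1") {
  map <- toy_map(n_markers)
  f <- simulate_founders(n_parents, map,
                         list(dist = "uniform", min = 0.1, max = 0.9),
                         seed = seed)
  plan <- random_cross_plan(f, n_crosses, lines_per_cross,
                            line_type = line_type, seed = seed + 1)
  pop <- simulate_population(f, plan, seed = seed + 2, population_id = id)
  list(map = map, founders = f, plan = plan, pop = pop)
}

# Two populations sharing the same founder panel and marker set, as in a
# cross-population prediction setting.
toy_population_pair <- function(n_markers = 300, n_parents = 30, seed = 7,
                                n_crosses = 12, lines_per_cross = 6:8) {
  map <- toy_map(n_markers, n_chrom = 5)
  f <- simulate_founders(n_parents, map,
                         list(dist = "uniform", min = 0.1, max = 0.9),
                         seed = seed)
  p1 <- simulate_population(
    f, random_cross_plan(f, n_crosses, lines_per_cross, "DH", seed = seed + 1),
    seed = seed + 2, population_id = "A")
  p2 <- simulate_population(
    f, random_cross_plan(f, n_crosses, lines_per_cross, "DH", seed = seed + 3),
    seed = seed + 4, population_id = "B")
  list(map = map, founders = f, pop1 = p1, pop2 = p2)
}

# Balanced augmented-design phenotype table: `n_lines` unreplicated test
# lines spread over `n_blocks` sub-blocks, plus `n_controls` controls
# repeated in every block, with known block offsets added.
toy_field_trial <- function(n_lines = 24, n_blocks = 3, n_controls = 2,
                            block_offsets = c(2, -2, 0), sigma = 0,
                            location = "loc1", trait = "tw", seed = 11) {
  set.seed(seed)
  g_test <- stats::setNames(stats::rnorm(n_lines, 10, 1),
                            sprintf("L%02d", seq_len(n_lines)))
  g_ctl <- stats::setNames(stats::rnorm(n_controls, 10, 1),
                           sprintf("C%d", seq_len(n_controls)))
  blk_of_line <- rep(seq_len(n_blocks), length.out = n_lines)
  rec_line <- c(names(g_test), rep(names(g_ctl), each = n_blocks))
  rec_block <- c(blk_of_line, rep(seq_len(n_blocks), n_controls))
  rec_ctl <- c(rep(FALSE, n_lines), rep(TRUE, n_controls * n_blocks))
  truth <- c(g_test, g_ctl)[rec_line]
  value <- truth + block_offsets[rec_block] +
    stats::rnorm(length(truth), 0, sigma)
  list(tab = phenotype_table(rec_line, location, paste0("b", rec_block),
                             rec_ctl, trait, value),
       genotype_values = c(g_test, g_ctl),
       block_offsets = block_offsets)
}
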