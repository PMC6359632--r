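# Shared fixtures and independent oracles for the test suite.

# Small hand-built matrix: 3 proteins, 2 groups x 2 runs.
toy_matrix <- function() {
  counts <- matrix(c(10, 0, 5,
                     12, 0, 7,
                     20, 3, 0,
                     18, 5, 0),
                   nrow = 3,
                   dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  proteins <- tibble::tibble(
    accession = c("P1", "P2", "P3"),
    gene = c("G1", "G2", "G3"),
    description = c("one", "two", "three"),
    length = c(100L, 200L, 400L)
  )
  design <- tibble::tibble(
    run_id = c("a1", "a2", "b1", "b2"),
    group = c("gA", "gA", "gB", "gB"),
    replicate = c(1L, 2L, 1L, 2L)
  )
  spectral_counts(counts, proteins, design)
}

# Random spectral_counts for property-style tests.
random_matrix <- function(n_proteins, n_runs, seed) {
  withr::with_seed(seed, {
    counts <- matrix(stats::rpois(n_proteins * n_runs, 20),
                     nrow = n_proteins)
    # guard against an all-zero run
    counts[1, ] <- counts[1, ] + 1
    proteins <- tibble::tibble(
      accession = sprintf("P%03d", seq_len(n_proteins)),
      gene = sprintf("G%03d", seq_len(n_proteins)),
      description = "random",
      length = sample(100:1000, n_proteins, replace = TRUE)
    )
    design <- tibble::tibble(
      run_id = sprintf("r%02d", seq_len(n_runs)),
      group = rep(c("gA", "gB"), length.out = n_runs),
      replicate = as.integer(ceiling(seq_len(n_runs) / 2))
    )
    spectral_counts(counts, proteins, design)
  })
}

# Brute-force pooled-variance two-sample t-test, written from the textbook
# formula and kept independent of the package (and of stats::t.test).
pooled_t_oracle <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
}

neat_fixture <- function() {
  read_dep_summary(nsafdep_example("neat_comparison"))
}

processed_fixture <- function() {
  read_dep_summary(nsafdep_example("processed_comparison"))
}

control_fixture <- function() {
  read_dep_summary(nsafdep_example("control_comparison"))
}

# Full fixture run: pseudo-replicates + published ratios + decoys.
fixture_dep_result <- function(tab, group_ref, group_cmp, n_decoys = 0) {
  fx <- pseudo_replicate_counts(tab, group_ref, group_cmp,
                                n_decoys = n_decoys)
  call_dep_table(fx$counts, group_ref, group_cmp,
                 ratio_override = fx$ratio_override)
}
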