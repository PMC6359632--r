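test_that("count matrix TSV round trip preserves counts exactly", {
  x <- toy_matrix()
  dir <- withr::local_tempdir()
  cpath <- file.path(dir, "counts.tsv")
  dpath <- file.path(dir, "design.tsv")
  write_count_matrix(x, cpath, dpath)
  y <- read_count_matrix(cpath, dpath)

  expect_identical(unname(y$counts), unname(x$counts))
  expect_equal(y$proteins, x$proteins)
  expect_equal(y$design, x$design)

  # writing the re-read object reproduces the files byte for byte
  cpath2 <- file.path(dir, "counts2.tsv")
  dpath2 <- file.path(dir, "design2.tsv")
  write_count_matrix(y, cpath2, dpath2)
  expect_identical(readLines(cpath2), readLines(cpath))
  expect_identical(readLines(dpath2), readLines(dpath))
})

test_that("malformed count inputs are rejected with input errors", {
  dir <- withr::local_tempdir()
  dpath <- file.path(dir, "design.tsv")
  writeLines(c("run_id\tgroup\treplicate", "N1\tg1\t1"), dpath)

  dup <- file.path(dir, "dup.tsv")
  writeLines(c("accession\tgene\tdescription\tlength\tN1",
               "P02788\tLTF\tx\t710\t3",
               "P02788\tLTF\tx\t710\t4"), dup)
  expect_error(read_count_matrix(dup, dpath), class = "nsafdep_input_error")

  neg <- file.path(dir, "neg.tsv")
  writeLines(c("accession\tgene\tdescription\tlength\tN1",
               "P02788\tLTF\tx\t710\t-3"), neg)
  expect_error(read_count_matrix(neg, dpath), class = "nsafdep_input_error")

  orphan <- file.path(dir, "orphan.tsv")
  writeLines(c("accession\tgene\tdescription\tlength\tN1\tN9",
               "P02788\tLTF\tx\t710\t3\t4"), orphan)
  expect_error(read_count_matrix(orphan, dpath),
               class = "nsafdep_input_error")
})

test_that("bundled comparison tables load with the expected row counts", {
  expect_equal(nrow(neat_fixture()), 26)
  expect_equal(nrow(processed_fixture()), 6)
  expect_equal(nrow(control_fixture()), 26)
})

test_that("FASTA lengths are parsed for UniProt and bare headers", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "seqs.fasta")
  writeLines(c(
    ">sp|P02788|TRFL_HUMAN Lactotransferrin",
    strrep("A", 50),
    ">Q12345 some description",
    paste(strrep("M", 10), strrep("K", 10), sep = "")
  ), fa)
  lens <- read_lengths_fasta(fa)
  expect_equal(lens$length[lens$accession == "P02788"], 50)
  expect_equal(lens$length[lens$accession == "Q12345"], 20)

  dup <- file.path(dir, "dup.fasta")
  writeLines(c(">sp|P02788|TRFL_HUMAN", "AAA", ">P02788", "CCC"), dup)
  expect_error(read_lengths_fasta(dup), class = "nsafdep_input_error")

  empty <- file.path(dir, "empty.fasta")
  writeLines(character(0), empty)
  expect_error(read_lengths_fasta(empty))
})

test_that("identification filter applies strict probability cutoffs", {
  recs <- tibble::tibble(
    accession = c("A", "B", "C", "D", "E"),
    protein_probability = c(0.95, 0.99, 0.90, 0.95, 0.95),
    n_peptides = c(2L, 1L, 5L, 2L, 2L),
    peptide_probability = c(0.99, 0.99, 0.99, 0.95, 0.96)
  )
  got <- filter_identifications(recs)$accession
  # B: one peptide; C: protein prob not strictly above 0.90;
  # D: peptide prob not strictly above 0.95
  expect_setequal(got, c("A", "E"))
  expect_equal(nrow(filter_identifications(recs[0, ])), 0)
})

test_that("identification filter is monotone and order-invariant", {
  withr::with_seed(42, {
    recs <- tibble::tibble(
      accession = sprintf("P%03d", 1:200),
      protein_probability = round(stats::runif(200), 2),
      n_peptides = sample(0:5, 200, replace = TRUE),
      peptide_probability = round(stats::runif(200), 2)
    )
    strict <- filter_identifications(recs)$accession
    for (relax in list(
      list(min_peptides = 1),
      list(min_protein_prob = 0.5),
      list(min_peptide_prob = 0.5),
      list(min_peptides = 0, min_protein_prob = 0, min_peptide_prob = 0)
    )) {
      loose <- do.call(filter_identifications, c(list(recs), relax))$accession
      expect_true(all(strict %in% loose))
    }
    shuffled <- recs[sample.int(nrow(recs)), ]
    expect_setequal(filter_identifications(shuffled)$accession, strict)
  })
})
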