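#' Read a spectral-count matrix and its run design from TSV
#'
#' The count file is tab-separated with a header row and columns
#' `accession`, `gene`, `description`, `length`, followed by one numeric
#' column per run. The design file maps `run_id` to `group` and `replicate`.
#' Run order in the returned object follows the design file.
#'
#' @param path Path to the count TSV.
#' @param design_path Path to the design TSV (`run_id`, `group`, `replicate`).
#' @return A [spectral_counts] object.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines(c("accession\tgene\tdescription\tlength\tN1\tN2",
#'              "P02788\tLTF\tLactotransferrin\t710\t12\t15"),
#'            file.path(dir, "counts.tsv"))
#' writeLines(c("run_id\tgroup\treplicate", "N1\tg1\t1", "N2\tg1\t2"),
#'            file.path(dir, "design.tsv"))
#' read_count_matrix(file.path(dir, "counts.tsv"), file.path(dir, "design.tsv"))
#' @export
read_count_matrix <- function(path, design_path) {
  tab <- read_tsv_strict(path)
  design <- read_tsv_strict(design_path)

  need <- c("accession", "gene", "description", "length")
  if (!all(need %in% names(tab))) {
    abort_input("count file must start with columns ",
                paste(need, collapse = ", "))
  }
  need_d <- c("run_id", "group", "replicate")
  if (!all(need_d %in% names(design))) {
    abort_input("design file must have columns ",
                paste(need_d, collapse = ", "))
  }
  run_cols <- setdiff(names(tab), need)
  if (length(run_cols) == 0) abort_input("count file has no run columns")
  missing_runs <- setdiff(run_cols, design$run_id)
  if (length(missing_runs) > 0) {
    abort_input("run(s) absent from design: ",
                paste(missing_runs, collapse = ", "))
  }
  extra_runs <- setdiff(design$run_id, run_cols)
  if (length(extra_runs) > 0) {
    abort_input("design run(s) absent from count file: ",
                paste(extra_runs, collapse = ", "))
  }

  counts <- as.matrix(tab[, design$run_id, drop = FALSE])
  if (!is.numeric(counts)) abort_input("run columns must be numeric")
  design$replicate <- as.integer(design$replicate)
  spectral_counts(counts, tab[, need], design)
}

#' Write a spectral-count matrix and design back to TSV
#'
#' Inverse of [read_count_matrix()]; a read -> write -> read round trip
#' reproduces counts exactly.
#'
#' @param x A [spectral_counts] object.
#' @param path,design_path Output paths for the count and design TSVs.
#' @return `x`, invisibly.
#' @export
write_count_matrix <- function(x, path, design_path) {
  tab <- dplyr::bind_cols(x$proteins,
                          tibble::as_tibble(x$counts, .name_repair = "minimal"))
  readr::write_tsv(tab, path)
  readr::write_tsv(x$design, design_path)
  invisible(x)
}

#' Protein sequence lengths from a FASTA file
#'
#' Lengths supply the L in NSAF = (SC/L) / sum(SC/L). The accession is the
#' first whitespace-delimited token of each header; UniProt-style
#' `sp|ACC|NAME` / `tr|ACC|NAME` headers are reduced to the central accession,
#' bare-accession headers are taken as-is.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return A tibble with columns `accession` and `length` (residues).
#' @export
read_lengths_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort_input("FASTA file '", path, "' has no records")
  first_tok <- sub("\\s.*$", "", names(seqs))
  acc <- ifelse(grepl("^(sp|tr)\\|", first_tok),
                vapply(strsplit(first_tok, "\\|"), `[`, "", 2),
                first_tok)
  if (anyDuplicated(acc)) {
    dup <- unique(acc[duplicated(acc)])
    abort_input("duplicate accession(s) in FASTA: ",
                paste(dup, collapse = ", "))
  }
  tibble::tibble(accession = acc,
                 length = Biostrings::width(seqs))
}

#' Read protein identification records
#'
#' Expects a TSV with columns `accession`, `protein_probability`,
#' `n_peptides`, `peptide_probability` — the per-protein summary that protein
#' validation software (e.g. Scaffold running the Peptide/Protein Prophet
#' models) exports. The probability models themselves are out of scope here;
#' their outputs are consumed as plain fields.
#'
#' @param path Path to the identification TSV.
#' @return A tibble of identification records.
#' @export
read_identifications <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("accession", "protein_probability", "n_peptides",
            "peptide_probability")
  if (!all(need %in% names(tab))) {
    abort_input("identification file must have columns ",
                paste(need, collapse = ", "))
  }
  bad <- with(tab, protein_probability < 0 | protein_probability > 1 |
                peptide_probability < 0 | peptide_probability > 1)
  if (any(bad, na.rm = TRUE) || anyNA(tab[need[-1]])) {
    abort_input("probabilities must lie in [0, 1] and fields must be complete")
  }
  tibble::as_tibble(tab[need])
}

#' Filter identifications by probability and peptide-count thresholds
#'
#' A protein is accepted when its protein-level probability exceeds
#' `min_protein_prob` (strictly — a probability of exactly 0.90 is rejected
#' under the default ">90%" rule), it has at least `min_peptides` distinct
#' identified peptides, and its best peptide-level probability strictly
#' exceeds `min_peptide_prob`. Defaults correspond to the common
#' ">90% protein probability, >= 2 peptides, >95% peptide probability"
#' acceptance rule giving a protein FDR below 1%.
#'
#' @param records Data frame of identification records
#'   (see [read_identifications()]).
#' @param min_peptides Minimum number of distinct peptides (inclusive).
#' @param min_protein_prob Protein-probability threshold (exclusive).
#' @param min_peptide_prob Peptide-probability threshold (exclusive).
#' @return The accepted rows of `records`, as a tibble. The accepted
#'   accession set is `$accession` of the result.
#' @examples
#' recs <- tibble::tibble(
#'   accession = c("A", "B"),
#'   protein_probability = c(0.95, 0.99),
#'   n_peptides = c(2L, 1L),
#'   peptide_probability = c(0.99, 0.99))
#' filter_identifications(recs)$accession  # "A": B has only one peptide
#' @export
filter_identifications <- function(records,
                                   min_peptides = 2,
                                   min_protein_prob = 0.90,
                                   min_peptide_prob = 0.95) {
  records <- tibble::as_tibble(records)
  keep <- records$protein_probability > min_protein_prob &
    records$n_peptides >= min_peptides &
    records$peptide_probability > min_peptide_prob
  records[keep, , drop = FALSE]
}

read_tsv_strict <- function(path) {
  if (!file.exists(path)) abort_input("file not found: ", path)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
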