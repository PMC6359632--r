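#' Normalized spectral abundance factor for one run
#'
#' NSAF_i = (SC_i / L_i) / sum_j (SC_j / L_j): each protein's spectral count
#' is divided by its sequence length (longer proteins yield more tryptic
#' peptides and hence more spectra at equal molar abundance) and the
#' length-corrected counts are renormalized to sum to one within the run.
#'
#' @param counts Non-negative numeric vector of spectral counts for one run.
#' @param lengths Positive integer vector of protein lengths (amino acids),
#'   same order as `counts`. A missing length is only an error if that protein
#'   carries counts: silent drops would change the NSAF denominator for every
#'   other protein.
#' @return Numeric vector of NSAF values summing to 1; zero exactly where the
#'   count is zero.
#' @examples
#' compute_nsaf(c(10, 20), c(100, 100))  # 1/3, 2/3
#' @export
compute_nsaf <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    abort_input("`counts` and `lengths` must have the same length")
  }
  if (anyNA(counts) || any(counts < 0)) {
    abort_input("counts must be non-negative")
  }
  needs_len <- counts > 0
  if (any(is.na(lengths[needs_len]))) {
    abort_input("missing sequence length for protein(s) with nonzero counts")
  }
  if (any(lengths[needs_len] < 1)) {
    abort_input("lengths must be >= 1")
  }
  if (all(counts == 0)) {
    abort_input("all-zero run: NSAF normalization is degenerate")
  }
  saf <- ifelse(needs_len, counts / lengths, 0)
  saf / sum(saf)
}

#' Per-run NSAF values for a whole matrix
#'
#' @param x A [spectral_counts] object.
#' @return A numeric matrix of the same shape as `x$counts`, each column
#'   (run) summing to 1.
#' @export
nsaf_matrix <- function(x) {
  m <- vapply(seq_len(ncol(x$counts)),
              function(j) compute_nsaf(x$counts[, j], x$proteins$length),
              numeric(nrow(x$counts)))
  m <- matrix(m, nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  m
}

#' Group-mean NSAF vector
#'
#' NSAF is computed per run, then averaged arithmetically over the group's
#' technical replicates.
#'
#' @param x A [spectral_counts] object.
#' @param group Group label present in the design.
#' @return A tibble with columns `accession` and `mean_nsaf`.
#' @export
group_mean_nsaf <- function(x, group) {
  runs <- group_runs(x, group)
  nsaf <- nsaf_matrix(x)[, runs, drop = FALSE]
  tibble::tibble(accession = rownames(x$counts),
                 mean_nsaf = unname(rowMeans(nsaf)))
}

#' NSAF ratio, comparison over reference
#'
#' Oriented as comparison-group mean divided by reference-group mean, so a
#' protein more abundant in the comparison group has ratio > 1. The ratio is
#' 0 when the protein is absent from the comparison group and `Inf` when
#' absent from the reference group only.
#'
#' @param mean_ref,mean_cmp Non-negative group-mean NSAF (or any abundance)
#'   values; vectors recycle as usual.
#' @return `mean_cmp / mean_ref` with the zero conventions above.
#' @export
nsaf_ratio <- function(mean_ref, mean_cmp) {
  if (any(mean_ref < 0 | mean_cmp < 0, na.rm = TRUE)) {
    abort_input("means must be non-negative")
  }
  if (any(mean_ref == 0 & mean_cmp == 0)) {
    abort_input("ratio undefined when both means are zero")
  }
  ifelse(mean_cmp == 0, 0,
         ifelse(mean_ref == 0, Inf, mean_cmp / mean_ref))
}
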