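#' Spectral-count matrix with run design
#'
#' Bundles a proteins-by-runs matrix of spectral counts with per-protein
#' metadata and the run design (which LC-MS/MS run belongs to which group and
#' technical replicate). Counts are stored as non-negative reals rather than
#' integers because published summary tables often report triplicate means
#' (e.g. a mean spectral count of 26.3); simulated per-run counts are integers
#' but share the container.
#'
#' @param counts Numeric matrix, proteins x runs, all entries `>= 0`.
#'   Row names (if any) must agree with `proteins$accession`.
#' @param proteins Data frame with columns `accession`, `gene`, `description`,
#'   `length`. Accessions must be unique; isoform-suffixed accessions (e.g.
#'   `"P05023-4"`) are distinct proteins and are never collapsed to their
#'   canonical accession. `length` is the sequence length in amino acids and
#'   may be `NA` where unknown (NSAF computation then fails loudly for any
#'   such protein that carries counts).
#' @param design Data frame with columns `run_id`, `group`, `replicate`;
#'   `(group, replicate)` pairs must be unique and `run_id` must match the
#'   column order of `counts`.
#'
#' @return An object of class `spectral_counts`.
#' @seealso [read_count_matrix()], [tidy.spectral_counts()]
#' @export
spectral_counts <- function(counts, proteins, design) {
  proteins <- tibble::as_tibble(proteins)
  design <- tibble::as_tibble(design)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"

  need_p <- c("accession", "gene", "description", "length")
  if (!all(need_p %in% names(proteins))) {
    abort_input("`proteins` must have columns ",
                paste(need_p, collapse = ", "))
  }
  need_d <- c("run_id", "group", "replicate")
  if (!all(need_d %in% names(design))) {
    abort_input("`design` must have columns ", paste(need_d, collapse = ", "))
  }
  if (anyDuplicated(proteins$accession)) {
    dup <- unique(proteins$accession[duplicated(proteins$accession)])
    abort_input("duplicate accession(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(design$run_id)) {
    abort_input("duplicate run_id in design")
  }
  if (anyDuplicated(design[, c("group", "replicate")])) {
    abort_input("duplicate (group, replicate) pair in design")
  }
  if (nrow(counts) != nrow(proteins) || ncol(counts) != nrow(design)) {
    abort_input("count matrix dimensions (", nrow(counts), " x ", ncol(counts),
                ") do not match proteins (", nrow(proteins),
                ") and design (", nrow(design), ")")
  }
  if (anyNA(counts) || any(counts < 0)) {
    abort_input("counts must be non-negative and non-missing")
  }
  bad_len <- !is.na(proteins$length) & proteins$length < 1
  if (any(bad_len)) {
    abort_input("protein length must be >= 1 amino acid")
  }
  dimnames(counts) <- list(proteins$accession, design$run_id)

  structure(
    list(counts = counts, proteins = proteins, design = design),
    class = "spectral_counts"
  )
}

#' @export
print.spectral_counts <- function(x, ...) {
  cat("<spectral_counts> ", nrow(x$counts), " proteins x ",
      ncol(x$counts), " runs\n", sep = "")
  groups <- split(x$design$run_id, x$design$group)
  for (g in names(groups)) {
    cat("  group ", g, ": ", paste(groups[[g]], collapse = ", "), "\n",
        sep = "")
  }
  cat("  total counts per run: ",
      paste(format(round(colSums(x$counts), 1)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Long-format view of a spectral-count matrix
#'
#' @param x A [spectral_counts] object.
#' @param ... Unused.
#' @return A tibble with one row per protein x run: `accession`, `run_id`,
#'   `group`, `replicate`, `count`.
#' @export
tidy.spectral_counts <- function(x, ...) {
  long <- tibble::tibble(
    accession = rep(rownames(x$counts), times = ncol(x$counts)),
    run_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
  dplyr::left_join(long, x$design, by = "run_id")[
    , c("accession", "run_id", "group", "replicate", "count")
  ]
}

#' Runs belonging to one group
#' @noRd
group_runs <- function(x, group) {
  runs <- x$design$run_id[x$design$group == group]
  if (length(runs) == 0) {
    abort_input("group '", group, "' has no runs in the design")
  }
  runs
}

#' Mean spectral count per protein within a group
#' @noRd
group_mean_sc <- function(x, group) {
  runs <- group_runs(x, group)
  rowMeans(x$counts[, runs, drop = FALSE])
}

abort_input <- function(...) {
  rlang::abort(paste0(...), class = "nsafdep_input_error")
}
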