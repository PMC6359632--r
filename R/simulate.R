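#' Simulation configuration for spectral-count matrices
#'
#' Describes a two-group experiment of pooled samples run in technical
#' replicates. Each protein draws a relative molar abundance from a
#' log-normal law and a sequence length from a log-normal law clamped to
#' `[50, 5000]` amino acids; its expected spectral count in a run is
#' proportional to abundance x length (longer proteins yield more spectra —
#' exactly the bias NSAF removes), scaled so that each run's expected total
#' equals `depth`. A random subset of `n_dep` proteins carries a planted
#' fold change in the comparison group. Per-run counts are Poisson when
#' `dispersion = 0`, negative binomial with that overdispersion otherwise,
#' and counts below `detection_floor` are zeroed — a crude stand-in for the
#' "at least two identified peptides" acceptance rule, not a peptide model.
#'
#' @param n_proteins Number of proteins.
#' @param n_dep Number of proteins with a planted fold change
#'   (`<= n_proteins`).
#' @param fold_changes Positive fold changes assigned to planted proteins
#'   (recycled/sampled over the DEP subset; values below 1 plant
#'   underexpression in the comparison group).
#' @param depth Expected total spectral counts per run.
#' @param n_replicates Technical replicates per group.
#' @param dispersion Negative-binomial overdispersion; 0 means Poisson.
#'   Technical replicates of a pooled sample mostly carry instrument noise,
#'   so Poisson is the default.
#' @param length_meanlog,length_sdlog Log-normal parameters for protein
#'   length (amino acids), clamped to `[50, 5000]`.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters for
#'   relative molar abundance. The default `sdlog = 2` gives the several
#'   orders of magnitude of dynamic range typical of a cellular proteome.
#' @param detection_floor Per-run counts below this are set to 0 (default 2).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(n_proteins,
                       n_dep = 0,
                       fold_changes = c(4, 0.25),
                       depth = 10000,
                       n_replicates = 3,
                       dispersion = 0,
                       length_meanlog = log(400),
                       length_sdlog = 0.6,
                       abundance_meanlog = 0,
                       abundance_sdlog = 2,
                       detection_floor = 2,
                       seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins), n_dep = as.integer(n_dep),
    fold_changes = as.numeric(fold_changes), depth = depth,
    n_replicates = as.integer(n_replicates), dispersion = dispersion,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    detection_floor = detection_floor, seed = as.integer(seed)
  )
  if (cfg$n_proteins < 1) abort_input("n_proteins must be >= 1")
  if (cfg$n_dep < 0 || cfg$n_dep > cfg$n_proteins) {
    abort_input("n_dep must lie in [0, n_proteins]")
  }
  if (cfg$n_dep > 0 &&
      (length(cfg$fold_changes) == 0 || any(cfg$fold_changes <= 0))) {
    abort_input("fold_changes must be positive")
  }
  if (!is.finite(cfg$depth) || cfg$depth <= 0) {
    abort_input("depth must be positive")
  }
  if (cfg$n_replicates < 1) abort_input("n_replicates must be >= 1")
  if (cfg$dispersion < 0) abort_input("dispersion must be >= 0")
  if (cfg$length_sdlog < 0 || cfg$abundance_sdlog < 0) {
    abort_input("sdlog parameters must be >= 0")
  }
  if (cfg$detection_floor < 0) abort_input("detection_floor must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a flat key=value file
#'
#' Lines of the form `key = value` (or `key<TAB>value`); `fold_changes` may
#' be a comma-separated list. Blank lines and `#` comments are ignored.
#'
#' @param path Path to the config file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*|\t")
  bad <- lengths(kv) != 2
  if (any(bad)) abort_input("malformed config line: ", lines[bad][1])
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  args <- lapply(vals, function(v) as.numeric(strsplit(v, ",")[[1]]))
  known <- names(formals(sim_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0) {
    abort_input("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, args)
}

#' Simulate a two-group spectral-count matrix with planted fold changes
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `counts` (a [spectral_counts] with groups
#'   `"group_ref"` and `"group_cmp"`, `n_replicates` runs each) and `truth`
#'   (a tibble `accession`, `is_dep`, `true_fold`).
#' @examples
#' sim <- simulate_counts(sim_config(n_proteins = 50, n_dep = 5, seed = 7))
#' sim$counts
#' dplyr::count(sim$truth, is_dep)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    acc <- sprintf("SIM%04d", seq_len(n))
    len <- pmin(pmax(round(stats::rlnorm(n, config$length_meanlog,
                                         config$length_sdlog)), 50), 5000)
    abun <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)

    fold <- rep(1, n)
    is_dep <- rep(FALSE, n)
    if (config$n_dep > 0) {
      idx <- sample.int(n, config$n_dep)
      is_dep[idx] <- TRUE
      # index-based sampling: sample(x, ...) on a length-1 numeric would
      # sample from 1:x instead of x
      pick <- sample.int(length(config$fold_changes), config$n_dep,
                         replace = TRUE)
      fold[idx] <- config$fold_changes[pick]
    }

    w_ref <- abun * len
    w_cmp <- abun * len * fold
    mu_ref <- config$depth * w_ref / sum(w_ref)
    mu_cmp <- config$depth * w_cmp / sum(w_cmp)

    draw <- function(mu) {
      if (config$dispersion == 0) {
        stats::rpois(length(mu), mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
      }
    }
    r <- config$n_replicates
    counts <- cbind(
      vapply(seq_len(r), function(j) draw(mu_ref), numeric(n)),
      vapply(seq_len(r), function(j) draw(mu_cmp), numeric(n))
    )
    counts[counts < config$detection_floor] <- 0

    design <- tibble::tibble(
      run_id = c(paste0("ref_N", seq_len(r)), paste0("cmp_N", seq_len(r))),
      group = rep(c("group_ref", "group_cmp"), each = r),
      replicate = rep(seq_len(r), 2)
    )
    proteins <- tibble::tibble(
      accession = acc, gene = acc,
      description = "simulated protein", length = as.integer(len)
    )
    list(
      counts = spectral_counts(counts, proteins, design),
      truth = tibble::tibble(accession = acc, is_dep = is_dep,
                             true_fold = fold)
    )
  })
}

#' Score classifier recovery of planted fold changes
#'
#' A planted protein counts as recovered only when it is called in the
#' direction of its true fold: overexpressed or unique-to-comparison for
#' `true_fold > 1`, underexpressed or unique-to-reference for
#' `true_fold < 1`. Any call on an unplanted protein — or a planted one in
#' the wrong direction — is a false call.
#'
#' @param calls A tibble of per-protein calls ([tidy.dep_result()]) or a
#'   `dep_result`.
#' @param truth The `truth` tibble from [simulate_counts()].
#' @return A list: `sensitivity` (recovered / planted), `fdp` (false calls /
#'   max(1, total calls)), and `confusion`, a per-governing-tier tibble of
#'   called/true-positive/false-positive counts.
#' @export
evaluate_recovery <- function(calls, truth) {
  if (inherits(calls, "dep_result")) calls <- tidy(calls)
  if (!setequal(calls$accession, truth$accession)) {
    abort_input("calls and truth must cover the same accessions")
  }
  d <- dplyr::left_join(calls, truth, by = "accession")
  up_calls <- c("overexpressed", "unique_to_cmp")
  down_calls <- c("underexpressed", "unique_to_ref")
  called <- d$call %in% c(up_calls, down_calls)
  right_dir <- (d$call %in% up_calls & d$true_fold > 1) |
    (d$call %in% down_calls & d$true_fold < 1)
  tp <- called & d$is_dep & right_dir
  fp <- called & !(d$is_dep & right_dir)

  n_dep <- sum(d$is_dep)
  confusion <- d |>
    dplyr::filter(called) |>
    dplyr::summarise(
      n_called = dplyr::n(),
      n_true_positive = sum(.data$is_dep &
                              ((.data$call %in% up_calls &
                                  .data$true_fold > 1) |
                                 (.data$call %in% down_calls &
                                    .data$true_fold < 1))),
      n_false_positive = .data$n_called - .data$n_true_positive,
      .by = "governing_tier"
    )

  list(
    sensitivity = if (n_dep > 0) sum(tp) / n_dep else NA_real_,
    fdp = sum(fp) / max(1, sum(called)),
    confusion = confusion
  )
}

#' Write simulated truth to TSV
#'
#' @param truth The `truth` tibble from [simulate_counts()].
#' @param path Output TSV path.
#' @return `truth`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(truth)
}
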