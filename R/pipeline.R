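#' Run the full spectral-counting comparison pipeline
#'
#' Orchestrates ingest -> identification filtering -> NSAF -> tiered DEP
#' calls -> technical-replicate QC -> optional control-proteome annotation,
#' and writes the report files. Progress and row counts are logged to
#' standard error via `message()`; errors are rethrown with the failing
#' stage's name so shell callers can exit non-zero with context.
#'
#' @param counts,design Paths to the count and design TSVs
#'   (see [read_count_matrix()]).
#' @param group_ref,group_cmp Reference and comparison group labels.
#' @param lengths Optional FASTA path; sequence lengths found there replace
#'   missing/placeholder lengths in the count file.
#' @param identifications Optional identification TSV
#'   (see [read_identifications()]); when given, only proteins passing
#'   [filter_identifications()] are kept.
#' @param control,control_design Optional paths to control-proteome count
#'   and design TSVs for [annotate_with_control()].
#' @param thresholds A [tier_thresholds()] tibble.
#' @param sd_type CV flavor for QC, see [cv_percent()].
#' @param out_dir Output directory (created if needed): `dep_report.tsv`,
#'   `qc_report.tsv`, `summary.json`, and `control_report.tsv` when a
#'   control is given.
#' @return Invisibly, a list with `dep` (`dep_result`), `qc` (`qc_summary`),
#'   `control` (`control_annotation` or `NULL`), and `files`.
#' @export
run_pipeline <- function(counts, design, group_ref, group_cmp,
                         lengths = NULL,
                         identifications = NULL,
                         control = NULL, control_design = NULL,
                         thresholds = tier_thresholds(),
                         sd_type = "sample",
                         out_dir = ".") {
  x <- with_stage("ingest", {
    m <- read_count_matrix(counts, design)
    message("ingest: ", nrow(m$counts), " proteins, ", ncol(m$counts),
            " runs")
    m
  })

  if (!is.null(lengths)) {
    x <- with_stage("lengths", {
      lens <- read_lengths_fasta(lengths)
      hit <- match(x$proteins$accession, lens$accession)
      x$proteins$length <- ifelse(is.na(hit), x$proteins$length,
                                  lens$length[hit])
      message("lengths: ", sum(!is.na(hit)), " accessions matched in FASTA")
      x
    })
  }

  if (!is.null(identifications)) {
    x <- with_stage("filter", {
      ids <- read_identifications(identifications)
      keep <- filter_identifications(ids)$accession
      sel <- x$proteins$accession %in% keep
      message("filter: ", sum(sel), " of ", length(sel),
              " proteins pass identification thresholds")
      spectral_counts(x$counts[sel, , drop = FALSE],
                      x$proteins[sel, , drop = FALSE], x$design)
    })
  }

  dep <- with_stage("dep", {
    d <- call_dep_table(x, group_ref, group_cmp, thresholds)
    message("dep: ", d$summary$n_dep, " DEPs among ",
            d$summary$n_proteins_union, " proteins (",
            round(d$summary$dep_fraction_percent, 2), "%)")
    d
  })

  qc <- with_stage("qc", {
    q <- qc_summary(x, dep, sd_type = sd_type)
    message("qc: verdict ", q$verdict)
    q
  })

  ctl_ann <- NULL
  if (!is.null(control)) {
    ctl_ann <- with_stage("control", {
      ctl <- read_count_matrix(control, control_design)
      a <- annotate_with_control(dep, ctl, thresholds)
      message("control: ", a$n_shared_all_three,
              " DEPs present in all three proteomes")
      a
    })
  }

  with_stage("report", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      dep_report = file.path(out_dir, "dep_report.tsv"),
      qc_report = file.path(out_dir, "qc_report.tsv"),
      summary = file.path(out_dir, "summary.json")
    )
    write_dep_report(dep, files[["dep_report"]])
    write_qc_report(qc, files[["qc_report"]])
    summary <- c(dep$summary,
                 list(verdict = qc$verdict,
                      max_cv_percent = suppressWarnings(
                        max(qc$per_group_cv$cv_percent, na.rm = TRUE))))
    if (!is.null(ctl_ann)) {
      files[["control_report"]] <- file.path(out_dir, "control_report.tsv")
      write_control_report(ctl_ann, files[["control_report"]])
      summary$n_shared_all_three <- ctl_ann$n_shared_all_three
    }
    jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                         digits = NA)
    message("report: wrote ", length(files), " files to ", out_dir)
    invisible(list(dep = dep, qc = qc, control = ctl_ann, files = files))
  })
}

#' Simulate a dataset and write it in the ingest TSV dialect
#'
#' @param config A [sim_config()] object or a path to a flat key=value
#'   config file (see [read_sim_config()]).
#' @param out_dir Output directory: `counts.tsv`, `design.tsv`, `truth.tsv`.
#' @param seed Optional integer overriding the config's seed.
#' @return Invisibly, the list from [simulate_counts()] plus `files`.
#' @export
simulate_pipeline <- function(config, out_dir = ".", seed = NULL) {
  with_stage("simulate", {
    if (is.character(config)) config <- read_sim_config(config)
    if (!is.null(seed)) {
      config$seed <- as.integer(seed)
    }
    sim <- simulate_counts(config)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      counts = file.path(out_dir, "counts.tsv"),
      design = file.path(out_dir, "design.tsv"),
      truth = file.path(out_dir, "truth.tsv")
    )
    write_count_matrix(sim$counts, files[["counts"]], files[["design"]])
    write_sim_truth(sim$truth, files[["truth"]])
    message("simulate: ", config$n_proteins, " proteins (",
            config$n_dep, " planted), seed ", config$seed)
    invisible(c(sim, list(files = files)))
  })
}

with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      rlang::abort(paste0("stage '", stage, "' failed: ",
                          conditionMessage(e)),
                   class = "nsafdep_stage_error", parent = e)
    }
  )
}
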