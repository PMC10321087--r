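# End-to-end orchestration: ingest (or simulate) -> clones -> dominant-clone
# summaries -> repertoire metrics -> overlap/turnover -> CDR3 clustering ->
# clinical associations, with every stage's table written to the output
# directory and a single machine-readable run summary.

#' Pipeline run configuration
#'
#' Bundles all pipeline parameters. Defaults follow the standard analysis
#' conventions: 0.5% dominance threshold, TIS >= 40 responder cutoff,
#' alpha = 0.05, top 100 shared clones for the cluster analysis.
#'
#' @param input_dir Directory of per-sample sequence TSVs plus
#'   `clinical.tsv`; `NULL` (default) simulates a cohort instead.
#' @param out_dir Output directory for stage tables and the run summary.
#' @param hec_threshold Dominance threshold (default 0.005).
#' @param cluster_mode Comparability mode for clustering (`"cdr3"` or
#'   `"stratified"`).
#' @param cluster_fallback Fallback Hamming threshold (default 0.15).
#' @param cluster_bandwidth Density bandwidth for threshold selection
#'   (default 0.02).
#' @param top_n Number of most expanded shared clones entering the
#'   per-patient cluster analysis (default 100).
#' @param alpha Significance level for the association panel (default 0.05).
#' @param tis_cutoff Responder cutoff on TIS (default 40).
#' @param seed Seed for all randomness in the run (simulation included).
#' @param cohort A [cohort_config()] used when simulating.
#' @return A `bcr_run_config` list.
#' @export
run_config <- function(input_dir = NULL, out_dir = tempfile("bcr_run_"),
                       hec_threshold = 0.005, cluster_mode = "cdr3",
                       cluster_fallback = 0.15, cluster_bandwidth = 0.02,
                       top_n = 100, alpha = 0.05, tis_cutoff = 40,
                       seed = 42L, cohort = cohort_config(seed = seed)) {
  check_threshold(hec_threshold)
  structure(
    list(
      input_dir = input_dir, out_dir = out_dir,
      hec_threshold = hec_threshold, cluster_mode = cluster_mode,
      cluster_fallback = cluster_fallback,
      cluster_bandwidth = cluster_bandwidth, top_n = as.integer(top_n),
      alpha = alpha, tis_cutoff = tis_cutoff, seed = as.integer(seed),
      cohort = cohort
    ),
    class = "bcr_run_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [run_config()].
#' @return A `bcr_run_config` (read) or `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  if (!is.null(cohort_args$subtype_mix)) {
    cohort_args$subtype_mix <- unlist(cohort_args$subtype_mix)
  }
  if (!is.null(cohort_args$antibody_mix)) {
    cohort_args$antibody_mix <- unlist(cohort_args$antibody_mix)
  }
  y$cohort <- NULL
  args <- y
  args$cohort <- do.call(cohort_config, cohort_args)
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$cohort <- lapply(unclass(y$cohort), function(v) {
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}

read_cohort_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  clin_file <- files[basename(files) == "clinical.tsv"]
  seq_files <- setdiff(files, clin_file)
  if (length(clin_file) != 1 || length(seq_files) == 0) {
    rlang::abort(sprintf("%s must contain clinical.tsv plus sample TSVs", dir),
                 class = "bcr_io_error")
  }
  sequences <- dplyr::bind_rows(lapply(seq_files, read_sequence_table))
  list(sequences = sequences, clinical = read_clinical_table(clin_file))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)),
                 class = "bcr_pipeline_error")
  })
}

#' Run the full repertoire-clonality pipeline
#'
#' Executes every stage in order on either a simulated cohort or a directory
#' of sequence/clinical TSVs, writing each stage's table under
#' `config$out_dir` plus a machine-readable `run_summary.json`. Output is
#' reproducible: fixed inputs, config and seed give byte-identical files.
#'
#' @param config A [run_config()].
#' @return A `bcr_run` list with all stage results (invisibly also written
#'   to disk): `clones`, `hec`, `summaries`, `overlap`, `turnover`,
#'   `sharing_matrix`, `thresholds`, `clusters`, `relatedness`,
#'   `associations`, `summary`.
#' @export
run_pipeline <- function(config = run_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  thr <- config$hec_threshold

  inputs <- with_stage("ingest", {
    if (is.null(config$input_dir)) {
      generate_cohort(config$cohort, seed = config$seed)
    } else {
      read_cohort_dir(config$input_dir)
    }
  })

  clones <- with_stage("clone_calling", {
    call_clones_all(inputs$sequences, threshold = thr)
  })
  write_clone_table(clones, file.path(out, "clones.tsv"))

  hec <- with_stage("hec", call_dominant(clones, threshold = thr))
  readr::write_tsv(hec, file.path(out, "hec_summary.tsv"), progress = FALSE)

  summaries <- with_stage("metrics", summarize_repertoire(clones, thr))
  readr::write_tsv(summaries, file.path(out, "repertoire_summary.tsv"),
                   progress = FALSE)
  usage <- with_stage("metrics", vj_usage(clones))
  readr::write_tsv(usage$v, file.path(out, "v_usage.tsv"), progress = FALSE)
  readr::write_tsv(usage$j, file.path(out, "j_usage.tsv"), progress = FALSE)

  patients <- sort(unique(clones$patient_id))
  sample_of <- function(p, comp, tp) {
    dplyr::filter(clones, .data$patient_id == p, .data$compartment == comp,
                  .data$timepoint == tp)
  }

  overlap_g <- list(); overlap_t <- list()
  turnover_g <- list(); turnover_t <- list()
  thresholds <- list(); clusters_t <- list(); related_t <- list()
  for (p in patients) {
    mus <- sample_of(p, "muscle", "baseline")
    blb <- sample_of(p, "blood", "baseline")
    blw <- sample_of(p, "blood", "week9")
    if (nrow(mus) > 0 && nrow(blb) > 0) {
      ov <- with_stage("overlap", compute_overlap(mus, blb))
      overlap_g[[p]] <- glance(ov)
      overlap_t[[p]] <- dplyr::mutate(tidy(ov), patient_id = p)
      if (nrow(ov$shared) > 0) {
        topn <- utils::head(ov$shared, config$top_n)
        pool <- dplyr::filter(dplyr::bind_rows(mus, blb),
                              .data$clone_key %in% topn$clone_key)
        dyn <- with_stage("cluster", dynamic_threshold(
          dplyr::bind_rows(mus, blb),
          bandwidth = config$cluster_bandwidth,
          fallback = config$cluster_fallback
        ))
        thresholds[[p]] <- tibble::tibble(
          patient_id = p, threshold = dyn$threshold, mode = dyn$mode,
          n_distances = dyn$n_distances
        )
        cl <- with_stage("cluster", cluster_clones(
          pool, threshold = dyn$threshold, mode = config$cluster_mode
        ))
        clusters_t[[p]] <- dplyr::mutate(tidy(cl), patient_id = p)
      }
    }
    if (nrow(blb) > 0 && nrow(blw) > 0) {
      tv <- with_stage("turnover", turnover(blb, blw))
      turnover_g[[p]] <- glance(tv)
      turnover_t[[p]] <- dplyr::mutate(tidy(tv), patient_id = p)
      w9dom <- dplyr::filter(blw, .data$is_dominant)
      if (nrow(w9dom) > 0) {
        rel <- with_stage("cluster", relatedness_test(
          w9dom, dplyr::bind_rows(mus, blb),
          threshold = config$cluster_fallback, mode = config$cluster_mode
        ))
        related_t[[p]] <- dplyr::mutate(rel, patient_id = p)
      }
    }
  }
  overlap_g <- dplyr::bind_rows(overlap_g)
  turnover_g <- dplyr::bind_rows(turnover_g)
  readr::write_tsv(overlap_g, file.path(out, "overlap_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(dplyr::bind_rows(overlap_t),
                   file.path(out, "overlap_clones.tsv"), progress = FALSE)
  readr::write_tsv(turnover_g, file.path(out, "turnover_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(dplyr::bind_rows(turnover_t),
                   file.path(out, "turnover_clones.tsv"), progress = FALSE)
  readr::write_tsv(dplyr::bind_rows(thresholds),
                   file.path(out, "cluster_thresholds.tsv"), progress = FALSE)
  readr::write_tsv(dplyr::bind_rows(clusters_t),
                   file.path(out, "clusters.tsv"), progress = FALSE)
  readr::write_tsv(dplyr::bind_rows(related_t),
                   file.path(out, "relatedness.tsv"), progress = FALSE)

  sharing <- with_stage("overlap", cross_patient_sharing(clones))
  sharing_long <- as_tibble(as.data.frame.table(sharing,
                                                stringsAsFactors = FALSE)) |>
    rlang::set_names(c("patient_a", "patient_b", "n_shared_dominant"))
  readr::write_tsv(sharing_long, file.path(out, "cross_patient_sharing.tsv"),
                   progress = FALSE)

  assoc <- with_stage("associations", run_association_suite(
    hec, inputs$clinical, alpha = config$alpha,
    tis_cutoff = config$tis_cutoff
  ))
  readr::write_tsv(tidy(assoc), file.path(out, "associations.tsv"),
                   progress = FALSE)

  summary <- list(
    seed = config$seed,
    hec_threshold = thr,
    n_patients = length(patients),
    n_samples = length(unique(clones$sample_id)),
    n_clones_total = nrow(clones),
    n_blood_baseline_with_dominant = sum(
      hec$compartment == "blood" & hec$timepoint == "baseline" &
        hec$n_dominant > 0
    ),
    n_patients_sharing_dominant = sum(overlap_g$n_shared_dominant > 0),
    n_patients_with_persisting_dominant = sum(turnover_g$n_persisting > 0),
    mean_lost_fraction = mean(turnover_g$lost_fraction, na.rm = TRUE),
    max_cross_patient_dominant_sharing = max(sharing),
    n_association_tests = glance(assoc)$n_tests,
    n_significant = glance(assoc)$n_significant
  )
  jsonlite::write_json(summary, file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  bcr_log("pipeline complete: %d samples, outputs in %s",
          summary$n_samples, out)

  invisible(structure(
    list(clones = clones, hec = hec, summaries = summaries,
         overlap = overlap_g, turnover = turnover_g,
         sharing_matrix = sharing,
         thresholds = dplyr::bind_rows(thresholds),
         clusters = dplyr::bind_rows(clusters_t),
         relatedness = dplyr::bind_rows(related_t),
         associations = assoc, summary = summary, out_dir = out),
    class = "bcr_run"
  ))
}

#' @export
print.bcr_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<bcr_run> %d patients / %d samples; %d/%d blood baselines with dominant clones; outputs in %s\n",
    s$n_patients, s$n_samples, s$n_blood_baseline_with_dominant,
    s$n_patients, x$out_dir
  ))
  invisible(x)
}
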