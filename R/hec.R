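# Dominant-clone (HEC) calling and the cumulative-frequency "impact"
# statistic.

#' Summarise dominant clones per sample
#'
#' A clone is dominant (highly expanded, "HEC") when its frequency is at or
#' above `threshold` (default 0.5% of the sample's UMI-corrected repertoire;
#' inclusive comparison). The per-sample `impact` is the cumulative frequency
#' of all dominant clones — the headline per-sample clonality statistic.
#'
#' @param clones A clone tibble (one or more samples).
#' @param threshold Dominance threshold in (0, 1); default 0.005.
#' @return A tibble with one row per sample: `sample_id`, metadata columns
#'   when present, `n_clones`, `n_dominant`, `impact` (in \[0, 1\]) and
#'   `dominant_keys` (`;`-joined clone keys). Samples without dominant clones
#'   get `n_dominant = 0`, `impact = 0`.
#' @export
#' @examples
#' cl <- tibble::tibble(
#'   sample_id = "s1", clone_key = paste0("k", 1:4),
#'   frequency = c(0.006, 0.005, 0.004, 0.985)
#' )
#' call_dominant(cl)
call_dominant <- function(clones, threshold = 0.005) {
  check_threshold(threshold)
  stopifnot_cols(clones, c("sample_id", "clone_key", "frequency"),
                 what = "clones")
  meta <- intersect(seq_cols_meta, names(clones))
  clones |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(meta), dplyr::first),
      n_clones = dplyr::n(),
      n_dominant = sum(.data$frequency >= threshold),
      impact = sum(.data$frequency[.data$frequency >= threshold]),
      dominant_keys = paste(
        .data$clone_key[.data$frequency >= threshold][
          order(-.data$frequency[.data$frequency >= threshold],
                .data$clone_key[.data$frequency >= threshold])],
        collapse = ";"
      ),
      .groups = "drop"
    )
}

#' Change in dominant-clone impact between two timepoints
#'
#' Returns follow-up impact minus baseline impact (week 9 minus week 0), a
#' signed fraction in \[-1, 1\]. Both summaries must describe the same
#' patient and compartment.
#'
#' @param baseline,followup Single-sample rows from [call_dominant()].
#' @return A single signed number.
#' @export
impact_delta <- function(baseline, followup) {
  for (x in list(baseline, followup)) {
    if (nrow(x) != 1) {
      rlang::abort("impact_delta expects one-row summaries",
                   class = "bcr_input_error")
    }
  }
  for (col in c("patient_id", "compartment")) {
    if (col %in% names(baseline) && col %in% names(followup) &&
        !identical(baseline[[col]], followup[[col]])) {
      rlang::abort(sprintf("baseline and followup differ on %s", col),
                   class = "bcr_input_error")
    }
  }
  followup$impact - baseline$impact
}

#' Per-patient impact and dominant-count deltas for a longitudinal cohort
#'
#' Pivots a multi-sample dominant-clone summary to one row per patient and
#' compartment with baseline and week-9 values side by side plus
#' `delta_impact` and `delta_n_dominant` (week 9 minus baseline).
#'
#' @param hec A [call_dominant()] summary containing `patient_id`,
#'   `compartment` and `timepoint` (values `"baseline"` and `"week9"`).
#' @return A tibble, one row per patient/compartment with both timepoints.
#' @export
impact_delta_table <- function(hec) {
  stopifnot_cols(hec, c("patient_id", "compartment", "timepoint",
                        "n_dominant", "impact"), what = "hec summary")
  hec |>
    dplyr::select(dplyr::all_of(c("patient_id", "compartment", "timepoint",
                                  "n_dominant", "impact"))) |>
    tidyr::pivot_wider(
      names_from = "timepoint",
      values_from = c("n_dominant", "impact")
    ) |>
    dplyr::filter(!is.na(.data$impact_baseline) & !is.na(.data$impact_week9)) |>
    dplyr::mutate(
      delta_impact = .data$impact_week9 - .data$impact_baseline,
      delta_n_dominant = .data$n_dominant_week9 - .data$n_dominant_baseline
    )
}
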