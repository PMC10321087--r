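# Compartment overlap (muscle vs blood) and longitudinal dominant-clone
# turnover (baseline vs week 9).

#' Clone sharing between two repertoires
#'
#' Intersects two samples on the exact clonotype key (V gene, J gene, CDR3
#' amino-acid sequence) and reports, for every shared clone, its frequency in
#' each sample and whether it is dominant in both. The operation is
#' symmetric: `compute_overlap(a, b)` and `compute_overlap(b, a)` agree on
#' all counts.
#'
#' @param clones_a,clones_b Single-sample clone tibbles (with `is_dominant`
#'   flags set, e.g. by [call_clones()]).
#' @return A `bcr_overlap` object. `tidy()` gives the per-shared-clone table
#'   (`clone_key`, `freq_a`, `freq_b`, `dominant_a`, `dominant_b`);
#'   `glance()` gives one row of counts (`n_shared`, `n_shared_dominant`,
#'   ...); `autoplot()` draws the frequency-frequency scatter.
#' @export
compute_overlap <- function(clones_a, clones_b) {
  for (x in list(clones_a, clones_b)) {
    stopifnot_cols(x, c("sample_id", "clone_key", "frequency", "is_dominant"),
                   what = "clones")
  }
  a <- dplyr::distinct(clones_a, .data$clone_key, .keep_all = TRUE)
  b <- dplyr::distinct(clones_b, .data$clone_key, .keep_all = TRUE)
  shared <- dplyr::inner_join(
    dplyr::select(a, "clone_key", freq_a = "frequency",
                  dominant_a = "is_dominant"),
    dplyr::select(b, "clone_key", freq_b = "frequency",
                  dominant_b = "is_dominant"),
    by = "clone_key"
  ) |>
    dplyr::arrange(dplyr::desc(.data$freq_a + .data$freq_b), .data$clone_key)
  structure(
    list(
      pair = c(a = clones_a$sample_id[1], b = clones_b$sample_id[1]),
      shared = shared,
      n_a = nrow(a),
      n_b = nrow(b)
    ),
    class = "bcr_overlap"
  )
}

#' @export
tidy.bcr_overlap <- function(x, ...) x$shared

#' @export
glance.bcr_overlap <- function(x, ...) {
  tibble::tibble(
    sample_a = x$pair[["a"]],
    sample_b = x$pair[["b"]],
    n_a = x$n_a,
    n_b = x$n_b,
    n_shared = nrow(x$shared),
    n_shared_dominant = sum(x$shared$dominant_a & x$shared$dominant_b)
  )
}

#' @export
print.bcr_overlap <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<bcr_overlap> %s (%d clones) vs %s (%d clones): %d shared, %d dominant in both\n",
    g$sample_a, g$n_a, g$sample_b, g$n_b, g$n_shared, g$n_shared_dominant
  ))
  invisible(x)
}

#' Dominant-clone turnover between baseline and follow-up
#'
#' Classifies each dominant clone of a longitudinal pair of repertoires from
#' the same patient and compartment: `persisting` (dominant at both
#' timepoints), `lost` (dominant at baseline, absent or below threshold at
#' follow-up — the two sub-cases are distinguished), and `new` (dominant at
#' follow-up only). Each new dominant clone is also tested for presence at
#' any frequency at baseline (the key-level "de novo" test).
#'
#' @param baseline,followup Single-sample clone tibbles with `is_dominant`
#'   set, sharing `patient_id` and `compartment`.
#' @return A `bcr_turnover` object; `tidy()` gives one row per involved
#'   dominant clone key with its `status` (`persisting`, `lost_absent`,
#'   `lost_subthreshold`, `new`) and a `present_at_baseline` flag; `glance()`
#'   gives the counts and the lost fraction.
#' @export
turnover <- function(baseline, followup) {
  for (x in list(baseline, followup)) {
    stopifnot_cols(x, c("sample_id", "clone_key", "frequency", "is_dominant"),
                   what = "clones")
  }
  for (col in c("patient_id", "compartment")) {
    if (col %in% names(baseline) && col %in% names(followup)) {
      va <- unique(baseline[[col]]); vb <- unique(followup[[col]])
      if (!identical(va, vb)) {
        rlang::abort(sprintf("baseline and followup differ on %s (%s vs %s)",
                             col, va[1], vb[1]),
                     class = "bcr_input_error")
      }
    }
  }
  dom_base <- baseline$clone_key[baseline$is_dominant]
  dom_fu <- followup$clone_key[followup$is_dominant]
  all_fu <- followup$clone_key
  all_base <- baseline$clone_key

  persisting <- intersect(dom_base, dom_fu)
  lost <- setdiff(dom_base, dom_fu)
  newk <- setdiff(dom_fu, dom_base)
  status <- tibble::tibble(
    clone_key = c(persisting, lost, newk),
    status = c(
      rep("persisting", length(persisting)),
      ifelse(lost %in% all_fu, "lost_subthreshold", "lost_absent"),
      rep("new", length(newk))
    ),
    present_at_baseline = c(
      rep(TRUE, length(persisting) + length(lost)),
      newk %in% all_base
    )
  ) |>
    dplyr::arrange(.data$status, .data$clone_key)

  structure(
    list(
      patient_id = if ("patient_id" %in% names(baseline)) {
        baseline$patient_id[1]
      } else NA_character_,
      pair = c(baseline = baseline$sample_id[1],
               followup = followup$sample_id[1]),
      status = status,
      n_dominant_baseline = length(dom_base),
      n_dominant_followup = length(dom_fu)
    ),
    class = "bcr_turnover"
  )
}

#' @export
tidy.bcr_turnover <- function(x, ...) x$status

#' @export
glance.bcr_turnover <- function(x, ...) {
  s <- x$status$status
  n_lost <- sum(s %in% c("lost_absent", "lost_subthreshold"))
  tibble::tibble(
    patient_id = x$patient_id,
    n_dominant_baseline = x$n_dominant_baseline,
    n_dominant_followup = x$n_dominant_followup,
    n_persisting = sum(s == "persisting"),
    n_lost = n_lost,
    n_lost_absent = sum(s == "lost_absent"),
    n_lost_subthreshold = sum(s == "lost_subthreshold"),
    n_new = sum(s == "new"),
    n_new_de_novo = sum(s == "new" & !x$status$present_at_baseline),
    lost_fraction = if (x$n_dominant_baseline > 0) {
      n_lost / x$n_dominant_baseline
    } else NA_real_
  )
}

#' @export
print.bcr_turnover <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<bcr_turnover> patient %s: %d/%d baseline dominant clones lost, %d persisting, %d new (%d de novo)\n",
    g$patient_id, g$n_lost, g$n_dominant_baseline, g$n_persisting,
    g$n_new, g$n_new_de_novo
  ))
  invisible(x)
}

#' Cross-patient sharing of dominant clones
#'
#' Counts dominant clone keys shared between every pair of patients (pooling
#' each patient's dominant keys over the selected samples). In a healthy
#' analysis of patient-specific clonal responses the off-diagonal entries are
#' expected to be zero.
#'
#' @param clones A multi-sample clone tibble with `patient_id` and
#'   `is_dominant` columns.
#' @return A symmetric integer matrix (patients x patients) of shared
#'   dominant-key counts with a zero diagonal.
#' @export
cross_patient_sharing <- function(clones) {
  stopifnot_cols(clones, c("patient_id", "clone_key", "is_dominant"),
                 what = "clones")
  patients <- sort(unique(clones$patient_id))
  if (length(patients) < 2) {
    rlang::abort("need at least 2 patients", class = "bcr_input_error")
  }
  keysets <- lapply(patients, function(p) {
    unique(clones$clone_key[clones$patient_id == p & clones$is_dominant])
  })
  n <- length(patients)
  m <- matrix(0L, n, n, dimnames = list(patients, patients))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- length(intersect(keysets[[i]], keysets[[j]]))
      m[i, j] <- k
      m[j, i] <- k
    }
  }
  m
}
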