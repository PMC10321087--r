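# Clinical association layer: responder classification, normality gating,
# nonparametric group comparisons, Spearman correlations with Fisher-z CIs,
# and the cohort association panel. All tests are two-sided; no
# multiple-testing correction is applied (the suite reports the number of
# tests so users can apply their own).

#' Classify treatment response from the total improvement score
#'
#' A patient is a responder when `tis >= tis_cutoff` (inclusive; default 40).
#' Records with missing TIS are flagged `NA` with a warning.
#'
#' @param clinical A clinical tibble with a `tis` column.
#' @param tis_cutoff Response cutoff on the 0-100 TIS scale (default 40).
#' @return `clinical` with a logical `responder` column.
#' @export
classify_responders <- function(clinical, tis_cutoff = 40) {
  stopifnot_cols(clinical, "tis", what = "clinical")
  n_missing <- sum(is.na(clinical$tis))
  if (n_missing > 0) {
    rlang::warn(sprintf("%d records with missing tis skipped (responder = NA)",
                        n_missing))
  }
  dplyr::mutate(clinical, responder = .data$tis >= tis_cutoff)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) skewness z and the Anscombe-Glynn (1983)
#' kurtosis z into the omnibus statistic \eqn{K^2 = z_s^2 + z_k^2}, referred
#' to a chi-squared distribution with 2 degrees of freedom.
#'
#' @param x Numeric vector, `n >= 8`.
#' @return A one-row tibble: `n`, `statistic` (K2), `p_value`, `z_skew`,
#'   `z_kurtosis`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) {
    rlang::abort("dagostino_pearson requires n >= 8",
                 class = "bcr_parameter_error")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    rlang::abort("constant sample: moments undefined",
                 class = "bcr_input_error")
  }
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness z (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  if (y == 0) y <- 1
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_beta1 * (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  z_kurt <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  tibble::tibble(
    n = n, statistic = k2, p_value = stats::pchisq(k2, df = 2,
                                                   lower.tail = FALSE),
    z_skew = z_skew, z_kurtosis = z_kurt
  )
}

#' Gate a sample as normal or non-normal
#'
#' Applies the D'Agostino-Pearson omnibus test at `alpha`; samples with
#' `n < 8` (below the test's requirement) or zero variance are classified
#' non-normal. Returns the matching descriptive pair: mean (SD) for normal
#' data, median (IQR) otherwise.
#'
#' @param values Numeric vector.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `classification` (`"normal"`/`"non_normal"`),
#'   `n`, `p_value`, `center`, `spread_low`, `spread_high`, `summary_type`,
#'   `degenerate`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  x <- values[!is.na(values)]
  n <- length(x)
  degenerate <- n > 0 && stats::var(x) == 0
  small <- n < 8
  if (small && !degenerate) {
    rlang::warn(sprintf("n = %d < 8: omnibus test not applicable, classified non_normal", n))
  }
  p <- NA_real_
  if (!small && !degenerate) p <- dagostino_pearson(x)$p_value
  normal <- !small && !degenerate && p >= alpha
  if (normal) {
    tibble::tibble(
      classification = "normal", n = n, p_value = p,
      center = mean(x), spread_low = mean(x) - stats::sd(x),
      spread_high = mean(x) + stats::sd(x),
      summary_type = "mean_sd", degenerate = FALSE
    )
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(
      classification = "non_normal", n = n, p_value = p,
      center = q[2], spread_low = q[1], spread_high = q[3],
      summary_type = "median_iqr", degenerate = degenerate
    )
  }
}

#' Nonparametric group comparison
#'
#' Two groups are compared with the two-sided Mann-Whitney test (exact for
#' small tie-free samples, normal approximation with tie correction
#' otherwise); three or more groups with the Kruskal-Wallis test.
#'
#' @param values Numeric vector of per-sample metric values.
#' @param groups Group labels (coerced to factor), same length as `values`.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return A one-row tibble: `test_used`, `n`, `n_groups`, `statistic`,
#'   `p_value`, `significant`.
#' @export
group_compare <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 1)) {
    rlang::abort("group_compare needs at least two non-empty groups",
                 class = "bcr_input_error")
  }
  if (length(sizes) == 2) {
    lv <- levels(groups)
    ht <- suppressWarnings(stats::wilcox.test(
      values[groups == lv[1]], values[groups == lv[2]],
      alternative = "two.sided"
    ))
    test_used <- "mann_whitney"
  } else {
    ht <- stats::kruskal.test(values, groups)
    test_used <- "kruskal_wallis"
  }
  tibble::tibble(
    test_used = test_used, n = length(values), n_groups = length(sizes),
    statistic = unname(ht$statistic), p_value = ht$p.value,
    significant = ht$p.value < alpha
  )
}

#' Spearman rank correlation with Fisher-z confidence interval
#'
#' Spearman's rho on ranks (average ranks for ties) with a two-sided p-value,
#' plus an approximate 95% CI from the Fisher z transform with variance
#' `1.06 / (n - 3)`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 4` complete pairs.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `test_used`, `n`, `rho`, `statistic`,
#'   `p_value`, `ci_low`, `ci_high`, `significant`.
#' @export
spearman_correlation <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) {
    rlang::abort("x and y must have equal length", class = "bcr_input_error")
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) {
    rlang::abort("spearman_correlation requires n >= 4 complete pairs",
                 class = "bcr_input_error")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    rlang::abort("correlation undefined for a constant variable",
                 class = "bcr_input_error")
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided"))
  rho <- unname(ht$estimate)
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  se <- sqrt(1.06 / (n - 3))
  crit <- stats::qnorm(1 - alpha / 2)
  tibble::tibble(
    test_used = "spearman", n = n, rho = rho,
    statistic = unname(ht$statistic), p_value = ht$p.value,
    ci_low = tanh(z - crit * se), ci_high = tanh(z + crit * se),
    significant = ht$p.value < alpha
  )
}

# run one panel entry, tolerating degenerate inputs (constant metric, empty
# group) by returning an NA row with a note instead of aborting the suite
panel_try <- function(pair_name, fn) {
  res <- tryCatch(fn(), error = function(e) conditionMessage(e))
  if (is.character(res)) {
    tibble::tibble(
      pair = pair_name, test_used = NA_character_, n = NA_integer_,
      rho = NA_real_, statistic = NA_real_, p_value = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, significant = NA,
      note = res
    )
  } else {
    res$pair <- pair_name
    res$note <- NA_character_
    if (!"rho" %in% names(res)) res$rho <- NA_real_
    if (!"ci_low" %in% names(res)) { res$ci_low <- NA_real_; res$ci_high <- NA_real_ }
    res[, c("pair", "test_used", "n", "rho", "statistic", "p_value",
            "ci_low", "ci_high", "significant", "note")]
  }
}

#' Join repertoire summaries to clinical outcomes
#'
#' Builds the per-patient analysis table behind the association panel:
#' baseline blood impact and dominant-clone count, their week-9 values and
#' deltas (week 9 minus baseline), and the clinical variables (CK, MMT, TIS,
#' responder flag, antibody class).
#'
#' @param hec A [call_dominant()] summary over blood samples at `baseline`
#'   and `week9` (columns `patient_id`, `compartment`, `timepoint`).
#' @param clinical A clinical tibble ([read_clinical_table()]).
#' @param tis_cutoff Responder cutoff passed to [classify_responders()].
#' @return A tibble with one row per patient.
#' @export
join_clinical <- function(hec, clinical, tis_cutoff = 40) {
  stopifnot_cols(hec, c("patient_id", "compartment", "timepoint",
                        "n_dominant", "impact"), what = "hec summary")
  dup <- hec |>
    dplyr::count(.data$patient_id, .data$compartment, .data$timepoint) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(sprintf("duplicated patient/compartment/timepoint rows: %s",
                         paste(dup$patient_id, collapse = ", ")),
                 class = "bcr_input_error")
  }
  blood <- impact_delta_table(dplyr::filter(hec, .data$compartment == "blood"))
  unmatched <- setdiff(blood$patient_id, clinical$patient_id)
  if (length(unmatched) > 0) {
    rlang::abort(sprintf("patients missing from clinical table: %s",
                         paste(unmatched, collapse = ", ")),
                 class = "bcr_input_error")
  }
  clinical |>
    classify_responders(tis_cutoff = tis_cutoff) |>
    dplyr::inner_join(blood, by = "patient_id") |>
    dplyr::mutate(delta_mmt = .data$mmt_followup - .data$mmt_baseline)
}

#' Run the cohort association panel
#'
#' The standard exploratory panel relating blood clonality to outcomes:
#' Spearman correlations of baseline impact and dominant-clone count with CK
#' and baseline MMT; of the week-9-minus-baseline deltas with TIS and
#' delta-MMT; Mann-Whitney responder comparisons of impact and dominant
#' count at both timepoints; and Kruskal-Wallis antibody-class comparisons.
#' P-values are unadjusted; `glance()` reports the number of tests run.
#'
#' @param hec A [call_dominant()] summary of blood samples at both timepoints.
#' @param clinical A clinical tibble.
#' @param alpha Significance level (default 0.05).
#' @param tis_cutoff Responder cutoff (default 40).
#' @param include_no_hec Keep patients whose baseline blood carries no
#'   dominant clone, as impact = 0 (default `TRUE`); `FALSE` drops them.
#' @return A `bcr_association_suite` object; `tidy()` gives one row per
#'   panel test, `glance()` the totals.
#' @export
run_association_suite <- function(hec, clinical, alpha = 0.05,
                                  tis_cutoff = 40, include_no_hec = TRUE) {
  d <- join_clinical(hec, clinical, tis_cutoff = tis_cutoff)
  if (!include_no_hec) {
    d <- dplyr::filter(d, .data$n_dominant_baseline > 0)
  }
  sp <- function(xv, yv) function() {
    spearman_correlation(d[[xv]], d[[yv]], alpha = alpha)
  }
  gc <- function(xv, gv) function() {
    group_compare(d[[xv]], d[[gv]], alpha = alpha)
  }
  panel <- list(
    "impact_baseline~ck_baseline" = sp("impact_baseline", "ck_baseline"),
    "n_dominant_baseline~ck_baseline" = sp("n_dominant_baseline", "ck_baseline"),
    "impact_baseline~mmt_baseline" = sp("impact_baseline", "mmt_baseline"),
    "n_dominant_baseline~mmt_baseline" = sp("n_dominant_baseline", "mmt_baseline"),
    "delta_impact~tis" = sp("delta_impact", "tis"),
    "delta_impact~delta_mmt" = sp("delta_impact", "delta_mmt"),
    "delta_n_dominant~tis" = sp("delta_n_dominant", "tis"),
    "delta_n_dominant~delta_mmt" = sp("delta_n_dominant", "delta_mmt"),
    "impact_baseline~responder" = gc("impact_baseline", "responder"),
    "n_dominant_baseline~responder" = gc("n_dominant_baseline", "responder"),
    "impact_week9~responder" = gc("impact_week9", "responder"),
    "n_dominant_week9~responder" = gc("n_dominant_week9", "responder"),
    "impact_baseline~antibody_class" = gc("impact_baseline", "antibody_class"),
    "n_dominant_baseline~antibody_class" = gc("n_dominant_baseline", "antibody_class")
  )
  results <- purrr::imap(panel, function(fn, nm) panel_try(nm, fn)) |>
    dplyr::bind_rows()
  structure(
    list(results = results, data = d, alpha = alpha,
         n_tests = nrow(results)),
    class = "bcr_association_suite"
  )
}

#' @export
tidy.bcr_association_suite <- function(x, ...) x$results

#' @export
glance.bcr_association_suite <- function(x, ...) {
  tibble::tibble(
    n_tests = x$n_tests,
    n_run = sum(!is.na(x$results$p_value)),
    n_significant = sum(x$results$significant, na.rm = TRUE),
    alpha = x$alpha,
    adjusted = FALSE
  )
}

#' @export
print.bcr_association_suite <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<bcr_association_suite> %d tests (%d run, %d significant at alpha = %g, unadjusted)\n",
    g$n_tests, g$n_run, g$n_significant, g$alpha
  ))
  print(x$results, n = nrow(x$results))
  invisible(x)
}
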