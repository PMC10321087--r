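# Per-sample repertoire profiling: diversity indices, mutation load, CDR3
# length/charge distributions, V/J gene usage.

#' Simpson, Shannon and Gini indices of a clone-frequency vector
#'
#' Simpson's index is the concentration form \eqn{\sum f_i^2} (1 for a
#' monoclonal sample, 1/n for a uniform one); `variant = "gini_simpson"`
#' returns \eqn{1 - \sum f_i^2}. Shannon entropy is \eqn{-\sum f_i \log f_i}
#' in nats by default (`base = 2` for bits), with \eqn{0 \log 0 := 0}. The
#' Gini index uses the Lorenz-curve formulation on clone frequencies with no
#' small-sample correction: 0 for a uniform repertoire, approaching 1 under
#' extreme inequality.
#'
#' @param f Numeric vector of clone frequencies (non-negative, summing to 1).
#' @param variant Simpson variant, `"concentration"` (default) or
#'   `"gini_simpson"`.
#' @param base Logarithm base for Shannon entropy; default `exp(1)` (nats).
#' @return A named list with `simpson`, `shannon`, `gini`.
#' @export
#' @examples
#' diversity_vec(rep(0.25, 4)) # simpson 0.25, shannon log(4), gini 0
diversity_vec <- function(f, variant = c("concentration", "gini_simpson"),
                          base = exp(1)) {
  variant <- match.arg(variant)
  if (length(f) == 0) {
    rlang::abort("empty frequency vector", class = "bcr_input_error")
  }
  simpson <- sum(f^2)
  if (variant == "gini_simpson") simpson <- 1 - simpson
  pos <- f[f > 0]
  shannon <- -sum(pos * log(pos, base = base))
  list(simpson = simpson, shannon = shannon, gini = gini_index(f))
}

#' Gini inequality index
#'
#' Sorted O(n log n) form of the mean-absolute-difference definition
#' \eqn{G = \sum_i \sum_j |f_i - f_j| / (2 n \sum f)}.
#'
#' @param f Non-negative numeric vector.
#' @return Gini index in \[0, 1).
#' @export
gini_index <- function(f) {
  if (length(f) == 0) {
    rlang::abort("empty frequency vector", class = "bcr_input_error")
  }
  n <- length(f)
  s <- sort(f)
  2 * sum(seq_len(n) * s) / (n * sum(s)) - (n + 1) / n
}

#' Per-sample diversity indices
#'
#' @param clones A clone tibble (one or more samples).
#' @inheritParams diversity_vec
#' @return A tibble with one row per sample: `sample_id`, `n_clones`,
#'   `simpson`, `shannon`, `gini`.
#' @export
diversity_indices <- function(clones,
                              variant = c("concentration", "gini_simpson"),
                              base = exp(1)) {
  variant <- match.arg(variant)
  stopifnot_cols(clones, c("sample_id", "frequency"), what = "clones")
  if (nrow(clones) == 0) {
    rlang::abort("empty clone table", class = "bcr_input_error")
  }
  clones |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_clones = dplyr::n(),
      simpson = {
        s <- sum(.data$frequency^2)
        if (variant == "gini_simpson") 1 - s else s
      },
      shannon = {
        p <- .data$frequency[.data$frequency > 0]
        -sum(p * log(p, base = base))
      },
      gini = gini_index(.data$frequency),
      .groups = "drop"
    )
}

#' Per-sample mutation load
#'
#' Summarises somatic mutation load (mismatches versus germline V per aligned
#' base pair) across the clones of each sample. Clones without mutation data
#' are excluded and counted.
#'
#' @param clones A clone tibble with a `mutation_rate` column.
#' @return A tibble per sample: `mean_mutation_rate` (UMI-weighted),
#'   `median_mutation_rate` (unweighted per-clone median), `n_clones_rated`,
#'   `n_clones_excluded`.
#' @export
mutation_load <- function(clones) {
  stopifnot_cols(clones, c("sample_id", "umi_count", "mutation_rate"),
                 what = "clones")
  out <- clones |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_clones_rated = sum(!is.na(.data$mutation_rate)),
      n_clones_excluded = sum(is.na(.data$mutation_rate)),
      mean_mutation_rate = {
        ok <- !is.na(.data$mutation_rate)
        if (any(ok)) {
          sum(.data$umi_count[ok] * .data$mutation_rate[ok]) /
            sum(.data$umi_count[ok])
        } else NA_real_
      },
      median_mutation_rate = stats::median(.data$mutation_rate, na.rm = TRUE),
      .groups = "drop"
    )
  n_excl <- sum(out$n_clones_excluded)
  if (n_excl > 0) bcr_log("mutation_load: %d clones lacked mutation data", n_excl)
  out
}

#' Net charge of a CDR3 amino-acid sequence
#'
#' Integer count model at neutral pH: `count(R, K) - count(D, E)`; histidine
#' is not counted.
#'
#' @param aa Character vector of amino-acid sequences.
#' @return Integer net charges (`NA` for sequences with non-standard letters).
#' @export
#' @examples
#' cdr3_charge("CARDRSYW") # 2 R - 1 D = +1
cdr3_charge <- function(aa) {
  std <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", aa)
  pos <- stringr::str_count(aa, "[RK]")
  neg <- stringr::str_count(aa, "[DE]")
  ifelse(std, as.integer(pos - neg), NA_integer_)
}

#' Frequency-weighted CDR3 length and charge distributions
#'
#' Lengths are amino-acid lengths of `cdr3_aa`; charges use [cdr3_charge()].
#' Clones whose CDR3 contains non-standard letters are excluded from the
#' charge distribution (with a logged count). Weights are clone frequencies,
#' renormalised over the included clones so each distribution sums to 1.
#'
#' @param clones A clone tibble.
#' @return A list of two long tibbles, `length` (`sample_id`, `cdr3_length`,
#'   `weight`) and `charge` (`sample_id`, `cdr3_charge`, `weight`).
#' @export
cdr3_profiles <- function(clones) {
  stopifnot_cols(clones, c("sample_id", "cdr3_aa", "frequency"),
                 what = "clones")
  len <- clones |>
    dplyr::mutate(cdr3_length = nchar(.data$cdr3_aa)) |>
    dplyr::group_by(.data$sample_id, .data$cdr3_length) |>
    dplyr::summarise(weight = sum(.data$frequency), .groups = "drop_last") |>
    dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup()
  ch <- clones |>
    dplyr::mutate(cdr3_charge = cdr3_charge(.data$cdr3_aa))
  n_bad <- sum(is.na(ch$cdr3_charge))
  if (n_bad > 0) {
    bcr_log("cdr3_profiles: %d clones with non-standard CDR3 letters excluded",
            n_bad)
  }
  ch <- ch |>
    dplyr::filter(!is.na(.data$cdr3_charge)) |>
    dplyr::group_by(.data$sample_id, .data$cdr3_charge) |>
    dplyr::summarise(weight = sum(.data$frequency), .groups = "drop_last") |>
    dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup()
  list(length = len, charge = ch)
}

#' V/J gene-usage tables
#'
#' Normalised usage per V gene, per J gene and per V-J pair, weighted either
#' by clone count (each clonotype counts once) or by UMI abundance.
#'
#' @param clones A clone tibble.
#' @param weighting `"clone"` (default) or `"umi"`.
#' @return A list of long tibbles `v`, `j`, `vj` with columns `sample_id`,
#'   gene column(s), and `frequency` (summing to 1 per sample).
#' @export
vj_usage <- function(clones, weighting = c("clone", "umi")) {
  weighting <- match.arg(weighting)
  stopifnot_cols(clones, c("sample_id", "v_call", "j_call", "umi_count"),
                 what = "clones")
  w <- if (weighting == "clone") rep(1, nrow(clones)) else clones$umi_count
  base <- dplyr::mutate(clones, .w = w)
  usage_by <- function(...) {
    base |>
      dplyr::group_by(.data$sample_id, ...) |>
      dplyr::summarise(frequency = sum(.data$.w), .groups = "drop") |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(frequency = .data$frequency / sum(.data$frequency)) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$sample_id, dplyr::desc(.data$frequency))
  }
  list(
    v = usage_by(.data$v_call),
    j = usage_by(.data$j_call),
    vj = usage_by(.data$v_call, .data$j_call)
  )
}

#' Top-k most used genes per sample
#'
#' @param usage One element of the [vj_usage()] result (e.g. `$v`).
#' @param k Number of genes to keep per sample.
#' @return The `k` highest-frequency rows per sample.
#' @export
top_genes <- function(usage, k = 5) {
  usage |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::slice_max(.data$frequency, n = k, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' One-row-per-sample repertoire summary
#'
#' Combines clone counts, dominant-clone statistics, diversity indices,
#' mutation load and mean CDR3 length/charge into a single tibble — the
#' per-sample feature table consumed by the clinical association layer.
#'
#' @param clones A clone tibble (one or more samples).
#' @param threshold Dominance threshold passed to [call_dominant()].
#' @return A tibble with one row per sample.
#' @export
summarize_repertoire <- function(clones, threshold = 0.005) {
  hec <- call_dominant(clones, threshold = threshold)
  div <- dplyr::select(diversity_indices(clones), -"n_clones")
  mut <- mutation_load(clones)
  prof <- clones |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      mean_cdr3_length = sum(.data$frequency * nchar(.data$cdr3_aa)) /
        sum(.data$frequency),
      mean_cdr3_charge = {
        q <- cdr3_charge(.data$cdr3_aa)
        ok <- !is.na(q)
        sum(.data$frequency[ok] * q[ok]) / sum(.data$frequency[ok])
      },
      .groups = "drop"
    )
  hec |>
    dplyr::left_join(div, by = "sample_id") |>
    dplyr::left_join(mut, by = "sample_id") |>
    dplyr::left_join(prof, by = "sample_id")
}
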