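# CDR3 amino-acid Hamming clustering: metric, data-driven threshold
# selection from nearest-neighbour distances, single-linkage grouping, and
# the query-vs-reference relatedness test.

#' Normalised Hamming distance between CDR3 sequences
#'
#' Mismatch count divided by length for equal-length strings; strings of
#' different length are incomparable and return `NA` (treated as infinite
#' distance by the clustering functions).
#'
#' @param cdr3_a,cdr3_b Single non-empty strings.
#' @return A number in \[0, 1\], or `NA_real_` if the lengths differ.
#' @export
#' @examples
#' hamming_distance("CARDY", "CARDF") # 0.2
hamming_distance <- function(cdr3_a, cdr3_b) {
  if (length(cdr3_a) != 1 || length(cdr3_b) != 1 ||
      is.na(cdr3_a) || is.na(cdr3_b) ||
      nchar(cdr3_a) == 0 || nchar(cdr3_b) == 0) {
    rlang::abort("hamming_distance expects two non-empty strings",
                 class = "bcr_input_error")
  }
  if (nchar(cdr3_a) != nchar(cdr3_b)) return(NA_real_)
  a <- utf8ToInt(cdr3_a)
  b <- utf8ToInt(cdr3_b)
  sum(a != b) / length(a)
}

# pairwise normalised Hamming distances within a set of equal-length strings
hamming_matrix <- function(seqs) {
  g <- length(seqs)
  L <- nchar(seqs[1])
  D <- matrix(0, g, g)
  if (g < 2) return(D)
  M <- matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = L)
  for (i in seq_len(g - 1)) {
    di <- colSums(M[, (i + 1):g, drop = FALSE] != M[, i]) / L
    D[i, (i + 1):g] <- di
    D[(i + 1):g, i] <- di
  }
  D
}

# comparability group labels for a clone table
comparability_groups <- function(clones, mode) {
  if (mode == "stratified") {
    paste(clones$v_call, clones$j_call, nchar(clones$cdr3_aa), sep = "|")
  } else {
    as.character(nchar(clones$cdr3_aa))
  }
}

#' Nearest-neighbour CDR3 distances within V/J/length strata
#'
#' For every clone, the normalised Hamming distance to its nearest neighbour
#' among clones with identical V gene, J gene and CDR3 length. Clones alone
#' in their stratum contribute nothing. This pooled distribution is the input
#' to data-driven threshold selection: clonally related sequences produce a
#' low-distance mode, unrelated ones a high-distance mode.
#'
#' @param clones A clone tibble with `v_call`, `j_call`, `cdr3_aa`.
#' @return A numeric vector of nearest-neighbour distances.
#' @export
nn_distances <- function(clones) {
  stopifnot_cols(clones, c("v_call", "j_call", "cdr3_aa"), what = "clones")
  cl <- dplyr::distinct(clones, .data$v_call, .data$j_call, .data$cdr3_aa)
  groups <- split(cl$cdr3_aa, comparability_groups(cl, "stratified"))
  out <- lapply(groups, function(seqs) {
    if (length(seqs) < 2) return(numeric(0))
    D <- hamming_matrix(seqs)
    diag(D) <- Inf
    apply(D, 1, min)
  })
  unlist(out, use.names = FALSE)
}

#' Select a clustering threshold from a nearest-neighbour distance pool
#'
#' Smooths the empirical nearest-neighbour distance distribution with a
#' fixed-bandwidth Gaussian kernel density on \[0, 1\] and returns the
#' location of the density minimum between the low-distance (clonally
#' related) and high-distance (unrelated) modes. If the distribution has no
#' interior minimum between two modes (e.g. it is unimodal), the configured
#' fallback is returned with `mode = "fallback"`. Local maxima below 5% of
#' the peak density are ignored as numerical ripple.
#'
#' @param distances Numeric vector of nearest-neighbour distances in \[0, 1\].
#' @param bandwidth Kernel bandwidth (default 0.02).
#' @param fallback Threshold returned when no valley is found (default 0.15).
#' @return A `bcr_threshold` list: `threshold`, `mode` (`"dynamic"` or
#'   `"fallback"`), `n_distances`, and the density object (or `NULL`).
#' @export
select_threshold <- function(distances, bandwidth = 0.02, fallback = 0.15) {
  distances <- distances[is.finite(distances)]
  if (length(distances) < 2 || stats::var(distances) == 0) {
    return(structure(list(threshold = fallback, mode = "fallback",
                          n_distances = length(distances), density = NULL),
                     class = "bcr_threshold"))
  }
  dens <- stats::density(distances, bw = bandwidth, from = 0, to = 1, n = 512)
  y <- dens$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  # ignore numerical ripple: a mode must reach 5% of the peak density
  modes <- which(is_max & y >= 0.05 * max(y))
  thr <- fallback
  mode <- "fallback"
  if (length(modes) >= 2) {
    lo <- min(modes)
    hi <- max(modes)
    inner <- (lo + 1):(hi - 1)
    valley <- inner[which.min(y[inner])]
    if (y[valley] < y[lo] && y[valley] < y[hi]) {
      thr <- dens$x[valley]
      mode <- "dynamic"
    }
  }
  structure(list(threshold = thr, mode = mode,
                 n_distances = length(distances), density = dens),
            class = "bcr_threshold")
}

#' @export
print.bcr_threshold <- function(x, ...) {
  cat(sprintf("<bcr_threshold> %.4f (%s, from %d nearest-neighbour distances)\n",
              x$threshold, x$mode, x$n_distances))
  invisible(x)
}

#' Data-driven CDR3 clustering threshold for a clone pool
#'
#' Pools nearest-neighbour distances within V/J/CDR3-length strata
#' ([nn_distances()]) and picks the density valley between the related and
#' unrelated modes ([select_threshold()]). With fewer than `min_pool`
#' usable distances the fallback is returned with a warning.
#'
#' @param clones A clone tibble.
#' @inheritParams select_threshold
#' @param min_pool Minimum pooled nearest-neighbour distances required for
#'   estimation (default 20).
#' @return A `bcr_threshold` object.
#' @export
dynamic_threshold <- function(clones, bandwidth = 0.02, fallback = 0.15,
                              min_pool = 20) {
  d <- nn_distances(clones)
  if (length(d) < min_pool) {
    rlang::warn(sprintf(
      "only %d nearest-neighbour distances (< %d); using fallback threshold %.3f",
      length(d), min_pool, fallback
    ))
    return(structure(list(threshold = fallback, mode = "fallback",
                          n_distances = length(d), density = NULL),
                     class = "bcr_threshold"))
  }
  select_threshold(d, bandwidth = bandwidth, fallback = fallback)
}

#' Group related clones by CDR3 Hamming distance
#'
#' Single-linkage connected components over the graph whose edges join
#' comparable clones at normalised Hamming distance at or below `threshold`.
#' In `"cdr3"` mode (default) clones are comparable whenever their CDR3
#' amino-acid sequences have equal length; `"stratified"` mode additionally
#' requires identical V and J genes. Incomparable pairs are never linked.
#' Clusters are numbered deterministically by their largest member frequency,
#' ties broken by the lexicographically smallest clone key.
#'
#' @param clones A clone tibble (duplicated clone keys across samples are
#'   collapsed; a key's frequency is its maximum over samples).
#' @param threshold Normalised Hamming threshold in \[0, 1\].
#' @param mode `"cdr3"` or `"stratified"`.
#' @return A `bcr_clusters` object; `tidy()` gives `clone_key`, `cdr3_aa`,
#'   `cluster_id`, `cluster_size`; `glance()` the cluster count and settings.
#' @export
cluster_clones <- function(clones, threshold, mode = c("cdr3", "stratified")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    rlang::abort("threshold must be in [0, 1]", class = "bcr_parameter_error")
  }
  stopifnot_cols(clones, c("clone_key", "v_call", "j_call", "cdr3_aa"),
                 what = "clones")
  cl <- clones |>
    dplyr::group_by(.data$clone_key) |>
    dplyr::summarise(
      v_call = dplyr::first(.data$v_call),
      j_call = dplyr::first(.data$j_call),
      cdr3_aa = dplyr::first(.data$cdr3_aa),
      frequency = if ("frequency" %in% names(clones)) {
        max(.data$frequency)
      } else NA_real_,
      .groups = "drop"
    )
  n <- nrow(cl)
  groups <- split(seq_len(n), comparability_groups(cl, mode))
  edges <- lapply(groups, function(idx) {
    if (length(idx) < 2) return(NULL)
    D <- hamming_matrix(cl$cdr3_aa[idx])
    hit <- which(upper.tri(D) & D <= threshold, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    cbind(idx[hit[, 1]], idx[hit[, 2]])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)$membership

  # deterministic numbering: by max member frequency, then smallest key
  ord <- tibble::tibble(comp = comp, freq = cl$frequency, key = cl$clone_key) |>
    dplyr::group_by(.data$comp) |>
    dplyr::summarise(top = max(.data$freq), key = min(.data$key),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$top), .data$key)
  relabel <- stats::setNames(seq_len(nrow(ord)), ord$comp)
  cluster_id <- unname(relabel[as.character(comp)])
  members <- cl |>
    dplyr::mutate(cluster_id = cluster_id) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::mutate(cluster_size = dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cluster_id, dplyr::desc(.data$frequency),
                   .data$clone_key)
  structure(
    list(members = members, threshold_used = threshold, threshold_mode = mode,
         n_clusters = max(cluster_id)),
    class = "bcr_clusters"
  )
}

#' @export
tidy.bcr_clusters <- function(x, ...) x$members

#' @export
glance.bcr_clusters <- function(x, ...) {
  tibble::tibble(
    n_clones = nrow(x$members),
    n_clusters = x$n_clusters,
    threshold_used = x$threshold_used,
    comparability = x$threshold_mode
  )
}

#' @export
print.bcr_clusters <- function(x, ...) {
  cat(sprintf("<bcr_clusters> %d clones in %d clusters (threshold %.3f, %s comparability)\n",
              nrow(x$members), x$n_clusters, x$threshold_used,
              x$threshold_mode))
  invisible(x)
}

#' Test query clones for relatedness to a reference pool
#'
#' For every query clone, reports whether any comparable reference clone lies
#' within the Hamming threshold and the distance to the nearest comparable
#' reference (or `NA` when no reference shares its CDR3 length / stratum).
#' Used to ask whether newly dominant follow-up clones relate to anything in
#' the baseline repertoire.
#'
#' @param query,reference Clone tibbles.
#' @param threshold Normalised Hamming threshold in \[0, 1\].
#' @param mode Comparability mode as in [cluster_clones()].
#' @return A tibble: `clone_key`, `cdr3_aa`, `related`, `nearest_distance`.
#' @export
relatedness_test <- function(query, reference, threshold,
                             mode = c("cdr3", "stratified")) {
  mode <- match.arg(mode)
  if (nrow(query) == 0 || nrow(reference) == 0) {
    rlang::abort("query and reference must be non-empty",
                 class = "bcr_input_error")
  }
  q <- dplyr::distinct(query, .data$clone_key, .keep_all = TRUE)
  r <- dplyr::distinct(reference, .data$clone_key, .keep_all = TRUE)
  qg <- comparability_groups(q, mode)
  rg <- comparability_groups(r, mode)
  nearest <- vapply(seq_len(nrow(q)), function(i) {
    cand <- r$cdr3_aa[rg == qg[i]]
    if (length(cand) == 0) return(NA_real_)
    L <- nchar(q$cdr3_aa[i])
    a <- utf8ToInt(q$cdr3_aa[i])
    M <- matrix(utf8ToInt(paste(cand, collapse = "")), nrow = L)
    min(colSums(M != a) / L)
  }, numeric(1))
  tibble::tibble(
    clone_key = q$clone_key,
    cdr3_aa = q$cdr3_aa,
    nearest_distance = nearest,
    related = !is.na(nearest) & nearest <= threshold
  )
}
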