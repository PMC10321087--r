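# Clonotype aggregation: sequence records -> per-sample clone tables with
# UMI-based relative frequencies.

#' Aggregate sequence records into clones
#'
#' Groups records by clonotype key — V gene, J gene and CDR3 sequence
#' (amino-acid by default, allele suffixes stripped) — sums UMI counts,
#' computes each clone's relative frequency as its share of the sample's
#' total UMI-corrected reads, and the clone's mutation rate as the
#' UMI-weighted mean of the member records' mutations per aligned V base
#' pair. Clones at or above `threshold` are flagged dominant (highly
#' expanded).
#'
#' @param records A sequence-record tibble (see [read_sequence_table()]).
#'   All rows must share one `sample_id`; use [call_clones_all()] for
#'   multi-sample tables. Metadata columns `patient_id`, `compartment`,
#'   `timepoint` are carried through when present.
#' @param key Clone identity on the CDR3 amino-acid (`"aa"`, default) or
#'   nucleotide (`"nt"`) sequence.
#' @param threshold Dominance threshold on clone frequency (default 0.005,
#'   i.e. 0.5% of the repertoire; comparison is inclusive).
#' @return A clone tibble: one row per clonotype with `sample_id`, `v_call`,
#'   `j_call`, `cdr3_aa`, `cdr3_nt` (`;`-joined variants), `clone_key`,
#'   `umi_count`, `frequency`, `mutation_rate`, `is_dominant`. Frequencies
#'   sum to 1 per sample.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   sample_id = "s1", v_call = c("IGHV3-23", "IGHV3-23", "IGHV1-2"),
#'   j_call = "IGHJ4", cdr3_nt = NA_character_,
#'   cdr3_aa = c("CARDYW", "CARDYW", "CAKGGW"),
#'   umi_count = c(3L, 2L, 5L), v_mutation_count = c(6L, 6L, 0L),
#'   v_aligned_bp = 300L
#' )
#' call_clones(rec)
call_clones <- function(records, key = c("aa", "nt"), threshold = 0.005) {
  key <- match.arg(key)
  stopifnot_cols(records, setdiff(seq_cols_required, c("cdr3_nt")),
                 what = "records")
  if (nrow(records) == 0) {
    rlang::abort("cannot call clones on an empty record set",
                 class = "bcr_input_error")
  }
  ids <- unique(records$sample_id)
  if (length(ids) != 1) {
    rlang::abort(sprintf(
      "records mix %d sample_ids (%s ...); use call_clones_all()",
      length(ids), paste(head(ids, 3), collapse = ", ")
    ), class = "bcr_input_error")
  }
  call_clones_impl(records, key = key, threshold = threshold)
}

#' Call clones for every sample in a multi-sample record table
#'
#' @param records A sequence-record tibble covering one or more samples.
#' @inheritParams call_clones
#' @return A clone tibble with one block per sample (frequencies sum to 1
#'   within each `sample_id`).
#' @export
call_clones_all <- function(records, key = c("aa", "nt"), threshold = 0.005) {
  key <- match.arg(key)
  stopifnot_cols(records, setdiff(seq_cols_required, c("cdr3_nt")),
                 what = "records")
  if (nrow(records) == 0) {
    rlang::abort("cannot call clones on an empty record set",
                 class = "bcr_input_error")
  }
  call_clones_impl(records, key = key, threshold = threshold)
}

# vectorised clonotype aggregation across one or more samples; numeric
# reductions run through base rowsum() on integer group codes (the tested
# dplyr formulation of the same sums is kept in the test suite as an oracle)
call_clones_impl <- function(records, key, threshold) {
  cdr3_id <- if (key == "aa") records$cdr3_aa else records$cdr3_nt
  meta <- intersect(seq_cols_meta, names(records))

  ckey <- clone_key(records$v_call, records$j_call, cdr3_id)
  gid_chr <- paste(records$sample_id, ckey, sep = "\r")
  first_idx <- which(!duplicated(gid_chr))
  gid <- match(gid_chr, gid_chr[first_idx])

  rate_ok <- !is.na(records$v_mutation_count) & !is.na(records$v_aligned_bp)
  rate_num <- ifelse(rate_ok,
                     records$umi_count * records$v_mutation_count /
                       records$v_aligned_bp, 0)
  rate_den <- ifelse(rate_ok, as.numeric(records$umi_count), 0)
  sums <- rowsum(cbind(umi = as.numeric(records$umi_count),
                       num = rate_num, den = rate_den),
                 gid, reorder = FALSE)

  clones <- tibble::tibble(
    sample_id = records$sample_id[first_idx],
    clone_key = ckey[first_idx],
    v_call = strip_allele(records$v_call[first_idx]),
    j_call = strip_allele(records$j_call[first_idx]),
    cdr3_aa = records$cdr3_aa[first_idx],
    umi_count = as.integer(unname(sums[, "umi"])),
    mutation_rate = unname(ifelse(sums[, "den"] > 0,
                                  sums[, "num"] / sums[, "den"], NA_real_))
  )
  for (m in meta) clones[[m]] <- records[[m]][first_idx]

  nt <- clone_nt_variants(records, gid)
  clones$cdr3_nt <- nt[match(seq_len(nrow(clones)), nt$gid), "cdr3_nt",
                       drop = TRUE]

  totals <- rowsum(as.numeric(clones$umi_count), clones$sample_id,
                   reorder = FALSE)
  clones$frequency <- clones$umi_count /
    unname(totals[match(clones$sample_id, rownames(totals)), 1])

  clones <- clones[order(clones$sample_id, -clones$frequency,
                         clones$clone_key, method = "radix"), ]
  clones <- flag_dominant(clones, threshold = threshold)
  cols <- c("sample_id", meta, "v_call", "j_call", "cdr3_aa", "cdr3_nt",
            "clone_key", "umi_count", "frequency", "mutation_rate",
            "is_dominant")
  clones[, cols]
}

# ;-joined sorted CDR3 nucleotide variants per clonotype (gid = integer
# clonotype code per record); the common single-variant case is vectorised,
# only true multi-variant clones pay for a per-group paste
clone_nt_variants <- function(records, gid) {
  keep <- !is.na(records$cdr3_nt)
  nt <- unique(data.frame(gid = gid[keep], cdr3_nt = records$cdr3_nt[keep],
                          stringsAsFactors = FALSE))
  if (nrow(nt) == 0) {
    return(tibble::tibble(gid = integer(), cdr3_nt = character()))
  }
  dup_groups <- unique(nt$gid[duplicated(nt$gid)])
  single <- nt[!nt$gid %in% dup_groups, ]
  if (length(dup_groups) > 0) {
    multi_rows <- nt[nt$gid %in% dup_groups, ]
    joined <- vapply(split(multi_rows$cdr3_nt, multi_rows$gid), function(v) {
      paste(sort(v), collapse = ";")
    }, character(1))
    multi <- data.frame(gid = as.integer(names(joined)),
                        cdr3_nt = unname(joined), stringsAsFactors = FALSE)
    tibble::as_tibble(rbind(single, multi))
  } else {
    tibble::as_tibble(single)
  }
}

#' Set dominance flags on a clone table
#'
#' A clone is dominant (a highly expanded clone) when its frequency is at or
#' above `threshold`; the comparison is inclusive, so a clone exactly at the
#' threshold is dominant.
#'
#' @param clones A clone tibble.
#' @param threshold Frequency threshold in (0, 1); default 0.005.
#' @return `clones` with `is_dominant` recomputed.
#' @export
flag_dominant <- function(clones, threshold = 0.005) {
  check_threshold(threshold)
  dplyr::mutate(clones, is_dominant = .data$frequency >= threshold)
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold <= 0 || threshold >= 1) {
    rlang::abort("threshold must be a single number in (0, 1)",
                 class = "bcr_parameter_error")
  }
  invisible(threshold)
}
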