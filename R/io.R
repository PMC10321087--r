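# Readers/writers for AIRR-style sequence tables, clone tables and the
# clinical metadata table. All readers are strict: rows that violate the
# domain invariants are rejected with row-numbered diagnostics, never
# silently dropped.

seq_cols_required <- c(
  "sample_id", "v_call", "j_call", "cdr3_nt", "cdr3_aa",
  "umi_count", "v_mutation_count", "v_aligned_bp"
)
seq_cols_meta <- c("patient_id", "compartment", "timepoint")

# AIRR Rearrangement column names accepted as aliases of the minimal dialect
airr_aliases <- c(
  junction = "cdr3_nt",
  junction_aa = "cdr3_aa",
  duplicate_count = "umi_count",
  v_sequence_alignment_length = "v_aligned_bp",
  v_mutation = "v_mutation_count"
)

#' Read an AIRR-style heavy-chain sequence table
#'
#' Reads a tab-separated table with one row per unique UMI-quantified
#' heavy-chain sequence. Two dialects are accepted: `"minimal"` uses the
#' package's own column names (`sample_id`, `v_call`, `j_call`, `cdr3_nt`,
#' `cdr3_aa`, `umi_count`, `v_mutation_count`, `v_aligned_bp`), while
#' `"airr"` additionally accepts AIRR Rearrangement names (`junction`,
#' `junction_aa`, `duplicate_count`) as aliases. Empty fields and `"."` are
#' read as missing.
#'
#' Rows violating the record invariants (`umi_count >= 1`,
#' `v_mutation_count <= v_aligned_bp`, CDR3 nucleotide length equal to three
#' times the amino-acid length when both are present) are rejected; the
#' returned tibble carries a `diagnostics` attribute with one row per
#' rejected input row, and the reader guarantees
#' `nrow(input) == nrow(records) + nrow(diagnostics)`.
#'
#' @param path Path to a TSV file.
#' @param dialect `"airr"` (default; accepts AIRR aliases) or `"minimal"`.
#' @return A tibble of validated sequence records in file order, with a
#'   `diagnostics` attribute (tibble with columns `row` and `problem`).
#' @export
read_sequence_table <- function(path, dialect = c("airr", "minimal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "bcr_io_error")
  }
  raw <- readr::read_tsv(
    path,
    na = c("", ".", "NA"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (dialect == "airr") {
    hits <- intersect(names(airr_aliases), names(raw))
    for (h in hits) {
      if (!airr_aliases[[h]] %in% names(raw)) {
        names(raw)[names(raw) == h] <- airr_aliases[[h]]
      }
    }
  }
  stopifnot_cols(raw, seq_cols_required, what = basename(path))
  validate_sequence_records(raw, source = basename(path))
}

# Shared validator: coerces types, rejects invariant-violating rows with
# row-numbered diagnostics attached as an attribute.
validate_sequence_records <- function(raw, source = "records") {
  n_in <- nrow(raw)
  out <- raw
  int_cols <- c("umi_count", "v_mutation_count", "v_aligned_bp")
  problems <- character(n_in)

  is_intlike <- function(x) grepl("^[0-9]+$", x %||% "")
  for (col in int_cols) {
    x <- as.character(out[[col]])
    bad <- !is.na(x) & !is_intlike(x)
    problems[bad] <- paste0(problems[bad], sprintf("non-integer %s; ", col))
    x[bad] <- NA
    out[[col]] <- suppressWarnings(as.integer(x))
  }
  bad_na <- rowSums(is.na(out[c("sample_id", "v_call", "j_call", "cdr3_aa",
                                "umi_count")])) > 0
  problems[bad_na & problems == ""] <- "missing required field; "
  ok_umi <- !is.na(out$umi_count) & out$umi_count >= 1L
  problems[!ok_umi & problems == ""] <- "umi_count < 1; "
  bad_mut <- !is.na(out$v_mutation_count) & !is.na(out$v_aligned_bp) &
    (out$v_mutation_count > out$v_aligned_bp | out$v_aligned_bp < 1L |
       out$v_mutation_count < 0L)
  problems[bad_mut & problems == ""] <- "v_mutation_count exceeds v_aligned_bp; "
  both <- !is.na(out$cdr3_nt) & !is.na(out$cdr3_aa)
  bad_len <- both & nchar(out$cdr3_nt) != 3L * nchar(out$cdr3_aa)
  problems[bad_len & problems == ""] <- "cdr3_nt length != 3 x cdr3_aa length; "

  keep <- problems == ""
  diagnostics <- tibble::tibble(
    row = which(!keep),
    problem = sub("; $", "", problems[!keep])
  )
  records <- tibble::as_tibble(out[keep, , drop = FALSE])
  if (nrow(diagnostics) > 0) {
    rlang::warn(sprintf(
      "%s: rejected %d of %d rows (see attr(x, 'diagnostics'))",
      source, nrow(diagnostics), n_in
    ))
  }
  bcr_log("%s: %d rows in, %d records kept, %d rejected",
          source, n_in, nrow(records), nrow(diagnostics))
  attr(records, "diagnostics") <- diagnostics
  records
}

clinical_subtypes <- c("DM", "NM/OM", "IMNM", "ASS")
clinical_ab_classes <- c("MSA", "MAA", "seronegative")

#' Read a clinical metadata table
#'
#' One row per patient: `patient_id`, `subtype` (DM, NM/OM, IMNM, ASS),
#' `antibody_class` (MSA, MAA, seronegative), `ck_baseline` (serum creatine
#' kinase, U/L), `mmt_baseline`, `mmt_followup` (manual muscle testing
#' scores), `tis` (total improvement score, 0-100) and `weeks_observed`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of validated clinical records.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "bcr_io_error")
  }
  raw <- readr::read_tsv(path, na = c("", ".", "NA"),
                         show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(raw, c("patient_id", "subtype", "antibody_class",
                        "ck_baseline", "tis"), what = basename(path))
  dup <- raw$patient_id[duplicated(raw$patient_id)]
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicate patient_id: %s",
                         paste(unique(dup), collapse = ", ")),
                 class = "bcr_format_error")
  }
  bad_sub <- !is.na(raw$subtype) & !raw$subtype %in% clinical_subtypes
  if (any(bad_sub)) {
    rlang::abort(sprintf("row %s: unknown subtype label '%s'",
                         which(bad_sub)[1], raw$subtype[bad_sub][1]),
                 class = "bcr_format_error")
  }
  bad_tis <- !is.na(raw$tis) & (raw$tis < 0 | raw$tis > 100)
  if (any(bad_tis)) {
    rlang::abort(sprintf("row %s: tis = %s outside [0, 100]",
                         which(bad_tis)[1], raw$tis[bad_tis][1]),
                 class = "bcr_format_error")
  }
  bad_ck <- !is.na(raw$ck_baseline) & raw$ck_baseline <= 0
  if (any(bad_ck)) {
    rlang::abort(sprintf("row %s: ck_baseline must be > 0", which(bad_ck)[1]),
                 class = "bcr_format_error")
  }
  bcr_log("%s: %d clinical records", basename(path), nrow(raw))
  tibble::as_tibble(raw)
}

#' Write / read a clone table
#'
#' Writes one row per clone with its frequency, dominance flag and mutation
#' rate. Multiple CDR3 nucleotide variants of a clone are `;`-joined in the
#' `cdr3_nt` field. The round trip `read_clone_table(write_clone_table(x))`
#' preserves integer fields exactly and frequencies to full double precision.
#'
#' @param clones A clone tibble as produced by [call_clones()].
#' @param path Output TSV path.
#' @return `path`, invisibly (for `write_clone_table`); a clone tibble (for
#'   `read_clone_table`).
#' @export
write_clone_table <- function(clones, path) {
  cols <- c("sample_id", "v_call", "j_call", "cdr3_aa", "cdr3_nt",
            "umi_count", "frequency", "is_dominant", "mutation_rate")
  extra <- intersect(seq_cols_meta, names(clones))
  out <- clones[, c(intersect(cols, names(clones)), extra), drop = FALSE]
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(out, path, progress = FALSE)
  bcr_log("wrote %d clones to %s", nrow(out), path)
  invisible(path)
}

#' @rdname write_clone_table
#' @export
read_clone_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "bcr_io_error")
  }
  x <- readr::read_tsv(
    path,
    na = c("", ".", "NA"),
    col_types = readr::cols(
      umi_count = readr::col_integer(),
      frequency = readr::col_double(),
      is_dominant = readr::col_logical(),
      mutation_rate = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  x$clone_key <- clone_key(x$v_call, x$j_call, x$cdr3_aa)
  tibble::as_tibble(x)
}
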