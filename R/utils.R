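# Internal helpers: logging, validation, clone keys.

# Stage logging is plain messages so pipelines remain auditable; silence with
# options(bcrclonality.quiet = TRUE).
bcr_log <- function(...) {
  if (!isTRUE(getOption("bcrclonality.quiet", FALSE))) {
    rlang::inform(paste0("[bcrclonality] ", sprintf(...)))
  }
  invisible(NULL)
}

stopifnot_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "bcr_format_error")
  }
  invisible(df)
}

#' Strip IG allele suffixes from gene calls
#'
#' Removes the `*01`-style allele designation so clonotype keys are defined at
#' the gene level (e.g. `"IGHV3-23*01"` becomes `"IGHV3-23"`).
#'
#' @param x Character vector of V or J gene calls.
#' @return Character vector of gene-level calls.
#' @export
#' @examples
#' strip_allele(c("IGHV3-23*01", "IGHJ4"))
strip_allele <- function(x) {
  sub("\\*.*$", "", x)
}

#' Build clonotype keys
#'
#' A clonotype is identified by its V gene, J gene and CDR3 amino-acid
#' sequence (allele suffixes stripped). Keys are `"V|J|CDR3"` strings so they
#' can be compared across samples and patients.
#'
#' @param v_call,j_call,cdr3 Character vectors (recycled to common length).
#' @param key Identity level for the CDR3 component: `"aa"` (default) or
#'   `"nt"`.
#' @return Character vector of clone keys.
#' @export
#' @examples
#' clone_key("IGHV3-23*01", "IGHJ4", "CARDYW")
clone_key <- function(v_call, j_call, cdr3, key = c("aa", "nt")) {
  key <- match.arg(key)
  paste(strip_allele(v_call), strip_allele(j_call), cdr3, sep = "|")
}

# fraction formatted as percent for reports
fmt_pct <- function(x, digits = 1) sprintf(paste0("%.", digits, "f%%"), 100 * x)
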