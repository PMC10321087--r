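# Independent oracles and fixture builders shared across tests.
# Every oracle here is deliberately naive (loops, enumeration, O(n^2))
# and stays independent of the package implementation it checks.

options(bcrclonality.quiet = TRUE)

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_cdr3 <- function(n, len_choices = 10:16) {
  lens <- if (length(len_choices) == 1) {
    rep(len_choices, n)
  } else {
    sample(len_choices, n, replace = TRUE)
  }
  vapply(lens, function(L) {
    paste(sample(aa20, L, replace = TRUE), collapse = "")
  }, character(1))
}

# minimal clone tibble from a frequency vector
clones_from_freq <- function(f, sample_id = "s1", keys = NULL) {
  n <- length(f)
  if (is.null(keys)) keys <- sprintf("IGHV3-23|IGHJ4|K%06d", seq_len(n))
  tibble::tibble(
    sample_id = sample_id,
    v_call = "IGHV3-23", j_call = "IGHJ4",
    cdr3_aa = sub("^.*\\|", "", keys),
    clone_key = keys,
    umi_count = 1L,
    frequency = f,
    mutation_rate = 0.01,
    is_dominant = f >= 0.005
  )
}

# random clone tibble with integer UMI counts (exact frequencies)
random_repertoire <- function(n, sample_id = "s1", max_size = 5000L) {
  sizes <- as.integer(floor(runif(n)^(-2 / 3)))  # heavy-tailed
  sizes <- pmin(pmax(sizes, 1L), max_size)
  f <- sizes / sum(sizes)
  cl <- clones_from_freq(f, sample_id = sample_id)
  cl$umi_count <- sizes
  cl
}

# naive dominant-clone oracle: plain filter-and-sum scan
naive_dominant <- function(f, threshold) {
  keep <- f >= threshold
  list(n_dominant = sum(keep), impact = sum(f[keep]))
}

# O(n^2) pairwise-difference Gini
gini_pairwise <- function(f) {
  n <- length(f)
  sum(abs(outer(f, f, "-"))) / (2 * n * sum(f))
}

# brute-force single-linkage components via union-find;
# comparable = equal CDR3 length (mode "cdr3") or equal V/J/length
brute_components <- function(cdr3, groups, threshold) {
  n <- length(cdr3)
  ints <- lapply(cdr3, utf8ToInt)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (groups[i] != groups[j]) next
      a <- ints[[i]]; b <- ints[[j]]
      if (length(a) != length(b)) next
      if (sum(a != b) / length(a) <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# canonical form of a partition for set comparison
partition_sets <- function(labels, items) {
  unname(sort(vapply(split(items, labels), function(v) {
    paste(sort(v), collapse = ",")
  }, character(1))))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# small synthetic sequence-record table
toy_records <- function() {
  tibble::tibble(
    sample_id = "s1",
    v_call = c("IGHV3-23*01", "IGHV3-23", "IGHV1-2"),
    j_call = c("IGHJ4", "IGHJ4*02", "IGHJ6"),
    cdr3_nt = c("TGTGCAAGATGG", "TGTGCAAGGTGG", "TGTGCAAAATGG"),
    cdr3_aa = c("CARW", "CARW", "CAKW"),
    umi_count = c(3L, 2L, 5L),
    v_mutation_count = c(6L, 9L, 0L),
    v_aligned_bp = c(300L, 300L, 250L)
  )
}

write_tsv_tmp <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path, progress = FALSE)
  path
}
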