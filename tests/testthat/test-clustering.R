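test_that("normalised Hamming distance counts mismatches per position", {
  expect_equal(hamming_distance("CARDY", "CARDF"), 0.2)
  expect_equal(hamming_distance("CARDY", "CARDY"), 0)
  expect_true(is.na(hamming_distance("CARDY", "CARDYY")))
  expect_error(hamming_distance("", "A"), class = "bcr_input_error")
})

test_that("hamming distance satisfies the metric axioms on equal lengths", {
  withr::local_seed(31)
  for (i in 1:50) {
    s <- rand_cdr3(3, len_choices = 12)
    dab <- hamming_distance(s[1], s[2])
    dba <- hamming_distance(s[2], s[1])
    dac <- hamming_distance(s[1], s[3])
    dbc <- hamming_distance(s[2], s[3])
    expect_identical(dab, dba)
    expect_gte(dab + dbc, dac - 1e-12)
    expect_identical(hamming_distance(s[1], s[1]), 0)
    expect_true(dab > 0 || s[1] == s[2])
  }
})

clone_pool <- function(cdr3, v = "IGHV3-23", j = "IGHJ4", freq = NULL) {
  n <- length(cdr3)
  if (is.null(freq)) freq <- rep(1 / n, n)
  tibble::tibble(
    sample_id = "s1", v_call = v, j_call = j, cdr3_aa = cdr3,
    clone_key = paste(v, j, cdr3, sep = "|"),
    frequency = freq, umi_count = 1L,
    is_dominant = FALSE
  )
}

test_that("threshold limit cases: 0 groups identical CDR3s, 1 merges lengths", {
  cdr3 <- c("CARDY", "CARDY", "CARDF", "CAKLMW", "CAKLMW")
  cl <- clone_pool(cdr3)
  cl$clone_key <- paste0(cl$clone_key, "#", seq_len(nrow(cl)))  # keep dupes

  t0 <- tidy(cluster_clones(cl, threshold = 0))
  grp <- split(t0$cdr3_aa, t0$cluster_id)
  expect_true(all(vapply(grp, function(g) length(unique(g)) == 1,
                         logical(1))))

  t1 <- tidy(cluster_clones(cl, threshold = 1))
  expect_equal(glance(cluster_clones(cl, threshold = 1))$n_clusters,
               length(unique(nchar(cdr3))))
  expect_true(all(tapply(nchar(t1$cdr3_aa), t1$cluster_id,
                         function(x) length(unique(x))) == 1))
})

test_that("raising the threshold only merges clusters", {
  withr::local_seed(12)
  cl <- clone_pool(rand_cdr3(80, len_choices = c(10, 11)))
  prev <- tidy(cluster_clones(cl, 0.05))
  for (th in c(0.2, 0.5, 1)) {
    cur <- tidy(cluster_clones(cl, th))
    m <- match(prev$clone_key, cur$clone_key)
    # every cluster of the finer partition maps into one coarser cluster
    expect_true(all(tapply(cur$cluster_id[m], prev$cluster_id,
                           function(x) length(unique(x))) == 1))
    prev <- cur
  }
})

test_that("stratified mode never links across V/J strata", {
  cdr3 <- rep("CARDYW", 4)
  cl <- clone_pool(cdr3, v = c("IGHV3-23", "IGHV3-23", "IGHV1-2", "IGHV1-2"))
  cl$clone_key <- paste(cl$v_call, cl$j_call, cl$cdr3_aa, seq_len(4),
                        sep = "|")
  g_cdr3 <- glance(cluster_clones(cl, 0.2, mode = "cdr3"))
  g_strat <- glance(cluster_clones(cl, 0.2, mode = "stratified"))
  expect_equal(g_cdr3$n_clusters, 1)
  expect_equal(g_strat$n_clusters, 2)
})

test_that("dynamic threshold finds the valley between separated modes", {
  withr::local_seed(77)
  ok <- 0
  for (i in 1:20) {
    d <- c(pmax(rnorm(120, 0.07, 0.02), 0), pmin(rnorm(120, 0.5, 0.08), 1))
    th <- select_threshold(d)
    if (th$mode == "dynamic" && th$threshold > 0.1 && th$threshold < 0.4) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, 19)
})

test_that("degenerate pools fall back to the configured threshold", {
  expect_equal(select_threshold(rep(0, 50))$mode, "fallback")
  expect_equal(select_threshold(rep(0, 50), fallback = 0.2)$threshold, 0.2)
  # all clones identical -> unimodal at zero -> fallback, with warning
  cl <- clone_pool(rep("CARDYW", 30))
  expect_warning(th <- dynamic_threshold(cl), "fallback")
  expect_equal(th$mode, "fallback")
})

test_that("threshold estimation is invariant to duplicating every clone", {
  withr::local_seed(41)
  cl <- clone_pool(rand_cdr3(60, len_choices = 12))
  dup <- dplyr::bind_rows(cl, dplyr::mutate(cl, sample_id = "s2"))
  expect_identical(nn_distances(cl), nn_distances(dup))
})

test_that("relatedness test reports nearest comparable reference", {
  q <- clone_pool(c("CARDYW", "CARDFW", "CAKLMNPQW"))
  ref <- clone_pool(c("CARDYW", "CAAAAA"))
  r <- relatedness_test(q, ref, threshold = 0.2)
  expect_true(r$related[1])
  expect_equal(r$nearest_distance[1], 0)
  expect_equal(r$nearest_distance[2], 1 / 6)   # one mismatch to CARDYW
  # length 9 absent from the reference -> incomparable
  expect_false(r$related[3])
  expect_true(is.na(r$nearest_distance[3]))
  expect_error(relatedness_test(q[0, ], ref, 0.2), class = "bcr_input_error")
})
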