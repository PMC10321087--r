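make_pair <- function(n_a = 60, n_b = 80, n_shared = 30, n_dom_shared = 5) {
  keys_a <- sprintf("IGHV3-23|IGHJ4|A%03d", seq_len(n_a))
  keys_b <- sprintf("IGHV3-23|IGHJ4|B%03d", seq_len(n_b))
  keys_b[seq_len(n_shared)] <- keys_a[seq_len(n_shared)]
  fa <- rep(1 / n_a, n_a); fb <- rep(1 / n_b, n_b)
  a <- clones_from_freq(fa, "a", keys_a)
  b <- clones_from_freq(fb, "b", keys_b)
  # plant dominant-in-both flags on the first n_dom_shared shared keys
  a$is_dominant <- b$is_dominant <- FALSE
  a$is_dominant[seq_len(n_dom_shared)] <- TRUE
  b$is_dominant[seq_len(n_dom_shared)] <- TRUE
  list(a = a, b = b)
}

test_that("overlap recovers planted shared and dominant-in-both counts", {
  p <- make_pair()
  g <- glance(compute_overlap(p$a, p$b))
  expect_equal(g$n_shared, 30)
  expect_equal(g$n_shared_dominant, 5)
  t <- tidy(compute_overlap(p$a, p$b))
  expect_true(all(t$freq_a == 1 / 60 & t$freq_b == 1 / 80))
})

test_that("overlap is symmetric and handles disjoint/identical inputs", {
  p <- make_pair()
  g_ab <- glance(compute_overlap(p$a, p$b))
  g_ba <- glance(compute_overlap(p$b, p$a))
  expect_equal(g_ab$n_shared, g_ba$n_shared)
  expect_equal(g_ab$n_shared_dominant, g_ba$n_shared_dominant)

  disj <- clones_from_freq(rep(0.1, 10), "c",
                           sprintf("IGHV1-2|IGHJ6|C%03d", 1:10))
  expect_equal(glance(compute_overlap(p$a, disj))$n_shared, 0)
  g_id <- glance(compute_overlap(p$a, p$a))
  expect_equal(g_id$n_shared, nrow(p$a))
  expect_equal(g_id$n_shared_dominant, sum(p$a$is_dominant))
})

test_that("turnover partitions baseline dominants into persisting and lost", {
  withr::local_seed(2)
  base <- random_repertoire(300, "P1_blood_baseline")
  base$patient_id <- "P1"; base$compartment <- "blood"
  fup <- base
  fup$sample_id <- "P1_blood_week9"

  # identity case
  tv <- turnover(base, fup)
  g <- glance(tv)
  expect_equal(g$n_persisting, g$n_dominant_baseline)
  expect_equal(g$n_lost, 0)
  expect_equal(g$n_new, 0)

  # entirely fresh dominant keys
  fresh <- fup
  fresh$clone_key <- sub("\\|K", "|X", fresh$clone_key)
  g2 <- glance(turnover(base, fresh))
  expect_equal(g2$n_persisting, 0)
  expect_equal(g2$n_new, g2$n_dominant_followup)
  expect_equal(g2$n_lost, g2$n_dominant_baseline)
  expect_equal(g2$n_new_de_novo, g2$n_new)  # keys absent at baseline

  # bookkeeping identities on a mixed case
  mixed <- fresh
  keep_n <- min(3, sum(base$is_dominant))
  mixed$clone_key[seq_len(keep_n)] <-
    base$clone_key[base$is_dominant][seq_len(keep_n)]
  mixed$is_dominant[seq_len(keep_n)] <- TRUE
  mixed$frequency[seq_len(keep_n)] <- 0.01
  g3 <- glance(turnover(base, mixed))
  expect_equal(g3$n_persisting + g3$n_lost, g3$n_dominant_baseline)
  expect_equal(g3$n_persisting + g3$n_new, g3$n_dominant_followup)
  expect_equal(g3$n_lost_absent + g3$n_lost_subthreshold, g3$n_lost)
})

test_that("turnover rejects mismatched patients", {
  a <- clones_from_freq(c(0.6, 0.4), "a"); a$patient_id <- "P1"
  b <- clones_from_freq(c(0.6, 0.4), "b"); b$patient_id <- "P2"
  expect_error(turnover(a, b), "patient", class = "bcr_input_error")
})

test_that("cross-patient sharing finds planted pairs and is symmetric", {
  withr::local_seed(4)
  cohort <- dplyr::bind_rows(lapply(1:4, function(i) {
    cl <- clones_from_freq(rep(0.05, 20), sprintf("P%d_b", i),
                           sprintf("IGHV3-7|IGHJ4|P%d_%03d", i, 1:20))
    cl$patient_id <- sprintf("P%d", i)
    cl$is_dominant <- TRUE
    cl
  }))
  m0 <- cross_patient_sharing(cohort)
  expect_true(all(m0[upper.tri(m0)] == 0))
  expect_identical(m0, t(m0))

  cohort$clone_key[cohort$patient_id == "P2"][1] <-
    cohort$clone_key[cohort$patient_id == "P1"][1]
  m1 <- cross_patient_sharing(cohort)
  expect_equal(m1["P1", "P2"], 1L)
  expect_equal(sum(m1), 2L)  # one symmetric pair only
})
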