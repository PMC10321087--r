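small_cfg <- function(...) {
  cohort_config(n_patients = 6, clones_per_sample = c(120L, 250L), ...)
}

test_that("generation is deterministic given config and seed", {
  cfg <- small_cfg()
  c1 <- generate_cohort(cfg, seed = 5)
  c2 <- generate_cohort(cfg, seed = 5)
  expect_identical(c1$sequences, c2$sequences)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(c1$sequences, c3$sequences))
})

test_that("generated records satisfy the sequence-record invariants", {
  co <- generate_cohort(small_cfg(), seed = 9)
  s <- co$sequences
  expect_true(all(s$umi_count >= 1))
  expect_true(all(s$v_mutation_count <= s$v_aligned_bp))
  expect_true(all(nchar(s$cdr3_nt) == 3 * nchar(s$cdr3_aa)))
  expect_true(all(grepl("^C[ACDEFGHIKLMNPQRSTVWY]+W$", s$cdr3_aa)))
  expect_equal(length(unique(s$sample_id)), 6 * 3)
  # written cohort passes the strict reader without diagnostics
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  one <- read_sequence_table(file.path(dir, "P01_blood_baseline.tsv"))
  expect_equal(nrow(attr(one, "diagnostics")), 0)
  clin <- read_clinical_table(file.path(dir, "clinical.tsv"))
  expect_equal(nrow(clin), 6)
})

test_that("zero sharing rate produces disjoint compartments", {
  co <- generate_cohort(small_cfg(muscle_blood_sharing_rate = 0), seed = 3)
  cl <- call_clones_all(co$sequences)
  for (p in unique(cl$patient_id)) {
    mus <- dplyr::filter(cl, patient_id == p, compartment == "muscle")
    blb <- dplyr::filter(cl, patient_id == p, compartment == "blood",
                         timepoint == "baseline")
    expect_equal(glance(compute_overlap(mus, blb))$n_shared, 0)
  }
})

test_that("planted dominant sharing and HEC-free designations are recovered", {
  co <- generate_cohort(cohort_config(n_patients = 10,
                                      clones_per_sample = c(200L, 400L),
                                      frac_blood_without_dominant = 0.3,
                                      dominant_sharing_patients = 2),
                        seed = 17)
  cl <- call_clones_all(co$sequences)
  hec <- call_dominant(cl)
  bb <- dplyr::filter(hec, compartment == "blood", timepoint == "baseline")
  expect_setequal(bb$patient_id[bb$n_dominant == 0],
                  co$truth$no_dominant_blood_patients)

  sharing <- vapply(sort(unique(cl$patient_id)), function(p) {
    mus <- dplyr::filter(cl, patient_id == p, compartment == "muscle")
    blb <- dplyr::filter(cl, patient_id == p, compartment == "blood",
                         timepoint == "baseline")
    glance(compute_overlap(mus, blb))$n_shared_dominant
  }, integer(1))
  expect_setequal(names(sharing)[sharing > 0],
                  co$truth$dominant_sharing_patients)
})

test_that("turnover ledger matches the pipeline-recovered loss counts", {
  co <- generate_cohort(small_cfg(frac_blood_without_dominant = 0), seed = 23)
  cl <- call_clones_all(co$sequences)
  for (pt in co$truth$patients) {
    blb <- dplyr::filter(cl, patient_id == pt$patient_id,
                         compartment == "blood", timepoint == "baseline")
    blw <- dplyr::filter(cl, patient_id == pt$patient_id,
                         compartment == "blood", timepoint == "week9")
    g <- glance(turnover(blb, blw))
    expect_equal(g$n_dominant_baseline, pt$n_turnover_trials)
    expect_equal(g$n_lost, pt$n_lost)
    expect_setequal(tidy(turnover(blb, blw))$clone_key[
      tidy(turnover(blb, blw))$status == "persisting"], pt$kept_keys)
  }
})

test_that("muscle repertoires carry a higher mutation load than blood", {
  co <- generate_cohort(small_cfg(), seed = 29)
  cl <- call_clones_all(co$sequences)
  base <- dplyr::filter(cl, timepoint == "baseline")
  p <- group_compare(base$mutation_rate, base$compartment)$p_value
  expect_lt(p, 1e-10)
  ml <- mutation_load(base) |>
    dplyr::left_join(dplyr::distinct(base, sample_id, compartment),
                     by = "sample_id")
  expect_gt(min(ml$mean_mutation_rate[ml$compartment == "muscle"]),
            max(ml$mean_mutation_rate[ml$compartment == "blood"]))
})

test_that("muscle V-gene usage is biased toward the configured genes", {
  withr::local_seed(1)
  hits <- replicate(10, {
    co <- generate_cohort(small_cfg(), seed = sample.int(1e6, 1))
    cl <- call_clones_all(co$sequences)
    mus <- dplyr::filter(cl, compartment == "muscle")
    u <- vj_usage(mus)$v |>
      dplyr::group_by(v_call) |>
      dplyr::summarise(frequency = mean(frequency), .groups = "drop")
    u$v_call[which.max(u$frequency)] %in%
      c("IGHV4-31", "IGHV3-23", "IGHV3-3", "IGHV3-74")
  })
  expect_true(all(hits))
})

test_that("clone-size tail exponent matches the configured law", {
  withr::local_seed(13)
  s <- bcrclonality:::sample_clone_sizes(1e4, alpha = 1.5, cap_freq = 0.99,
                                         min_depth = 0)
  u <- quantile(s, 0.9)
  tail <- s[s >= u]
  hill <- 1 / mean(log(tail / u))          # Hill estimator of the exponent
  expect_lt(abs(hill - 1.5), 0.2)
})

test_that("null cohorts zero the clinical couplings but keep turnover", {
  cfg <- small_cfg()
  co <- generate_null_cohort(cfg, seed = 37)
  expect_equal(unname(unlist(co$truth$couplings)), rep(0, 4))
  expect_equal(co$truth$turnover, cfg$turnover)
  # repertoire side unchanged in structure: same sample inventory
  expect_equal(length(unique(co$sequences$sample_id)), 18)
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(subtype_mix = c(DM = 0.5, `NM/OM` = 0.2,
                                             IMNM = 0.2, ASS = 0.2)),
               "sum to 1", class = "bcr_parameter_error")
  expect_error(cohort_config(turnover = 1.2), class = "bcr_parameter_error")
  expect_error(cohort_config(clone_size_law = 0.9),
               class = "bcr_parameter_error")
  expect_error(generate_cohort(small_cfg(muscle_blood_sharing_rate = 1),
                               seed = 2),
               class = "bcr_parameter_error")
})
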