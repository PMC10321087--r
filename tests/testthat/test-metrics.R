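test_that("sorted Gini matches the O(n^2) pairwise oracle", {
  withr::local_seed(9)
  expect_equal(gini_index(c(0.9, 0.1)), gini_pairwise(c(0.9, 0.1)),
               tolerance = 1e-12)
  for (i in 1:10) {
    f <- runif(sample(2:200, 1))
    f <- f / sum(f)
    expect_equal(gini_index(f), gini_pairwise(f), tolerance = 1e-10)
  }
})

test_that("gini-simpson and log2 entropy variants are available", {
  f <- c(0.5, 0.25, 0.25)
  d <- diversity_vec(f, variant = "gini_simpson", base = 2)
  expect_equal(d$simpson, 1 - sum(f^2))
  expect_equal(d$shannon, -sum(f * log2(f)))
})

test_that("merging two identical repertoires leaves indices unchanged", {
  withr::local_seed(3)
  cl <- random_repertoire(200)
  doubled <- cl
  doubled$umi_count <- doubled$umi_count * 2L
  doubled$frequency <- doubled$umi_count / sum(doubled$umi_count)
  d1 <- diversity_indices(cl)
  d2 <- diversity_indices(doubled)
  expect_equal(d1$simpson, d2$simpson, tolerance = 1e-12)
  expect_equal(d1$shannon, d2$shannon, tolerance = 1e-12)
  expect_equal(d1$gini, d2$gini, tolerance = 1e-12)
})

test_that("mutation load is the UMI-weighted mean over rated clones", {
  cl <- clones_from_freq(c(0.6, 0.3, 0.1))
  cl$umi_count <- c(6L, 3L, 1L)
  cl$mutation_rate <- c(6 / 300, 0, NA)
  ml <- mutation_load(cl)
  expect_equal(ml$mean_mutation_rate, (6 * 0.02 + 3 * 0) / 9)
  expect_equal(ml$n_clones_excluded, 1L)
  cl$mutation_rate <- c(0, 0, 0)
  expect_equal(mutation_load(cl)$mean_mutation_rate, 0)
})

test_that("CDR3 net charge counts R/K against D/E, ignoring histidine", {
  expect_equal(cdr3_charge("CARDRSYW"), 1L)   # 2 R - 1 D
  expect_equal(cdr3_charge("CAAAAW"), 0L)
  expect_equal(cdr3_charge("CHHHW"), 0L)      # H not counted
  expect_true(is.na(cdr3_charge("CAXBW")))    # non-standard letters
})

test_that("cdr3 profiles are frequency weighted and sum to one", {
  cl <- clones_from_freq(c(0.5, 0.3, 0.2))
  cl$cdr3_aa <- c("CARDYW", "CARW", "CAKW")   # lengths 6, 4, 4
  p <- cdr3_profiles(cl)
  expect_equal(sum(p$length$weight), 1)
  expect_equal(p$length$weight[p$length$cdr3_length == 4], 0.5)
  wm <- sum(cl$frequency * nchar(cl$cdr3_aa))
  expect_equal(sum(p$length$cdr3_length * p$length$weight), wm)
  expect_equal(sum(p$charge$weight), 1)
})

test_that("V/J usage normalises per sample and respects the weighting", {
  cl <- clones_from_freq(c(0.7, 0.2, 0.1))
  cl$v_call <- c("IGHV3-23", "IGHV3-23", "IGHV1-2")
  cl$j_call <- "IGHJ4"
  cl$umi_count <- c(70L, 20L, 10L)
  u_clone <- vj_usage(cl, weighting = "clone")
  u_umi <- vj_usage(cl, weighting = "umi")
  expect_equal(u_clone$v$frequency[u_clone$v$v_call == "IGHV3-23"], 2 / 3)
  expect_equal(u_umi$v$frequency[u_umi$v$v_call == "IGHV3-23"], 0.9)
  expect_equal(u_clone$j$frequency, 1)  # point mass on IGHJ4
  expect_equal(sum(u_umi$vj$frequency), 1)
  expect_equal(nrow(top_genes(u_clone$v, k = 1)), 1)
})

test_that("per-sample summary combines clonality, diversity and mutation", {
  withr::local_seed(15)
  cl <- dplyr::bind_rows(random_repertoire(100, "a"),
                         random_repertoire(50, "b"))
  s <- summarize_repertoire(cl)
  expect_equal(nrow(s), 2)
  expect_true(all(c("impact", "simpson", "shannon", "gini",
                    "mean_mutation_rate", "mean_cdr3_length") %in% names(s)))
  expect_equal(s$n_clones, c(100L, 50L))
  expect_true(all(s$simpson >= 1 / s$n_clones - 1e-12))
  expect_true(all(s$shannon <= log(s$n_clones) + 1e-12))
})
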