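# Frozen oracle values for the D'Agostino-Pearson omnibus test were computed
# independently with scipy.stats.normaltest (scipy 1.17.1) on the fixed
# vectors below.
dap_fixtures <- list(
  normal60 = list(
    x = c(0.454747,0.955391,-0.937624,-0.304331,0.888678,0.925275,-0.432089,
          1.826972,0.182075,1.196351,-0.561080,-0.655929,0.714524,-0.034036,
          0.560299,-0.304407,0.231201,-0.857105,-2.274552,-0.515066,0.604499,
          0.494550,0.068057,-0.832264,0.601322,1.089255,-0.299243,-0.559912,
          0.363529,-1.089734,2.011034,0.298619,1.179401,-0.941445,-0.387707,
          1.327025,-0.001350,0.541235,0.666760,-1.781450,1.334013,-0.818674,
          -0.706324,0.716277,-0.668970,2.130391,-0.274970,-1.536902,-0.842435,
          0.550224,1.100909,-0.115912,-0.444609,0.273577,0.999535,1.330279,
          -0.459537,-0.959432,-0.342151,-2.508577),
    k2 = 0.5832472772929798, p = 0.7470496436860363
  ),
  lognorm40 = list(
    x = c(0.787904,1.179080,0.197018,4.374684,1.089893,0.608221,0.842136,
          0.684944,1.759561,0.857571,1.271950,0.857168,1.806297,0.619755,
          2.764261,0.727826,1.247506,2.554774,0.649133,1.293874,0.656569,
          6.895962,7.533411,1.193790,1.983857,0.461395,2.117189,1.162725,
          0.505458,0.847322,1.895125,0.260805,1.333692,2.957757,0.850180,
          2.798152,1.027565,1.239784,0.227018,0.282185),
    k2 = 38.37577648848466, p = 4.64307839152438e-09
  ),
  unif25 = list(
    x = c(0.753383,0.452999,0.541467,0.720257,0.236405,0.648342,0.488258,
          0.254876,0.119884,0.381973,0.607058,0.140578,0.839922,0.560559,
          0.454854,0.410710,0.608428,0.399389,0.645980,0.583356,0.827762,
          0.407565,0.600823,0.341839,0.092643),
    k2 = 0.6793089763840325, p = 0.7120162903035945
  )
)

test_that("omnibus normality statistic matches the independent oracle", {
  for (f in dap_fixtures) {
    res <- dagostino_pearson(f$x)
    expect_equal(res$statistic, f$k2, tolerance = 1e-10)
    expect_equal(res$p_value, f$p, tolerance = 1e-8)
  }
  expect_error(dagostino_pearson(rnorm(5)), class = "bcr_parameter_error")
  expect_error(dagostino_pearson(rep(1, 20)), class = "bcr_input_error")
})

test_that("normality gate returns the matching descriptive pair", {
  g <- normality_gate(dap_fixtures$normal60$x)
  expect_equal(g$classification, "normal")
  expect_equal(g$summary_type, "mean_sd")
  expect_equal(g$center, mean(dap_fixtures$normal60$x))

  g2 <- normality_gate(dap_fixtures$lognorm40$x)
  expect_equal(g2$classification, "non_normal")
  expect_equal(g2$summary_type, "median_iqr")
  expect_equal(g2$center, median(dap_fixtures$lognorm40$x))

  expect_warning(g3 <- normality_gate(c(1, 2, 3, 4, 5)), "n = 5")
  expect_equal(g3$classification, "non_normal")
  g4 <- normality_gate(rep(2, 30))
  expect_true(g4$degenerate)
  expect_equal(g4$classification, "non_normal")
})

test_that("two-group comparison is an exact Mann-Whitney for small n", {
  r <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$test_used, "mann_whitney")
  expect_equal(r$p_value, 0.1)                      # full enumeration: 2/20
  expect_equal(r$p_value, mw_enum_p(c(1, 2, 3), c(4, 5, 6)))

  same <- group_compare(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)

  expect_error(group_compare(1:3, rep("a", 3)), class = "bcr_input_error")
})

test_that("three or more groups go through Kruskal-Wallis", {
  x <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("a", "b", "c"), each = 3)
  r <- group_compare(x, g)
  expect_equal(r$test_used, "kruskal_wallis")
  expect_equal(r$statistic, unname(kruskal.test(x, factor(g))$statistic))
})

test_that("spearman correlation handles monotone data and transforms", {
  x <- c(3, 1, 7, 9, 2, 8, 5)
  r <- spearman_correlation(x, x^3)          # strictly monotone transform
  expect_equal(r$rho, 1)
  expect_equal(spearman_correlation(x, -x)$rho, -1)
  r2 <- spearman_correlation(x, exp(x))
  expect_equal(r2$rho, 1)
  expect_true(r2$ci_low <= r2$rho && r2$rho <= r2$ci_high)
  expect_error(spearman_correlation(1:3, 1:3), class = "bcr_input_error")
  expect_error(spearman_correlation(1:5, rep(1, 5)),
               class = "bcr_input_error")
})

test_that("fisher-z interval uses variance 1.06/(n-3)", {
  withr::local_seed(8)
  x <- rnorm(19); y <- 0.5 * x + rnorm(19)
  r <- spearman_correlation(x, y)
  z <- atanh(r$rho); se <- sqrt(1.06 / (19 - 3))
  expect_equal(r$ci_low, tanh(z - qnorm(0.975) * se))
  expect_equal(r$ci_high, tanh(z + qnorm(0.975) * se))
})

test_that("rank-coupled bivariate samples recover the planted correlation", {
  withr::local_seed(19)
  rhos <- replicate(200, {
    z <- rnorm(19)
    y <- 0.5 * z + sqrt(1 - 0.25) * rnorm(19)
    suppressWarnings(cor(z, y, method = "spearman"))
  })
  # latent 0.5 corresponds to Spearman (6/pi) asin(0.5/2) ~ 0.482
  expect_lt(abs(mean(rhos) - (6 / pi) * asin(0.25)), 0.1)
})

test_that("responder classification is inclusive at the cutoff", {
  clin <- tibble::tibble(tis = c(40, 39.9, 55, NA))
  expect_warning(r <- classify_responders(clin), "missing tis")
  expect_equal(r$responder, c(TRUE, FALSE, TRUE, NA))
})

test_that("the association panel joins, runs and reports coherently", {
  withr::local_seed(33)
  co <- generate_cohort(cohort_config(), seed = 101)
  hec <- call_dominant(call_clones_all(co$sequences))
  suite <- run_association_suite(hec, co$clinical)
  res <- tidy(suite)
  expect_equal(nrow(res), 14)
  expect_equal(glance(suite)$n_tests, 14)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  sp <- res[res$test_used %in% "spearman", ]
  expect_true(all(sp$ci_low <= sp$rho & sp$rho <= sp$ci_high,
                  na.rm = TRUE))
  # excluding no-HEC patients reduces n for baseline tests
  suite2 <- run_association_suite(hec, co$clinical, include_no_hec = FALSE)
  n1 <- tidy(suite)$n[1]; n2 <- tidy(suite2)$n[1]
  expect_lt(n2, n1)

  # join failure lists unmatched ids
  expect_error(
    run_association_suite(hec, co$clinical[-1, ]),
    "missing from clinical", class = "bcr_input_error"
  )
})
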