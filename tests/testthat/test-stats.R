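test_that("kendall tau hits the perfect concordance bounds", {
  x <- c(1, 4, 6, 9, 12)
  expect_equal(kendall_tau(x, x * 2 + 1)$statistic, 1)
  expect_equal(kendall_tau(x, rev(x))$statistic, -1)
  expect_error(kendall_tau(1:3, 1:4), class = "biofilmq_validation_error")
  expect_error(kendall_tau(c(1, 1, 1), 1:3),
               class = "biofilmq_validation_error")
})

test_that("kendall tau-b agrees with exhaustive pair counting under ties", {
  x <- c(0, 0, 1, 2); y <- c(0, 1, 1, 2)
  expect_equal(kendall_tau(x, y)$statistic, brute_tau_b(x, y),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:300) {
    x <- sample(0:5, 8, replace = TRUE)
    y <- sample(0:5, 8, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y)$statistic, brute_tau_b(x, y),
                 tolerance = 1e-12)
  }
})

test_that("welch test matches the hand formula and is antisymmetric", {
  wt <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(wt$t, -1.2247, tolerance = 1e-4)
  expect_equal(wt$df, 4)
  oracle <- brute_welch(c(1, 2, 3), c(2, 3, 4))
  expect_equal(wt$t, oracle$t, tolerance = 1e-12)
  expect_equal(wt$df, oracle$df, tolerance = 1e-12)

  a <- c(1.2, 3.1, 0.4, 2.2); b <- c(5.5, 4.1, 6.6)
  f <- welch_test(a, b); r <- welch_test(b, a)
  expect_equal(f$t, -r$t)
  expect_equal(f$p_value, r$p_value)

  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  flat <- welch_test(c(2, 2), c(2, 2))
  expect_equal(flat$t, 0); expect_equal(flat$p_value, 1)
  expect_equal(welch_test(c(2, 2), c(3, 3))$p_value, 0)
  expect_error(welch_test(1, c(1, 2)), class = "biofilmq_validation_error")
})

test_that("BH adjustment follows the step-up rule and stays monotone", {
  expect_equal(fdr_adjust(0.03)$q_values, 0.03)
  res <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(res$q_values, rep(0.04, 4))
  expect_true(all(res$significant))
  expect_false(any(fdr_adjust(rep(1, 5))$significant))
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "biofilmq_validation_error")

  set.seed(4)
  for (i in 1:20) {
    p <- runif(12)
    q <- fdr_adjust(p)$q_values
    expect_true(all(q >= p - 1e-12))
    expect_equal(order(q[order(p)]), seq_along(p))  # q preserves p order
  }
})

test_that("OLS fit matches the normal-equations solution", {
  expect_equal(ols_fit(1:5, 1:5)$statistic, 1)
  expect_equal(ols_fit(1:5, 1:5)$r_squared, 1)
  x <- c(0, 1, 2, 3); y <- 3 - 2 * x
  f <- ols_fit(x, y)
  expect_equal(f$statistic, -2); expect_equal(f$r_squared, 1)

  y2 <- c(1, 3, 2, 5)
  f2 <- ols_fit(x, y2)
  o <- brute_ols(x, y2)
  expect_equal(f2$statistic, o$slope, tolerance = 1e-12)
  expect_equal(f2$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(f2$r_squared, o$r_squared, tolerance = 1e-12)

  # R^2 is invariant under affine maps of either axis
  f3 <- ols_fit(3 * x - 1, -2 * y2 + 7)
  expect_equal(f3$r_squared, f2$r_squared, tolerance = 1e-12)

  expect_error(ols_fit(rep(1, 4), y2), class = "biofilmq_validation_error")
  flat <- ols_fit(x, rep(2, 4))
  expect_equal(flat$statistic, 0); expect_equal(flat$r_squared, 0)
})

test_that("identical haploid and diploid replicates give only no_change", {
  rows <- expand.grid(strain = c("A", "B", "C"),
                      ploidy = c("haploid", "diploid"),
                      phenotype = c("flocculation", "invasion"),
                      replicate_id = 1:3, stringsAsFactors = FALSE)
  rows$replicate_type <- "technical"
  # the same {1,2,3} replicate triple in every stratum
  rows$value <- ave(seq_len(nrow(rows)), rows$strain, rows$phenotype,
                    rows$ploidy, FUN = seq_along)
  rows$ordinal_score <- NA_integer_
  pan <- rows[, c("strain", "ploidy", "phenotype", "replicate_type",
                  "replicate_id", "value", "ordinal_score")]
  calls <- classify_ploidy_changes(pan, phenotypes = c("flocculation",
                                                       "invasion"))
  expect_true(all(calls$call == "no_change"))
  expect_true(all(calls$p_value == 1))
})

test_that("strains missing a ploidy are excluded with a warning", {
  pan <- simulate_panel(panel_spec(n_strains = 5, seed = 2))
  pan <- pan[!(pan$strain == "S003" & pan$ploidy == "diploid" &
                 pan$phenotype == "flocculation"), ]
  expect_warning(
    calls <- classify_ploidy_changes(pan, phenotypes = "flocculation"),
    "S003")
  expect_false("S003" %in% calls$strain)
  expect_equal(nrow(calls), 4)
})

test_that("an attenuated phenotype is called decrease, null ones no_change", {
  eff <- setNames(rep(1, length(BIOFILM_PHENOTYPES)), BIOFILM_PHENOTYPES)
  eff["flocculation"] <- 0.2
  pan <- simulate_panel(panel_spec(n_strains = 25, diploid_effect = eff,
                                   replicate_sd = 0.02, seed = 14))
  calls <- classify_ploidy_changes(pan)
  floc <- calls[calls$phenotype == "flocculation", ]
  other <- calls[calls$phenotype != "flocculation", ]
  expect_gte(mean(floc$call == "decrease"), 0.95)
  expect_lte(mean(other$call != "no_change"), 0.10)
  smry <- ploidy_change_summary(calls)
  expect_equal(smry$n_decrease[smry$phenotype == "flocculation"],
               sum(floc$call == "decrease"))
  expect_equal(rowSums(smry[, c("n_decrease", "n_no_change", "n_increase")]),
               smry$n_strains, ignore_attr = TRUE)
})

test_that("the paired-on-means variant reports one test per phenotype", {
  pan <- simulate_panel(panel_spec(n_strains = 12, seed = 6))
  calls <- classify_ploidy_changes(pan, phenotypes = c("flocculation",
                                                       "adhesion"),
                                   paired_on_means = TRUE)
  paired <- attr(calls, "paired_on_means")
  expect_setequal(names(paired), c("flocculation", "adhesion"))
  expect_true(all(vapply(paired, function(p) p$p_value >= 0 & p$p_value <= 1,
                         logical(1))))
})
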