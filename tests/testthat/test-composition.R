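test_that("identical compositions in both conditions give null statistics", {
  tab <- expand.grid(replicate_id = paste0("r", 1:4),
                     cluster = paste0("c", 1:3), stringsAsFactors = FALSE)
  tab$condition <- rep(c("A", "A", "B", "B"), 3)
  tab$count <- rep(c(10, 20, 30), each = 4)
  res <- propeller_test(tab)
  expect_true(all(res$statistic == 0))
  expect_true(all(res$fdr == 1))
  expect_equal(res$test_kind, rep("t", 3))
})

test_that("propeller test is invariant to cluster relabeling and row order", {
  cfg <- composition_config(4, rep(0.25, 4), seed = 6,
                            effect = list(treated = c(2, 1, 1, 1)))
  tab <- simulate_composition_cohort(cfg)
  res <- propeller_test(tab)
  set.seed(3)
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(propeller_test(shuf), res)
  relab <- tab
  relab$cluster <- paste0("z", relab$cluster)  # names change, stats must not
  res2 <- propeller_test(relab)
  expect_equal(res2$p_raw[order(res2$cluster)], res$p_raw[order(res$cluster)])
})

test_that("a strongly shifted cluster attains the smallest FDR", {
  hits <- vapply(1:200, function(s) {
    cfg <- composition_config(4, rep(0.25, 4), seed = s, dispersion = 500,
                              effect = list(treated = c(2, 1, 1, 1)))
    res <- propeller_test(simulate_composition_cohort(cfg))
    res$cluster[which.min(res$fdr)] == "cluster1"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("propeller preconditions are enforced", {
  tab <- data.frame(replicate_id = c("r1", "r1", "r2", "r2"),
                    condition = c("A", "A", "B", "B"),
                    cluster = c("c1", "c2", "c1", "c2"),
                    count = c(1, 2, 3, 4))
  expect_error(propeller_test(tab), "single replicate")
  dup <- rbind(tab, tab[1, ])
  expect_error(propeller_test(dup), "only once")
  tab$condition <- "A"
  expect_error(propeller_test(tab), "two conditions")
})

test_that("three conditions switch the per-cluster test to ANOVA", {
  cfg <- composition_config(3, c(0.5, 0.3, 0.2),
                            conditions = c("A", "B", "C"), seed = 10)
  res <- propeller_test(simulate_composition_cohort(cfg))
  expect_equal(unique(res$test_kind), "anova")
  expect_true(all(res$p_raw >= 0 & res$p_raw <= 1))
})

test_that("arcsine square-root transform is monotone from [0,1] onto [0, pi/2]", {
  p <- seq(0, 1, by = 0.01)
  y <- asin(sqrt(p))
  expect_equal(y[1], 0)
  expect_equal(y[length(y)], pi / 2)
  expect_true(all(diff(y) > 0))
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  # hand step-up: sorted (.001,.03,.04,.5) -> (.004,.06,.0533,.5),
  # monotone cap from the top gives (.004,.0533,.0533,.5)
  p <- c(0.04, 0.001, 0.5, 0.03)
  adj <- bh_fdr(p)
  expect_equal(adj, c(0.16 / 3, 0.004, 0.5, 0.16 / 3), tolerance = 1e-12)
  expect_true(all(adj >= p))  # never below the raw p-value
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("chi-squared tests match closed-form evaluation", {
  r <- chisq_test(c(25, 25, 25), expected = c(25, 25, 25))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)

  # stroke-response gene split: 266 vs 13 against a uniform expectation
  r <- chisq_test(c(266, 13))
  expect_equal(unname(r$statistic),
               sum((c(266, 13) - 139.5)^2 / 139.5), tolerance = 1e-12)
  expect_equal(unname(r$parameter), 1)
  expect_equal(unname(r$statistic), 229.4, tolerance = 1e-3)

  # 2x2 independence against the textbook margins formula
  set.seed(12)
  m <- matrix(rpois(4, 40) + 1, 2)
  r <- chisq_test(m)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(unname(r$statistic), sum((m - e)^2 / e), tolerance = 1e-9)
  expect_equal(unname(r$parameter), 1)
  expect_error(chisq_test(matrix(c(0, 0, 1, 2), 2)), "margins")
  expect_error(chisq_test(c(1, 2), expected = c(0, 1)), "> 0")
})

test_that("Brunner-Munzel handles identity, separation and n < 2", {
  r <- brunner_munzel(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r$estimate), 0.5)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
  r <- brunner_munzel(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$p.value, 1)
  expect_error(brunner_munzel(c(1, 2, 3), c(10, 11, 12)), "separated")
  expect_error(brunner_munzel(1, c(1, 2)), "n >= 2")
})

test_that("Brunner-Munzel agrees with an independent reference implementation", {
  # expected values frozen from scipy.stats.brunnermunzel on the same inputs
  cases <- list(
    list(a = c(1.0, 2.0, 4.5, 7.0, 3.3), b = c(2.2, 5.5, 6.1, 7.8, 9.9, 4.4),
         stat = 1.6979054399120355, p = 0.1284743576205112,
         phat = 0.7666666666666666),
    list(a = c(0.1, 0.2, 0.3, 0.15), b = c(0.25, 0.05, 0.4, 0.35, 0.3),
         stat = 1.1163126113028763, p = 0.3131129309135199, phat = 0.725),
    list(a = c(5, 5, 6, 7, 8, 9), b = c(5, 6, 6, 7, 7, 10),  # tied data
         stat = 0.1517941851797293, p = 0.8825319436280213,
         phat = 0.5277777777777778),
    list(a = c(-1.2, 0.4, 2.2, 1.1, 0.0, 0.9, 2.5), b = c(0.3, 0.6, 0.7, 1.9),
         stat = -0.18786728732554503, p = 0.8553699097465981,
         phat = 0.4642857142857143))
  for (cs in cases) {
    r <- brunner_munzel(cs$a, cs$b)
    expect_equal(unname(r$statistic), cs$stat, tolerance = 1e-8)
    expect_equal(r$p.value, cs$p, tolerance = 1e-8)
    expect_equal(unname(r$estimate), cs$phat, tolerance = 1e-12)
  }
})
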