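test_that("noiseless treated densities sit exactly on the logistic curve", {
  cfg <- one_stratum_config(L = 100, k = 0.5, t0 = 8, noise_cv = 0,
                            baseline_cv = 0, days = c(1, 8, 14),
                            treated_n = c(3L, 3L, 3L))
  tab <- simulate_density_cohort(cfg)
  at_t0 <- tab$density[tab$group == "treated" & tab$day == 8]
  expect_equal(at_t0, rep(50, 3))  # curve midpoint at the inflection day
  ctl <- tab$density[tab$group == "control"]
  expect_true(all(ctl == 100))
})

test_that("density simulation is deterministic in the seed and streams are independent", {
  cfg <- one_stratum_config(seed = 42)
  expect_identical(simulate_density_cohort(cfg), simulate_density_cohort(cfg))

  # adding a second region must not perturb the first region's draws
  cfg2 <- cfg
  cfg2$regions <- c("cortex", "cerebellum")
  cfg2$true_kinetics <- rbind(cfg2$true_kinetics,
                              data.frame(region = "cerebellum",
                                         cell_type = "MG",
                                         L = 98, k = 1, t0 = 4))
  cfg2$control_baseline <- rbind(cfg2$control_baseline,
                                 data.frame(region = "cerebellum",
                                            cell_type = "MG",
                                            mean = 100, cv = 0.15))
  tab1 <- simulate_density_cohort(cfg)
  tab2 <- simulate_density_cohort(cfg2)
  expect_identical(tab1, tab2[tab2$region == "cortex", ])
})

test_that("density config validation names the offending stratum", {
  expect_error(
    cohort_config("cortex", "MG", c(1, 5),
                  data.frame(group = "treated", day = c(1, 5), n = 3L),
                  data.frame(region = "cortex", cell_type = "MG",
                             L = 98, k = 1, t0 = 4),
                  data.frame(region = "cortex", cell_type = "MG",
                             mean = -5, cv = 0.1)),
    "cortex.*MG")
  expect_error(one_stratum_config(k = -1), "k > 0")
  expect_error(
    cohort_config("cortex", "MG", c(5, 1),
                  data.frame(group = "treated", day = c(1, 5), n = 3L),
                  data.frame(region = "cortex", cell_type = "MG",
                             L = 98, k = 1, t0 = 4),
                  data.frame(region = "cortex", cell_type = "MG",
                             mean = 5, cv = 0.1)),
    "strictly increasing")
})

test_that("simulated densities are nonnegative with the configured mean", {
  cfg <- one_stratum_config(seed = 11, days = 14, treated_n = 3000L,
                            control_n = 3000L, noise_cv = 0.3)
  tab <- simulate_density_cohort(cfg)
  expect_true(all(tab$density > 0))
  trt <- tab$density[tab$group == "treated"]
  mu <- 100 * (98 / 100) / (1 + exp(-1 * (14 - 4)))
  se <- sd(trt) / sqrt(length(trt))
  expect_lt(abs(mean(trt) - mu), 3 * se)
})

test_that("label cohort boundary cases produce zero labeled cells", {
  lines <- data.frame(line = c("hscLine", "resLine"),
                      lineage_class = c("hsc", "resident"),
                      efficiency = c(0.7, 1.0))
  cfg <- fatemap_config(lines[1, ], f_hsc_true = c(pvM = 0), seed = 2)
  expect_true(all(simulate_label_cohort(cfg)$n_labeled == 0))
  cfg <- fatemap_config(lines[2, ], f_hsc_true = c(pvM = 1), seed = 2)
  expect_true(all(simulate_label_cohort(cfg)$n_labeled == 0))
})

test_that("label cohort pooled fraction matches its binomial expectation", {
  lines <- data.frame(line = "hscLine", lineage_class = "hsc",
                      efficiency = 0.85)
  cfg <- fatemap_config(lines, f_hsc_true = c(pvM = 0.3),
                        cells_per_mouse = 2000L, mice_per_group = 5L,
                        seed = 12)
  obs <- simulate_label_cohort(cfg)
  p <- 0.85 * 0.3
  n <- sum(obs$n_total)
  expect_lt(abs(sum(obs$n_labeled) / n - p), 3 * sqrt(p * (1 - p) / n))
  expect_identical(obs, simulate_label_cohort(cfg))
  expect_error(fatemap_config(lines, c(pvM = 0.3), cells_per_mouse = 0),
               "positive")
})

test_that("composition cohort concentrates on the baseline simplex", {
  base <- c(0.4, 0.3, 0.2, 0.1)
  cfg <- composition_config(4, base, dispersion = 1e6,
                            cells_per_replicate = 200000L, seed = 4)
  tab <- simulate_composition_cohort(cfg)
  for (rep_id in unique(tab$replicate_id)) {
    p <- tab$count[tab$replicate_id == rep_id]
    p <- p / sum(p)
    expect_true(all(abs(p - base) < 1e-2))
  }
  expect_identical(tab, simulate_composition_cohort(cfg))
})

test_that("composition config rejects degenerate inputs", {
  expect_error(composition_config(3, c(0.5, 0.3, 0.1)), "sum to 1")
  expect_error(composition_config(3, c(0.5, 0.3, 0.2), dispersion = 0), "> 0")
  expect_error(
    composition_config(3, c(0.5, 0.3, 0.2),
                       effect = list(treated = c(1, 1, -2))),
    "nonpositive")
})
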