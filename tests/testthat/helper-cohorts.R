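# shared fixtures built in code

paper_days <- c(1, 5, 14, 56, 84, 182)
paper_treated_n <- c(3L, 5L, 6L, 4L, 4L, 4L)

# one-stratum cohort with the unbalanced group sizes of the original design
one_stratum_config <- function(L = 98, k = 1.0, t0 = 4, seed = 1,
                               noise_cv = 0.15, baseline = 100,
                               baseline_cv = 0.15, days = paper_days,
                               treated_n = paper_treated_n, control_n = 3L) {
  gs <- rbind(
    data.frame(group = "treated", day = days, n = treated_n),
    data.frame(group = "control", day = days, n = control_n)
  )
  cohort_config(
    regions = "cortex", cell_types = "MG", timepoints_days = days,
    group_sizes = gs,
    true_kinetics = data.frame(region = "cortex", cell_type = "MG",
                               L = L, k = k, t0 = t0),
    control_baseline = data.frame(region = "cortex", cell_type = "MG",
                                  mean = baseline, cv = baseline_cv),
    noise_cv = noise_cv, seed = seed)
}

true_t90 <- function(L, k, t0, threshold = 90) {
  t0 - log(L / threshold - 1) / k
}

# independent global-optimum oracle for the logistic least-squares problem:
# dense grid over (L, k, t0) followed by a Nelder-Mead polish of the best cell
grid_polish_logistic <- function(days, y) {
  obj <- function(p) {
    mu <- p[1] / (1 + exp(-p[2] * (days - p[3])))
    sum((y - mu)^2)
  }
  grid <- expand.grid(L = seq(50, 150, by = 5),
                      k = exp(seq(log(0.01), log(5), length.out = 25)),
                      t0 = seq(0, max(days) / 2, length.out = 25))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  op <- stats::optim(best, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  op2 <- stats::optim(op$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(par = op2$par, value = op2$value)
}

# 12-gene toy list used for prefilter exactness checks
toy_genes <- c("Rpl13", "Cd74", "Gm12345", "Saa3", "Lyve1", "Mrc1",
               "Atp5f1", "Polr2a", "2310022B05Rik", "H2-Aa", "Snca", "Folr2")
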