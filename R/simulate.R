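#' Configure a synthetic depletion-repopulation cohort
#'
#' Describes the design of a simulated cohort: which brain regions and
#' macrophage populations are measured, at which days after the end of
#' CSF-1R-inhibitor treatment, with how many animals per group and day, and
#' with which true logistic recovery kinetics per (region, cell type) stratum.
#'
#' Treated animals follow the three-parameter logistic recovery curve
#' `density = baseline * (L/100) / (1 + exp(-k * (day - t0)))`; control
#' animals sit at the baseline density at every sampled day. Biological and
#' technical variability is multiplicative lognormal, parameterized by a
#' coefficient of variation and mean-corrected so the expected density equals
#' the curve.
#'
#' @param regions character vector of region labels.
#' @param cell_types character vector of cell-type labels.
#' @param timepoints_days strictly increasing vector of nonnegative sampling
#'   days (post-treatment).
#' @param group_sizes data frame with columns `group` (`"control"` or
#'   `"treated"`), `day`, `n`; one row per sampled (group, day).
#' @param true_kinetics data frame with columns `region`, `cell_type`, `L`
#'   (asymptote, % of control), `k` (growth rate per day, > 0), `t0`
#'   (inflection day); one row per stratum.
#' @param control_baseline data frame with columns `region`, `cell_type`,
#'   `mean` (control density, cells per unit area, > 0) and `cv`
#'   (coefficient of variation of control animals, >= 0).
#' @param noise_cv coefficient of variation of treated animals around the
#'   recovery curve (>= 0; 0 gives noiseless densities).
#' @param seed integer global seed; fanned out into per-stratum child streams.
#' @return An object of class `cohort_config`.
#' @seealso [simulate_density_cohort()], [default_cohort_config()]
#' @export
cohort_config <- function(regions, cell_types, timepoints_days, group_sizes,
                          true_kinetics, control_baseline,
                          noise_cv = 0.15, seed = 1L) {
  stopifnot(is.character(regions), length(regions) >= 1L,
            is.character(cell_types), length(cell_types) >= 1L)
  if (any(timepoints_days < 0) || any(diff(timepoints_days) <= 0)) {
    stop("timepoints_days must be nonnegative and strictly increasing")
  }
  group_sizes <- as.data.frame(group_sizes)
  need <- c("group", "day", "n")
  if (!all(need %in% names(group_sizes))) {
    stop("group_sizes needs columns: ", paste(need, collapse = ", "))
  }
  if (any(group_sizes$n < 1)) stop("group sizes must be positive")
  true_kinetics <- as.data.frame(true_kinetics)
  if (!all(c("region", "cell_type", "L", "k", "t0") %in% names(true_kinetics))) {
    stop("true_kinetics needs columns: region, cell_type, L, k, t0")
  }
  if (any(true_kinetics$k <= 0)) stop("true kinetics require k > 0")
  control_baseline <- as.data.frame(control_baseline)
  if (!all(c("region", "cell_type", "mean", "cv") %in% names(control_baseline))) {
    stop("control_baseline needs columns: region, cell_type, mean, cv")
  }
  bad <- control_baseline$mean <= 0 | control_baseline$cv < 0
  if (any(bad)) {
    off <- control_baseline[bad, , drop = FALSE][1L, ]
    stop(sprintf("nonpositive baseline or negative CV for (%s, %s)",
                 off$region, off$cell_type))
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(regions = regions, cell_types = cell_types,
                 timepoints_days = as.numeric(timepoints_days),
                 group_sizes = group_sizes, true_kinetics = true_kinetics,
                 control_baseline = control_baseline,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default cohort configuration mirroring the depletion-repopulation design
#'
#' Three regions (cerebral cortex, cerebellum, olfactory tubercle) by three
#' populations (microglia `MG`, leptomeningeal `lmM` and perivascular `pvM`
#' macrophages), sampled at days 1, 5, 14, 56, 84 and 182 after treatment with
#' the unbalanced group sizes of the original experiment (treated n = 3, 5, 6,
#' 4, 4, 4 by day; control n = 3). Microglia recover fast (k = 1.0/day,
#' t0 = 4 d), leptomeningeal macrophages at intermediate speed and
#' perivascular macrophages slowly (k = 0.15/day, t0 = 12 d); all approach an
#' asymptote of 98% of control. Noise CV defaults to 0.15.
#'
#' @param seed integer seed.
#' @param noise_cv treated-group coefficient of variation.
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(seed = 1L, noise_cv = 0.15) {
  regions <- c("cortex", "cerebellum", "olf_tubercle")
  cell_types <- c("MG", "lmM", "pvM")
  days <- c(1, 5, 14, 56, 84, 182)
  gs <- rbind(
    data.frame(group = "treated", day = days, n = c(3L, 5L, 6L, 4L, 4L, 4L)),
    data.frame(group = "control", day = days, n = 3L)
  )
  kin <- expand.grid(region = regions, cell_type = cell_types,
                     stringsAsFactors = FALSE)
  kin$L <- 98
  kin$k <- c(MG = 1.0, lmM = 0.35, pvM = 0.15)[kin$cell_type]
  kin$t0 <- c(MG = 4, lmM = 8, pvM = 12)[kin$cell_type]
  base <- expand.grid(region = regions, cell_type = cell_types,
                      stringsAsFactors = FALSE)
  base$mean <- c(MG = 300, lmM = 40, pvM = 25)[base$cell_type]
  base$cv <- 0.15
  cohort_config(regions, cell_types, days, gs, kin, base,
                noise_cv = noise_cv, seed = seed)
}

# mean-corrected lognormal multiplicative noise: E[x] = mu, CV as given
rlnorm_cv <- function(n, mu, cv) {
  if (cv == 0) return(rep(mu, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a per-animal cell-density cohort
#'
#' Draws one density per (mouse, day, region, cell type). Treated animals
#' follow the configured logistic recovery curve scaled by the control
#' baseline; control animals are sampled at every timepoint at baseline.
#' Identical seed and configuration give identical tables.
#'
#' @param config a [cohort_config()].
#' @return A tidy data frame (a `DensityTable`) with columns `mouse_id`,
#'   `group`, `day`, `region`, `cell_type`, `density`, `unit`.
#' @examples
#' cfg <- default_cohort_config(seed = 7)
#' head(simulate_density_cohort(cfg))
#' @export
simulate_density_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  out <- vector("list", nrow(config$true_kinetics))
  for (i in seq_len(nrow(config$true_kinetics))) {
    kin <- config$true_kinetics[i, ]
    reg <- kin$region; ct <- kin$cell_type
    bl <- config$control_baseline[
      config$control_baseline$region == reg &
        config$control_baseline$cell_type == ct, ]
    if (nrow(bl) != 1L) {
      stop(sprintf("missing control baseline for (%s, %s)", reg, ct))
    }
    rows <- with_seed(child_seed(config$seed, paste(reg, ct, sep = "|")), {
      rr <- list(); j <- 0L
      for (g in c("control", "treated")) {
        gsz <- config$group_sizes[config$group_sizes$group == g, ]
        for (d in config$timepoints_days) {
          n <- gsz$n[match(d, gsz$day)]
          if (is.na(n)) next
          mu <- if (g == "control") bl$mean else {
            bl$mean * (kin$L / 100) / (1 + exp(-kin$k * (d - kin$t0)))
          }
          cv <- if (g == "control") bl$cv else config$noise_cv
          j <- j + 1L
          rr[[j]] <- data.frame(
            mouse_id = sprintf("%s_%s_%s_d%g_m%d", substr(g, 1, 3), reg, ct,
                               d, seq_len(n)),
            group = g, day = d, region = reg, cell_type = ct,
            density = rlnorm_cv(n, mu, cv), unit = "cells/mm^2",
            stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rr)
    })
    out[[i]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Configure a fate-mapping label cohort
#'
#' Complementary tamoxifen-inducible reporter lines mark either the resident
#' (yolk-sac-derived) or the hematopoietic-stem-cell (HSC)-derived lineage
#' with a line-specific labeling efficiency. In a compartment whose true
#' HSC-derived fraction is `f_hsc`, the expected labeled fraction is
#' `efficiency * f_hsc` for an hsc-class line and `efficiency * (1 - f_hsc)`
#' for a resident-class line; observed labeled counts are binomial per mouse.
#'
#' @param lines data frame with columns `line`, `lineage_class` (`"resident"`
#'   or `"hsc"`) and `efficiency` in `[0, 1]`.
#' @param f_hsc_true named numeric vector in `[0, 1]`: true HSC-derived
#'   fraction per compartment.
#' @param cells_per_mouse positive integer: cells scored per mouse.
#' @param mice_per_group positive integer.
#' @param seed integer seed.
#' @return An object of class `fatemap_config`.
#' @export
fatemap_config <- function(lines, f_hsc_true, cells_per_mouse = 2000L,
                           mice_per_group = 5L, seed = 1L) {
  lines <- as.data.frame(lines)
  stopifnot(all(c("line", "lineage_class", "efficiency") %in% names(lines)))
  if (!all(lines$lineage_class %in% c("resident", "hsc"))) {
    stop("lineage_class must be 'resident' or 'hsc'")
  }
  if (any(lines$efficiency < 0 | lines$efficiency > 1)) {
    stop("labeling efficiencies must lie in [0, 1]")
  }
  if (any(f_hsc_true < 0 | f_hsc_true > 1)) stop("f_hsc_true must lie in [0, 1]")
  if (is.null(names(f_hsc_true))) stop("f_hsc_true must be named by compartment")
  if (cells_per_mouse <= 0) stop("cells_per_mouse must be positive")
  if (mice_per_group <= 0) stop("mice_per_group must be positive")
  structure(list(lines = lines, f_hsc_true = f_hsc_true,
                 cells_per_mouse = as.integer(cells_per_mouse),
                 mice_per_group = as.integer(mice_per_group),
                 seed = as.integer(seed)),
            class = "fatemap_config")
}

#' Simulate reporter-labeling observations from fate-mapping lines
#'
#' @param config a [fatemap_config()].
#' @return A data frame of `LabelObservation` rows: `line`, `lineage_class`,
#'   `compartment`, `condition`, `mouse_id`, `n_labeled`, `n_total`.
#' @examples
#' cfg <- fatemap_config(
#'   lines = data.frame(line = c("resR26", "hscR26"),
#'                      lineage_class = c("resident", "hsc"),
#'                      efficiency = c(0.9, 0.85)),
#'   f_hsc_true = c(pvM = 0.3), seed = 3)
#' simulate_label_cohort(cfg)
#' @export
simulate_label_cohort <- function(config) {
  stopifnot(inherits(config, "fatemap_config"))
  out <- list(); j <- 0L
  for (i in seq_len(nrow(config$lines))) {
    ln <- config$lines[i, ]
    for (cmp in names(config$f_hsc_true)) {
      fh <- config$f_hsc_true[[cmp]]
      p <- if (ln$lineage_class == "hsc") ln$efficiency * fh else {
        ln$efficiency * (1 - fh)
      }
      labeled <- with_seed(child_seed(config$seed, paste(ln$line, cmp, sep = "|")),
                           stats::rbinom(config$mice_per_group,
                                         config$cells_per_mouse, p))
      j <- j + 1L
      out[[j]] <- data.frame(
        line = ln$line, lineage_class = ln$lineage_class, compartment = cmp,
        condition = "repopulated",
        mouse_id = sprintf("%s_%s_m%d", ln$line, cmp,
                           seq_len(config$mice_per_group)),
        n_labeled = labeled, n_total = config$cells_per_mouse,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Configure a replicate-by-cluster composition cohort
#'
#' Emulates per-animal single-cell cluster compositions: each replicate's
#' cluster proportions are a Dirichlet draw around a (possibly
#' condition-shifted) baseline simplex, and observed counts are multinomial.
#'
#' @param n_clusters number of clusters.
#' @param baseline_proportions numeric simplex of length `n_clusters`.
#' @param effect named list: per condition, a multiplicative shift vector of
#'   length `n_clusters` applied to the baseline and renormalized. Conditions
#'   absent from the list use the unshifted baseline.
#' @param conditions character vector of condition labels.
#' @param replicates_per_condition positive integer.
#' @param cells_per_replicate positive integer.
#' @param dispersion Dirichlet concentration scalar (> 0); larger means
#'   replicate proportions hug the baseline more tightly.
#' @param seed integer seed.
#' @return An object of class `composition_config`.
#' @export
composition_config <- function(n_clusters, baseline_proportions,
                               effect = list(), conditions = c("CTL", "treated"),
                               replicates_per_condition = 4L,
                               cells_per_replicate = 2000L,
                               dispersion = 50, seed = 1L) {
  stopifnot(length(baseline_proportions) == n_clusters)
  if (abs(sum(baseline_proportions) - 1) > 1e-12) {
    stop("baseline proportions must sum to 1 (within 1e-12)")
  }
  if (any(baseline_proportions <= 0)) stop("baseline proportions must be positive")
  if (dispersion <= 0) stop("dispersion (Dirichlet concentration) must be > 0")
  for (cond in names(effect)) {
    shifted <- baseline_proportions * effect[[cond]]
    if (any(shifted <= 0)) {
      stop(sprintf("effect for condition '%s' produces a nonpositive proportion",
                   cond))
    }
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 baseline_proportions = baseline_proportions,
                 effect = effect, conditions = conditions,
                 replicates_per_condition = as.integer(replicates_per_condition),
                 cells_per_replicate = as.integer(cells_per_replicate),
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "composition_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a replicate-by-cluster composition table
#'
#' @param config a [composition_config()].
#' @return A tidy data frame (a `CompositionTable`) with columns
#'   `replicate_id`, `condition`, `cluster`, `count`.
#' @export
simulate_composition_cohort <- function(config) {
  stopifnot(inherits(config, "composition_config"))
  clusters <- paste0("cluster", seq_len(config$n_clusters))
  out <- list(); j <- 0L
  for (cond in config$conditions) {
    base <- config$baseline_proportions
    if (cond %in% names(config$effect)) {
      base <- base * config$effect[[cond]]
      base <- base / sum(base)
    }
    counts <- with_seed(child_seed(config$seed, cond), {
      vapply(seq_len(config$replicates_per_condition), function(r) {
        p <- rdirichlet1(config$dispersion * base)
        stats::rmultinom(1, config$cells_per_replicate, p)[, 1]
      }, numeric(config$n_clusters))
    })
    for (r in seq_len(config$replicates_per_condition)) {
      j <- j + 1L
      out[[j]] <- data.frame(
        replicate_id = sprintf("%s_rep%d", cond, r), condition = cond,
        cluster = clusters, count = counts[, r], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
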