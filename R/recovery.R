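#' Percent-of-control recovery with delta-method standard error
#'
#' Expresses the treated-group mean density as a percentage of the
#' control-group mean, with the standard error of the ratio propagated from
#' the two group standard errors by the first-order delta method (group means
#' treated as independent):
#' \deqn{SE = 100 \sqrt{ s_T^2/(n_T m_C^2) + m_T^2 s_C^2 / (n_C m_C^4) }}
#' where \eqn{m, s^2, n} are group means, sample variances and sizes.
#'
#' @param treated,control numeric density vectors (one value per animal).
#' @return One-row data frame: `recovery_pct`, `se_pct`, `n_treated`,
#'   `n_control`. `se_pct` is `NA` when either group has a single animal
#'   (variance undefined), never silently zero.
#' @examples
#' recovery_estimate(c(1, 2, 3), c(4, 4, 4))  # 50% of control, SE ~ 14.43
#' @export
recovery_estimate <- function(treated, control) {
  treated <- as.numeric(treated); control <- as.numeric(control)
  if (length(treated) < 1L || length(control) < 1L) {
    stop("both groups must be nonempty")
  }
  m_c <- mean(control)
  if (m_c <= 0) stop("control mean must be > 0 for a percent-of-control ratio")
  m_t <- mean(treated)
  n_t <- length(treated); n_c <- length(control)
  if (n_t < 2L || n_c < 2L) {
    se <- NA_real_
  } else {
    s2_t <- stats::var(treated); s2_c <- stats::var(control)
    se <- 100 * sqrt(s2_t / (n_t * m_c^2) + m_t^2 * s2_c / (n_c * m_c^4))
  }
  data.frame(recovery_pct = 100 * m_t / m_c, se_pct = se,
             n_treated = n_t, n_control = n_c)
}

# pull the per-day treated and control density vectors for one stratum
stratum_slices <- function(table, region, cell_type, control) {
  tab <- table[table$region == region & table$cell_type == cell_type, ,
               drop = FALSE]
  if (nrow(tab) == 0L) {
    stop(sprintf("stratum (%s, %s) not present in the table", region, cell_type))
  }
  ctl <- tab[tab$group == "control", , drop = FALSE]
  if (nrow(ctl) == 0L) {
    stop(sprintf("no control animals for stratum (%s, %s)", region, cell_type))
  }
  trt <- tab[tab$group == "treated", , drop = FALSE]
  if (nrow(trt) == 0L) {
    stop(sprintf("no treated animals for stratum (%s, %s)", region, cell_type))
  }
  days <- sort(unique(trt$day))
  ctl_for_day <- function(d) {
    if (control == "per_day") {
      v <- ctl$density[ctl$day == d]
      if (length(v) == 0L) {
        stop(sprintf("no control animals at day %g for stratum (%s, %s); %s",
                     d, region, cell_type,
                     "use control = 'pooled' or add controls"))
      }
      v
    } else ctl$density
  }
  list(days = days,
       treated = lapply(days, function(d) trt$density[trt$day == d]),
       control = lapply(days, ctl_for_day))
}

#' Recovery-over-time curve for one (region, cell type) stratum
#'
#' One percent-of-control [recovery_estimate()] per treated sampling day,
#' sorted by day. Controls are pooled across sampling days by default (a
#' single control group measured once is the common design); with
#' `control = "per_day"` each day is compared to its own control animals.
#'
#' @param table a `DensityTable` data frame (see [simulate_density_cohort()]
#'   or [read_density_table()]).
#' @param region,cell_type stratum labels.
#' @param control `"pooled"` or `"per_day"`.
#' @return Data frame with one row per treated day: `day`, `region`,
#'   `cell_type`, `recovery_pct`, `se_pct`, `n_treated`, `n_control`.
#' @export
recovery_curve <- function(table, region, cell_type,
                           control = c("pooled", "per_day")) {
  control <- match.arg(control)
  sl <- stratum_slices(table, region, cell_type, control)
  if (length(sl$days) < 2L) {
    stop(sprintf("stratum (%s, %s) needs >= 2 distinct treated days",
                 region, cell_type))
  }
  est <- do.call(rbind, Map(function(trt, ctl) recovery_estimate(trt, ctl),
                            sl$treated, sl$control))
  cbind(data.frame(day = sl$days, region = region, cell_type = cell_type),
        est)
}

#' Per-timepoint Welch tests with Bonferroni correction
#'
#' For each treated sampling day in a stratum, a two-sided Welch two-sample
#' t-test (treated vs control densities) with Satterthwaite degrees of
#' freedom, followed by Bonferroni correction across the `m` comparisons
#' (default: the number of tested days).
#'
#' @inheritParams recovery_curve
#' @param m number of comparisons for the Bonferroni correction; defaults to
#'   the number of tested days.
#' @return Data frame with one row per day: `day`, `t_statistic`,
#'   `satterthwaite_df`, `p_raw`, `p_bonferroni`, `m_comparisons`.
#' @export
welch_bonferroni_scan <- function(table, region, cell_type, m = NULL,
                                  control = c("pooled", "per_day")) {
  control <- match.arg(control)
  sl <- stratum_slices(table, region, cell_type, control)
  res <- Map(function(trt, ctl, d) {
    if (length(trt) < 2L || length(ctl) < 2L) {
      stop(sprintf("day %g has a group with n < 2; Welch test needs n >= 2", d))
    }
    if (stats::var(trt) == 0 && stats::var(ctl) == 0) {
      if (mean(trt) == mean(ctl)) {
        message(sprintf("day %g: zero variance in both groups, equal means; p = 1 by convention", d))
        return(c(t = 0, df = NA_real_, p = 1))
      }
      warning(sprintf("day %g: zero variance in both groups, unequal means; p = 0 by convention", d))
      return(c(t = sign(mean(trt) - mean(ctl)) * Inf, df = NA_real_, p = 0))
    }
    tt <- stats::t.test(trt, ctl, var.equal = FALSE)
    c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }, sl$treated, sl$control, sl$days)
  res <- do.call(rbind, res)
  if (is.null(m)) m <- length(sl$days)
  data.frame(day = sl$days, t_statistic = res[, "t"],
             satterthwaite_df = res[, "df"], p_raw = res[, "p"],
             p_bonferroni = pmin(1, m * res[, "p"]),
             m_comparisons = as.integer(m), row.names = NULL)
}
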