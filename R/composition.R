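#' Differential cluster-composition test on arcsine square-root proportions
#'
#' For each replicate (animal), cluster counts are converted to proportions;
#' the variance-stabilizing transform `y = asin(sqrt(p))` is applied; per
#' cluster, transformed values are compared between conditions with a
#' two-sided two-sample t-test (two conditions) or a one-way ANOVA (three or
#' more), and p-values are adjusted across clusters by Benjamini-Hochberg.
#' The t-test is unmoderated and pools variances by default (the transform is
#' variance stabilizing); `var_equal = FALSE` gives the Welch variant.
#'
#' @param table a `CompositionTable` data frame with columns `replicate_id`,
#'   `condition`, `cluster`, `count`; each (replicate, cluster) pair at most
#'   once, absent pairs count as zero.
#' @param var_equal pool variances in the two-condition t-test (default TRUE).
#' @return Data frame with one row per cluster: mean proportion per condition
#'   (`mean_<condition>` columns), `statistic`, `p_raw`, `fdr`, `test_kind`.
#' @examples
#' cfg <- composition_config(4, rep(0.25, 4), seed = 5,
#'                           effect = list(treated = c(2, 1, 1, 1)))
#' propeller_test(simulate_composition_cohort(cfg))
#' @export
propeller_test <- function(table, var_equal = TRUE) {
  table <- as.data.frame(table)
  stopifnot(all(c("replicate_id", "condition", "cluster", "count") %in%
                  names(table)))
  if (any(table$count < 0)) stop("counts must be nonnegative")
  if (anyDuplicated(table[, c("replicate_id", "cluster")])) {
    stop("each (replicate_id, cluster) pair may appear only once")
  }
  counts <- stats::xtabs(count ~ replicate_id + cluster, data = table)
  tot <- rowSums(counts)
  if (any(tot <= 0)) {
    stop("replicate(s) with zero total count: ",
         paste(rownames(counts)[tot <= 0], collapse = ", "))
  }
  cond <- table$condition[match(rownames(counts), table$replicate_id)]
  conds <- sort(unique(cond))
  if (length(conds) < 2L) stop("need at least two conditions")
  ncond <- table(cond)
  if (any(ncond < 2L)) {
    stop("condition(s) with a single replicate: ",
         paste(names(ncond)[ncond < 2L], collapse = ", "),
         "; at least two replicates per condition are required")
  }
  props <- counts / tot
  y <- asin(sqrt(props))
  test_kind <- if (length(conds) == 2L) "t" else "anova"
  res <- lapply(colnames(counts), function(cl) {
    yy <- y[, cl]
    means <- vapply(conds, function(cn) mean(props[cond == cn, cl]), numeric(1))
    if (test_kind == "t") {
      a <- yy[cond == conds[1]]; b <- yy[cond == conds[2]]
      if (stats::sd(c(a, b)) == 0 || (stats::sd(a) == 0 && stats::sd(b) == 0 &&
                                      mean(a) == mean(b))) {
        stat <- 0; p <- 1
      } else {
        tt <- stats::t.test(a, b, var.equal = var_equal)
        stat <- unname(tt$statistic); p <- tt$p.value
      }
    } else {
      df <- data.frame(y = yy, cond = factor(cond))
      if (stats::sd(yy) == 0) {
        stat <- 0; p <- 1
      } else {
        an <- stats::anova(stats::aov(y ~ cond, data = df))
        stat <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
      }
    }
    c(means, statistic = stat, p_raw = p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(cluster = colnames(counts), res, row.names = NULL,
                    check.names = FALSE)
  names(out)[2:(1 + length(conds))] <- paste0("mean_", conds)
  out$fdr <- bh_fdr(out$p_raw)
  out$test_kind <- test_kind
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (delegates to
#' `stats::p.adjust(method = "BH")`), with input validation; input order is
#' preserved.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Chi-squared goodness-of-fit and independence tests
#'
#' Thin, validated wrapper around [stats::chisq.test()]. A matrix `observed`
#' runs the test of independence (expected counts from the margins,
#' df = (r-1)(c-1)); a vector runs the goodness-of-fit test against
#' `expected` counts (uniform when omitted), df = cells - 1. No continuity
#' correction by default.
#'
#' @param observed nonnegative count vector (goodness of fit) or matrix
#'   (independence).
#' @param expected expected counts for goodness-of-fit mode; rescaled to
#'   probabilities internally. Ignored in independence mode.
#' @param correct apply the Yates continuity correction in 2x2 independence
#'   tables (default FALSE).
#' @return The `htest` object from [stats::chisq.test()] (`statistic`,
#'   `parameter` = df, `p.value`).
#' @examples
#' chisq_test(c(266, 13))  # goodness of fit against a uniform split
#' @export
chisq_test <- function(observed, expected = NULL, correct = FALSE) {
  if (any(observed < 0)) stop("observed counts must be nonnegative")
  if (is.matrix(observed)) {
    if (any(rowSums(observed) == 0) || any(colSums(observed) == 0)) {
      stop("independence test requires all row and column margins > 0")
    }
    return(stats::chisq.test(observed, correct = correct))
  }
  if (is.null(expected)) expected <- rep(1, length(observed))
  if (length(expected) != length(observed)) {
    stop("expected must match observed in length")
  }
  if (any(expected <= 0)) stop("expected counts must be > 0 in goodness-of-fit mode")
  stats::chisq.test(observed, p = expected / sum(expected))
}

#' Brunner-Munzel two-sample rank test
#'
#' Tests the relative effect `p = P(A < B) + 0.5 P(A = B)` against 0.5 using
#' mid-ranks, the studentized Brunner-Munzel statistic and a Welch-type
#' t-approximation for the degrees of freedom. Robust to unequal variances
#' and ties; suited to discrete scores. The statistic is positive when the
#' second sample tends to be larger.
#'
#' @param a,b numeric vectors, each with at least two values.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return An object of class `htest` with `statistic`, `parameter` (df),
#'   `p.value` and `estimate` (the relative effect p-hat).
#' @examples
#' brunner_munzel(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
brunner_munzel <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("both samples need n >= 2")
  r <- rank(c(a, b))  # mid-ranks for ties
  r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
  m1 <- mean(r1); m2 <- mean(r2)
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  s1 <- sum((r1 - rank(a) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  s2 <- sum((r2 - rank(b) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  v <- n1 * s1 + n2 * s2
  dname <- paste(deparse1(substitute(a)), "and", deparse1(substitute(b)))
  if (v == 0) {
    if (p_hat == 0.5) {
      # both samples carry the identical value pattern: no evidence either way
      res <- list(statistic = c(W = 0), parameter = c(df = NA_real_),
                  p.value = 1,
                  estimate = c("P(A<B) + 0.5*P(A=B)" = p_hat),
                  alternative = alternative,
                  method = "Brunner-Munzel test", data.name = dname)
      class(res) <- "htest"
      return(res)
    }
    stop("degenerate rank variance (completely separated or constant samples; ",
         "relative effect = ", p_hat, "); ",
         "use an exact or permutation test instead")
  }
  w <- n1 * n2 * (m2 - m1) / ((n1 + n2) * sqrt(v))
  df <- v^2 / ((n1 * s1)^2 / (n1 - 1) + (n2 * s2)^2 / (n2 - 1))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(w), df),
              greater = stats::pt(w, df, lower.tail = FALSE),
              less = stats::pt(w, df))
  res <- list(statistic = c(W = w), parameter = c(df = df), p.value = p,
              estimate = c("P(A<B) + 0.5*P(A=B)" = p_hat),
              alternative = alternative,
              method = "Brunner-Munzel test", data.name = dname)
  class(res) <- "htest"
  res
}
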