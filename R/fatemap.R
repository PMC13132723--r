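#' Pooled reporter-labeled fraction with Wilson and bootstrap intervals
#'
#' Pools labeled and total cell counts across mice of one group and reports
#' the labeled fraction with a Wilson score interval on the pooled counts,
#' plus a mouse-level bootstrap percentile interval (mice, not cells, are the
#' biological replicates).
#'
#' @param obs data frame of label observations with columns `n_labeled`,
#'   `n_total` (one row per mouse; extra columns ignored).
#' @param conf confidence level (default 0.95).
#' @param n_boot bootstrap resamples of mice (default 2000); 0 disables the
#'   bootstrap interval.
#' @param seed optional integer seed for the bootstrap.
#' @return List: `fraction`, `ci_low`, `ci_high` (Wilson), `boot_ci_low`,
#'   `boot_ci_high` (mouse bootstrap, `NA` if disabled or a single mouse),
#'   `n_mice`, `n_labeled`, `n_total`.
#' @examples
#' label_fraction_ci(data.frame(n_labeled = 50, n_total = 100), n_boot = 0)
#' @export
label_fraction_ci <- function(obs, conf = 0.95, n_boot = 2000L, seed = NULL) {
  obs <- as.data.frame(obs)
  stopifnot(all(c("n_labeled", "n_total") %in% names(obs)), nrow(obs) >= 1L)
  if (any(obs$n_total <= 0)) stop("every observation needs n_total > 0")
  if (any(obs$n_labeled < 0 | obs$n_labeled > obs$n_total)) {
    stop("n_labeled must lie in [0, n_total]")
  }
  x <- sum(obs$n_labeled); n <- sum(obs$n_total)
  # prop.test without continuity correction yields the Wilson score interval
  wi <- stats::prop.test(x, n, correct = FALSE, conf.level = conf)$conf.int
  boot <- c(NA_real_, NA_real_)
  if (n_boot > 0 && nrow(obs) > 1L) {
    fr <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(obs), replace = TRUE)
        sum(obs$n_labeled[idx]) / sum(obs$n_total[idx])
      }, numeric(1))
    })
    boot <- unname(stats::quantile(fr, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  list(fraction = x / n, ci_low = wi[1], ci_high = wi[2],
       boot_ci_low = boot[1], boot_ci_high = boot[2],
       n_mice = nrow(obs), n_labeled = x, n_total = n)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Infer the HSC-derived fraction of a compartment from reporter labeling
#'
#' Normalizes the labeled fraction of a target compartment by a reference
#' labeled fraction that calibrates the line's labeling efficiency. For an
#' hsc-class line (labels the hematopoietic lineage; reference = labeled
#' fraction of Ly6C-high blood monocytes in the same animals)
#' `f_hsc = p_target / p_reference`; for a resident-class line (labels the
#' yolk-sac lineage; reference = the same compartment in untreated controls)
#' `f_hsc = 1 - p_target / p_reference`. Estimates are clipped to `[0, 1]`
#' (clipping is flagged). Confidence intervals come from a seeded mouse-level
#' bootstrap of both groups.
#'
#' @param target label observations (data frame with `n_labeled`, `n_total`
#'   per mouse) for the repopulated target compartment, or a single labeled
#'   fraction.
#' @param reference label observations (or a single fraction) for the
#'   efficiency reference.
#' @param lineage_class `"hsc"` or `"resident"`.
#' @param compartment optional compartment label carried into the result.
#' @param conf confidence level.
#' @param n_boot bootstrap resamples (default 2000); only available when both
#'   inputs are observation tables.
#' @param seed optional integer seed for the bootstrap.
#' @return An object of class `ontogeny_estimate`: `compartment`, `f_hsc`,
#'   `ci_low`, `ci_high`, `method`, `n_mice`, `defined`, `reason`, `clipped`.
#' @examples
#' ontogeny_fraction(0.255, 0.85, "hsc")       # f_hsc = 0.3
#' ontogeny_fraction(0.595, 0.85, "resident")  # also f_hsc = 0.3
#' @export
ontogeny_fraction <- function(target, reference,
                              lineage_class = c("hsc", "resident"),
                              compartment = NA_character_, conf = 0.95,
                              n_boot = 2000L, seed = NULL) {
  lineage_class <- match.arg(lineage_class)
  frac <- function(x) {
    if (is.data.frame(x)) sum(x$n_labeled) / sum(x$n_total) else as.numeric(x)
  }
  p_t <- frac(target); p_r <- frac(reference)
  out <- list(compartment = compartment, f_hsc = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_,
              method = paste0(lineage_class, "-line ratio"),
              n_mice = if (is.data.frame(target)) nrow(target) else NA_integer_,
              defined = FALSE, reason = NA_character_, clipped = FALSE)
  if (!is.finite(p_r) || p_r <= 0) {
    out$reason <- "reference labeled fraction is zero; efficiency cannot be calibrated"
    class(out) <- "ontogeny_estimate"
    return(out)
  }
  point <- function(pt, pr) {
    r <- pt / pr
    if (lineage_class == "hsc") clip01(r) else clip01(1 - r)
  }
  raw <- if (lineage_class == "hsc") p_t / p_r else 1 - p_t / p_r
  out$f_hsc <- point(p_t, p_r)
  out$clipped <- raw < 0 || raw > 1
  out$defined <- TRUE
  if (is.data.frame(target) && is.data.frame(reference) && n_boot > 0) {
    bs <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        it <- sample.int(nrow(target), replace = TRUE)
        ir <- sample.int(nrow(reference), replace = TRUE)
        pr <- sum(reference$n_labeled[ir]) / sum(reference$n_total[ir])
        if (pr <= 0) return(NA_real_)
        point(sum(target$n_labeled[it]) / sum(target$n_total[it]), pr)
      }, numeric(1))
    })
    bs <- bs[is.finite(bs)]
    if (length(bs) > 0) {
      qs <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2))
      out$ci_low <- unname(qs[1]); out$ci_high <- unname(qs[2])
      out$method <- paste0(out$method, ", mouse-level bootstrap CI")
    }
  }
  class(out) <- "ontogeny_estimate"
  out
}

#' @export
print.ontogeny_estimate <- function(x, ...) {
  if (!x$defined) {
    cat("HSC-derived fraction undefined:", x$reason, "\n")
  } else {
    cat(sprintf("HSC-derived fraction%s: %.3f",
                if (is.na(x$compartment)) "" else paste0(" (", x$compartment, ")"),
                x$f_hsc))
    if (!is.na(x$ci_low)) cat(sprintf(" [%.3f, %.3f]", x$ci_low, x$ci_high))
    cat("  (", x$method, ")\n", sep = "")
    if (x$clipped) cat("  note: raw ratio outside [0, 1], estimate clipped\n")
  }
  invisible(x)
}
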