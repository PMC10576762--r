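#' @title Agreement statistics between in-silico and in-vivo flow
#'
#' @description Non-parametric validation statistics for small paired
#' cohorts: exact Wilcoxon signed-rank test (shift-algorithm null
#' enumeration with average ranks for ties and zero-difference exclusion),
#' Spearman correlation, Bland-Altman bias and 95% limits of agreement,
#' relative differences, median/IQR summaries using the inverse-CDF
#' quantile convention, and left/right flow splits.
#'
#' @name analysis
NULL

#' Relative difference of a prediction against a measurement
#'
#' @param insilico predicted value(s)
#' @param invivo measured value(s); must be nonzero
#' @return `(insilico - invivo) / invivo`, vectorized
#' @export
relative_difference <- function(insilico, invivo) {
  if (any(invivo == 0)) stop("`invivo` must be nonzero", call. = FALSE)
  (insilico - invivo) / invivo
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences receive average
#' ranks; the two-sided p-value comes, by default, from exact enumeration
#' of the signed-rank null distribution over all `2^n` sign assignments
#' (computed with the shift algorithm on a half-unit rank grid, so tied
#' average ranks are handled exactly). `method = "normal"` gives the
#' large-sample normal approximation with tie-corrected variance,
#' optionally continuity-corrected.
#'
#' @param x,y paired numeric vectors of equal length (>= 5 pairs)
#' @param method `"exact"` (default) or `"normal"`
#' @param correct continuity correction for the normal approximation
#' @return object of class `htest` with the statistic `V` (sum of positive
#'   ranks) and the two-sided p-value
#' @export
wilcoxon_signed_rank <- function(x, y, method = c("exact", "normal"),
                                 correct = TRUE) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 pairs", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate input: all paired differences are zero",
                   call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (method == "exact") {
    r2 <- as.integer(round(2 * r))      # half-unit grid -> integers
    f <- 1                               # counts over 2V
    for (ri in r2) {
      g <- c(f, numeric(ri))
      g[(ri + 1):(ri + length(f))] <- g[(ri + 1):(ri + length(f))] + f
      f <- g
    }
    probs <- f / 2^n
    grid <- seq_along(f) - 1
    v2 <- round(2 * V)
    p <- min(1, 2 * min(sum(probs[grid <= v2]), sum(probs[grid >= v2])))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- V - mu
    if (correct) z <- z - sign(z) * 0.5
    z <- z / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = c(V = V), p.value = p,
                 method = paste("Wilcoxon signed-rank test,", method),
                 alternative = "two.sided",
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y))),
                 n = n),
            class = "htest")
}

#' Spearman rank correlation
#'
#' Pearson correlation of the average-ranked series.
#'
#' @param x,y numeric vectors of equal length (>= 3)
#' @return correlation coefficient in `[-1, 1]`
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant series", call. = FALSE)
  }
  stats::cor(rank(x), rank(y))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`; bias is `mean(d)` and the 95% limits of
#' agreement are `bias +/- 1.96 sd(d)` (sample standard deviation, n-1
#' denominator).
#'
#' @param x,y paired numeric vectors (length >= 2); conventionally `x` is
#'   the new method (in-silico) and `y` the reference (in-vivo)
#' @return list of class `bland_altman` with `bias`, `loa_lower`,
#'   `loa_upper`, `sd_diff`, `n`, and the paired `means`/`diffs`
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  s <- stats::sd(d)
  structure(list(bias = mean(d), loa_lower = mean(d) - 1.96 * s,
                 loa_upper = mean(d) + 1.96 * s, sd_diff = s,
                 n = length(d), means = (x + y) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, 95%% LoA [%.3f, %.3f]\n",
              x$n, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods",
                              ylab = "difference", ...) {
  graphics::plot(x$means, x$diffs, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2), col = "grey40")
  invisible(x)
}

#' Left/right coronary flow split
#'
#' @param cbf_left,cbf_right flows, any common unit; both > 0
#' @return named vector `c(left = , right = )` in percent, summing to 100
#' @export
flow_split <- function(cbf_left, cbf_right) {
  .check_positive(cbf_left, "cbf_left")
  .check_positive(cbf_right, "cbf_right")
  l <- 100 * cbf_left / (cbf_left + cbf_right)
  c(left = l, right = 100 - l)
}

#' Median and interquartile range summary
#'
#' Uses the inverse-CDF quantile convention (`type = 1`), under which the
#' 25th/75th percentiles of a sample of 19 are the 5th and 15th order
#' statistics — the convention that reproduces the packaged validation
#' cohort's printed percentile rows.
#'
#' @param values non-empty numeric vector
#' @return list with `median`, `iqr`, `q25`, `q75`
#' @export
cohort_summary <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 1))
  list(median = q[2], iqr = q[3] - q[1], q25 = q[1], q75 = q[3])
}

#' Full validation-statistics report for a cohort comparison
#'
#' For each coronary side and condition computes the exact Wilcoxon
#' signed-rank p-value, Spearman correlation, Bland-Altman bias and limits
#' of agreement, median/IQR of both series and of the recomputed relative
#' differences; additionally the per-patient left/right flow splits with
#' cohort medians. Differences are flagged significant below the
#' two-comparison threshold p < 0.025.
#'
#' @param comparison a long comparison table as returned by
#'   [cohort_cbf_long()] or [run_cohort()]: columns `patient_id`, `ca`,
#'   `condition`, `cbf_insilico`, `cbf_invivo` (ml/s)
#' @param alpha_adjusted significance threshold (default 0.025)
#' @return object of class `cohort_validation`: list with one
#'   `agreement` entry per (ca, condition) and a `flow_split` block
#' @export
cohort_validation <- function(comparison, alpha_adjusted = 0.025) {
  needed <- c("patient_id", "ca", "condition", "cbf_insilico", "cbf_invivo")
  .require_fields(comparison, needed, "comparison table")
  agreement <- list()
  for (cond in unique(comparison$condition)) {
    for (side in unique(comparison$ca)) {
      sub <- comparison[comparison$ca == side &
                          comparison$condition == cond, ]
      xs <- sub$cbf_insilico
      ys <- sub$cbf_invivo
      ba <- bland_altman(xs, ys)
      rd <- relative_difference(xs, ys)
      agreement[[paste(side, cond, sep = ".")]] <- list(
        ca = side, condition = cond, n = nrow(sub),
        wilcoxon_p = wilcoxon_signed_rank(xs, ys)$p.value,
        spearman_rho = spearman_rho(xs, ys),
        bias = ba$bias, loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
        insilico = cohort_summary(xs), invivo = cohort_summary(ys),
        reldiff = cohort_summary(round(rd, 2)))
    }
  }
  splits <- list()
  for (cond in unique(comparison$condition)) {
    for (kind in c("cbf_invivo", "cbf_insilico")) {
      sub <- comparison[comparison$condition == cond, ]
      wide <- merge(sub[sub$ca == "left", c("patient_id", kind)],
                    sub[sub$ca == "right", c("patient_id", kind)],
                    by = "patient_id", suffixes = c("_l", "_r"))
      fs <- 100 * wide[[paste0(kind, "_l")]] /
        (wide[[paste0(kind, "_l")]] + wide[[paste0(kind, "_r")]])
      splits[[paste(cond, sub("cbf_", "", kind), sep = ".")]] <-
        c(cohort_summary(fs), list(per_patient = fs))
    }
  }
  structure(list(agreement = agreement, flow_split = splits,
                 alpha_adjusted = alpha_adjusted),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation: in-silico vs in-vivo CBF\n")
  for (a in x$agreement) {
    sig <- if (a$wilcoxon_p < x$alpha_adjusted) " *" else ""
    cat(sprintf(
      "  %-5s %-9s n=%d  p=%.3f%s  rho=%.4f  bias=%+.2f  LoA [%+.2f, %+.2f]\n",
      a$ca, a$condition, a$n, a$wilcoxon_p, sig, a$spearman_rho, a$bias,
      a$loa_lower, a$loa_upper))
    cat(sprintf(
      "        median (IQR): in-silico %.2f (%.2f), in-vivo %.2f (%.2f) ml/s\n",
      a$insilico$median, a$insilico$iqr, a$invivo$median, a$invivo$iqr))
  }
  for (nm in names(x$flow_split)) {
    fs <- x$flow_split[[nm]]
    cat(sprintf("  flow split %-18s left %.0f(%.0f)%% / right %.0f(%.0f)%%\n",
                nm, fs$median, fs$iqr, 100 - fs$median, fs$iqr))
  }
  cat(sprintf("  (* significant at the adjusted threshold p < %.3f)\n",
              x$alpha_adjusted))
  invisible(x)
}

#' Simulate a whole cohort and build the comparison table
#'
#' @param patients list of [patient_record()] objects (or paths)
#' @param control an [lpm_control()]
#' @param conditions conditions to simulate
#' @return long comparison data.frame (see [cohort_validation()]) with an
#'   additional `converged` column
#' @export
run_cohort <- function(patients, control = lpm_control(),
                       conditions = c("rest", "hyperemia")) {
  rows <- lapply(patients, function(p) {
    fit <- coronary_lpm(p, conditions = conditions, control = control)
    predict(fit)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
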