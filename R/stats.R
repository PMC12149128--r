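#' Median and interquartile range
#'
#' Summary pair used for all channel-metric tables: paired fast-vs-enhanced
#' differences are not normally distributed, so location and spread are
#' reported as median and IQR (Q3 - Q1, linear-interpolation quantiles).
#'
#' @param values numeric vector (at least one value).
#' @return named numeric vector `c(median, iqr)`.
#' @export
median_iqr <- function(values) {
  if (length(values) < 1L) stop("empty value set", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], iqr = q[3] - q[1])
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test on paired per-channel values (fast wave vs
#' enhanced). Zero differences are dropped, tied absolute differences get
#' averaged ranks, the null distribution is enumerated exactly when 25 or
#' fewer non-zero pairs remain and no ties interfere, and the normal
#' approximation with continuity correction is used otherwise. Significance
#' is conventionally read at 0.05.
#'
#' @param fast,enhanced numeric vectors of paired per-channel values.
#' @param metric label carried into the result.
#' @return An `ehg_paired` list: `metric`, `n_pairs` (non-zero), `W`
#'   (positive-rank sum), `p_value`, `exact`, per-arm `median`/`iqr`, and
#'   the median paired difference.
#' @export
wilcoxon_signed_rank <- function(fast, enhanced, metric = "metric") {
  if (length(fast) != length(enhanced))
    stop("arms must be paired: lengths differ", call. = FALSE)
  d <- enhanced - fast
  nz <- d[d != 0]
  if (length(nz) == 0L)
    stop("all paired differences are zero: test undefined", call. = FALSE)
  if (length(nz) < 5L)
    stop("need at least 5 non-zero paired differences", call. = FALSE)
  ties <- anyDuplicated(abs(nz)) > 0L
  use_exact <- length(nz) <= 25L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(enhanced, fast, paired = TRUE, exact = use_exact,
                       correct = TRUE, alternative = "two.sided"))
  mf <- median_iqr(fast); me <- median_iqr(enhanced)
  structure(list(metric = metric, n_pairs = length(nz),
                 W = unname(ht$statistic), p_value = ht$p.value,
                 exact = use_exact,
                 fast_median = unname(mf["median"]), fast_iqr = unname(mf["iqr"]),
                 enhanced_median = unname(me["median"]),
                 enhanced_iqr = unname(me["iqr"]),
                 diff_median = stats::median(d)),
            class = "ehg_paired")
}

#' @export
print.ehg_paired <- function(x, ...) {
  cat(sprintf(
    "<ehg_paired> %s: n = %d, W = %g, p = %.4g (%s)\n  fast %.3g [IQR %.3g] vs enhanced %.3g [IQR %.3g]\n",
    x$metric, x$n_pairs, x$W, x$p_value,
    if (x$exact) "exact" else "normal approx.",
    x$fast_median, x$fast_iqr, x$enhanced_median, x$enhanced_iqr))
  invisible(x)
}

#' Compare fast-wave and enhanced quality metrics
#'
#' Runs one paired signed-rank comparison per quality metric (skewness,
#' kurtosis, PAER), per subject or pooled over all subjects. Inputs are
#' metric tables as produced by [recording_metrics()], optionally with a
#' `subject` column; channels are matched by (`subject`,) `channel_id` and
#' must pair completely.
#'
#' @param metrics_fast,metrics_enhanced data.frames with `channel_id`,
#'   `skewness`, `kurtosis`, `paer` and optionally `subject`.
#' @param group `"pooled"` (all channels together) or `"per-subject"`.
#' @return data.frame with one row per metric (per subject when grouped):
#'   group, metric, n, W, p_value, medians and IQRs per arm.
#' @export
compare_bands <- function(metrics_fast, metrics_enhanced,
                          group = c("pooled", "per-subject")) {
  group <- match.arg(group)
  key <- function(df) {
    if ("subject" %in% names(df)) paste(df$subject, df$channel_id, sep = "\r")
    else df$channel_id
  }
  kf <- key(metrics_fast); ke <- key(metrics_enhanced)
  if (!setequal(kf, ke) || anyDuplicated(kf) || anyDuplicated(ke)) {
    missing <- c(setdiff(kf, ke), setdiff(ke, kf))
    stop(sprintf("channel sets do not pair: %s",
                 paste(gsub("\r", "/", unique(missing)), collapse = ", ")),
         call. = FALSE)
  }
  metrics_enhanced <- metrics_enhanced[match(kf, ke), , drop = FALSE]
  groups <- if (group == "per-subject" && "subject" %in% names(metrics_fast))
    split(seq_along(kf), metrics_fast$subject) else list(pooled = seq_along(kf))
  rows <- list()
  for (g in names(groups)) {
    i <- groups[[g]]
    for (m in c("skewness", "kurtosis", "paer")) {
      cmp <- wilcoxon_signed_rank(metrics_fast[[m]][i],
                                  metrics_enhanced[[m]][i], metric = m)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, n = cmp$n_pairs, W = cmp$W,
        p_value = cmp$p_value, exact = cmp$exact,
        fast_median = cmp$fast_median, fast_iqr = cmp$fast_iqr,
        enhanced_median = cmp$enhanced_median,
        enhanced_iqr = cmp$enhanced_iqr,
        significant = cmp$p_value < 0.05, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
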