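#' Threshold an energy series into a contraction mask
#'
#' Samples whose window energy lies strictly above the threshold are marked
#' as contraction; ties at the threshold count as baseline.
#'
#' @param e numeric energy series.
#' @param thr finite energy threshold.
#' @param fs sampling rate to stamp on the mask (Hz).
#' @return an [ehg_mask()].
#' @examples
#' detect_mask(c(0, 1, 2, 3), 1.5)$values   # 0 0 1 1
#' @export
detect_mask <- function(e, thr, fs = 5) {
  if (!is.numeric(thr) || length(thr) != 1L || !is.finite(thr))
    stop("threshold must be a single finite number", call. = FALSE)
  ehg_mask(as.integer(e > thr), fs)
}

#' Z-score threshold grid for ROC sweeping
#'
#' 121 thresholds `mu + k * 0.05 * sd` for `k = -60, ..., 60`, i.e. z-scores
#' from -3 to +3 in steps of 0.05, covering essentially all of a
#' normal-shaped energy distribution. Mean and sample standard deviation are
#' taken over the full, untrimmed energy series.
#'
#' @param e numeric energy series with positive spread.
#' @return list with `mu`, `sd` and the 121 strictly increasing `values`.
#' @export
build_threshold_grid <- function(e) {
  mu <- mean(e)
  sdev <- stats::sd(e)
  if (!is.finite(sdev) || sdev == 0)
    stop("threshold grid undefined: energy sd is zero", call. = FALSE)
  list(mu = mu, sd = sdev, values = mu + (-60:60) * 0.05 * sdev)
}

roc_counts <- function(e, truth_values, thr) {
  pred <- e > thr
  pos <- truth_values == 1L
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  fp <- sum(pred & !pos); tn <- sum(!pred & !pos)
  c(tpr = tp / (tp + fn), fpr = fp / (fp + tn))
}

#' ROC curve of energy detection against a ground-truth mask
#'
#' Sweeps the 121-point z-score threshold grid, scores each threshold's
#' detection mask per sample against the reference mask (TPR = TP/(TP+FN),
#' FPR = FP/(FP+TN)), and integrates the curve by the trapezoid rule with
#' anchors (0,0) and (1,1). The optimal threshold maximizes Youden's
#' J = TPR - FPR; ties resolve to the lower threshold (higher sensitivity).
#'
#' @param e numeric energy series.
#' @param truth an [ehg_mask()] of the same length and rate, containing both
#'   classes.
#' @param fs rate of `e` in Hz (must equal `truth$fs`).
#' @return An object of class `ehg_roc`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `optimal_threshold`, `youden_j`.
#' @export
roc_against_mask <- function(e, truth, fs = 5) {
  stopifnot(inherits(truth, "ehg_mask"))
  if (length(e) != length(truth$values))
    stop("energy series and mask lengths differ", call. = FALSE)
  if (fs != truth$fs)
    stop("energy series and mask sampling rates differ", call. = FALSE)
  tv <- truth$values
  if (all(tv == 0L) || all(tv == 1L))
    stop("reference mask must contain both classes", call. = FALSE)
  grid <- build_threshold_grid(e)
  rates <- vapply(grid$values, roc_counts, numeric(2), e = e,
                  truth_values = tv)
  tpr <- rates["tpr", ]; fpr <- rates["fpr", ]
  # thresholds increasing => (fpr, tpr) non-increasing; integrate left-to-right
  ord <- order(fpr, tpr)
  fx <- c(0, fpr[ord], 1); fy <- c(0, tpr[ord], 1)
  auc <- sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  j <- tpr - fpr
  opt <- grid$values[which.max(j)]   # which.max takes the first (lowest) tie
  structure(list(thresholds = grid$values, tpr = tpr, fpr = fpr, auc = auc,
                 optimal_threshold = opt, youden_j = max(j)),
            class = "ehg_roc")
}

#' @export
print.ehg_roc <- function(x, ...) {
  cat(sprintf("<ehg_roc> AUC = %.3f, optimal threshold = %.4g (J = %.3f)\n",
              x$auc, x$optimal_threshold, x$youden_j))
  invisible(x)
}

#' @export
plot.ehg_roc <- function(x, ...) {
  ord <- order(x$fpr, x$tpr)
  graphics::plot(c(0, x$fpr[ord], 1), c(0, x$tpr[ord], 1), type = "l",
                 xlab = "FPR", ylab = "TPR",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Exact rank-based AUC
#'
#' Threshold-free AUC via the Mann-Whitney identity: the probability that a
#' random contraction-sample energy exceeds a random baseline-sample energy
#' (ties counted half). Serves as the continuous reference the 121-point
#' grid AUC approximates.
#'
#' @param e numeric energy (or score) series.
#' @param truth an [ehg_mask()] of matching length with both classes.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(e, truth) {
  stopifnot(inherits(truth, "ehg_mask"))
  tv <- truth$values
  if (length(e) != length(tv))
    stop("energy series and mask lengths differ", call. = FALSE)
  n1 <- sum(tv == 1L); n0 <- sum(tv == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("reference mask must contain both classes", call. = FALSE)
  r <- rank(e)
  (sum(r[tv == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-channel AUC over a recording
#'
#' Runs the window-energy + grid-ROC pipeline on every channel and joins the
#' result to electrode coordinates, giving the body-surface AUC map that the
#' spatial consistency analysis consumes.
#'
#' @param rec an [ehg_recording()] at the mask's rate (channels should
#'   already have passed quality screening).
#' @param truth an [ehg_mask()] at `rec$fs`.
#' @param layout optional [ehg_layout()]; when supplied, x/y/z columns are
#'   joined.
#' @param n energy window in samples.
#' @return data.frame: `channel_id`, `auc`, `optimal_threshold` (+ `x`,
#'   `y`, `z` if a layout is given).
#' @export
channel_auc_map <- function(rec, truth, layout = NULL, n = 50L) {
  stopifnot(inherits(rec, "ehg_recording"))
  res <- lapply(seq_len(n_channels(rec)), function(i) {
    roc <- roc_against_mask(window_energy(rec$data[i, ], n), truth,
                            fs = rec$fs)
    data.frame(channel_id = rec$channel_ids[i], auc = roc$auc,
               optimal_threshold = roc$optimal_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(layout)) {
    xyz <- layout_coords(layout, out$channel_id)
    out <- cbind(out, as.data.frame(xyz, row.names = seq_len(nrow(out))))
  }
  rownames(out) <- NULL
  out
}
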