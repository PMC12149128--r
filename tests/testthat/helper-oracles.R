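# Independent brute-force oracles. These deliberately avoid the package's
# cumulative-sum / grid / chull code paths: everything is direct summation
# or exhaustive enumeration at small n.

oracle_rms <- function(s, n) {
  N <- length(s); half <- n %/% 2
  sapply(seq_len(N), function(i) {
    w <- s[max(1, i - half):min(N, i + half)]
    sqrt(sum(w^2) / length(w))
  })
}

oracle_energy <- function(x, n) {
  N <- length(x); half <- n %/% 2
  sapply(seq_len(N), function(i) sum(x[max(1, i - half):min(N, i + half)]^2))
}

oracle_skewness <- function(e) {
  m <- sum(e) / length(e)
  s <- sqrt(sum((e - m)^2) / length(e))
  sum(((e - m) / s)^3) / length(e)
}

oracle_kurtosis <- function(e) {
  m <- sum(e) / length(e)
  s <- sqrt(sum((e - m)^2) / length(e))
  sum(((e - m) / s)^4) / length(e)
}

# pair-counting AUC: P(score_pos > score_neg) + 0.5 P(tie)
oracle_auc <- function(score, truth) {
  pos <- score[truth == 1]; neg <- score[truth == 0]
  gt <- outer(pos, neg, ">"); eq <- outer(pos, neg, "==")
  (sum(gt) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

# O(n^3)-flavoured strict extreme-point test: p_i is a hull vertex iff it is
# not contained in the convex hull of the remaining points (boundary counts
# as contained, so collinear edge points are not vertices). Containment is
# checked by enumerating triangles of the other points.
in_triangle <- function(p, a, b, c, tol = 1e-9) {
  s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
  s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
  (s1 >= -tol & s2 >= -tol & s3 >= -tol) |
    (s1 <= tol & s2 <= tol & s3 <= tol)
}

oracle_hull_vertices <- function(pts) {
  n <- nrow(pts)
  is_vertex <- logical(n)
  for (i in seq_len(n)) {
    others <- pts[-i, , drop = FALSE]
    inside <- FALSE
    m <- nrow(others)
    if (m >= 3) {
      combs <- utils::combn(m, 3)
      for (k in seq_len(ncol(combs))) {
        tri <- others[combs[, k], ]
        if (in_triangle(pts[i, ], tri[1, ], tri[2, ], tri[3, ])) {
          inside <- TRUE; break
        }
      }
    }
    # also covered if it lies on a segment between two others
    if (!inside && m >= 2) {
      combs2 <- utils::combn(m, 2)
      for (k in seq_len(ncol(combs2))) {
        a <- others[combs2[1, k], ]; b <- others[combs2[2, k], ]
        cr <- (b[1] - a[1]) * (pts[i, 2] - a[2]) -
          (b[2] - a[2]) * (pts[i, 1] - a[1])
        dot <- (pts[i, 1] - a[1]) * (b[1] - a[1]) +
          (pts[i, 2] - a[2]) * (b[2] - a[2])
        len2 <- sum((b - a)^2)
        if (abs(cr) <= 1e-9 && dot >= -1e-9 && dot <= len2 + 1e-9) {
          inside <- TRUE; break
        }
      }
    }
    is_vertex[i] <- !inside
  }
  which(is_vertex)
}

oracle_hull_distance <- function(pts) {
  v <- oracle_hull_vertices(pts)
  vert <- pts[v, , drop = FALSE]
  cen <- colMeans(vert)
  mean(sqrt((vert[, 1] - cen[1])^2 + (vert[, 2] - cen[2])^2))
}

oracle_interval_mask <- function(start_s, end_s, fs, duration_s) {
  n <- ceiling(duration_s * fs)
  i <- seq_len(n) - 1L                      # sample i covers time i/fs
  member <- rep(FALSE, n)
  for (k in seq_along(start_s)) {
    # half-open [start, end) with floor/ceiling index conversion
    lo <- floor(start_s[k] * fs); hi <- ceiling(end_s[k] * fs) - 1L
    member <- member | (i >= lo & i <= hi)
  }
  as.integer(member)
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- signs %*% r
  mu <- sum(r) / 2
  p <- mean(abs(Wnull - mu) >= abs(W - mu) - 1e-12)
  min(1, p)
}

# FFT amplitude of a sinusoid component at frequency f_hz
fft_amplitude <- function(x, fs, f_hz) {
  n <- length(x)
  k <- round(f_hz * n / fs)
  2 * abs(stats::fft(x)[k + 1]) / n
}

run_detection_pipeline <- function(sim, n_env = 50L) {
  pre <- suppressMessages(preprocess_recording(sim$recording))
  fast <- apply_screen(pre$fast, pre$quality)
  slow <- apply_screen(pre$slow, pre$quality)
  enh <- enhance_recording(fast, slow, n = n_env)
  mask <- truth_mask(sim$truth, fast$fs, n_samples(fast) / fast$fs)
  list(fast = fast, slow = slow, enh = enh, mask = mask,
       quality = pre$quality, layout = sim$layout, truth = sim$truth)
}
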