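#' Channels with high TOCO consistency
#'
#' Channels whose detector AUC against the TOCO mask reaches the threshold
#' (0.8 by default, inclusive) are treated as carrying a contraction signal
#' consistent with the mechanical reference.
#'
#' @param auc_map data.frame from [channel_auc_map()] (needs `channel_id`
#'   and `auc`).
#' @param threshold inclusive AUC cutoff.
#' @return list with `channel_ids`, `count`, `threshold`.
#' @export
high_consistency <- function(auc_map, threshold = 0.8) {
  ids <- auc_map$channel_id[auc_map$auc >= threshold]
  list(channel_ids = as.character(ids), count = length(ids),
       threshold = threshold)
}

#' Growth ratio of high-consistency channel counts
#'
#' `(ch_E - ch_f) / ch_f`, the relative gain in the number of
#' high-consistency channels after enhancement.
#'
#' @param ch_f count for the fast wave (> 0).
#' @param ch_e count for the enhanced signal.
#' @return exact ratio (round to 2 decimals for tabulation).
#' @examples
#' channel_growth_ratio(50, 55)  # 0.1
#' @export
channel_growth_ratio <- function(ch_f, ch_e) {
  if (ch_f <= 0) stop("growth ratio undefined: ch_f must be positive",
                      call. = FALSE)
  (ch_e - ch_f) / ch_f
}

#' Growth ratio of signaling distances
#'
#' `(d_E - d_f) / d_f`, the relative gain in hull-based signaling distance
#' after enhancement.
#'
#' @param d_f fast-wave signaling distance in mm (> 0).
#' @param d_e enhanced-signal signaling distance in mm.
#' @return exact ratio.
#' @examples
#' distance_growth_ratio(77, 110)  # 0.4286
#' @export
distance_growth_ratio <- function(d_f, d_e) {
  if (d_f <= 0) stop("growth ratio undefined: d_f must be positive",
                     call. = FALSE)
  (d_e - d_f) / d_f
}

# strict 2-D convex hull vertices: counterclockwise, starting from the
# lexicographically smallest point, collinear boundary points dropped
hull_vertices_2d <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  if (n == 1L) return(1L)
  scale <- max(1, max(abs(pts)))
  cross2 <- function(o, a, b)
    (pts[a, 1] - pts[o, 1]) * (pts[b, 2] - pts[o, 2]) -
    (pts[a, 2] - pts[o, 2]) * (pts[b, 1] - pts[o, 1])
  # collinear (incl. 2 distinct points): extreme points of the segment
  far <- which.max((pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2)
  dir <- c(pts[far, 1] - pts[1, 1], pts[far, 2] - pts[1, 2])
  if (all(dir == 0)) return(1L)              # all points coincide
  collinear <- n == 2L ||
    all(abs(vapply(seq_len(n), function(b) cross2(1L, far, b), 0)) <=
          tol * scale^2)
  if (collinear) {
    proj <- pts[, 1] * dir[1] + pts[, 2] * dir[2]
    return(unique(c(which.min(proj), which.max(proj))))
  }
  h <- rev(grDevices::chull(pts[, 1], pts[, 2]))  # counterclockwise
  # drop collinear boundary vertices, if chull kept any (strict hull)
  m <- length(h)
  keep <- vapply(seq_len(m), function(i) {
    o <- h[if (i == 1L) m else i - 1L]
    b <- h[if (i == m) 1L else i + 1L]
    abs(cross2(o, h[i], b)) > tol * scale^2
  }, logical(1))
  h <- h[keep]
  # start from the lexicographically smallest (x, then z) vertex
  start <- which(h == h[order(pts[h, 1], pts[h, 2])[1L]])
  c(h[start:length(h)], h[seq_len(start - 1L)])
}

#' Convex-hull signaling distance
#'
#' Estimates how far detectable contraction signal spreads across the
#' electrode array: positions of the given channels are projected along the
#' anterior-posterior y axis onto the frontal x-z plane, the convex hull of
#' the projections is taken, and the distance is the mean Euclidean distance
#' from the hull vertices to their centroid (the mean of the vertices).
#'
#' Degenerate sets are handled explicitly: a single point gives distance 0;
#' two points or a collinear set give the segment's endpoints as the hull,
#' so the distance is half the segment length.
#'
#' @param channel_ids channels in the high-consistency set (nonempty).
#' @param layout an [ehg_layout()] covering all of them.
#' @param project_y if `TRUE` (default) all geometry lives in the projected
#'   x-z plane; if `FALSE` the hull is still found on the projection, but
#'   centroid and distances use the full 3-D coordinates of the hull
#'   vertices.
#' @return list with `hull_vertex_ids`, `centroid` (x, y, z; y is 0 under
#'   projection), and distance `d` in mm.
#' @examples
#' lay <- ehg_layout(letters[1:4], x = c(-1, 1, 1, -1), y = rep(0, 4),
#'                   z = c(-1, -1, 1, 1))
#' signaling_distance(letters[1:4], lay)$d  # sqrt(2)
#' @export
signaling_distance <- function(channel_ids, layout, project_y = TRUE) {
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) == 0L)
    stop("signaling distance undefined for an empty channel set",
         call. = FALSE)
  xyz <- layout_coords(layout, channel_ids)
  proj <- xyz[, c("x", "z"), drop = FALSE]
  v <- hull_vertices_2d(proj)
  vert <- if (project_y) cbind(proj[v, 1], 0, proj[v, 2])
          else xyz[v, , drop = FALSE]
  cen <- colMeans(matrix(vert, ncol = 3L))
  d <- mean(sqrt(colSums((t(matrix(vert, ncol = 3L)) - cen)^2)))
  list(hull_vertex_ids = channel_ids[v],
       centroid = c(x = cen[1], y = cen[2], z = cen[3]), d = d)
}

#' Full spatial comparison of fast vs enhanced AUC maps
#'
#' @param auc_fast,auc_enhanced data.frames from [channel_auc_map()].
#' @param layout an [ehg_layout()].
#' @param threshold inclusive AUC cutoff for high consistency.
#' @param project_y see [signaling_distance()].
#' @return list with per-band consistency sets and distances plus the two
#'   growth ratios `r_c` and `r_d` (NA when the fast-wave denominator is 0).
#' @export
spatial_comparison <- function(auc_fast, auc_enhanced, layout,
                               threshold = 0.8, project_y = TRUE) {
  set_f <- high_consistency(auc_fast, threshold)
  set_e <- high_consistency(auc_enhanced, threshold)
  d_f <- if (set_f$count > 0)
    signaling_distance(set_f$channel_ids, layout, project_y)$d else NA_real_
  d_e <- if (set_e$count > 0)
    signaling_distance(set_e$channel_ids, layout, project_y)$d else NA_real_
  r_c <- if (set_f$count > 0)
    channel_growth_ratio(set_f$count, set_e$count) else NA_real_
  r_d <- if (!is.na(d_f) && d_f > 0 && !is.na(d_e))
    distance_growth_ratio(d_f, d_e) else NA_real_
  list(fast = list(set = set_f, d = d_f),
       enhanced = list(set = set_e, d = d_e),
       r_c = r_c, r_d = r_d)
}
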