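square_layout <- function() {
  ehg_layout(c("a", "b", "c", "d"), x = c(-1, 1, 1, -1),
             y = c(5, -3, 2, 0), z = c(-1, -1, 1, 1))
}

test_that("high-consistency selection is inclusive at the threshold", {
  am <- data.frame(channel_id = c("a", "b", "c"), auc = c(0.79, 0.80, 0.95))
  expect_identical(high_consistency(am)$channel_ids, c("b", "c"))
  expect_identical(high_consistency(am)$count, 2L)
  expect_identical(high_consistency(am[0, ])$count, 0L)
  expect_identical(high_consistency(am, 0)$count, 3L)
})

test_that("growth ratios reproduce the published subject extremes", {
  expect_equal(round(channel_growth_ratio(50, 55), 2), 0.1)
  expect_equal(round(channel_growth_ratio(7, 13), 2), 0.86)
  expect_equal(channel_growth_ratio(30, 30), 0)
  expect_error(channel_growth_ratio(0, 5), "positive")
  expect_equal(round(distance_growth_ratio(77, 110), 2), 0.43)
  expect_equal(round(distance_growth_ratio(166, 174), 2), 0.05)
  expect_equal(distance_growth_ratio(88, 88), 0)
  expect_error(distance_growth_ratio(0, 5), "positive")
})

test_that("a unit square projects to centroid zero and distance sqrt(2)", {
  sd_ <- signaling_distance(c("a", "b", "c", "d"), square_layout())
  expect_equal(unname(sd_$centroid), c(0, 0, 0))
  expect_equal(sd_$d, sqrt(2))
  expect_setequal(sd_$hull_vertex_ids, c("a", "b", "c", "d"))
})

test_that("degenerate channel sets are handled explicitly", {
  lay <- ehg_layout(c("p", "q", "r"), x = c(0, 4, 2), y = c(1, 2, 3),
                    z = c(0, 0, 0))
  expect_equal(signaling_distance("p", lay)$d, 0)
  expect_equal(signaling_distance(c("p", "q"), lay)$d, 2)   # half of 4 mm
  # collinear triple: hull is the segment's extremes, r is interior
  s3 <- signaling_distance(c("p", "q", "r"), lay)
  expect_equal(s3$d, 2)
  expect_setequal(s3$hull_vertex_ids, c("p", "q"))
  expect_error(signaling_distance(character(0), lay), "empty")
})

test_that("hull vertices and distance match the brute-force extreme-point oracle", {
  set.seed(51)
  for (rep in 1:40) {
    n <- sample(5:30, 1)
    pts <- cbind(runif(n, -50, 50), runif(n, -50, 50))
    lay <- ehg_layout(sprintf("c%02d", 1:n), x = pts[, 1],
                      y = rnorm(n), z = pts[, 2])
    got <- signaling_distance(lay$channel_id, lay)
    expect_setequal(got$hull_vertex_ids,
                    lay$channel_id[oracle_hull_vertices(pts)])
    expect_equal(got$d, oracle_hull_distance(pts), tolerance = 1e-9)
  }
})

test_that("signaling distance is rigid-motion invariant and scales linearly", {
  set.seed(52)
  n <- 15
  pts <- cbind(x = runif(n, -40, 40), y = runif(n, -10, 10),
               z = runif(n, -40, 40))
  mk <- function(p) ehg_layout(sprintf("c%02d", 1:n), p[, 1], p[, 2], p[, 3])
  ids <- sprintf("c%02d", 1:n)
  d0 <- signaling_distance(ids, mk(pts))$d
  # translation
  expect_equal(signaling_distance(ids, mk(sweep(pts, 2, c(12, -7, 30), "+")))$d,
               d0, tolerance = 1e-9)
  # rotation about the y (projection) axis rotates the x-z plane
  th <- 0.7
  rot <- pts
  rot[, 1] <- cos(th) * pts[, 1] - sin(th) * pts[, 3]
  rot[, 3] <- sin(th) * pts[, 1] + cos(th) * pts[, 3]
  expect_equal(signaling_distance(ids, mk(rot))$d, d0, tolerance = 1e-9)
  # isotropic scaling
  expect_equal(signaling_distance(ids, mk(pts * 3.5))$d, 3.5 * d0,
               tolerance = 1e-9)
})

test_that("adding an interior channel leaves the distance unchanged", {
  lay <- square_layout()
  inner <- ehg_layout(c(lay$channel_id, "mid"), c(lay$x, 0.1),
                      c(lay$y, 2), c(lay$z, -0.2))
  expect_equal(signaling_distance(c("a", "b", "c", "d", "mid"), inner)$d,
               signaling_distance(c("a", "b", "c", "d"), inner)$d)
})

test_that("unprojected mode measures 3-D distances of the projected hull's vertices", {
  lay <- square_layout()
  s2 <- signaling_distance(lay$channel_id, lay, project_y = FALSE)
  xyz <- layout_coords(lay, s2$hull_vertex_ids)
  cen <- colMeans(xyz)
  expect_equal(s2$d, mean(sqrt(rowSums(sweep(xyz, 2, cen)^2))))
  expect_gte(s2$d, signaling_distance(lay$channel_id, lay)$d)
})

test_that("spatial_comparison assembles counts, distances and ratios", {
  set.seed(53)
  n <- 10
  lay <- ehg_layout(sprintf("c%02d", 1:n), runif(n, -50, 50),
                    runif(n, -5, 5), runif(n, -50, 50))
  af <- data.frame(channel_id = lay$channel_id,
                   auc = c(rep(0.9, 4), rep(0.5, 6)))
  ae <- data.frame(channel_id = lay$channel_id,
                   auc = c(rep(0.9, 7), rep(0.5, 3)))
  sp <- spatial_comparison(af, ae, lay)
  expect_identical(sp$fast$set$count, 4L)
  expect_identical(sp$enhanced$set$count, 7L)
  expect_equal(sp$r_c, channel_growth_ratio(4, 7))
  expect_equal(sp$r_d, distance_growth_ratio(sp$fast$d, sp$enhanced$d))
})
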