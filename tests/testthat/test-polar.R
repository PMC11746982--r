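# analytic short-axis LV: uniform half-ellipsoid shell already aligned to -z
make_sa_shell <- function(tilt = c(0, 0), defect = NULL,
                          n = c(48, 48, 48), sp = c(3, 3, 3)) {
  g <- grid_spec(n, sp)
  spec <- cardiac_study_spec(lv_center_mm = c(0, -1e-9, 0),
                             lv_axis_tilt_deg = tilt, defect = defect)
  spec$lv_center_mm <- c(0, 0, 0)
  ct_g <- grid_spec(c(130, 130, 16), c(3.2, 3.2, 9))
  st <- generate_cardiac_study(spec, table_model(enabled = FALSE), ct_g, g)
  st
}

default_geom <- list(apex_z_mm = -(44 + 32) / 2, base_z_mm = 0.2 * 44,
                     max_radius_mm = 44)

test_that("reorientation of an already-aligned axis is the identity up to interpolation", {
  st <- make_sa_shell()
  act <- st$activity
  out <- reorient_short_axis(act, c(0, 0, -1), c(0, 0, 0))
  inside <- st$truth$lv_shell_mask
  expect_lt(sqrt(mean((out$values[inside] - act$values[inside])^2)), 0.02)
  expect_error(reorient_short_axis(act, c(0, 0, 0), c(0, 0, 0)), "zero-length")
})

test_that("reorienting a tilted LV reproduces its natively aligned twin", {
  aligned <- make_sa_shell()
  tilted <- make_sa_shell(tilt = c(-30, 40))
  sa <- reorient_short_axis(tilted$activity, tilted$truth$lv_axis,
                            tilted$truth$lv_center)
  pm_a <- polar_map(aligned$activity, polar_map_model(), default_geom)
  pm_t <- polar_map(sa, polar_map_model(), default_geom)
  expect_lt(max(abs(pm_a$segment_means - pm_t$segment_means)), 5)
})

test_that("a tilted synthetic LV reorients its long axis onto z", {
  st <- make_sa_shell(tilt = c(-30, 40))
  sa <- reorient_short_axis(st$activity, st$truth$lv_axis,
                            st$truth$lv_center)
  # after reorientation the in-plane shell centroids stack vertically:
  # regressing centroid (x, y) on z gives the axis direction
  centroid_axis_angle <- function(vol) {
    g <- vol$grid
    xs <- g$origin_mm[1] + (seq_len(g$shape[1]) - 1) * g$spacing_mm[1]
    ys <- g$origin_mm[2] + (seq_len(g$shape[2]) - 1) * g$spacing_mm[2]
    zs <- g$origin_mm[3] + (seq_len(g$shape[3]) - 1) * g$spacing_mm[3]
    cent <- t(sapply(seq_len(g$shape[3]), function(k) {
      sl <- vol$values[, , k] > 0.5  # myocardium only, not tissue background
      if (sum(sl) < 20) return(c(NA, NA))
      c(sum(rowSums(sl) * xs), sum(colSums(sl) * ys)) / sum(sl)
    }))
    ok <- !is.na(cent[, 1])
    bx <- coef(lm(cent[ok, 1] ~ zs[ok]))[2]
    by <- coef(lm(cent[ok, 2] ~ zs[ok]))[2]
    atan(sqrt(bx^2 + by^2)) * 180 / pi
  }
  expect_lt(centroid_axis_angle(sa), 2)
  # sanity guard: the unoriented tilted volume has a clearly slanted
  # centroid line (base-cut crescents damp the slope below the raw tilt)
  expect_gt(centroid_axis_angle(st$activity), 5)
})

test_that("a uniform shell yields a flat polar map with 17 near-equal segment means", {
  st <- make_sa_shell()
  pm <- polar_map(st$activity, polar_map_model(), default_geom)
  expect_length(pm$segment_means, 17)
  expect_true(all(pm$normalized >= 95))
  expect_lt(diff(range(pm$segment_means)) / mean(pm$segment_means), 0.05)
  expect_true(all(pm$normalized >= 0 & pm$normalized <= 100))
})

test_that("an inferior defect depresses inferior segments relative to anterior", {
  st <- make_sa_shell(defect = list(region = "inferior", residual = 0.4))
  pm <- polar_map(st$activity, polar_map_model(), default_geom)
  m <- pm$segment_means
  expect_lt(m["4"], m["1"])    # basal inferior vs basal anterior
  expect_lt(m["10"], m["7"])   # mid inferior vs mid anterior
  expect_lt(m["15"], m["13"])  # apical inferior vs apical anterior
})

test_that("the polar map of a rotationally symmetric LV is rotation invariant", {
  st <- make_sa_shell()
  na <- 60
  pm <- polar_map(st$activity, polar_map_model(radial_samples = na),
                  default_geom)
  shifted <- pm$normalized[, c(16:na, 1:15)]  # 90 degree angular shift
  expect_lt(max(abs(shifted - pm$normalized)) / 100, 0.03)
})

test_that("segment means are convex combinations of their samples", {
  st <- make_sa_shell(defect = list(region = "septal", residual = 0.3))
  pm <- polar_map(st$activity, polar_map_model(), default_geom)
  expect_true(all(pm$segment_means >= min(pm$normalized) - 1e-9))
  expect_true(all(pm$segment_means <= max(pm$normalized) + 1e-9))
})

test_that("scores follow the descending-threshold bins and are antitone in uptake", {
  st <- make_sa_shell()
  pm <- polar_map(st$activity, polar_map_model(), default_geom)
  pm$segment_means[] <- 100
  expect_true(all(score_segments(pm)$scores == 0))
  pm$segment_means[5] <- 40
  expect_equal(score_segments(pm)$scores[5], 2L)
  pm$segment_means[] <- c(95, 85, 75, 71, 70, 69, 50, 49.9, 30, 29, 10, 9.9,
                          5, 0, 100, 55, 35)
  sc <- score_segments(pm)$scores
  expect_equal(sc, c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L,
                     4L, 4L, 0L, 1L, 2L))
  # antitone: raising any mean never raises the score
  for (k in c(1, 6, 12)) {
    pm2 <- pm; pm2$segment_means[k] <- pm$segment_means[k] + 15
    expect_lte(score_segments(pm2)$scores[k], sc[k])
  }
  # permutation of uptake permutes scores identically
  perm <- sample(17)
  pm3 <- pm; pm3$segment_means <- pm$segment_means[perm]
  expect_equal(score_segments(pm3)$scores, sc[perm])
  expect_error(score_segments(pm, thresholds = c(70, 70, 30, 10)), "descending")
})
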