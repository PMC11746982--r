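coarse_ct <- grid_spec(c(64, 64, 24), c(9.6, 9.6, 12))
coarse_spect <- grid_spec(c(48, 48, 24), c(12.8, 12.8, 12))

test_that("phantom CT is built by construction: interior HU, air, no table below when disabled", {
  st <- generate_jaszczak(phantom_spec(), table_model(enabled = FALSE),
                          coarse_ct, coarse_spect)
  # nothing below the phantom's lowest point exceeds the removal threshold
  y <- st$ct$grid$origin_mm[2] + (seq_len(64) - 1) * 9.6
  below <- y > phantom_spec()$interior_diameter_mm / 2 + 9.5
  expect_true(all(st$ct$values[, below, ] <= -700))
  # interior voxels are exactly fill_hu (shared CT/activity grid instance)
  stt <- generate_jaszczak(phantom_spec(), table_model(), coarse_ct, coarse_ct)
  expect_true(all(stt$ct$values[stt$truth$interior_mask] == 0))
  # uniform activity inside, zero outside
  expect_setequal(unique(as.vector(st$activity$values)), c(0, 1))
  expect_true(all((st$activity$values > 0) == st$truth$interior_mask))
})

test_that("table mask voxel count matches the analytic arc-shell volume", {
  st <- generate_jaszczak(phantom_spec(), table_model(), coarse_ct, coarse_spect)
  vox <- sum(st$truth$table_mask) * prod(coarse_ct$spacing_mm)
  analytic <- oracle_arc_area(table_model()) * 24 * 12
  expect_lt(abs(vox - analytic) / analytic, 0.05)
})

test_that("voxelised volumes converge to the analytic values as spacing halves", {
  err <- sapply(list(grid_spec(c(48, 48, 24), c(12.8, 12.8, 12)),
                     grid_spec(c(96, 96, 48), c(6.4, 6.4, 6))), function(g) {
    st <- generate_jaszczak(phantom_spec(), table_model(), g, coarse_spect)
    vox <- sum(st$truth$table_mask) * prod(g$spacing_mm)
    analytic <- oracle_arc_area(table_model()) * g$shape[3] * g$spacing_mm[3]
    abs(vox - analytic) / analytic
  })
  expect_lt(err[2], err[1])
  # cylinder volume agreement at default-like resolution
  g <- grid_spec(c(96, 96, 48), c(6.4, 6.4, 6))
  st <- generate_jaszczak(phantom_spec(), table_model(), g, g)
  vol <- sum(st$truth$interior_mask) * prod(g$spacing_mm)
  analytic <- pi * (216 / 2)^2 * 186
  expect_lt(abs(vol - analytic) / analytic, 0.05)
})

test_that("table and body masks are disjoint and 6-connected", {
  st <- generate_jaszczak(phantom_spec(), table_model(), coarse_ct, coarse_spect)
  expect_false(any(st$truth$table_mask & st$truth$body_mask))
  expect_true(is_connected6(st$truth$table_mask))
  expect_true(is_connected6(st$truth$body_mask))
  cs <- generate_cardiac_study(cardiac_study_spec(), table_model(),
                               coarse_ct, coarse_spect)
  expect_false(any(cs$truth$table_mask & cs$truth$body_mask))
})

test_that("CT range and activity positivity invariants hold for both generators", {
  st <- generate_jaszczak(phantom_spec(), table_model(), coarse_ct, coarse_spect)
  cs <- generate_cardiac_study(cardiac_study_spec(), table_model(),
                               coarse_ct, coarse_spect)
  for (s in list(st, cs)) {
    expect_gte(min(s$ct$values), -1024)
    expect_lte(max(s$ct$values), 3071)
    expect_gte(min(s$activity$values), 0)
  }
})

test_that("geometry exceeding the grid raises an error naming the dimension", {
  small <- grid_spec(c(24, 24, 24), c(8, 8, 8))
  expect_error(generate_jaszczak(phantom_spec(), table_model(), small, small),
               "interior_diameter_mm|interior_height_mm")
  expect_error(generate_cardiac_study(cardiac_study_spec(), table_model(),
                                      small, small),
               "body_axes_mm|chord_width_mm")
})

test_that("a table at or below the removal threshold is refused", {
  expect_error(table_model(hu_value = -700), "-700")
  expect_error(table_model(hu_value = -850), "-700")
  expect_silent(table_model(hu_value = -699))
})

test_that("cardiac defect scales shell activity by the residual fraction", {
  cs0 <- generate_cardiac_study(cardiac_study_spec(), table_model(),
                                coarse_ct, coarse_spect)
  # no defect: uniform shell
  expect_equal(length(unique(cs0$activity$values[cs0$truth$lv_shell_mask])), 1)
  cs <- generate_cardiac_study(
    cardiac_study_spec(defect = list(region = "inferior", residual = 0.4)),
    table_model(), coarse_ct, coarse_spect)
  d <- cs$truth$defect_mask
  rest <- cs$truth$lv_shell_mask & !d
  expect_gt(sum(d), 0)
  expect_equal(mean(cs$activity$values[d]) / mean(cs$activity$values[rest]),
               0.4, tolerance = 0.01)
  expect_error(generate_cardiac_study(
    cardiac_study_spec(defect = list(region = "inferior", residual = 1.4)),
    table_model(), coarse_ct, coarse_spect), "residual")
})

test_that("generation is bit-identical under a repeated seed and spec", {
  a <- generate_cardiac_study(cardiac_study_spec(), table_model(),
                              coarse_ct, coarse_spect, seed = 11)
  b <- generate_cardiac_study(cardiac_study_spec(), table_model(),
                              coarse_ct, coarse_spect, seed = 11)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$activity$values, b$activity$values)
})

test_that("cohort sampling is reproducible, clamped, and mixes stress/rest as configured", {
  a <- sample_cohort(19, seed = 7)
  b <- sample_cohort(19, seed = 7)
  expect_identical(a, b)
  expect_length(a, 19)
  rng <- cohort_ranges()
  big <- sample_cohort(1000, seed = 3)
  ax <- vapply(big, function(s) s$body_axes_mm[1], numeric(1))
  expect_true(all(ax >= rng$body_ax_range[1] & ax <= rng$body_ax_range[2]))
  stress <- mean(vapply(big, function(s) s$protocol_label == "stress",
                        logical(1)))
  expect_lt(abs(stress - 13 / 19), 0.05)
})
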