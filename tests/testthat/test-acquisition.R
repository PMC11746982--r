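test_that("protocol presets match the clinical orbits", {
  qc <- acquisition_protocol("qc")
  expect_equal(qc$n_projections, 64L)
  expect_equal(qc$arc_deg, 360)
  expect_equal(qc$angles_deg, (0:63) * 5.625)
  mpi <- acquisition_protocol("mpi")
  expect_equal(mpi$n_projections, 34L)
  expect_equal(mpi$arc_deg, 204)
  # symmetric about the anterior axis
  expect_equal(sort(mpi$angles_deg), sort(-mpi$angles_deg))
  expect_error(acquisition_protocol("qc", n_projections = 1), ">= 2")
})

test_that("zero activity projects to zero and grids must match", {
  g <- tiny_grid()
  act <- voxel_volume(array(0, g$shape), g, "activity")
  ps <- forward_project(act, NULL, acquisition_protocol("qc", n_projections = 8))
  expect_true(all(ps$peak == 0))
  g2 <- grid_spec(c(8, 8, 3), c(5, 5, 5))
  mu <- voxel_volume(array(0.1, g2$shape), g2, "mu")
  expect_error(forward_project(act, mu, acquisition_protocol("qc")), "same grid")
})

test_that("a point at isocenter with no attenuation gives equal counts at every angle", {
  g <- grid_spec(c(33, 33, 3), c(4, 4, 4))
  a <- array(0, g$shape); a[17, 17, 2] <- 1  # voxel centred at world origin
  # the interpolation footprint of a single voxel needs sub-voxel detector
  # bins and ray steps to be integrated isotropically
  ps <- forward_project(voxel_volume(a, g, "activity"), NULL,
                        acquisition_protocol("qc"),
                        detector_spacing_mm = 1, nu = 133L, step_mm = 0.5)
  per_view <- apply(ps$peak, 3, sum)
  expect_lt(max(per_view) / min(per_view) - 1, 0.01)
  # extended activity conserves counts across angles already at the default
  # discretisation
  b <- array(0, g$shape)
  ij <- expand.grid(i = 1:33, j = 1:33)
  b[, , 2] <- exp(-((ij$i - 17)^2 + (ij$j - 17)^2) * 16 / 72)
  pb <- forward_project(voxel_volume(b, g, "activity"), NULL,
                        acquisition_protocol("qc"))
  pv <- apply(pb$peak, 3, sum)
  expect_lt(max(pv) / min(pv) - 1, 0.02)
})

test_that("a uniform slab attenuates a point source by the Beer-Lambert factor", {
  g <- grid_spec(c(41, 41, 3), c(5, 5, 5))
  a <- array(0, g$shape); a[21, 21, 2] <- 1
  act <- voxel_volume(a, g, "activity")
  # slab of mu = 0.154/cm anterior of the source, in the path of the view at
  # angle 0 (detector anterior); 10 voxels of 5 mm with linear edge ramps
  # give an effective thickness of exactly 50 mm
  mu <- array(0, g$shape)
  yv <- g$origin_mm[2] + (0:40) * 5
  mu[, yv >= -70.1 & yv <= -24.9, ] <- 0.154
  p0 <- forward_project(act, NULL, acquisition_protocol("qc"))
  p1 <- forward_project(act, voxel_volume(mu, g, "mu"),
                        acquisition_protocol("qc"))
  v_anterior <- which.min(abs(p0$angles_deg - 0))
  ratio <- sum(p1$peak[, , v_anterior]) / sum(p0$peak[, , v_anterior])
  expect_equal(ratio, exp(-0.154 * 5), tolerance = 0.02)
})

test_that("the projector is linear in activity", {
  set.seed(5)
  g <- tiny_grid()
  a1 <- array(runif(prod(g$shape)), g$shape)
  a2 <- array(runif(prod(g$shape)), g$shape)
  mu <- voxel_volume(array(0.02, g$shape), g, "mu")
  pr <- function(a) forward_project(voxel_volume(a, g, "activity"), mu,
                                    acquisition_protocol("qc", n_projections = 12))$peak
  expect_equal(pr(a1 + a2), pr(a1) + pr(a2), tolerance = 1e-6)
})

test_that("ray-traced projections agree with the exhaustive line-integral oracle", {
  set.seed(7)
  g <- tiny_grid()
  a <- array(runif(prod(g$shape)), g$shape)
  mu <- array(runif(prod(g$shape), 0, 0.03), g$shape)
  prot <- acquisition_protocol("qc", n_projections = 6)
  ps <- forward_project(voxel_volume(a, g, "activity"),
                        voxel_volume(mu, g, "mu"), prot)
  ref <- oracle_forward(a, mu, g, prot$angles_deg, ps$detector_spacing_mm,
                        ps$nu, ps$center, ps$step_mm)
  expect_lt(max(abs(ps$peak - ref)) / max(ref), 1e-4)
})

test_that("noise model: disabled is identity, seeded runs reproduce, scatter fraction calibrates", {
  ph <- get_phantom_fixture()
  ps <- forward_project(ph$study$activity, ph$mu_true,
                        acquisition_protocol("qc"))
  off <- add_noise_and_scatter(ps, noise_model(enabled = FALSE))
  expect_identical(off$peak, ps$peak)
  expect_true(all(off$scatter_window == 0))
  m <- noise_model(total_expected_counts = 2e6, seed = 31)
  n1 <- add_noise_and_scatter(ps, m)
  n2 <- add_noise_and_scatter(ps, m)
  expect_identical(n1$peak, n2$peak)
  expect_identical(n1$scatter_window, n2$scatter_window)
  # lower-window counts over primary counts approximate the model fraction
  primary_total <- m$total_expected_counts / (1 + 0.5 * 0.3)
  expect_equal(sum(n1$scatter_window) / primary_total, 0.3, tolerance = 0.03)
  expect_error(add_noise_and_scatter(ps, noise_model(total_expected_counts = 0)),
               "positive")
})

test_that("energy-window scatter correction subtracts half the lower window, clamped", {
  g <- tiny_grid()
  act <- voxel_volume(array(1, g$shape), g, "activity")
  ps <- forward_project(act, NULL, acquisition_protocol("qc", n_projections = 4))
  # no scatter counts: unchanged
  expect_identical(scatter_correct(ps)$peak, ps$peak)
  ps$peak[] <- 80; ps$scatter_window[] <- 100
  corr <- scatter_correct(ps)
  expect_true(all(corr$peak == 80 - 50))  # S = (100/21)*21/2 = 50
  expect_true(all(corr$scatter_window == 0))
  ps$peak[] <- 10
  expect_true(all(scatter_correct(ps)$peak == 0))  # never negative
})

test_that("count reduction: zero for identical maps, larger through thicker tables, posterior-view maximum", {
  ph <- get_phantom_fixture()
  qc <- acquisition_protocol("qc")
  red0 <- count_reduction_profile(ph$study$activity, ph$mu_true, ph$mu_true, qc)
  expect_equal(max(abs(red0)), 0)
  red <- count_reduction_profile(ph$study$activity, ph$mu_true, ph$mu_wo, qc)
  # the most-reduced views look through the table (posterior half of orbit)
  amax <- attr(red, "angles_deg")[which.max(red)]
  expect_gt(amax, 90); expect_lt(amax, 270)
  # lateral views are reduced, anterior views are not
  a <- attr(red, "angles_deg")
  expect_gt(red[a == 90], red[a == 0] + 0.01)
  # doubling thickness: reduction non-decreasing at every angle
  sg <- ph$spect_grid; cg <- ph$ct_grid
  st2 <- generate_jaszczak(phantom_spec(), table_model(thickness_mm = 30),
                           cg, sg)
  mu2 <- resample_to_grid(hu_to_mu(st2$ct), sg)
  rm2 <- remove_table(st2$ct)
  mu2_wo <- resample_to_grid(hu_to_mu(rm2$ct_without_table), sg)
  red2 <- count_reduction_profile(st2$activity, mu2, mu2_wo, qc)
  expect_true(all(red2 - red >= -1e-9))
})
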