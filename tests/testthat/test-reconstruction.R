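toy_problem <- function(seed = 3, n = c(16, 16, 3)) {
  set.seed(seed)
  g <- grid_spec(n, c(10, 10, 10))
  a <- array(0, g$shape)
  a[5:12, 5:12, 2] <- runif(64, 0.5, 2)
  mu <- voxel_volume(array(0.01, g$shape), g, "mu")
  act <- voxel_volume(a, g, "activity")
  prot <- acquisition_protocol("qc", n_projections = 16)
  list(g = g, act = act, mu = mu, prot = prot,
       projs = forward_project(act, mu, prot))
}

test_that("all-zero projections reconstruct to a zero volume with a warning", {
  tp <- toy_problem()
  z <- tp$projs; z$peak[] <- 0
  expect_warning(rec <- osem_reconstruct(z, tp$mu, recon_params(iterations = 2)),
                 "all-zero")
  expect_true(all(rec$values == 0))
  neg <- tp$projs; neg$peak[1] <- -1
  expect_error(osem_reconstruct(neg, tp$mu), "negative")
})

test_that("OSEM with one subset matches the explicit-matrix MLEM reference", {
  tp <- toy_problem()
  it <- 4L
  mine <- osem_reconstruct(tp$projs, tp$mu,
                           recon_params(iterations = it, subsets = 1L))
  ref <- oracle_mlem(tp$projs, tp$mu, tp$g, iterations = it)
  expect_lt(max(abs(mine$values - ref)) / max(ref), 1e-10)
})

test_that("the Poisson log-likelihood is non-decreasing over MLEM iterations", {
  tp <- toy_problem()
  loglik <- function(rec) {
    fp <- forward_project(rec, tp$mu, tp$prot)$peak
    sum(tp$projs$peak * log(pmax(fp, 1e-12)) - fp)
  }
  lls <- vapply(1:6, function(it) {
    loglik(osem_reconstruct(tp$projs, tp$mu,
                            recon_params(iterations = it, subsets = 1L)))
  }, numeric(1))
  expect_true(all(diff(lls) > -1e-8))
})

test_that("subset partition covers every view once, interleaved", {
  idx <- spectable:::subset_indices(34, 3)
  expect_setequal(unlist(idx), 1:34)
  expect_equal(sum(lengths(idx)), 34)
  # interleaving: each subset spans the angular range, not a contiguous block
  for (s in idx) expect_gt(max(s) - min(s), 20)
})

test_that("counts are preserved without attenuation on full-orbit data", {
  tp <- toy_problem()
  projs0 <- forward_project(tp$act, NULL, tp$prot)
  rec <- osem_reconstruct(projs0, NULL, recon_params(), grid = tp$g)
  fp <- forward_project(rec, NULL, tp$prot)$peak
  per_view_meas <- apply(projs0$peak, 3, sum)
  per_view_fit <- apply(fp, 3, sum)
  expect_lt(max(abs(per_view_fit / per_view_meas - 1)), 0.02)
})

test_that("noiseless uniform phantom with the true mu-map is recovered to 5%", {
  ph <- get_phantom_fixture()
  projs <- forward_project(ph$study$activity, ph$mu_true,
                           acquisition_protocol("qc"))
  rec <- osem_reconstruct(projs, ph$mu_true, recon_params())
  # interior eroded by 3 voxels to dodge partial-volume rims
  sp <- phantom_spec(); g <- ph$spect_grid
  xax <- g$origin_mm[1] + (seq_len(g$shape[1]) - 1) * g$spacing_mm[1]
  zax <- g$origin_mm[3] + (seq_len(g$shape[3]) - 1) * g$spacing_mm[3]
  er_r <- sp$interior_diameter_mm / 2 - 3 * g$spacing_mm[1]
  disc <- outer(xax^2, xax^2, "+") <= er_r^2
  zin <- abs(zax) <= sp$interior_height_mm / 2 - 3 * g$spacing_mm[3]
  eroded <- array(rep(disc, g$shape[3]), g$shape)
  eroded[, , !zin] <- FALSE
  vals <- rec$values[eroded]
  expect_lt(abs(mean(vals) - 1), 0.05)
  expect_lt(sd(vals) / mean(vals), 0.05)
  run_cache$uniform_recovery <- mean(vals)
})

test_that("reconstruct_pair: no table means bit-identical arms", {
  sg <- grid_spec(c(48, 48, 24), c(12.8, 12.8, 12))
  cg <- grid_spec(c(96, 96, 24), c(6.4, 6.4, 12))
  st <- generate_jaszczak(phantom_spec(), table_model(enabled = FALSE), cg, sg)
  mu <- resample_to_grid(hu_to_mu(st$ct), sg)
  projs <- forward_project(st$activity, mu,
                           acquisition_protocol("qc", n_projections = 16))
  expect_warning(pair <- reconstruct_pair(projs, st$ct,
                                          params = recon_params(iterations = 2),
                                          grid = sg),
                 "no table")
  expect_identical(pair$with_table$values, pair$without_table$values)
})

test_that("omitting the table underestimates activity posteriorly, boundedly", {
  qc <- get_experiment("qc")
  w <- qc$pair$with_table$values
  wo <- qc$pair$without_table$values
  interior <- qc$study$truth$interior_mask
  # posterior third of the interior (largest y)
  g <- qc$cfg$spect_grid
  yv <- g$origin_mm[2] + (seq_len(g$shape[2]) - 1) * g$spacing_mm[2]
  ylim <- quantile(yv[apply(interior, 2, any)], 2 / 3)
  post <- interior
  post[, yv < ylim, ] <- FALSE
  expect_gt(median(w[post] - wo[post]), 0)
  # and the anterior half is barely affected (rays there avoid the table)
  ant <- interior
  ant[, yv > 0, ] <- FALSE
  expect_lt(max(abs(w[ant] - wo[ant]) / w[ant]), 0.10)
})
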