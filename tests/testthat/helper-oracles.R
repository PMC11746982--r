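# Independent oracles and shared small fixtures. Everything here is written
# against the package's *documented contracts*, not its internals, so the
# same quantities are computed along two separate code paths.

# --- independent attenuated line-integral projector (plain R, loop form) ----
# Rays confined to transaxial planes; detector at angle theta from anterior
# rotating toward patient left; samples marched from the detector inward with
# the attenuation sum taken from the emission sample (inclusive) to the
# detector. Mirrors the documented discretisation, implemented independently.
oracle_forward <- function(act, mu, grid, angles_deg, det_spacing, nu,
                           center, step_mm) {
  sh <- grid$shape; sp <- grid$spacing_mm; or <- grid$origin_mm
  bil <- function(vol, cx, cy, k) {
    if (cx < -0.5 || cx > sh[1] - 0.5 || cy < -0.5 || cy > sh[2] - 0.5)
      return(0)
    ix <- floor(cx); iy <- floor(cy)
    fx <- cx - ix; fy <- cy - iy
    gv <- function(i, j) {
      if (i >= 0 && i < sh[1] && j >= 0 && j < sh[2]) vol[i + 1, j + 1, k] else 0
    }
    (1 - fx) * (1 - fy) * gv(ix, iy) + fx * (1 - fy) * gv(ix + 1, iy) +
      (1 - fx) * fy * gv(ix, iy + 1) + fx * fy * gv(ix + 1, iy + 1)
  }
  xlo <- or[1] - 0.5 * sp[1]; xhi <- or[1] + (sh[1] - 0.5) * sp[1]
  ylo <- or[2] - 0.5 * sp[2]; yhi <- or[2] + (sh[2] - 0.5) * sp[2]
  out <- array(0, c(nu, sh[3], length(angles_deg)))
  for (v in seq_along(angles_deg)) {
    th <- angles_deg[v] * pi / 180
    d <- c(sin(th), -cos(th)); uvec <- c(cos(th), sin(th))
    for (iu in seq_len(nu)) {
      off <- (iu - 1 - (nu - 1) / 2) * det_spacing
      r0 <- center + uvec * off
      ts <- c()
      for (ax in 1:2) {
        if (abs(d[ax]) < 1e-12) {
          if (r0[ax] < c(xlo, ylo)[ax] || r0[ax] > c(xhi, yhi)[ax]) ts <- NA
        } else {
          t1 <- (c(xlo, ylo)[ax] - r0[ax]) / d[ax]
          t2 <- (c(xhi, yhi)[ax] - r0[ax]) / d[ax]
          ts <- rbind(ts, sort(c(t1, t2)))
        }
      }
      if (anyNA(ts)) next
      tmin <- max(ts[, 1], -1e30); tmax <- min(ts[, 2], 1e30)
      if (tmax <= tmin) next
      nstep <- ceiling((tmax - tmin) / step_mm)
      for (k in seq_len(sh[3])) {
        acc <- 0; s <- 0
        for (st in seq_len(nstep)) {
          t <- tmax - (st - 0.5) * step_mm
          if (t < tmin) break
          cx <- (r0[1] + t * d[1] - or[1]) / sp[1]
          cy <- (r0[2] + t * d[2] - or[2]) / sp[2]
          acc <- acc + 0.1 * step_mm * bil(mu, cx, cy, k)
          av <- bil(act, cx, cy, k)
          if (av > 0) s <- s + step_mm * av * exp(-acc)
        }
        out[iu, k, v] <- s
      }
    }
  }
  out
}

# --- explicit-system-matrix MLEM reference ---------------------------------
# The system matrix is extracted column by column through the projector's
# public interface; the EM iteration itself is an independent matrix-algebra
# implementation.
oracle_mlem <- function(projs, mu, grid, iterations, init_value = 1,
                        floor = 1e-12) {
  nvox <- prod(grid$shape)
  cols <- vector("list", nvox)
  for (j in seq_len(nvox)) {
    e <- array(0, grid$shape); e[j] <- 1
    pj <- forward_project(voxel_volume(e, grid, "activity"), mu,
                          projs$protocol, center = projs$center,
                          nu = projs$nu,
                          detector_spacing_mm = projs$detector_spacing_mm,
                          step_mm = projs$step_mm)
    cols[[j]] <- as.vector(pj$peak)
  }
  C <- do.call(cbind, cols)
  p <- as.vector(projs$peak)
  sens <- colSums(C)
  a <- rep(init_value, nvox)
  for (it in seq_len(iterations)) {
    fp <- as.vector(C %*% a)
    ratio <- p / pmax(fp, floor)
    bp <- as.vector(crossprod(C, ratio))
    a <- pmax(a * ifelse(sens > 0, bp / pmax(sens, floor), 0), floor)
  }
  array(a, grid$shape)
}

# --- independent arc-shell area estimate (dense pixel counting) ------------
oracle_arc_area <- function(table, n = 4000) {
  R <- (table$arc_sagitta_mm^2 + (table$chord_width_mm / 2)^2) /
    (2 * table$arc_sagitta_mm)
  w <- table$chord_width_mm / 2; t <- table$thickness_mm
  xs <- seq(-w, w, length.out = n)
  dx <- xs[2] - xs[1]
  # for each x the shell occupies y in [sqrt(R^2-x^2), sqrt((R+t)^2-x^2)]
  lo <- sqrt(pmax(R^2 - xs^2, 0))
  hi <- sqrt(pmax((R + t)^2 - xs^2, 0))
  sum(hi - lo) * dx
}

# --- small shared fixtures -------------------------------------------------
tiny_grid <- function(n = c(8, 8, 3), sp = c(10, 10, 10))
  grid_spec(n, sp)

# cached desk-scale phantom study shared across test files
phantom_cache <- new.env(parent = emptyenv())
get_phantom_fixture <- function() {
  if (is.null(phantom_cache$study)) {
    sg <- grid_spec(c(64, 64, 64), c(9.6, 9.6, 9.6))
    cg <- grid_spec(c(192, 192, 64), c(3.2, 3.2, 9.6))
    st <- generate_jaszczak(phantom_spec(), table_model(), cg, sg)
    phantom_cache$study <- st
    phantom_cache$spect_grid <- sg
    phantom_cache$ct_grid <- cg
    phantom_cache$mu_true <- resample_to_grid(hu_to_mu(st$ct), sg)
    rmv <- remove_table(st$ct)
    phantom_cache$removal <- rmv
    phantom_cache$mu_wo <- resample_to_grid(hu_to_mu(rmv$ct_without_table), sg)
  }
  phantom_cache
}

# cached full experiments for the acceptance checks
run_cache <- new.env(parent = emptyenv())
get_experiment <- function(which) {
  key <- paste0("exp_", which)
  if (is.null(run_cache[[key]]))
    run_cache[[key]] <- switch(which,
      qc = run_phantom_experiment(experiment_config("qc_phantom", seed = 1)),
      mpi = run_phantom_experiment(experiment_config("mpi_phantom", seed = 1)),
      cohort = run_cohort_experiment(experiment_config("cohort", seed = 42,
                                                       n_studies = 19)))
  run_cache[[key]]
}

# 3-D 6-connectivity check: iterative flood fill by dilating a seed within
# the mask until it stops growing (vectorised over the whole array)
is_connected6 <- function(mask) {
  n <- sum(mask)
  if (n == 0) return(TRUE)
  d <- dim(mask)
  seed <- array(FALSE, d)
  seed[which(mask)[1]] <- TRUE
  shift <- function(a, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (by == 1) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  repeat {
    grown <- seed
    for (ax in 1:3) for (by in c(1, -1))
      grown <- grown | shift(seed, ax, by)
    grown <- grown & mask
    if (sum(grown) == sum(seed)) break
    seed <- grown
  }
  sum(seed) == n
}
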