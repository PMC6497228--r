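ff <- default_forcefield()

# build an md_trajectory directly from analytic per-frame positions
traj_from_fun <- function(fun, times, type = PARTICLE_TYPES[["TMP"]],
                          geometry = list(kind = "cylinder",
                                          box = c(0, 0, 100))) {
  frames <- lapply(times, fun)
  structure(list(times = times, steps = seq_along(times) - 1L,
                 frames = frames, orient_frames = NULL,
                 type = rep(type, nrow(frames[[1]])),
                 geometry = geometry, sigma_nm = 2.227),
            class = "md_trajectory")
}

test_that("cylindrical unwrap: axial, circling and helical paths", {
  r0 <- 20
  # purely axial motion: u constant, v follows z
  tj <- traj_from_fun(function(t) matrix(c(r0, 0, 0.3 * t), 1, 3),
                      times = 0:50)
  tr <- unwrap_cylinder(tj)
  expect_equal(diff(range(tr$u)), 0)
  expect_equal(tr$v[, 1], 0.3 * (0:50))
  # circling through three full turns: u advances 2*pi*r*n monotonically
  om <- 2 * pi * 3 / 200
  tj2 <- traj_from_fun(function(t)
    matrix(c(r0 * cos(om * t), r0 * sin(om * t), 5), 1, 3), times = 0:200)
  tr2 <- unwrap_cylinder(tj2)
  expect_true(all(diff(tr2$u[, 1]) > 0))
  expect_equal(tr2$u[201, 1] - tr2$u[1, 1], 2 * pi * r0 * 3,
               tolerance = 1e-9)
  # helix: planar arc length equals the geodesic length on the cylinder
  cz <- 0.11
  tj3 <- traj_from_fun(function(t)
    matrix(c(r0 * cos(0.02 * t), r0 * sin(0.02 * t), cz * t), 1, 3),
    times = 0:300)
  tr3 <- unwrap_cylinder(tj3)
  planar <- sum(sqrt(diff(tr3$u[, 1])^2 + diff(tr3$v[, 1])^2))
  geodesic <- 300 * sqrt((r0 * 0.02)^2 + cz^2)  # unrolled straight segments
  expect_equal(planar, geodesic, tolerance = 1e-6)
})

test_that("unwrap errors on undersampled angular steps and warns on radial drift", {
  tj <- traj_from_fun(function(t)
    matrix(c(20 * cos(pi * t), 20 * sin(pi * t), 0), 1, 3), times = 0:5)
  expect_error(unwrap_cylinder(tj), "sparsely")
  set.seed(12)
  tj2 <- traj_from_fun(function(t) {
    r <- 20 * (1 + 0.1 * sin(t))
    matrix(c(r, 0.01 * t * 20, 0), 1, 3)
  }, times = 0:60)
  expect_warning(unwrap_cylinder(tj2), "radial")
})

test_that("MSD estimator: static, Brownian and additivity properties", {
  # static particles give an all-zero curve
  tj <- traj_from_fun(function(t) cbind(c(10, 12), c(0, 1), c(0, 5)),
                      times = 0:20)
  cv <- msd(unwrap_cylinder(tj), "planar_2D", n_lags = 5)
  expect_true(all(cv$msd == 0))
  # Brownian walk: MSD(k) = 2 d D k dt within sampling error
  set.seed(13)
  d_in <- 2e-3
  tr <- simulate_brownian_walk(400, n_particles = 150, d = d_in, dt = 1)
  cv1 <- msd(tr, "longitudinal", n_lags = 12, max_lag_frames = 40)
  fit <- fit_normal(cv1)
  expect_equal(fit$par$D, d_in, tolerance = 0.05)
  # additivity: planar curve equals longitudinal + transverse exactly
  cv_l <- msd(tr, "longitudinal", n_lags = 10)
  cv_t <- msd(tr, "transverse", n_lags = 10)
  cv_p <- msd(tr, "planar_2D", n_lags = 10)
  expect_equal(cv_p$msd, cv_l$msd + cv_t$msd)
  expect_error(msd(tr, types = "actin"), "no particles")
})

test_that("MSD estimator is unbiased over independent replicates", {
  set.seed(14)
  d_in <- 1e-2
  one_curve <- function() {
    tr <- simulate_brownian_walk(60, n_particles = 2, d = d_in, dt = 1)
    msd(tr, "longitudinal", n_lags = 6, max_lag_frames = 30,
        spacing = "linear")
  }
  cv0 <- one_curve()
  ms <- replicate(60, one_curve()$msd[2])
  expected <- 2 * d_in * cv0$lag[2]
  se <- sd(ms) / sqrt(length(ms))
  expect_lt(abs(mean(ms) - expected), 2 * se + 0.02 * expected)
})

test_that("confined fit recovers exact and simulated parameters", {
  lag <- exp(seq(log(1), log(5000), length.out = 40))
  d_in <- 1.53e-3; l_in <- 48.5
  curve <- structure(data.frame(
    lag = lag, msd = l_in^2 / 6 * (1 - exp(-12 * d_in * lag / l_in^2)),
    n = 1000), class = c("msd_curve", "data.frame"))
  attr(curve, "component") <- "longitudinal"
  fit <- fit_confined(curve)
  expect_equal(fit$par$D_micro, d_in, tolerance = 1e-6)
  expect_equal(fit$par$L, l_in, tolerance = 1e-6)
  expect_lt(fit$resid_norm, 1e-12)
  # reflected walk in a box of width W: L ~ W, D_micro ~ input D
  set.seed(15)
  tr <- simulate_confined_walk(4000, n_particles = 80, d = 1e-2, dt = 1,
                               L = 5, confine = "v")
  cvw <- msd(tr, "longitudinal", n_lags = 25, max_lag_frames = 1500)
  fw <- fit_confined(cvw)
  expect_equal(fw$par$L, 5, tolerance = 0.1)
  expect_equal(fw$par$D_micro, 1e-2, tolerance = 0.1)
})

test_that("confined-hop fit separates micro and macro diffusion", {
  set.seed(16)
  tr <- simulate_hop_walk(6000, n_particles = 100, d = 1e-2, dt = 1, L = 5,
                          p_escape = 0.002, confine = "v")
  cv <- msd(tr, "longitudinal", n_lags = 30, max_lag_frames = 2500)
  fit <- fit_confined_hop(cv)
  expect_lt(fit$par$D_macro, fit$par$D_micro / 5)
  expect_equal(fit$par$D_micro, 1e-2, tolerance = 0.25)
  expect_gt(fit$par$D_macro, 0)
  # zero escape probability degenerates to pure confinement
  set.seed(17)
  tr0 <- simulate_hop_walk(4000, n_particles = 60, d = 1e-2, dt = 1, L = 5,
                           p_escape = 0, confine = "v")
  cv0 <- msd(tr0, "longitudinal", n_lags = 25, max_lag_frames = 1500)
  fit0 <- fit_confined_hop(cv0)
  expect_lt(fit0$par$D_macro, 0.05 * fit0$par$D_micro)
})

test_that("anomalous fit recovers power laws and flags curve shape", {
  lag <- exp(seq(log(1), log(1000), length.out = 30))
  curve <- structure(data.frame(lag = lag, msd = 0.37 * lag^0.5, n = 100),
                     class = c("msd_curve", "data.frame"))
  fit <- fit_anomalous(curve)
  expect_equal(fit$par$alpha_anom, 0.5, tolerance = 1e-6)
  expect_equal(fit$par$C, 0.37, tolerance = 1e-6)
  # Brownian input: exponent near 1
  set.seed(18)
  tr <- simulate_brownian_walk(2000, n_particles = 60, d = 1e-2, dt = 1)
  cvb <- msd(tr, "longitudinal", n_lags = 20, max_lag_frames = 600)
  expect_equal(fit_anomalous(cvb)$par$alpha_anom, 1, tolerance = 0.1)
  # saturating (confined) input: exponent below 1 on intermediate lags
  set.seed(19)
  trc <- simulate_confined_walk(3000, n_particles = 60, d = 1e-2, dt = 1,
                                L = 5, confine = "v")
  cvc <- msd(trc, "longitudinal", n_lags = 20, max_lag_frames = 1000)
  expect_lt(fit_anomalous(cvc)$par$alpha_anom, 0.8)
  curve$msd[20] <- -1   # inside the default fit window
  expect_error(fit_anomalous(curve), "positive")
})

test_that("model selection follows residual norm with parsimony tie-break", {
  set.seed(20)
  # synthetic hop data: confined-hop must beat anomalous
  tr <- simulate_hop_walk(6000, n_particles = 100, d = 1e-2, dt = 1, L = 5,
                          p_escape = 0.002, confine = "v")
  cv <- msd(tr, "longitudinal", n_lags = 30, max_lag_frames = 2500)
  best <- select_model(cv, models = c("confined_hop", "anomalous"))
  expect_equal(best$model, "confined_hop")
  rn <- attr(best, "residuals")
  expect_lt(rn[["confined_hop"]], rn[["anomalous"]])
  # exact power-law data: anomalous wins
  lag <- exp(seq(log(1), log(1000), length.out = 30))
  cpow <- structure(data.frame(lag = lag, msd = 0.2 * lag^0.6, n = 100),
                    class = c("msd_curve", "data.frame"))
  attr(cpow, "component") <- "longitudinal"
  expect_equal(select_model(cpow)$model, "anomalous")
  # ties resolve by parsimony: exact confined data fits confined_hop
  # equally well (D_macro = 0), but the simpler model is returned
  d_in <- 1.5e-3; l_in <- 10
  cconf <- structure(data.frame(
    lag = lag, msd = l_in^2 / 6 * (1 - exp(-12 * d_in * lag / l_in^2)),
    n = 100), class = c("msd_curve", "data.frame"))
  attr(cconf, "component") <- "longitudinal"
  expect_equal(select_model(cconf,
                            models = c("confined", "confined_hop"))$model,
               "confined")
})

test_that("stripe width adds the steric contact on both sides", {
  expect_equal(stripe_width(108, 30), 168)
  expect_equal(stripe_width(0, 15), 30)
  expect_equal(stripe_width(52 * 2.227, 27.5), 170.8, tolerance = 1e-3)
})

test_that("end-to-end statistics of a rigid chain equal the contour length", {
  ch <- build_spectrin_chain(n_particles = 11, ff = ff)
  tj <- traj_from_fun(function(t) ch$pos, times = 0:5,
                      type = PARTICLE_TYPES[["spectrin"]],
                      geometry = list(kind = "free", box = c(0, 0, 0)))
  tj$type <- ch$type
  st <- end_to_end_stats(tj)
  expect_equal(st$rms * ff$units$sigma_nm, 50, tolerance = 1e-9)
  expect_equal(st$sd, 0)
})
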