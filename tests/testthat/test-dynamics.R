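ff <- default_forcefield()

test_that("a free particle moves in a straight line", {
  sys <- particle_system(matrix(c(0, 0, 0), 1, 3),
                         PARTICLE_TYPES[["spectrin"]])
  v0 <- c(0.3, -0.1, 0.05)
  r <- run_md(sys, ff, n_steps = 1000, ensemble = "nve",
              velocities = list(vel = matrix(v0, 1, 3),
                                avel = matrix(0, 1, 3)),
              traj_every = 100, thermo_every = 0)
  for (f in seq_along(r$trajectory$frames)) {
    t <- r$trajectory$times[f]
    expect_equal(r$trajectory$frames[[f]][1, ], v0 * t, tolerance = 1e-12)
  }
})

test_that("a harmonic dimer oscillates at the analytic period", {
  # two lipid particles bonded at req = 4 sigma: beyond every non-bonded
  # cutoff, so the spring is the only interaction
  k <- 6.5
  sys <- particle_system(rbind(c(0, 0, 0), c(4.5, 0, 0)), c(1L, 1L),
                         rbind(c(0, 0, 1), c(0, 0, 1)))
  sys$topology$bonds <- cbind(i = 1, j = 2, k = k, req = 4)
  period <- 2 * pi * sqrt(1 / (2 * k))
  n_per <- 100
  r <- run_md(sys, ff, n_steps = ceiling(n_per * period / 0.01) + 50,
              ensemble = "nve",
              velocities = list(vel = matrix(0, 2, 3),
                                avel = matrix(0, 2, 3)),
              traj_every = 1, thermo_every = 0)
  sep <- vapply(r$trajectory$frames, function(p) p[2, 1] - p[1, 1],
                numeric(1)) - 4
  # count upward zero crossings to measure the period
  up <- which(sep[-1] > 0 & sep[-length(sep)] <= 0)
  measured <- (up[length(up)] - up[1]) * 0.01 / (length(up) - 1)
  expect_equal(measured, period, tolerance = 1e-3)
})

test_that("orientation vectors stay on the unit sphere", {
  set.seed(4)
  bl <- build_bilayer("slab", lx = 7, ly = 7, ff = ff)
  r <- run_md(bl, ff, n_steps = 1e4, seed = 4, traj_every = 0,
              thermo_every = 0, record_orient = FALSE)
  norms <- sqrt(rowSums(r$system$orient^2))
  expect_lt(max(abs(norms - 1)), 1e-8)
})

test_that("NVE conserves energy and momentum", {
  set.seed(5)
  bl <- build_bilayer("slab", lx = 12, ly = 12, ff = ff)
  eq <- run_md(bl, ff, n_steps = 2000, seed = 5, traj_every = 0,
               thermo_every = 0)
  r <- run_md(eq$system, ff, n_steps = 1.2e4, ensemble = "nve",
              velocities = eq$velocities, traj_every = 0, thermo_every = 500)
  e <- r$thermo$total_energy
  # drift measured after the startup transient, per particle per 1e4 steps
  i0 <- 5
  drift <- abs(e[length(e)] - e[i0]) / nrow(bl$pos) /
    ((r$thermo$step[length(e)] - r$thermo$step[i0]) / 1e4)
  expect_lt(drift, 1e-4)
  # momentum conservation
  p0 <- colSums(eq$velocities$vel)
  p1 <- colSums(r$velocities$vel)
  expect_lt(max(abs(p1 - p0)), 1e-10 * 1e4)
})

test_that("NVT holds the target kinetic temperature", {
  set.seed(6)
  bl <- build_bilayer("slab", lx = 12, ly = 12, ff = ff)
  r <- run_md(bl, ff, n_steps = 3e4, seed = 6, traj_every = 0,
              thermo_every = 500)
  tt <- r$thermo$temp_trans
  burn <- tt[-(1:10)]
  expect_equal(mean(burn), 0.22, tolerance = 0.02)
  # no secular drift: first and second half means agree
  h <- length(burn) %/% 2
  expect_lt(abs(mean(burn[1:h]) - mean(burn[(h + 1):(2 * h)])), 0.01)
})

test_that("identical seeds give bit-identical trajectories", {
  set.seed(8)
  bl <- build_bilayer("slab", lx = 6, ly = 6, ff = ff)
  r1 <- run_md(bl, ff, n_steps = 500, seed = 99, traj_every = 100)
  r2 <- run_md(bl, ff, n_steps = 500, seed = 99, traj_every = 100)
  expect_identical(r1$trajectory$frames, r2$trajectory$frames)
  expect_identical(r1$system$orient, r2$system$orient)
})

test_that("zero steps leave the system unchanged with an empty trajectory", {
  sys <- build_spectrin_chain(ff = ff)
  r <- run_md(sys, ff, n_steps = 0)
  expect_equal(n_frames(r$trajectory), 0)
  expect_identical(r$system$pos, sys$pos)
})

test_that("cell-list pair enumeration matches the brute-force oracle", {
  set.seed(11)
  for (geom in list(list(kind = "slab", box = c(10, 8, 0)),
                    list(kind = "cylinder", box = c(0, 0, 9)),
                    list(kind = "free", box = c(0, 0, 0)))) {
    pos <- cbind(runif(500, 0, 10), runif(500, 0, 8), runif(500, 0, 9))
    got <- neighbor_pairs(pos, geom, cutoff = 1.5)
    want <- brute_pairs(pos, geom, cutoff = 1.5)
    expect_identical(unname(sort_pairs(got)), unname(sort_pairs(want)))
  }
  # empty system and cutoff larger than the box
  expect_equal(nrow(neighbor_pairs(matrix(numeric(0), 0, 3),
                                   list(kind = "free", box = c(0, 0, 0)),
                                   cutoff = 1)), 0)
  pos <- cbind(runif(20, 0, 3), runif(20, 0, 3), 0)
  all_pairs <- neighbor_pairs(pos, list(kind = "slab", box = c(3, 3, 0)),
                              cutoff = 50)
  expect_equal(nrow(all_pairs), choose(20, 2))
})

test_that("breakable associations break and reform during dynamics", {
  sk <- skeleton_fixture(ff)
  ffk <- skeleton_fixture_ff()
  # pull one chain end far beyond the capture distance
  sk2 <- sk
  sk2$pos[sk2$topology$as_ends[1], ] <- c(200, 200, 200)
  res <- system_forces(sk2, ffk)
  expect_equal(res$as_partner[1], 0)     # bond broken
  expect_gt(res$as_partner[2], 0)        # the other end still bound
  # moving it back within capture distance lets it reform
  sk3 <- sk2
  sk3$topology$as_partner <- as.integer(res$as_partner)
  sk3$pos[sk3$topology$as_ends[1], ] <- sk$pos[sk$topology$as_ends[1], ]
  res2 <- system_forces(sk3, ffk)
  expect_gt(res2$as_partner[1], 0)
})

test_that("FENE blow-up aborts with a diagnostic", {
  ring <- build_actin_ring(6, 35, ff)
  ring$pos[1, ] <- ring$pos[1, ] + c(20, 20, 0)  # over-bends the ring
  expect_error(system_energy(ring, ff), "FENE")
})
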