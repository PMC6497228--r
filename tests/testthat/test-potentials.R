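ff <- default_forcefield()

num_deriv2 <- function(f, x, h = 1e-4) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

# one-sided second derivative from below, for minima that sit exactly at a
# truncation cutoff
num_deriv2_left <- function(f, x, h = 1e-4) {
  (f(x - 2 * h) - 2 * f(x - h) + f(x)) / h^2
}

test_that("spectrin repulsion is a WCA-truncated LJ with spring-matched curvature", {
  rmin <- 2 * 2^(1 / 6)
  expect_equal(u_spectrin_rep(rmin, ff), 0)
  expect_equal(u_spectrin_rep(rmin + 0.5, ff), 0)   # zero beyond cutoff
  expect_equal(u_spectrin_rep(2, ff), ff$eps1)      # bracket vanishes at scale
  # purely repulsive inside: energy decreases monotonically to the cutoff
  r <- seq(1.6, rmin, length.out = 50)
  expect_true(all(diff(u_spectrin_rep(r, ff)) < 0))
  # curvature at the minimum (= cutoff): finite differences from inside
  # match the closed form
  curv <- num_deriv2_left(function(r) u_spectrin_rep(r, ff), rmin, h = 1e-5)
  curv_analytic <- 144 * 2^(-4 / 3) * ff$eps1 / 4
  expect_equal(curv, curv_analytic, tolerance = 1e-3)
  expect_error(u_spectrin_rep(0, ff), "positive")
})

test_that("spring potential is harmonic and symmetric", {
  expect_equal(u_spring(5, 6.5, 5), 0)
  expect_equal(u_spring(5 + 1, 6.5, 5), 3.25)
  expect_equal(u_spring(4.3, 6.5, 5), u_spring(5.7, 6.5, 5))
  expect_error(u_spring(1, -1, 5), "non-negative")
})

test_that("breakable actin-spectrin association", {
  rmin <- 2^(1 / 6) * 8
  res <- u_breakable_as(rmin, ff)
  expect_equal(res$energy, 0)
  expect_false(res$broken)
  # the association minimum sits at about 20 nm
  expect_equal(rmin * ff$units$sigma_nm, 20, tolerance = 1e-3)
  expect_equal(u_breakable_as(8, ff)$energy, ff$eps2)
  beyond <- u_breakable_as(2.6 * 8, ff)
  expect_equal(beyond$energy, 0)
  expect_true(beyond$broken)
  # curvature at the association minimum matches the chain spring constant
  curv <- num_deriv2(function(r) u_breakable_as(r, ff)$energy, rmin, h = 1e-3)
  expect_equal(curv, 6.5, tolerance = 0.01)
})

test_that("FENE bending potential of the ring", {
  th0 <- ff$theta0
  expect_equal(th0, pi * 37 / 39)
  expect_equal(round(th0 * 180 / pi, 2), 170.77)
  expect_equal(u_fene_bend(th0, ff), 0)
  d <- 0.9 * ff$dthmax
  expect_equal(u_fene_bend(th0 + d, ff), u_fene_bend(th0 - d, ff))
  # small-deflection limit: U ~ (kb/dthmax)/2 * (theta-theta0)^2
  eps <- 1e-3
  expect_equal(u_fene_bend(th0 + eps, ff),
               0.5 * (ff$kb / ff$dthmax) * eps^2, tolerance = 1e-5)
  # diverges monotonically toward the bounds, errors outside
  qs <- c(0.5, 0.9, 0.99, 0.999)
  expect_true(all(diff(u_fene_bend(th0 + qs * ff$dthmax, ff)) > 0))
  expect_error(u_fene_bend(th0 + 1.0001 * ff$dthmax, ff), "domain")
})

test_that("FENE ring-spacing potential", {
  deq <- ff$deq_rr
  expect_equal(u_fene_ring_spacing(deq, ff), 0)
  d20 <- 20 / ff$units$sigma_nm
  expect_equal(u_fene_ring_spacing(deq + d20, ff),
               u_fene_ring_spacing(deq - d20, ff))
  curv <- num_deriv2(function(d) u_fene_ring_spacing(d, ff), deq, h = 1e-3)
  expect_equal(curv, ff$kmt / ff$ddmax, tolerance = 1e-5)
  expect_error(u_fene_ring_spacing(deq + ff$ddmax, ff), "domain")
})

test_that("orientation factor covers the aligned, anti-aligned and parallel cases", {
  x <- c(1, 0, 0)
  up <- c(0, 0, 1)
  expect_equal(orientation_factor(up, up, x)$a, 1)
  expect_equal(orientation_factor(up, up, x)$A, 1)
  expect_equal(orientation_factor(up, -up, x)$a, -1)
  expect_equal(orientation_factor(up, -up, x)$A, 1 - 2 * 1.55)
  expect_equal(orientation_factor(x, x, x)$a, 0)
  expect_error(orientation_factor(up, up, c(0, 0, 0)), "zero")
  expect_error(orientation_factor(c(0, 0, 2), up, x), "unit")
})

test_that("membrane pair potential: cutoff, minimum, orientation flip", {
  up <- c(0, 0, 1); x <- c(1, 0, 0)
  for (cls in c("LL", "LP", "PP")) {
    p <- axonmem:::membrane_class_params(cls, ff)
    expect_equal(u_membrane_pair(ff$rcut_mem, up, up, x, cls, ff), 0)
    expect_equal(u_membrane_pair(3.5, up, up, x, cls, ff), 0)
    # aligned normals perpendicular to the axis: minimum -k*eps at req
    expect_equal(u_membrane_pair(p$req, up, up, x, cls, ff), -p$k)
    slope <- (u_membrane_pair(p$req + 1e-5, up, up, x, cls, ff) -
              u_membrane_pair(p$req - 1e-5, up, up, x, cls, ff)) / 2e-5
    expect_lt(abs(slope), 1e-3)
    # the minimum is located at req within 1e-6 sigma
    opt <- stats::optimize(function(r) u_membrane_pair(r, up, up, x, cls, ff),
                           c(p$req - 0.1, p$req + 0.1), tol = 1e-9)
    expect_equal(opt$minimum, p$req, tolerance = 1e-6)
    # anti-aligned normals flip attraction to repulsion
    expect_equal(u_membrane_pair(p$req, up, -up, x, cls, ff),
                 p$k + 2.1 * 2 * p$k)
  }
  expect_error(u_membrane_pair(1, up, up, x, "XY", ff), "unknown")
})

test_that("inter-leaflet potential is continuous with a smooth minimum", {
  rcl <- ff$rcut_layer
  expect_equal(u_interlayer(rcl, ff), -ff$k_layer)
  expect_equal(u_interlayer(rcl - 1e-9, ff), -ff$k_layer, tolerance = 1e-6)
  expect_equal(u_interlayer(rcl + ff$wc, ff), 0)
  expect_equal(u_interlayer(rcl + ff$wc + 0.5, ff), 0)
  # LJ branch value at the join equals the cosine branch value
  expect_equal(4 * (rcl^-12 - rcl^-6) + (1 - ff$k_layer), -ff$k_layer,
               tolerance = 1e-12)
})

test_that("spectrin-lipid association follows the printed form exactly", {
  expect_equal(u_spectrin_lipid(c(0.5, 1.5, 3, 10), n = 0, ff = ff),
               rep(0, 4))
  expect_equal(u_spectrin_lipid(2^(1 / 6) * 1.5, n = 0.05, ff = ff), 0)
  expect_equal(u_spectrin_lipid(1.5, n = 0.02, ff = ff), 0.02)
  # the printed +n*eps shift leaves a step at the cutoff (implemented as
  # written, not smoothed)
  step <- u_spectrin_lipid(3.75 - 1e-9, n = 0.05, ff = ff)
  expect_equal(step, 4 * 0.05 * (0.4^12 - 0.4^6) + 0.05, tolerance = 1e-6)
  expect_gt(step, 0.045)
})

test_that("steric contact potential is zero at and beyond its contact distance", {
  req <- 30 / ff$units$sigma_nm
  expect_equal(u_steric(req, req), 0)
  expect_equal(u_steric(req + 1, req), 0)
  expect_gt(u_steric(0.9 * req, req), 0)
})

test_that("analytic forces match finite differences of the energy", {
  ffm <- default_forcefield(n_sl = 0.02)
  errs <- fd_force_errors(mixed_membrane_fixture(ffm), ffm)
  expect_lt(errs$force, 1e-5)
  expect_lt(errs$orient, 1e-5)
  errs2 <- fd_force_errors(skeleton_fixture(ff), skeleton_fixture_ff(),
                           n_probe = 17)
  expect_lt(errs2$force, 1e-5)
})

test_that("pair forces obey Newton's third law on an isolated system", {
  sk <- skeleton_fixture(ff)
  res <- system_forces(sk, skeleton_fixture_ff())
  expect_lt(max(abs(colSums(res$forces))), 1e-10)
})

test_that("engine energy agrees with an independent R-side assembly", {
  # spectrin chain: springs + all-pair repulsion
  set.seed(9)
  ch <- build_spectrin_chain(n_particles = 8, ff = ff)
  ch$pos <- ch$pos + matrix(rnorm(24, sd = 0.3), 8, 3)
  d <- as.matrix(dist(ch$pos))
  bonds <- ch$topology$bonds
  e_r <- sum(u_spring(d[bonds[, 1:2]], ff$k0, 2 * 2^(1 / 6))) +
    sum(u_spectrin_rep(d[upper.tri(d)], ff))
  expect_equal(system_energy(ch, ff), e_r, tolerance = 1e-12)

  # small bilayer: membrane pairs + inter-leaflet pairs with minimum image
  set.seed(10)
  bl <- build_bilayer("slab", lx = 5, ly = 5, ff = ff)
  n <- nrow(bl$pos)
  o <- bl$orient + matrix(runif(3 * n, -0.15, 0.15), n, 3)
  bl$orient <- o / sqrt(rowSums(o^2))
  box <- bl$geometry$box
  e_r <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- bl$pos[i, ] - bl$pos[j, ]
    dx[1:2] <- dx[1:2] - box[1:2] * round(dx[1:2] / box[1:2])
    r <- sqrt(sum(dx^2))
    same <- bl$type[i] == bl$type[j]
    if (same && r < ff$rcut_mem) {
      e_r <- e_r + u_membrane_pair(r, bl$orient[i, ], bl$orient[j, ], dx,
                                   "LL", ff)
    } else if (!same && r < ff$rcut_layer + ff$wc) {
      e_r <- e_r + u_interlayer(r, ff)
    }
  }
  expect_equal(system_energy(bl, ff), e_r, tolerance = 1e-10)
})
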