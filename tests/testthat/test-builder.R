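ff <- default_forcefield()
snm <- ff$units$sigma_nm

test_that("spectrin chain geometry and topology", {
  ch <- build_spectrin_chain(ff = ff)
  expect_equal(nrow(ch$pos), 41)
  expect_equal(nrow(ch$topology$bonds), 40)
  # contour length 200 nm
  contour <- sum(sqrt(rowSums((ch$pos[-1, ] - ch$pos[-41, ])^2))) * snm
  expect_equal(contour, 200, tolerance = 1e-9)
  ch2 <- build_spectrin_chain(n_particles = 2, ff = ff)
  expect_equal(nrow(ch2$topology$bonds), 1)
  expect_equal(sqrt(sum((ch2$pos[2, ] - ch2$pos[1, ])^2)) * snm, 5,
               tolerance = 1e-9)
  expect_error(build_spectrin_chain(n_particles = 1, ff = ff))
})

test_that("actin ring geometry, angles and topology", {
  ring <- build_actin_ring(ff = ff)
  expect_equal(nrow(ring$pos), 39)
  expect_equal(nrow(ring$topology$bonds), 39)
  expect_equal(nrow(ring$topology$angles), 39)
  expect_length(ring$topology$rings, 1)
  # diameter approx 434 nm, edges exactly one particle diameter
  diam <- 2 * mean(sqrt(ring$pos[, 1]^2 + ring$pos[, 2]^2)) * snm
  expect_equal(diam, 434, tolerance = 0.005)
  edges <- sqrt(rowSums((ring$pos[c(2:39, 1), ] - ring$pos)^2)) * snm
  expect_equal(edges, rep(35, 39), tolerance = 1e-9)
  # equilibrium interior angle 170.77 degrees, and the built ring sits at it
  expect_equal(round(unname(ring$topology$angles[1, "theta0"]) * 180 / pi, 2),
               170.77)
  expect_equal(system_energy(ring, ff), 0, tolerance = 1e-8)
  ring6 <- build_actin_ring(6, 1, ff)
  expect_equal(2 * mean(sqrt(ring6$pos[, 1]^2 + ring6$pos[, 2]^2)),
               (1 / snm) / sin(pi / 6), tolerance = 1e-9)
  expect_error(build_actin_ring(2, 35, ff), "at least 3")
})

test_that("periodic skeleton assembly", {
  ap <- build_apms(n_rings = 3, chains_per_ring = 4, ff = ff)
  expect_equal(ap$geometry$kind, "cylinder")
  expect_equal(ap$geometry$box[3] * snm, 555, tolerance = 1e-6)
  expect_length(ap$topology$rings, 3)
  expect_equal(nrow(ap$topology$ring_pairs), 3)  # periodic closure
  expect_equal(length(ap$topology$as_ends), 2 * 3 * 4)
  expect_true(all(ap$topology$as_partner > 0))
  # chain ends sit at their association equilibrium (about 20 nm),
  # including the pairs that wrap through the periodic boundary
  dd <- ap$pos[ap$topology$as_ends, ] - ap$pos[ap$topology$as_partner, ]
  lz <- ap$geometry$box[3]
  dd[, 3] <- dd[, 3] - lz * round(dd[, 3] / lz)
  d <- sqrt(rowSums(dd^2))
  expect_true(all(abs(d * snm - 20) < 1.0))
  # build respects all FENE domains: energies finite, spacing at equilibrium
  expect_true(is.finite(system_energy(ap, ff)))
  zbar <- vapply(ap$topology$rings, function(r) mean(ap$pos[r, 3]), numeric(1))
  expect_equal(diff(zbar) * snm, rep(185, 2), tolerance = 1e-6)
  mini <- build_apms(n_rings = 2, chains_per_ring = 1, ff = ff)
  expect_gt(nrow(mini$topology$bonds), 0)
  expect_length(mini$topology$as_ends, 4)
  expect_error(build_apms(chains_per_ring = 40, ff = ff), "exceed")
})

test_that("bilayer patch: packing density, orientations, geometry", {
  set.seed(1)
  bl <- build_bilayer("slab", lx = 20, ly = 20, ff = ff)
  a <- 2.5 / snm
  area <- prod(bl$geometry$box[1:2])
  expected <- 2 * area / (sqrt(3) / 2 * a^2)
  expect_equal(nrow(bl$pos), expected, tolerance = 0.02)
  expect_equal(sqrt(rowSums(bl$orient^2)), rep(1, nrow(bl$pos)))
  expect_setequal(unique(bl$type), c(1L, 2L))
  # leaflet separation at the inter-layer minimum
  sep <- mean(bl$pos[bl$type == 1, 3]) - mean(bl$pos[bl$type == 2, 3])
  expect_equal(sep, ff$rcut_layer, tolerance = 1e-9)
})

test_that("cylindrical bilayer: radii and radial orientations", {
  set.seed(2)
  cy <- build_bilayer("cylinder", radius_nm = 60, length_nm = 40, ff = ff)
  expect_equal(cy$geometry$kind, "cylinder")
  r_out <- sqrt(cy$pos[cy$type == 1, 1]^2 + cy$pos[cy$type == 1, 2]^2)
  r_in <- sqrt(cy$pos[cy$type == 2, 1]^2 + cy$pos[cy$type == 2, 2]^2)
  expect_gt(min(r_out), max(r_in))   # inner leaflet inside the outer
  expect_equal(mean(r_in) * snm, 60, tolerance = 0.01)
  # orientations point radially outward (outer) and inward (inner)
  xy <- cy$pos[, 1:2] / sqrt(rowSums(cy$pos[, 1:2]^2))
  dots <- rowSums(xy * cy$orient[, 1:2])
  expect_true(all(dots[cy$type == 1] > 0.99))
  expect_true(all(dots[cy$type == 2] < -0.99))
  expect_error(build_bilayer("cylinder", radius_nm = 2, ff = ff), "radius")
})

test_that("protein placement substitutes lipids and is seed-reproducible", {
  set.seed(3)
  bl <- build_bilayer("slab", lx = 14, ly = 14, ff = ff)
  n0 <- nrow(bl$pos)
  set.seed(100)
  s1 <- place_proteins(bl, n_tmp = 3, n_imp_outer = 2, n_imp_inner = 2,
                       ff = ff)
  expect_equal(sum(s1$type == PARTICLE_TYPES[["TMP"]]), 3)
  expect_equal(sum(s1$type == PARTICLE_TYPES[["IMP_outer"]]), 2)
  expect_equal(sum(s1$type == PARTICLE_TYPES[["IMP_inner"]]), 2)
  expect_lt(nrow(s1$pos), n0 + 7)   # lipids were carved out
  set.seed(100)
  s2 <- place_proteins(bl, n_tmp = 3, n_imp_outer = 2, n_imp_inner = 2,
                       ff = ff)
  expect_identical(s1$pos, s2$pos)
  expect_identical(s1$type, s2$type)
  # pprc interface and the no-op case
  expect_identical(place_proteins(bl, ff = ff), bl)
  set.seed(101)
  s3 <- place_proteins(bl, pprc = 3, n_corrals = 1, anchored = TRUE, ff = ff)
  expect_equal(sum(s3$type == PARTICLE_TYPES[["TMP_anchored"]]), 3)
  expect_equal(nrow(s3$topology$tethers), 3)
})

test_that("merged systems re-index their topology", {
  r1 <- build_actin_ring(6, 35, ff)
  ch <- build_spectrin_chain(n_particles = 4, ff = ff,
                             origin = c(30, 0, 5))
  m <- merge_systems(r1, ch)
  expect_equal(nrow(m$pos), 10)
  expect_equal(unname(m$topology$bonds[7, "i"]), 7)  # chain bonds shifted by 6
  expect_equal(unname(m$topology$rings[[1]]), 1:6)
})

test_that("full axon assembly: bilayer clears rings, anchors and channels wired", {
  # reduced fixture: small rings and period, force field scaled to match
  snm2 <- derive_sigma(5)
  ffm <- default_forcefield(overrides = list(
    req_aa = 12 / snm2, deq_rr = 60 / snm2, ddmax = 18 / snm2,
    eff_radius = c(2.5, 2.5, 5, 20, 25, 25, 5, 5, 12) / 2 / snm2))
  set.seed(40)
  ax <- build_axon(n_rings = 2, ring_spacing_nm = 60, chains_per_ring = 4,
                   ring_particles = 9, particle_diameter_nm = 12,
                   chain_particles = 21, chain_spacing_nm = 5,
                   anchors_per_ring = 3, ankyrin = TRUE, ff = ffm)
  tab <- table(type_label(ax$type))
  expect_equal(unname(tab[["actin"]]), 18)
  expect_equal(unname(tab[["spectrin"]]), 8 * 21)
  expect_equal(unname(tab[["actin_anchor_protein"]]), 6)
  expect_equal(unname(tab[["TMP_anchored"]]), 8)
  # inner leaflet clears the rings by the anchor bond length
  r_ring <- max(sqrt(ax$pos[ax$type == 9, 1]^2 + ax$pos[ax$type == 9, 2]^2))
  inner <- ax$type == 2
  expect_gt(min(sqrt(ax$pos[inner, 1]^2 + ax$pos[inner, 2]^2)),
            r_ring + 0.8 * ffm$req_ag)
  # anchoring springs present: one per G protein and per channel
  expect_equal(sum(ax$topology$bonds[, "k"] == ffm$k0 &
                   abs(ax$topology$bonds[, "req"] - ffm$req_ag) < 1e-9), 6)
  expect_equal(sum(abs(ax$topology$bonds[, "req"] - ffm$req_sk) < 1e-9), 8)
  expect_true(is.finite(system_energy(ax, ffm)))
  # the assembly survives a short thermostatted run
  r <- run_md(ax, ffm, n_steps = 200, seed = 40, traj_every = 0,
              thermo_every = 100)
  expect_true(all(is.finite(r$system$pos)))
  norms <- sqrt(rowSums(r$system$orient[ax$type <= 7, ]^2))
  expect_lt(max(abs(norms - 1)), 1e-8)
})
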