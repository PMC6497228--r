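# Shared fixtures: small mixed systems built in code, and a finite-difference
# force checker used by several suites.

# flat patch with one protein of each kind plus a short spectrin chain
# beneath it (exercises every membrane interaction class)
mixed_membrane_fixture <- function(ff, seed = 42) {
  set.seed(seed)
  sys <- build_bilayer("slab", lx = 8, ly = 8, ff = ff)
  sys <- place_proteins(sys, n_tmp = 1, n_imp_outer = 1, n_imp_inner = 1,
                        anchored = TRUE, ff = ff)
  ch <- build_spectrin_chain(n_particles = 5, ff = ff,
                             origin = c(2, 2, -6), axis = c(1, 0, 0))
  sys <- merge_systems(sys, ch)
  n <- nrow(sys$pos)
  sys$pos <- sys$pos + matrix(runif(3 * n, -0.06, 0.06), n, 3)
  mem <- sys$type <= 7
  o <- sys$orient + matrix(runif(3 * n, -0.2, 0.2), n, 3)
  o <- o / sqrt(rowSums(o^2))
  sys$orient[mem, ] <- o[mem, ]
  sys
}

# two small actin rings joined by the ring-spacing term plus a spectrin
# chain with breakable associations (exercises the skeleton terms);
# the matching force field overrides the ring-spacing equilibrium to the
# fixture geometry
skeleton_fixture <- function(ff, seed = 43) {
  set.seed(seed)
  ring1 <- build_actin_ring(6, 35, ff, center = c(0, 0, 0))
  ring2 <- build_actin_ring(6, 35, ff, center = c(0, 0, 30))
  sk <- merge_systems(ring1, ring2)
  sk$topology$ring_pairs <- cbind(a = 1, b = 2, shift = 0)
  ch <- build_spectrin_chain(n_particles = 5, ff = ff,
                             origin = c(14, 0, 5), axis = c(0.2, 0.1, 1))
  sk <- merge_systems(sk, ch)
  sk$topology$as_ends <- c(13L, 17L)
  sk$topology$as_partner <- c(1L, 7L)
  n <- nrow(sk$pos)
  sk$pos <- sk$pos + matrix(runif(3 * n, -0.08, 0.08), n, 3)
  sk
}

skeleton_fixture_ff <- function() {
  default_forcefield(overrides = list(deq_rr = 30, ddmax = 9))
}

# central finite differences of the total energy against analytic forces
# and (projected) orientation gradients; returns worst relative errors
fd_force_errors <- function(sys, ff, n_probe = 20, h = 1e-6) {
  n <- nrow(sys$pos)
  res <- system_forces(sys, ff)
  worst <- 0
  for (i in sample(n, min(n, n_probe))) {
    for (d in 1:3) {
      sp <- sys; sp$pos[i, d] <- sp$pos[i, d] + h
      sm <- sys; sm$pos[i, d] <- sm$pos[i, d] - h
      fd <- -(system_energy(sp, ff) - system_energy(sm, ff)) / (2 * h)
      err <- abs(fd - res$forces[i, d]) / max(1, abs(res$forces[i, d]))
      worst <- max(worst, err)
    }
  }
  worst_o <- 0
  mem <- which(sys$type <= 7)
  for (i in sample(mem, min(length(mem), 8))) {
    nv <- sys$orient[i, ]
    t1 <- c(-nv[2], nv[1], 0)
    if (sum(t1^2) < 1e-6) t1 <- c(0, -nv[3], nv[2])
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(nv[2] * t1[3] - nv[3] * t1[2], nv[3] * t1[1] - nv[1] * t1[3],
            nv[1] * t1[2] - nv[2] * t1[1])
    for (tv in list(t1, t2)) {
      sp <- sys; v <- nv + h * tv; sp$orient[i, ] <- v / sqrt(sum(v^2))
      sm <- sys; v <- nv - h * tv; sm$orient[i, ] <- v / sqrt(sum(v^2))
      fd <- (system_energy(sp, ff) - system_energy(sm, ff)) / (2 * h)
      an <- sum(res$orient_grad[i, ] * tv)
      worst_o <- max(worst_o, abs(fd - an) / max(1, abs(an)))
    }
  }
  list(force = worst, orient = worst_o)
}

# brute-force pair enumeration with minimum image, oracle for the cell list
brute_pairs <- function(pos, geometry, cutoff) {
  n <- nrow(pos)
  out <- matrix(integer(0), 0, 2)
  for (i in seq_len(n - 1)) {
    d <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    for (dim in 1:3)
      if (periodic <- axonmem:::periodic_dim(geometry$kind, dim)) {
        bx <- geometry$box[dim]
        d[, dim] <- d[, dim] - bx * round(d[, dim] / bx)
      }
    hit <- which(sqrt(rowSums(d^2)) < cutoff)
    if (length(hit))
      out <- rbind(out, cbind(i, i + hit))
  }
  out
}

sort_pairs <- function(m) {
  if (nrow(m) == 0) return(m)
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}
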