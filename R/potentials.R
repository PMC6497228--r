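# Energy terms of the model, as directly evaluable R functions.
# These mirror the kernels inside the compiled engine and are used for
# inspection, plotting and cross-checking; the engine re-implements them in
# C++ for speed.

lj_shifted <- function(r, eps, scale, shift, rcut) {
  u <- numeric(length(r))
  inside <- r < rcut
  sr6 <- (scale / r[inside])^6
  u[inside] <- 4 * eps * (sr6^2 - sr6) + shift
  u
}

#' Spectrin-spectrin steric repulsion
#'
#' Truncated, shifted Lennard-Jones potential of scale \code{2*sigma},
#' cut at its minimum \code{2*2^(1/6)*sigma} (the equilibrium bead spacing)
#' so only the repulsive branch survives.
#'
#' @param r pair distance(s), sigma units.
#' @param ff a [default_forcefield()].
#' @return energy in eps.
#' @export
u_spectrin_rep <- function(r, ff = default_forcefield()) {
  if (any(r <= 0)) stop("pair distance must be positive")
  lj_shifted(r, ff$eps1, 2, ff$eps1, ff$req_ss)
}

#' Harmonic spring potential
#'
#' \code{U = k/2 (r - req)^2}; used for the spectrin backbone, the actin
#' ring backbone, and all anchoring bonds.
#'
#' @param r distance(s).
#' @param k spring constant (eps/sigma^2).
#' @param req equilibrium length (sigma).
#' @export
u_spring <- function(r, k, req) {
  if (k < 0) stop("spring constant must be non-negative")
  0.5 * k * (r - req)^2
}

#' Breakable actin-spectrin association potential
#'
#' Shifted Lennard-Jones of scale \code{8*sigma} (minimum at
#' \code{2^(1/6)*8*sigma}, about 20 nm) and well depth \code{eps2},
#' truncated at the capture distance \code{2.5*8*sigma}: beyond it the
#' association is broken and both energy and force are zero, so bonds can
#' break and reform during dynamics.
#'
#' @inheritParams u_spectrin_rep
#' @return list with \code{energy} and logical \code{broken} per distance.
#' @export
u_breakable_as <- function(r, ff = default_forcefield()) {
  if (any(r <= 0)) stop("pair distance must be positive")
  list(energy = lj_shifted(r, ff$eps2, ff$scale_as, ff$eps2, ff$capture_as),
       broken = r > ff$capture_as)
}

fene <- function(x, k, x0, dmax) {
  q <- (x - x0) / dmax
  if (any(abs(q) >= 1))
    stop("FENE argument out of domain (|deviation| >= maximum)")
  -0.5 * k * dmax * log(1 - q^2)
}

#' FENE bending potential of the actin ring
#'
#' \code{U = -kb*dthmax/2 * log(1 - ((theta-theta0)/dthmax)^2)} with the
#' equilibrium interior angle of the 39-particle ring,
#' \code{theta0 = 180 * 37/39 deg = 170.77 deg}, and
#' \code{dthmax = 0.3*theta0}. Diverges at the domain bounds; an angle at
#' or beyond them signals an over-bent ring and is an error.
#'
#' @param theta angle(s) in radians.
#' @inheritParams u_spectrin_rep
#' @export
u_fene_bend <- function(theta, ff = default_forcefield()) {
  fene(theta, ff$kb, ff$theta0, ff$dthmax)
}

#' FENE ring-spacing potential (microtubule surrogate)
#'
#' Keeps the mean axial distance between two consecutive actin rings near
#' 185 nm, standing in for the microtubule/neurofilament core that the
#' model does not represent explicitly. The ring coordinate is the mean
#' axial position of the particles of each ring.
#'
#' @param d ring-centre spacing(s), sigma units.
#' @inheritParams u_spectrin_rep
#' @export
u_fene_ring_spacing <- function(d, ff = default_forcefield()) {
  fene(d, ff$kmt, ff$deq_rr, ff$ddmax)
}

#' Orientation factor of the membrane pair potential
#'
#' \code{a = (ni x xhat) . (nj x xhat) = ni.nj - (ni.xhat)(nj.xhat)},
#' ranging from -1 (anti-parallel normals, both perpendicular to the pair
#' axis) to +1 (parallel normals perpendicular to the pair axis), and the
#' linear amplification \code{A = 1 + alpha*(a - 1)} applied to the
#' attractive branch.
#'
#' @param n_i,n_j unit orientation vectors (length 3).
#' @param x_ij displacement vector from particle j to particle i.
#' @param alpha amplification factor.
#' @return list with \code{a} and \code{A}.
#' @export
orientation_factor <- function(n_i, n_j, x_ij, alpha = 1.55) {
  r <- sqrt(sum(x_ij^2))
  if (r < 1e-12) stop("zero displacement vector")
  for (v in list(n_i, n_j))
    if (abs(sqrt(sum(v^2)) - 1) > 1e-8) stop("orientations must be unit vectors")
  xh <- x_ij / r
  a <- sum(n_i * n_j) - sum(n_i * xh) * sum(n_j * xh)
  list(a = a, A = 1 + alpha * (a - 1))
}

#' Orientation-dependent membrane pair potential
#'
#' \code{u = uR + A*uA} with
#' \code{uR = k*eps*((Rc - r)/(Rc - req))^8} and
#' \code{uA = -2*k*eps*((Rc - r)/(Rc - req))^4} inside the cutoff
#' \code{Rc = 2.6 sigma}, zero at and beyond it. With aligned normals
#' perpendicular to the pair axis (\code{A = 1}) the minimum sits at
#' \code{req} with depth \code{-k*eps}.
#'
#' @param r pair distance(s), sigma units.
#' @param n_i,n_j unit orientation vectors.
#' @param x_ij displacement vector from j to i (its norm is ignored; use
#'   \code{r} for the distance so that \code{r} can be vectorised).
#' @param pair_class one of \code{"LL"}, \code{"LG"}, \code{"LP"},
#'   \code{"PP"}, \code{"GP"}, \code{"GG"}.
#' @inheritParams u_spectrin_rep
#' @export
u_membrane_pair <- function(r, n_i, n_j, x_ij, pair_class = "LL",
                            ff = default_forcefield()) {
  if (any(r <= 0)) stop("pair distance must be positive")
  par <- membrane_class_params(pair_class, ff)
  ofac <- orientation_factor(n_i, n_j, x_ij, ff$alpha)
  z <- (ff$rcut_mem - r) / (ff$rcut_mem - par$req)
  u <- ifelse(r < ff$rcut_mem, par$k * z^8 - ofac$A * 2 * par$k * z^4, 0)
  u
}

membrane_class_params <- function(pair_class, ff) {
  switch(pair_class,
         LL = list(k = ff$k_ll, req = ff$req_ll),
         LG = list(k = ff$k_lprot, req = ff$req_lg),
         LP = list(k = ff$k_lprot, req = ff$req_lp),
         PP = list(k = ff$k_lprot, req = ff$req_pp),
         GP = list(k = ff$k_lprot, req = ff$req_pp),
         GG = list(k = ff$k_lprot, req = ff$req_pp),
         stop("unknown membrane pair class '", pair_class, "'"))
}

#' Inter-leaflet cohesion potential
#'
#' Piecewise potential joining a repulsive Lennard-Jones core (shifted by
#' \code{(1-k)*eps}) to a compliant \code{cos^2} attraction of depth
#' \code{k*eps} over a width \code{wc}, after the solvent-free bilayer
#' model of Cooke and co-workers. With the inner cutoff at the LJ minimum
#' \code{2^(1/6) sigma} the two branches join continuously with zero slope,
#' so the potential has its (smooth) minimum of \code{-k*eps} exactly there.
#'
#' @inheritParams u_spectrin_rep
#' @export
u_interlayer <- function(r, ff = default_forcefield()) {
  if (any(r <= 0)) stop("pair distance must be positive")
  rcl <- ff$rcut_layer
  u <- numeric(length(r))
  core <- r < rcl
  u[core] <- lj_shifted(r[core], 1, 1, 1 - ff$k_layer, rcl)
  tail <- r >= rcl & r <= rcl + ff$wc
  u[tail] <- -ff$k_layer * cos(pi * (r[tail] - rcl) / (2 * ff$wc))^2
  u
}

#' Spectrin-lipid association potential
#'
#' Shifted Lennard-Jones of scale \code{1.5 sigma} and strength \code{n}
#' (the spectrin-lipid association parameter), truncated at
#' \code{3.75 sigma} exactly as specified, including the \code{+n*eps}
#' shift; identically zero when \code{n = 0}. The shift leaves a small
#' (\code{~0.98*n*eps}) step at the cutoff; the potential is implemented
#' as written rather than smoothed.
#'
#' @inheritParams u_spectrin_rep
#' @param n association strength; overrides the force field's \code{n_sl}
#'   when given.
#' @export
u_spectrin_lipid <- function(r, n = NULL, ff = default_forcefield()) {
  n <- if (is.null(n)) ff$n_sl else n
  if (n < 0) stop("association strength n must be >= 0")
  if (n == 0) return(numeric(length(r)))
  if (any(r <= 0)) stop("pair distance must be positive")
  lj_shifted(r, n, ff$scale_sl, n, ff$rcut_sl)
}

#' Steric (truncated-LJ) repulsion between proteins and the skeleton
#'
#' Purely repulsive contact potential used between the cytosolic domains of
#' membrane proteins and skeleton particles, and between actin particles:
#' the truncated-and-shifted Lennard-Jones form cut at the contact distance
#' \code{req} (the sum of the effective radii of the two particles), where
#' it is zero with zero slope.
#'
#' @param r pair distance(s), sigma units.
#' @param req contact distance, sigma units.
#' @param eps repulsion strength, eps units.
#' @export
u_steric <- function(r, req, eps = 0.46) {
  if (any(r <= 0)) stop("pair distance must be positive")
  lj_shifted(r, eps, req / 2^(1 / 6), eps, req)
}

#' Forces, orientation gradients and total energy of a system
#'
#' Assembles the full potential (all bonded and non-bonded terms) and
#' returns the analytic forces, the orientation gradients \code{dV/dn}
#' entering the constrained rotational equation of motion, and the total
#' potential energy. Mostly useful for testing and for single-point
#' evaluations; [run_md()] performs the same assembly internally.
#'
#' @param system a [particle_system()].
#' @param ff a [default_forcefield()].
#' @return list with \code{forces} (n x 3), \code{orient_grad} (n x 3),
#'   \code{energy} (eps) and the current actin-spectrin partner map.
#' @export
system_forces <- function(system, ff = default_forcefield()) {
  stopifnot(inherits(system, "particle_system"))
  cpp_forces(system$pos, orient_or_zero(system), system$type,
             system$geometry[c("kind", "box")], ff_for_cpp(ff),
             topo_for_cpp(system))
}

#' Total potential energy of a system
#'
#' @inheritParams system_forces
#' @return energy in eps.
#' @export
system_energy <- function(system, ff = default_forcefield()) {
  system_forces(system, ff)$energy
}
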