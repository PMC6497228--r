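# Force-field parameter set. All interaction parameters are stored in
# reduced units (sigma = 1, eps = 1); nanometre inputs are converted with
# the sigma of the attached unit system.

#' Default force field of the axon membrane model
#'
#' Assembles every interaction parameter of the model in reduced units:
#' the spectrin chain (harmonic springs plus truncated-LJ repulsion), the
#' actin ring (springs, steric repulsion, FENE bending), the breakable
#' actin-spectrin association, the FENE ring-spacing term standing in for
#' microtubules, the orientation-dependent membrane pair potential, the
#' inter-leaflet cohesion, the tunable spectrin-lipid attraction, anchoring
#' springs, and the effective sizes used for protein-skeleton sterics.
#'
#' @param units a [unit_system()]; supplies sigma (nm) and the reduced
#'   temperature used to express energies given in kB*T.
#' @param n_sl spectrin-lipid association strength \code{n} (0, 0.02, 0.05
#'   are the standard choices; 0 disables the interaction).
#' @param overrides named list of parameter overrides applied after
#'   construction (reduced units), e.g. \code{list(k_ll = 1.3)}.
#' @return an object of class \code{forcefield}: a named list of reduced
#'   parameters plus the unit system used to build it.
#' @export
default_forcefield <- function(units = unit_system(), n_sl = 0,
                               overrides = list()) {
  s <- units$sigma_nm          # nm per sigma
  kT <- units$epsilon_rel_temp # kB*T in eps
  nm <- function(x) x / s
  ff <- list(
    # spectrin chain
    k0 = 6.5, req_ss = 2 * 2^(1 / 6), eps1 = 0.46,
    # actin ring
    kA = 69.35, req_aa = nm(35),
    kb = 3500 * kT, theta0 = pi * 37 / 39, dthmax = 0.3 * pi * 37 / 39,
    # breakable actin-spectrin association
    eps2 = 7.3, scale_as = 8, capture_as = 2.5 * 8,
    # ring-spacing FENE (microtubule surrogate)
    kmt = 239 * kT, deq_rr = nm(185), ddmax = 0.3 * nm(185),
    # orientation-dependent membrane pair
    rcut_mem = 2.6, alpha = 1.55, k_ll = 1.2, k_lprot = 2.8,
    req_ll = nm(2.5), req_lg = nm(3.75), req_lp = nm(3.75), req_pp = nm(5),
    # inter-leaflet cohesion
    k_layer = 0.01, wc = 1.3775, rcut_layer = 2^(1 / 6),
    # spectrin-lipid association
    n_sl = n_sl, scale_sl = 1.5, rcut_sl = 3.75,
    # anchors
    req_sk = nm(15), req_ag = nm(20),
    # steric effective radii by particle type code (sigma units)
    eps_steric = 0.46,
    eff_radius = nm(c(2.5, 2.5, 5, 20, 25, 25, 5, 5, 35) / 2),
    # neighbour-list skin
    skin = 0.4
  )
  for (nmv in names(overrides)) {
    if (!nmv %in% names(ff)) stop("unknown force-field parameter: ", nmv)
    ff[[nmv]] <- overrides[[nmv]]
  }
  ff$units <- units
  class(ff) <- "forcefield"
  validate_forcefield(ff)
  ff
}

#' Validate a force field
#'
#' Checks positivity of lengths and stiffnesses and the structural
#' relations the model relies on (association energy above the chain
#' repulsion scale, capture radius beyond the association minimum,
#' continuity of the inter-leaflet potential).
#'
#' @param ff a \code{forcefield}.
#' @return the force field, invisibly; errors on violation.
#' @export
validate_forcefield <- function(ff) {
  lengths <- c("req_ss", "req_aa", "req_ll", "req_lg", "req_lp", "req_pp",
               "deq_rr", "req_sk", "req_ag", "rcut_mem", "rcut_layer",
               "wc", "scale_as", "capture_as", "scale_sl", "rcut_sl")
  for (nm in lengths)
    if (ff[[nm]] <= 0) stop("force-field length parameter '", nm,
                            "' must be positive")
  for (nm in c("k0", "kA", "kb", "kmt", "k_ll", "k_lprot", "eps1", "eps2"))
    if (ff[[nm]] <= 0) stop("force-field stiffness/energy '", nm,
                            "' must be positive")
  if (ff$n_sl < 0) stop("spectrin-lipid strength n must be >= 0")
  if (ff$eps2 <= ff$eps1)
    stop("actin-spectrin association energy must exceed the chain repulsion")
  if (ff$capture_as <= 2^(1 / 6) * ff$scale_as)
    stop("capture distance must lie beyond the association minimum")
  if (any(ff$eff_radius <= 0)) stop("effective radii must be positive")
  for (nm in c("dthmax", "ddmax", "skin"))
    if (ff[[nm]] <= 0) stop("'", nm, "' must be positive")
  invisible(ff)
}

#' @export
print.forcefield <- function(x, ...) {
  cat("axonmem force field (reduced units, sigma =",
      format(x$units$sigma_nm, digits = 5), "nm)\n")
  cat(sprintf("  chain:     k0 = %.3g, req = %.4g, eps1 = %.3g\n",
              x$k0, x$req_ss, x$eps1))
  cat(sprintf("  ring:      kA = %.4g, req = %.4g, kb = %.4g, theta0 = %.2f deg\n",
              x$kA, x$req_aa, x$kb, x$theta0 * 180 / pi))
  cat(sprintf("  assoc:     eps2 = %.3g, scale = %.3g, capture = %.3g\n",
              x$eps2, x$scale_as, x$capture_as))
  cat(sprintf("  membrane:  rcut = %.3g, alpha = %.3g, k = %.3g/%.3g\n",
              x$rcut_mem, x$alpha, x$k_ll, x$k_lprot))
  cat(sprintf("  interlayer: k = %.3g, wc = %.4g; spectrin-lipid n = %.3g\n",
              x$k_layer, x$wc, x$n_sl))
  invisible(x)
}

# strip non-numeric components before handing to the C++ kernels
ff_for_cpp <- function(ff) {
  ff[setdiff(names(ff), "units")]
}
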