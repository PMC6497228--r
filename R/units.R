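# Reduced-unit system and closed-form calibrations.

#' Boltzmann constant in eV/K (CODATA)
#' @keywords internal
KB_EV <- 8.617333e-5
#' Boltzmann constant in J/K (CODATA)
#' @keywords internal
KB_SI <- 1.380649e-23

#' Reduced unit system of the membrane model
#'
#' The model works in reduced units: length \code{sigma}, energy \code{eps}
#' with \code{kB*T/eps} fixed at the simulation temperature, and time
#' \code{t_s = sqrt(m sigma^2 / eps)}. The physical value of \code{t_s} is
#' obtained a posteriori by matching the simulated lipid self-diffusion
#' coefficient to an experimental one (see [calibrate_timescale()]).
#'
#' @param sigma_nm length unit in nanometres (default from the 5 nm
#'   spectrin bead spacing, see [derive_sigma()]).
#' @param kBT_over_eps dimensionless simulation temperature.
#' @param temperature_K absolute temperature used for energy conversions.
#' @param dt_in_ts integration time step in units of \code{t_s}.
#' @param d_sim,d_exp_um2s lipid diffusivity in sigma^2/t_s and um^2/s used
#'   to calibrate the physical time scale; set either to \code{NA} to leave
#'   \code{t_s_seconds} uncalibrated.
#' @return an object of class \code{unit_system}.
#' @export
unit_system <- function(sigma_nm = derive_sigma(5),
                        kBT_over_eps = 0.22,
                        temperature_K = 300,
                        dt_in_ts = 0.01,
                        d_sim = 1.14e-2, d_exp_um2s = 0.3) {
  stopifnot(sigma_nm > 0, kBT_over_eps > 0, temperature_K > 0, dt_in_ts > 0)
  ts <- if (is.na(d_sim) || is.na(d_exp_um2s)) NA_real_ else
    calibrate_timescale(d_sim, d_exp_um2s, sigma_nm)
  structure(list(sigma_nm = sigma_nm,
                 epsilon_rel_temp = kBT_over_eps,
                 temperature_K = temperature_K,
                 t_s_seconds = ts,
                 dt_in_ts = dt_in_ts,
                 epsilon_eV = KB_EV * temperature_K / kBT_over_eps),
            class = "unit_system")
}

#' @export
print.unit_system <- function(x, ...) {
  cat("Reduced unit system:\n")
  cat(sprintf("  sigma   = %.4f nm\n", x$sigma_nm))
  cat(sprintf("  eps     = %.4f eV  (kB*T/eps = %.2f at T = %g K)\n",
              x$epsilon_eV, x$epsilon_rel_temp, x$temperature_K))
  cat(sprintf("  t_s     = %s s\n",
              if (is.na(x$t_s_seconds)) "<uncalibrated>" else
                format(x$t_s_seconds, digits = 4)))
  cat(sprintf("  dt      = %g t_s\n", x$dt_in_ts))
  invisible(x)
}

#' Length unit from the spectrin bead spacing
#'
#' The spectrin-spectrin repulsion is a truncated Lennard-Jones potential of
#' scale \code{2*sigma} whose minimum, \code{2*2^(1/6)*sigma}, is identified
#' with the equilibrium bead spacing. Inverting gives the length unit:
#' a 5 nm spacing yields \code{sigma = 2.227 nm}.
#'
#' @param equilibrium_spacing_nm equilibrium spectrin bead spacing in nm.
#' @return sigma in nm.
#' @export
derive_sigma <- function(equilibrium_spacing_nm) {
  if (!is.numeric(equilibrium_spacing_nm) || any(equilibrium_spacing_nm <= 0))
    stop("equilibrium spacing must be positive")
  equilibrium_spacing_nm / (2 * 2^(1 / 6))
}

#' Persistence length of a flexible filament
#'
#' Uses the flexible-filament relation \code{<ree^2> ~= 2 * lp * Lc}, valid
#' when the persistence length is much smaller than the contour length.
#'
#' @param ree_rms root-mean-square end-to-end distance (any length unit).
#' @param contour_length contour length (same unit).
#' @return persistence length in the same unit.
#' @export
persistence_length <- function(ree_rms, contour_length) {
  if (!is.numeric(contour_length) || any(contour_length <= 0))
    stop("contour length must be positive")
  if (any(ree_rms < 0)) stop("ree_rms must be non-negative")
  ree_rms^2 / (2 * contour_length)
}

#' Physical time unit from diffusivity matching
#'
#' Matches a simulated diffusion coefficient in reduced units
#' (\code{sigma^2/t_s}) with an experimental one in um^2/s and solves for
#' the time unit: \code{t_s = D_sim * sigma^2 / D_exp}.
#'
#' @param d_sim simulated diffusivity in sigma^2/t_s.
#' @param d_exp_um2s experimental diffusivity in um^2/s.
#' @param sigma_nm length unit in nm.
#' @return t_s in seconds.
#' @export
calibrate_timescale <- function(d_sim, d_exp_um2s, sigma_nm) {
  if (any(c(d_sim, d_exp_um2s, sigma_nm) <= 0))
    stop("all arguments must be positive")
  sigma_um <- sigma_nm * 1e-3
  d_sim * sigma_um^2 / d_exp_um2s
}

#' Membrane viscosity by the Stokes-Einstein relation
#'
#' \code{eta = kB*T / (6*pi*D*r)} with the lipid-particle radius as the
#' hydrodynamic radius.
#'
#' @param temperature_K absolute temperature in K.
#' @param d_um2s diffusivity in um^2/s.
#' @param particle_radius_nm particle radius in nm.
#' @return viscosity in N s/m^2.
#' @export
stokes_einstein_viscosity <- function(temperature_K, d_um2s, particle_radius_nm) {
  if (any(c(temperature_K, d_um2s, particle_radius_nm) <= 0))
    stop("all arguments must be positive")
  KB_SI * temperature_K / (6 * pi * (d_um2s * 1e-12) * (particle_radius_nm * 1e-9))
}

#' Convert a multiple of the energy unit to electron-volts
#'
#' The energy unit is fixed by the simulation temperature:
#' \code{eps = kB*T_K / (kB*T/eps)}. At 300 K and a reduced temperature of
#' 0.22 one eps is about 0.118 eV, so e.g. the actin-spectrin association
#' energy 7.3 eps is about 0.86 eV.
#'
#' @param multiple_of_epsilon dimensionless energy in eps units.
#' @param units a [unit_system()].
#' @return energy in eV.
#' @export
energy_in_ev <- function(multiple_of_epsilon, units = unit_system()) {
  multiple_of_epsilon * units$epsilon_eV
}

#' Transmembrane-protein surface density to area coverage
#'
#' Converts a protein count per skeleton corral (pprc) to a percent surface
#' area coverage, \code{100 * pprc * pi * (d/2)^2 / A}. The default corral
#' area is calibrated so that one 5-nm protein per corral covers 0.29133%
#' of the corral, which reproduces the standard coverage ladder
#' (3, 20, 45, 60, 90 pprc -> 0.87, 5.83, 13.11, 17.48, 26.22%).
#'
#' @param pprc proteins per rectangular corral.
#' @param protein_diameter_nm in-membrane protein diameter in nm.
#' @param corral_area_nm2 corral area in nm^2.
#' @return coverage in percent.
#' @export
density_to_coverage <- function(pprc, protein_diameter_nm = 5,
                                corral_area_nm2 = 6739.67) {
  if (corral_area_nm2 <= 0) stop("corral area must be positive")
  if (any(pprc < 0) || protein_diameter_nm <= 0)
    stop("pprc and protein diameter must be non-negative/positive")
  100 * pprc * pi * (protein_diameter_nm / 2)^2 / corral_area_nm2
}
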