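# Time integration and neighbour-list plumbing around the compiled engine.

#' Run molecular dynamics
#'
#' Integrates the equations of motion with the Beeman algorithm:
#' translational motion \code{m x'' = -dV/dx} and, for membrane particles,
#' the constrained rotational equation
#' \code{m~ n'' = -dV/dn + (dV/dn . n) n - m~ (n'.n') n}, which confines
#' the orientation vectors to the unit sphere. Internally the rotational
#' state is carried as the angular velocity \code{omega = n x n'} (whose
#' equation of motion, \code{m~ domega/dt = n x (-dV/dn)}, is equivalent)
#' and orientations advance by exact rotations, so \code{|n| = 1} holds to
#' machine precision throughout. Temperature is held by a Nose-Hoover
#' chain thermostat (length 2) at the reduced target \code{kB*T/eps}; with
#' \code{ensemble = "nve"} the thermostat is off and total energy should be
#' conserved. Runs are bit-reproducible for a fixed seed in single-threaded
#' R.
#'
#' @param system a [particle_system()].
#' @param ff a [default_forcefield()].
#' @param n_steps number of time steps.
#' @param dt time step in t_s units.
#' @param ensemble \code{"nvt"} (Nose-Hoover) or \code{"nve"}.
#' @param temperature reduced target temperature kB*T/eps.
#' @param seed RNG seed for the initial Maxwell-Boltzmann velocities
#'   (ignored when \code{velocities} are supplied).
#' @param velocities optional list with \code{vel} and \code{avel}
#'   (n x 3 each) to continue a previous run.
#' @param traj_every record a trajectory frame every this many steps
#'   (0 = no trajectory).
#' @param thermo_every record thermodynamic output every this many steps.
#' @param record_orient also store orientation frames.
#' @param tau_t thermostat time constant in t_s; the Nose-Hoover chain
#'   masses are \code{Q1 = N_f*T*tau_t^2} and \code{Q2 = T*tau_t^2}.
#' @param thermo_rot include rotational degrees of freedom in the
#'   thermostat.
#' @param zero_com_every while thermostatting, remove the rigid-body zero
#'   modes (centre-of-mass drift; rigid rotation in free geometry; axial
#'   rotation on a cylinder) every this many steps, so the thermostat
#'   cannot pump kinetic energy into them (0 disables; ignored in NVE).
#' @return list with the advanced \code{system}, the \code{trajectory}
#'   (class \code{md_trajectory}), a \code{thermo} data frame (kinetic
#'   temperature, potential and total energy, thermostat variable, broken
#'   actin-spectrin bond count), final \code{velocities}, and
#'   \code{n_breaks}.
#' @export
run_md <- function(system, ff = default_forcefield(), n_steps,
                   dt = 0.01, ensemble = c("nvt", "nve"),
                   temperature = 0.22, seed = NULL, velocities = NULL,
                   traj_every = 100, thermo_every = 100,
                   record_orient = FALSE, tau_t = 1,
                   thermo_rot = TRUE, zero_com_every = 100) {
  stopifnot(inherits(system, "particle_system"), n_steps >= 0, dt > 0)
  ensemble <- match.arg(ensemble)
  n <- nrow(system$pos)
  if (n_steps == 0) {
    traj <- new_trajectory(list(), numeric(0), integer(0), system, NULL)
    return(list(system = system, trajectory = traj,
                thermo = empty_thermo(), velocities = velocities,
                n_breaks = 0))
  }
  if (is.null(velocities)) {
    if (!is.null(seed)) set.seed(seed)
    vel <- matrix(stats::rnorm(3 * n, sd = sqrt(temperature)), n, 3)
    vel <- sweep(vel, 2, colMeans(vel))  # zero centre-of-mass drift
    avel <- matrix(stats::rnorm(3 * n, sd = sqrt(temperature)), n, 3)
    mem <- is_membrane_type(system$type)
    # tangential projection: two rotational degrees of freedom per particle
    dotp <- rowSums(avel * system$orient)
    avel <- avel - dotp * system$orient
    avel[!mem, ] <- 0
  } else {
    vel <- velocities$vel
    avel <- velocities$avel
  }
  res <- cpp_md_run(system$pos, orient_or_zero(system), system$type,
                    vel, avel,
                    system$geometry[c("kind", "box")], ff_for_cpp(ff),
                    topo_for_cpp(system),
                    as.integer(n_steps), dt, ensemble == "nvt", temperature,
                    tau_t, thermo_rot,
                    as.integer(thermo_every), as.integer(traj_every),
                    record_orient, as.integer(zero_com_every))
  out <- system
  out$pos <- res$pos
  out$orient <- res$orient
  out$topology$as_partner <- as.integer(res$as_partner)
  thermo <- as.data.frame(res$thermo)
  traj <- new_trajectory(res$frames, res$frame_time, res$frame_step, out,
                         if (record_orient) res$orient_frames else NULL)
  list(system = out, trajectory = traj, thermo = thermo,
       velocities = list(vel = res$vel, avel = res$avel),
       n_breaks = res$n_breaks)
}

empty_thermo <- function() {
  as.data.frame(matrix(numeric(0), 0, 8, dimnames = list(NULL,
    c("step", "time", "temp_trans", "ke_rot_per_particle", "potential",
      "total_energy", "xi", "n_breaks"))))
}

new_trajectory <- function(frames, times, steps, system, orient_frames) {
  structure(list(times = times, steps = steps, frames = frames,
                 orient_frames = orient_frames,
                 type = system$type, geometry = system$geometry,
                 sigma_nm = system$sigma_nm),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d particles, geometry %s\n",
              length(x$frames), length(x$type), x$geometry$kind))
  if (length(x$times))
    cat(sprintf("  time range %g .. %g t_s\n", min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an \code{md_trajectory}.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Enumerate particle pairs within a cutoff
#'
#' Cell-list pair enumeration honouring the periodic directions of the
#' geometry; used internally for neighbour lists and exposed for
#' verification against a brute-force enumeration.
#'
#' @param pos n x 3 position matrix (sigma units) or a
#'   \code{particle_system}.
#' @param geometry geometry record (taken from the system if one is given).
#' @param cutoff pair distance cutoff (sigma).
#' @return two-column matrix of 1-based index pairs (i < j).
#' @export
neighbor_pairs <- function(pos, geometry = NULL, cutoff) {
  if (inherits(pos, "particle_system")) {
    geometry <- pos$geometry
    pos <- pos$pos
  }
  if (is.null(geometry)) geometry <- list(kind = "free", box = c(0, 0, 0))
  if (nrow(pos) < 2)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  m <- cpp_neighbor_pairs(pos, geometry[c("kind", "box")], cutoff)
  colnames(m) <- c("i", "j")
  m
}
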