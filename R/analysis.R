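# Trajectory post-processing: cylindrical unwrapping, directional MSDs,
# diffusion-model fitting and residual-norm model selection.

#' Unwrap a cylindrical trajectory onto the plane
#'
#' Distances on a cylindrical surface are preserved when the cylinder is
#' rolled onto a plane, so surface diffusion can be analysed in planar
#' coordinates \code{u = r*theta} (transverse, along the circumference) and
#' \code{v = z} (longitudinal, along the axis). The angular coordinate is
#' unwrapped across the +/-pi seam frame by frame and the axial coordinate
#' across the periodic box; radial displacements are discarded, which is
#' valid while radial fluctuations stay small against the radius (a
#' warning is issued beyond 5%).
#'
#' @param traj an \code{md_trajectory} with cylinder geometry, or any
#'   trajectory whose geometry is a flat patch (then \code{u = x},
#'   \code{v = y} and no unwrapping is needed).
#' @param particles optional particle index filter.
#' @return object of class \code{planar_tracks}: matrices \code{u},
#'   \code{v} (frames x particles), frame times, particle types.
#' @export
unwrap_cylinder <- function(traj, particles = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  if (nf < 1) stop("empty trajectory")
  idx <- if (is.null(particles)) seq_along(traj$type) else particles
  get <- function(f, col) traj$frames[[f]][idx, col]
  if (traj$geometry$kind != "cylinder") {
    u <- do.call(rbind, lapply(seq_len(nf), function(f) get(f, 1)))
    v <- do.call(rbind, lapply(seq_len(nf), function(f) get(f, 2)))
    return(planar_tracks(u, v, traj$times, traj$type[idx]))
  }
  x <- do.call(rbind, lapply(seq_len(nf), function(f) get(f, 1)))
  y <- do.call(rbind, lapply(seq_len(nf), function(f) get(f, 2)))
  z <- do.call(rbind, lapply(seq_len(nf), function(f) get(f, 3)))
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  if (nf > 1) {
    dth <- theta[-1, , drop = FALSE] - theta[-nf, , drop = FALSE]
    dth <- dth - 2 * pi * round(dth / (2 * pi))
    if (any(abs(dth) >= pi - 1e-9))
      stop("angular step of half a turn or more between frames; ",
           "trajectory too sparsely sampled to unwrap")
    theta <- rbind(theta[1, ], theta[rep(1, nf - 1), , drop = FALSE] +
                     apply(dth, 2, cumsum))
    lz <- traj$geometry$box[3]
    if (lz > 0) {
      dz <- z[-1, , drop = FALSE] - z[-nf, , drop = FALSE]
      dz <- dz - lz * round(dz / lz)
      z <- rbind(z[1, ], z[rep(1, nf - 1), , drop = FALSE] +
                   apply(dz, 2, cumsum))
    }
  }
  rbar <- colMeans(r)
  rad_fluct <- sqrt(colMeans(sweep(r, 2, rbar)^2)) / rbar
  if (any(rad_fluct > 0.05))
    warning("radial fluctuations exceed 5% of the radius for ",
            sum(rad_fluct > 0.05), " particle(s); the planar unwrap ",
            "approximation degrades")
  u <- sweep(theta, 2, rbar, "*")
  planar_tracks(u, v = z, traj$times, traj$type[idx], radius = mean(rbar))
}

planar_tracks <- function(u, v, times, type, radius = NA_real_) {
  structure(list(u = u, v = v, times = times, type = type, radius = radius),
            class = "planar_tracks")
}

#' @export
print.planar_tracks <- function(x, ...) {
  cat(sprintf("planar_tracks: %d frames x %d particles\n",
              nrow(x$u), ncol(x$u)))
  invisible(x)
}

#' Time-and-ensemble averaged mean squared displacement
#'
#' Averages squared displacements over all window start times
#' (overlapping origins) and all selected particles, per lag. The
#' transverse component uses the circumferential coordinate \code{u}, the
#' longitudinal component the axial coordinate \code{v}; the planar 2D MSD
#' is their sum.
#'
#' @param tracks a \code{planar_tracks} object.
#' @param component \code{"planar_2D"}, \code{"longitudinal"} or
#'   \code{"transverse"}.
#' @param particles optional column filter (by particle type code via
#'   \code{types}, or indices via \code{particles}).
#' @param types optional particle type filter (codes or names).
#' @param n_lags number of lag values (log-spaced by default).
#' @param max_lag_frames largest lag in frames (default: half the
#'   trajectory).
#' @param spacing \code{"log"} or \code{"linear"} lag grid.
#' @param drift collective-drift correction applied before computing
#'   displacements: \code{"none"}, \code{"com"} (subtract the per-frame
#'   centre of mass of the selected particles) or \code{"per_type"}
#'   (subtract it separately for each particle type, e.g. per leaflet --
#'   the standard correction when leaflets can slide as a whole).
#' @return data frame of class \code{msd_curve} with columns \code{lag}
#'   (t_s), \code{msd} (sigma^2) and \code{n} (displacement samples).
#' @export
msd <- function(tracks, component = c("planar_2D", "longitudinal",
                                      "transverse"),
                particles = NULL, types = NULL, n_lags = 50,
                max_lag_frames = NULL, spacing = c("log", "linear"),
                drift = c("none", "com", "per_type")) {
  stopifnot(inherits(tracks, "planar_tracks"))
  component <- match.arg(component)
  spacing <- match.arg(spacing)
  drift <- match.arg(drift)
  cols <- seq_len(ncol(tracks$u))
  if (!is.null(types)) {
    if (is.character(types)) types <- PARTICLE_TYPES[types]
    cols <- cols[tracks$type %in% types]
  }
  if (!is.null(particles)) cols <- intersect(cols, particles)
  if (length(cols) == 0) stop("no particles match the filter")
  nf <- nrow(tracks$u)
  if (nf < 2) stop("need at least two frames")
  if (is.null(max_lag_frames)) max_lag_frames <- max(1L, (nf - 1L) %/% 2L)
  max_lag_frames <- min(max_lag_frames, nf - 1L)
  lags <- if (spacing == "log")
    unique(round(exp(seq(log(1), log(max_lag_frames), length.out = n_lags))))
  else unique(round(seq(1, max_lag_frames, length.out = n_lags)))
  u <- tracks$u[, cols, drop = FALSE]
  v <- tracks$v[, cols, drop = FALSE]
  if (drift != "none") {
    groups <- if (drift == "com") rep(1L, length(cols)) else
      as.integer(factor(tracks$type[cols]))
    for (g in unique(groups)) {
      gc <- groups == g
      u[, gc] <- u[, gc, drop = FALSE] -
        rowMeans(u[, gc, drop = FALSE])
      v[, gc] <- v[, gc, drop = FALSE] -
        rowMeans(v[, gc, drop = FALSE])
    }
  }
  dtf <- if (nf > 1) tracks$times[2] - tracks$times[1] else 1
  res <- vapply(lags, function(k) {
    du <- u[(1 + k):nf, , drop = FALSE] - u[1:(nf - k), , drop = FALSE]
    dv <- v[(1 + k):nf, , drop = FALSE] - v[1:(nf - k), , drop = FALSE]
    m <- switch(component,
                planar_2D = mean(du^2) + mean(dv^2),
                longitudinal = mean(dv^2),
                transverse = mean(du^2))
    c(m, length(du))
  }, numeric(2))
  out <- data.frame(lag = lags * dtf, msd = res[1, ], n = res[2, ])
  attr(out, "component") <- component
  class(out) <- c("msd_curve", "data.frame")
  out
}

fit_window <- function(curve, window) {
  if (is.null(window)) return(curve)
  curve[curve$lag >= window[1] & curve$lag <= window[2], , drop = FALSE]
}

new_fit <- function(model, par, curve, fitted, converged = TRUE) {
  structure(list(model = model, par = par,
                 resid_norm = sum((curve$msd - fitted)^2),
                 fitted = fitted, lag = curve$lag, msd = curve$msd,
                 converged = converged),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion_fit [%s]%s\n", x$model,
              if (x$converged) "" else " (NOT converged)"))
  for (nm in names(x$par))
    cat(sprintf("  %-12s %.6g\n", nm, x$par[[nm]]))
  cat(sprintf("  residual squared norm %.6g over %d lags\n",
              x$resid_norm, length(x$lag)))
  invisible(x)
}

#' Fit normal (free) diffusion
#'
#' \code{MSD(t) = 2 d D t} with \code{d} the dimensionality of the
#' component (1 for a directional MSD, 2 for the planar MSD); least
#' squares through the origin.
#'
#' @param curve an \code{msd_curve}.
#' @param window optional \code{c(tmin, tmax)} fit window in t_s.
#' @param dimension spatial dimensionality; inferred from the curve's
#'   component when missing.
#' @return a \code{diffusion_fit} with parameter \code{D} (sigma^2/t_s).
#' @export
fit_normal <- function(curve, window = NULL, dimension = NULL) {
  cv <- fit_window(curve, window)
  if (is.null(dimension))
    dimension <- if (identical(attr(curve, "component"), "planar_2D")) 2 else 1
  slope <- sum(cv$msd * cv$lag) / sum(cv$lag^2)
  new_fit("normal", list(D = slope / (2 * dimension)), cv, slope * cv$lag)
}

#' Fit fully confined diffusion
#'
#' \code{MSD(t) = L^2/6 (1 - exp(-12 D_micro t / L^2))}: saturates at
#' \code{L^2/6} with initial slope \code{2 D_micro}. \code{L} is the
#' characteristic length of the confining corral and \code{D_micro} the
#' short-time (microscopic) diffusion coefficient.
#'
#' @inheritParams fit_normal
#' @param start optional named start values \code{c(D_micro=, L=)}.
#' @return a \code{diffusion_fit} with \code{D_micro} and \code{L}.
#' @export
fit_confined <- function(curve, window = NULL, start = NULL) {
  cv <- fit_window(curve, window)
  if (nrow(cv) < 10) stop("need at least 10 lags for the confined fit")
  if (is.null(start)) {
    head_n <- max(3, min(5, nrow(cv) %/% 3))
    d0 <- max(stats::coef(stats::lm(msd ~ 0 + lag, cv[seq_len(head_n), ])) / 2,
              1e-10)
    start <- list(D_micro = d0, L = sqrt(6 * max(cv$msd)))
  }
  fit <- try(minpack.lm::nlsLM(
    msd ~ L^2 / 6 * (1 - exp(-12 * D_micro * lag / L^2)),
    data = cv, start = start, lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    fitted <- start$L^2 / 6 * (1 - exp(-12 * start$D_micro * cv$lag / start$L^2))
    return(new_fit("confined", start, cv, fitted, converged = FALSE))
  }
  par <- as.list(stats::coef(fit))
  new_fit("confined", par[c("D_micro", "L")], cv, stats::fitted(fit))
}

#' Fit confined-hop diffusion
#'
#' Confined diffusion at short times superimposed on slow normal diffusion
#' at long times:
#' \code{MSD(t) = L^2/6 (1 - exp(-12 D_micro t / L^2)) + 2 D_macro t}.
#' \code{D_macro} (the long-time, inter-compartment hop coefficient) is
#' constrained to be non-negative and is typically an order of magnitude
#' below \code{D_micro}.
#'
#' @inheritParams fit_confined
#' @return a \code{diffusion_fit} with \code{D_micro}, \code{L},
#'   \code{D_macro}.
#' @export
fit_confined_hop <- function(curve, window = NULL, start = NULL) {
  cv <- fit_window(curve, window)
  if (nrow(cv) < 10) stop("need at least 10 lags for the confined-hop fit")
  if (is.null(start)) {
    head_n <- max(3, min(5, nrow(cv) %/% 3))
    d0 <- max(stats::coef(stats::lm(msd ~ 0 + lag, cv[seq_len(head_n), ])) / 2,
              1e-10)
    tail_cv <- cv[cv$lag >= stats::median(cv$lag), ]
    dmac <- max(stats::coef(stats::lm(msd ~ lag, tail_cv))[[2]] / 2, 1e-12)
    start <- list(D_micro = d0, L = sqrt(6 * max(cv$msd) / 2), D_macro = dmac)
  }
  fit <- try(minpack.lm::nlsLM(
    msd ~ L^2 / 6 * (1 - exp(-12 * D_micro * lag / L^2)) + 2 * D_macro * lag,
    data = cv, start = start, lower = c(1e-12, 1e-12, 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    fitted <- start$L^2 / 6 * (1 - exp(-12 * start$D_micro * cv$lag / start$L^2)) +
      2 * start$D_macro * cv$lag
    return(new_fit("confined_hop", start, cv, fitted, converged = FALSE))
  }
  par <- as.list(stats::coef(fit))
  new_fit("confined_hop", par[c("D_micro", "L", "D_macro")], cv,
          stats::fitted(fit))
}

#' Fit anomalous (power-law) diffusion
#'
#' \code{MSD(t) = C t^alpha}, fitted by linear least squares in log-log
#' space. By default the first decade of lags is excluded, where the
#' short-time (ballistic) regime would bias the exponent; the residual
#' squared norm is reported in linear space so it is comparable with the
#' other models.
#'
#' @inheritParams fit_normal
#' @param drop_first_decade exclude lags below ten times the smallest lag
#'   (ignored when an explicit \code{window} is given).
#' @return a \code{diffusion_fit} with \code{C} and \code{alpha_anom}.
#' @export
fit_anomalous <- function(curve, window = NULL, drop_first_decade = TRUE) {
  cv <- fit_window(curve, window)
  if (is.null(window) && drop_first_decade) {
    keep <- cv$lag >= 10 * min(cv$lag)
    if (sum(keep) >= 5) cv <- cv[keep, , drop = FALSE]
  }
  if (any(cv$msd <= 0))
    stop("anomalous fit requires strictly positive MSD values")
  co <- stats::coef(stats::lm(log(msd) ~ log(lag), cv))
  par <- list(C = exp(co[[1]]), alpha_anom = co[[2]])
  new_fit("anomalous", par, cv, par$C * cv$lag^par$alpha_anom)
}

#' Select the best diffusion model by residual norm
#'
#' Fits the candidate models over a common lag window and returns the one
#' with the smallest residual squared norm. Within the nested family
#' normal, confined, confined_hop a richer member is chosen only when it
#' improves the residual norm by more than a factor \code{1 + tie_tol}
#' (default three-fold), which guards against over-fitting the correlated
#' noise of time-averaged MSD curves with the extra parameter. The
#' survivor of the nested family then competes with the (non-nested)
#' anomalous model by plain residual norm; exact ties resolve by the
#' parsimony order normal < confined < confined_hop < anomalous.
#'
#' @param curve an \code{msd_curve}.
#' @param models candidate model names.
#' @param window common fit window \code{c(tmin, tmax)} (default: all lags).
#' @param tie_tol relative residual tolerance for the parsimony tie-break.
#' @return the winning \code{diffusion_fit}, with all candidate fits in
#'   attribute \code{"candidates"}.
#' @export
select_model <- function(curve, models = c("normal", "confined",
                                           "confined_hop", "anomalous"),
                         window = NULL, tie_tol = 2) {
  order_rank <- c(normal = 1, confined = 2, confined_hop = 3, anomalous = 4)
  models <- match.arg(models, several.ok = TRUE)
  if (length(models) < 2) stop("need at least two candidate models")
  fits <- lapply(models, function(m)
    switch(m,
           normal = fit_normal(curve, window),
           confined = fit_confined(curve, window),
           confined_hop = fit_confined_hop(curve, window),
           anomalous = fit_anomalous(curve, window, drop_first_decade = FALSE)))
  names(fits) <- models
  rn <- vapply(fits, function(f) f$resid_norm, numeric(1))
  # floor at the numerical-noise scale so that exact fits compare as ties
  rn <- rn + 1e-14 * sum(fits[[1]]$msd^2)
  nested <- intersect(c("normal", "confined", "confined_hop"), models)
  pick <- NULL
  if (length(nested)) {
    pick <- nested[1]
    for (m in nested[-1])          # richer model must earn its keep
      if (rn[[m]] < rn[[pick]] / (1 + tie_tol)) pick <- m
  }
  if ("anomalous" %in% models &&
      (is.null(pick) || rn[["anomalous"]] < rn[[pick]]))
    pick <- "anomalous"
  out <- fits[[pick]]
  attr(out, "candidates") <- fits
  attr(out, "residuals") <- rn
  out
}

#' Width of the accessible stripe between actin rings
#'
#' Adds the protein-actin steric contact distance on both sides to the
#' fitted characteristic confinement length, giving the physical stripe
#' width between two actin rings that the protein centre can explore,
#' e.g. 108 nm + 2 x 30 nm = 168 nm for transmembrane proteins.
#'
#' @param L characteristic confinement length (any length unit).
#' @param steric_distance protein-actin contact distance (same unit).
#' @return stripe width in the same unit.
#' @export
stripe_width <- function(L, steric_distance) {
  if (any(L < 0) || any(steric_distance < 0)) stop("lengths must be >= 0")
  L + 2 * steric_distance
}

#' End-to-end distance statistics of a chain
#'
#' Distance between the first and last particle of a chain across the
#' frames of a trajectory; reports the root-mean-square, moments and a
#' normality check of the sampled distances.
#'
#' @param traj an \code{md_trajectory}.
#' @param chain particle indices of the chain, in order.
#' @return list with \code{samples}, \code{rms}, \code{mean}, \code{sd}
#'   and \code{shapiro_p} (on at most 5000 samples).
#' @export
end_to_end_stats <- function(traj, chain = seq_along(traj$type)) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (length(chain) < 2) stop("chain must contain at least two particles")
  if (n_frames(traj) == 0) stop("empty trajectory")
  i <- chain[1]; j <- chain[length(chain)]
  ree <- vapply(traj$frames, function(f)
    sqrt(sum((f[i, ] - f[j, ])^2)), numeric(1))
  sub <- if (length(ree) > 5000)
    ree[round(seq(1, length(ree), length.out = 5000))] else ree
  sh <- if (length(sub) >= 3 && stats::sd(sub) > 0)
    stats::shapiro.test(sub)$p.value else NA_real_
  list(samples = ree, rms = sqrt(mean(ree^2)), mean = mean(ree),
       sd = stats::sd(ree), shapiro_p = sh)
}

# ---------------------------------------------------------------------------
# synthetic planar walks for validating the estimators and fitters

#' Synthetic planar random walks
#'
#' Generators for planar tracks with known diffusion law, used to validate
#' the MSD estimator and the model fitters: free Brownian motion,
#' diffusion confined to a box (reflecting walls), and hop diffusion
#' (confined with a per-contact escape probability into the neighbouring
#' compartment).
#'
#' @param n_steps,n_particles track length and count.
#' @param d microscopic diffusion coefficient (sigma^2/t_s) per component.
#' @param dt frame interval (t_s).
#' @param L compartment width (sigma) for the confined/hop walks.
#' @param p_escape probability that a wall contact crosses into the next
#'   compartment (hop walk).
#' @param confine which components are confined: \code{"u"}, \code{"v"} or
#'   \code{"both"}.
#' @return a \code{planar_tracks} object.
#' @name synthetic_walks
NULL

#' @rdname synthetic_walks
#' @export
simulate_brownian_walk <- function(n_steps, n_particles = 1, d = 1e-2,
                                   dt = 1) {
  stepm <- function() matrix(stats::rnorm((n_steps) * n_particles,
                                          sd = sqrt(2 * d * dt)),
                             n_steps, n_particles)
  u <- apply(stepm(), 2, cumsum)
  v <- apply(stepm(), 2, cumsum)
  planar_tracks(rbind(0, u), rbind(0, v), seq(0, n_steps) * dt,
                rep(PARTICLE_TYPES[["TMP"]], n_particles))
}

reflect_fold <- function(x, L) {
  y <- x %% (2 * L)
  ifelse(y > L, 2 * L - y, y)
}

#' @rdname synthetic_walks
#' @export
simulate_confined_walk <- function(n_steps, n_particles = 1, d = 1e-2,
                                   dt = 1, L = 5, confine = "both") {
  free <- simulate_brownian_walk(n_steps, n_particles, d, dt)
  off <- L / 2
  if (confine %in% c("u", "both")) free$u <- reflect_fold(free$u + off, L)
  if (confine %in% c("v", "both")) free$v <- reflect_fold(free$v + off, L)
  free
}

#' @rdname synthetic_walks
#' @export
simulate_hop_walk <- function(n_steps, n_particles = 1, d = 1e-2, dt = 1,
                              L = 5, p_escape = 0.05, confine = "both") {
  step_sd <- sqrt(2 * d * dt)
  mk <- function(active) {
    if (!active) {
      m <- matrix(stats::rnorm(n_steps * n_particles, sd = step_sd),
                  n_steps, n_particles)
      return(rbind(0, apply(m, 2, cumsum)))
    }
    x <- matrix(0, n_steps + 1, n_particles)
    x[1, ] <- L / 2
    for (t in seq_len(n_steps)) {
      prop <- x[t, ] + stats::rnorm(n_particles, sd = step_sd)
      cell_old <- floor(x[t, ] / L)
      crossed <- floor(prop / L) != cell_old
      bounce <- crossed & stats::runif(n_particles) > p_escape
      if (any(bounce))  # reflected at the compartment boundary
        prop[bounce] <- reflect_fold(prop[bounce] - cell_old[bounce] * L, L) +
          cell_old[bounce] * L
      x[t + 1, ] <- prop
    }
    x
  }
  planar_tracks(mk(confine %in% c("u", "both")),
                mk(confine %in% c("v", "both")),
                seq(0, n_steps) * dt,
                rep(PARTICLE_TYPES[["TMP"]], n_particles))
}
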