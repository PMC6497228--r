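# Readers/writers: extended-XYZ trajectories and flat key-value configs.
# Values are written with 17 significant digits so that reduced-unit
# coordinates round-trip bit-exactly through the text format.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a trajectory as extended XYZ
#'
#' One block per frame: a particle count line, a comment line carrying the
#' periodic box (\code{Lattice}), the column layout (\code{Properties}),
#' frame time/step, the geometry kind and the length unit, then one line
#' per particle with the species label, position and orientation columns.
#'
#' @param traj an \code{md_trajectory}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(traj$type)
  box <- traj$geometry$box
  labels <- type_label(traj$type)
  for (f in seq_len(n_frames(traj))) {
    pos <- traj$frames[[f]]
    ori <- if (!is.null(traj$orient_frames) &&
               length(traj$orient_frames) >= f &&
               !is.null(traj$orient_frames[[f]]))
      traj$orient_frames[[f]] else matrix(0, n, 3)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%s 0 0 0 %s 0 0 0 %s" Properties=species:S:1:pos:R:3:orient:R:3 Time=%s Step=%d geometry=%s sigma_nm=%s',
      fmt_num(box[1]), fmt_num(box[2]), fmt_num(box[3]),
      fmt_num(traj$times[f]), traj$steps[f], traj$geometry$kind,
      fmt_num(traj$sigma_nm)), con)
    writeLines(paste(labels,
                     fmt_num(pos[, 1]), fmt_num(pos[, 2]), fmt_num(pos[, 3]),
                     fmt_num(ori[, 1]), fmt_num(ori[, 2]), fmt_num(ori[, 3])),
               con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of [write_trajectory()]; reading back a written trajectory
#' reproduces positions, orientations, times and metadata exactly.
#'
#' @param path file path.
#' @return an \code{md_trajectory}.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list(); oframes <- list()
  times <- numeric(0); steps <- integer(0)
  type <- integer(0); geometry <- list(kind = "free", box = c(0, 0, 0))
  sigma_nm <- derive_sigma(5)
  i <- 1L; f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(lines[i])
    if (is.na(n)) stop("malformed frame header at line ", i)
    hdr <- lines[i + 1L]
    lat <- regmatches(hdr, regexec('Lattice="([^"]*)"', hdr))[[1]][2]
    latv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
    kv <- function(key, default = NA) {
      m <- regmatches(hdr, regexec(paste0(key, "=([^ \"]+)"), hdr))[[1]]
      if (length(m) < 2) default else m[2]
    }
    geometry <- list(kind = kv("geometry", "free"),
                     box = latv[c(1, 5, 9)])
    sigma_nm <- as.numeric(kv("sigma_nm", fmt_num(derive_sigma(5))))
    tt <- as.numeric(kv("Time", "0"))
    st <- as.integer(as.numeric(kv("Step", "0")))
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(body, "\\s+")
    lab <- vapply(parts, `[[`, character(1), 1)
    num <- t(vapply(parts, function(p) as.numeric(p[2:7]), numeric(6)))
    f <- f + 1L
    frames[[f]] <- num[, 1:3, drop = FALSE]
    oframes[[f]] <- num[, 4:6, drop = FALSE]
    times[f] <- tt; steps[f] <- st
    type <- unname(PARTICLE_TYPES[lab])
    if (anyNA(type)) stop("unknown species label in trajectory file")
    i <- i + 2L + n
  }
  structure(list(times = times, steps = steps, frames = frames,
                 orient_frames = if (f > 0) oframes else NULL,
                 type = if (f > 0) type else integer(0),
                 geometry = geometry, sigma_nm = sigma_nm),
            class = "md_trajectory")
}

#' Write a particle system as a single-frame extended-XYZ file
#'
#' @param system a \code{particle_system}.
#' @param path output path.
#' @export
write_system <- function(system, path) {
  traj <- new_trajectory(list(system$pos), 0, 0L, system,
                         list(system$orient))
  write_trajectory(traj, path)
}

# ---------------------------------------------------------------------------
# flat key-value configuration files

config_known_run_keys <- c("steps", "dt", "temperature", "ensemble", "seed",
                           "traj_every", "thermo_every", "preset", "pprc",
                           "anchored", "n_lags")

#' Read a configuration file
#'
#' Flat \code{key = value} text format with dotted sections and \code{#}
#' comments. Keys under \code{forcefield.} override force-field parameters
#' (reduced units, matching the parameter names of
#' [default_forcefield()]); \code{units.} keys configure the unit system
#' (\code{sigma_nm}, \code{kBT_over_eps}, \code{temperature_K},
#' \code{dt_in_ts}); \code{run.} keys carry run settings. Unknown keys are
#' rejected by name; an empty file yields the full default force field.
#'
#' @param path configuration file path.
#' @return list with \code{forcefield} (validated), \code{units} and
#'   \code{run} settings.
#' @export
read_config <- function(path) {
  lines <- if (file.exists(path)) readLines(path) else
    stop("config file not found: ", path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  unit_args <- list(); ff_over <- list(); run <- list()
  ff_names <- setdiff(names(default_forcefield()), "units")
  for (key in names(kv)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("unknown configuration key: '", key, "'")
    sec <- parts[1]; nm <- parts[2]
    val <- kv[[key]]
    num <- suppressWarnings(as.numeric(val))
    if (sec == "forcefield") {
      if (!nm %in% ff_names)
        stop("unknown force-field parameter in config: '", nm, "'")
      if (is.na(num)) stop("non-numeric value for forcefield.", nm)
      ff_over[[nm]] <- num
    } else if (sec == "units") {
      if (!nm %in% c("sigma_nm", "kBT_over_eps", "temperature_K", "dt_in_ts"))
        stop("unknown unit-system key in config: '", nm, "'")
      if (is.na(num)) stop("non-numeric value for units.", nm)
      unit_args[[nm]] <- num
    } else if (sec == "run") {
      if (!nm %in% config_known_run_keys)
        stop("unknown run key in config: '", nm, "'")
      run[[nm]] <- if (!is.na(num)) num else val
    } else stop("unknown configuration section: '", sec, "'")
  }
  units <- do.call(unit_system, unit_args)
  ff <- default_forcefield(units = units, overrides = ff_over)
  list(forcefield = ff, units = units, run = run)
}

#' Write the default force field as a configuration file
#'
#' Emits every force-field parameter (reduced units) in the flat
#' key-value dialect understood by [read_config()].
#'
#' @param ff force field to serialise.
#' @param path output path.
#' @export
write_config <- function(ff = default_forcefield(), path) {
  nms <- setdiff(names(ff), c("units", "eff_radius"))
  lines <- c("# axonmem force field (reduced units: sigma, eps, t_s)",
             sprintf("units.sigma_nm = %s", fmt_num(ff$units$sigma_nm)),
             sprintf("units.kBT_over_eps = %s",
                     fmt_num(ff$units$epsilon_rel_temp)),
             sprintf("forcefield.%s = %s", nms,
                     vapply(ff[nms], fmt_num, character(1))))
  writeLines(lines, path)
  invisible(path)
}
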