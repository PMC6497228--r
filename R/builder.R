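# System construction: particle containers, topology, and builders for
# spectrin chains, actin rings, the periodic skeleton, bilayer patches and
# cylinders, and protein placement.

#' Particle type codes
#'
#' Integer codes identifying each coarse-grained species. Membrane
#' particles (codes 1-7) carry an orientation vector; skeleton particles
#' (spectrin, actin) do not. Ankyrin is not a separate particle: the
#' ankyrin linkage is represented by the anchoring spring that ties an
#' anchored transmembrane protein to the 20th bead of a spectrin chain.
#'
#' @format named integer vector.
#' @export
PARTICLE_TYPES <- c(lipid_outer = 1L, lipid_inner = 2L,
                    IMP_outer = 3L, IMP_inner = 4L,
                    TMP = 5L, TMP_anchored = 6L,
                    actin_anchor_protein = 7L,
                    spectrin = 8L, actin = 9L)

type_label <- function(code) names(PARTICLE_TYPES)[match(code, PARTICLE_TYPES)]

is_membrane_type <- function(code) code >= 1L & code <= 7L

empty_topology <- function() {
  list(bonds = matrix(numeric(0), ncol = 4,
                      dimnames = list(NULL, c("i", "j", "k", "req"))),
       tethers = matrix(numeric(0), ncol = 6,
                        dimnames = list(NULL, c("i", "x", "y", "z", "k", "req"))),
       angles = matrix(numeric(0), ncol = 6,
                       dimnames = list(NULL, c("i", "j", "k", "kb",
                                               "theta0", "dthmax"))),
       rings = list(),
       chains = list(),
       ring_pairs = matrix(numeric(0), ncol = 3,
                           dimnames = list(NULL, c("a", "b", "shift"))),
       as_ends = integer(0), as_partner = integer(0))
}

#' Construct a particle system
#'
#' The container used throughout the package: particle positions in sigma
#' units, unit orientation vectors for membrane particles, per-particle
#' type codes, a geometry record, and the bonded topology.
#'
#' @param pos n x 3 matrix of positions (sigma units).
#' @param type integer vector of [PARTICLE_TYPES] codes.
#' @param orient n x 3 matrix of orientations; rows for skeleton particles
#'   are ignored. Required when membrane particles are present.
#' @param geometry list with \code{kind} (\code{"free"}, \code{"slab"} for a
#'   doubly-periodic flat patch, or \code{"cylinder"} for an axially
#'   periodic tube) and \code{box = c(Lx, Ly, Lz)} (periodic extents;
#'   unused entries 0).
#' @param topology bonded-topology list; see [empty_topology()] for the
#'   layout. Defaults to no bonded terms.
#' @param sigma_nm length unit, recorded for unit conversions at I/O.
#' @return object of class \code{particle_system}.
#' @export
particle_system <- function(pos, type, orient = NULL,
                            geometry = list(kind = "free", box = c(0, 0, 0)),
                            topology = empty_topology(),
                            sigma_nm = derive_sigma(5)) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, length(type) == nrow(pos))
  type <- as.integer(type)
  n <- nrow(pos)
  if (is.null(orient)) {
    if (any(is_membrane_type(type)))
      stop("membrane particles require orientation vectors")
    orient <- matrix(0, n, 3)
  }
  orient <- as.matrix(orient)
  stopifnot(nrow(orient) == n, ncol(orient) == 3)
  mem <- is_membrane_type(type)
  if (any(mem)) {
    norms <- sqrt(rowSums(orient[mem, , drop = FALSE]^2))
    if (any(abs(norms - 1) > 1e-10))
      stop("orientation vectors of membrane particles must have unit norm")
  }
  stopifnot(geometry$kind %in% c("free", "slab", "cylinder"),
            length(geometry$box) == 3)
  structure(list(pos = pos, orient = orient, type = type,
                 geometry = geometry, topology = topology,
                 sigma_nm = sigma_nm),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  tab <- table(type_label(x$type))
  cat(sprintf("particle_system: %d particles, geometry %s\n",
              nrow(x$pos), x$geometry$kind))
  for (nm in names(tab)) cat(sprintf("  %-22s %d\n", nm, tab[[nm]]))
  tp <- x$topology
  cat(sprintf("  bonds %d | angles %d | rings %d | breakable AS %d | tethers %d\n",
              nrow(tp$bonds), nrow(tp$angles), length(tp$rings),
              length(tp$as_ends), nrow(tp$tethers)))
  invisible(x)
}

orient_or_zero <- function(system) system$orient

topo_for_cpp <- function(system) {
  tp <- system$topology
  list(bonds = tp$bonds, tethers = tp$tethers,
       angles = tp$angles, rings = tp$rings, ring_pairs = tp$ring_pairs,
       as_ends = as.integer(tp$as_ends), as_partner = as.integer(tp$as_partner))
}

#' Merge two particle systems
#'
#' Concatenates particles and re-indexes the topology of the second system.
#' The geometry of the first system is kept (the second must either match
#' it or be \code{"free"}).
#'
#' @param a,b particle systems.
#' @return merged \code{particle_system}.
#' @export
merge_systems <- function(a, b) {
  stopifnot(inherits(a, "particle_system"), inherits(b, "particle_system"))
  if (b$geometry$kind != "free" && !identical(a$geometry, b$geometry))
    stop("cannot merge systems with conflicting geometries")
  off <- nrow(a$pos)
  ta <- a$topology; tb <- b$topology
  shift_idx <- function(m, cols) { m[, cols] <- m[, cols] + off; m }
  topology <- list(
    bonds = rbind(ta$bonds, shift_idx(tb$bonds, 1:2)),
    tethers = rbind(ta$tethers, shift_idx(tb$tethers, 1)),
    angles = rbind(ta$angles, shift_idx(tb$angles, 1:3)),
    rings = c(ta$rings, lapply(tb$rings, function(r) r + off)),
    chains = c(ta$chains, lapply(tb$chains, function(r) r + off)),
    ring_pairs = rbind(ta$ring_pairs,
                       if (nrow(tb$ring_pairs))
                         tb$ring_pairs + cbind(length(ta$rings),
                                               length(ta$rings), 0)
                       else tb$ring_pairs),
    as_ends = c(ta$as_ends, tb$as_ends + off),
    as_partner = c(ta$as_partner,
                   ifelse(tb$as_partner > 0, tb$as_partner + off, 0L)))
  particle_system(rbind(a$pos, b$pos), c(a$type, b$type),
                  rbind(a$orient, b$orient), a$geometry, topology, a$sigma_nm)
}

#' Build a spectrin tetramer chain
#'
#' A straight chain of beads connected by harmonic springs of stiffness
#' \code{k0}; all beads additionally repel through the truncated LJ term,
#' which is a non-bonded interaction and needs no topology entry. The
#' default 41 beads at 5 nm spacing give the 200 nm contour length of a
#' spectrin tetramer.
#'
#' @param n_particles number of beads (>= 2).
#' @param spacing_nm equilibrium bead spacing in nm.
#' @param ff force field (supplies \code{k0} and the unit system).
#' @param origin position of the first bead (sigma units).
#' @param axis chain direction (normalised internally).
#' @return a \code{particle_system} with \code{n_particles - 1} springs.
#' @export
build_spectrin_chain <- function(n_particles = 41, spacing_nm = 5,
                                 ff = default_forcefield(),
                                 origin = c(0, 0, 0), axis = c(0, 0, 1)) {
  stopifnot(n_particles >= 2)
  s <- ff$units$sigma_nm
  axis <- axis / sqrt(sum(axis^2))
  spacing <- spacing_nm / s
  pos <- t(sapply(seq_len(n_particles) - 1, function(k) origin + k * spacing * axis))
  idx <- seq_len(n_particles - 1)
  topo <- empty_topology()
  topo$bonds <- cbind(i = idx, j = idx + 1, k = ff$k0, req = spacing)
  topo$chains <- list(seq_len(n_particles))
  particle_system(pos, rep(PARTICLE_TYPES[["spectrin"]], n_particles),
                  topology = topo, sigma_nm = s)
}

#' Build an actin ring
#'
#' A closed ring of actin particles in a plane perpendicular to the axon
#' axis (z): a regular n-gon with edge length equal to the particle
#' diameter, so every spring and bending angle starts exactly at its
#' equilibrium (diameter \code{d/sin(pi/n)}, about 434 nm for the default
#' 39 x 35 nm). Springs have stiffness \code{kA}; the FENE bending
#' potential holds the interior equilibrium angle \code{180*(n-2)/n}
#' degrees.
#'
#' @param n_particles particles in the ring (>= 3).
#' @param particle_diameter_nm actin particle diameter in nm.
#' @param ff force field.
#' @param center ring centre (sigma units).
#' @return a \code{particle_system} with ring topology (springs, angles,
#'   ring membership for the ring-spacing term).
#' @export
build_actin_ring <- function(n_particles = 39, particle_diameter_nm = 35,
                             ff = default_forcefield(), center = c(0, 0, 0)) {
  if (n_particles < 3) stop("an actin ring needs at least 3 particles")
  s <- ff$units$sigma_nm
  d <- particle_diameter_nm / s
  radius <- d / (2 * sin(pi / n_particles))
  ang <- 2 * pi * (seq_len(n_particles) - 1) / n_particles
  pos <- cbind(center[1] + radius * cos(ang),
               center[2] + radius * sin(ang),
               center[3])
  idx <- seq_len(n_particles)
  nxt <- c(idx[-1], 1L)
  prv <- c(n_particles, idx[-n_particles])
  theta0 <- pi * (n_particles - 2) / n_particles
  topo <- empty_topology()
  topo$bonds <- cbind(i = idx, j = nxt, k = ff$kA, req = d)
  topo$angles <- cbind(i = prv, j = idx, k = nxt, kb = ff$kb,
                       theta0 = theta0, dthmax = 0.3 * theta0)
  topo$rings <- list(idx)
  particle_system(pos, rep(PARTICLE_TYPES[["actin"]], n_particles),
                  topology = topo, sigma_nm = s)
}

#' Build the periodic actin/spectrin membrane skeleton
#'
#' Actin rings at 185 nm axial spacing joined by spectrin chains running
#' along the axis, with breakable actin-spectrin association bonds at the
#' chain ends and the FENE ring-spacing term between consecutive rings.
#' The geometry is an axially periodic cylinder of length
#' \code{n_rings * ring_spacing}. Because the chain contour length (200 nm)
#' exceeds the 145 nm gap between association points, chains are laid out
#' as shallow helices at the ring radius, preserving the 5 nm bead spacing.
#'
#' @param n_rings number of rings (>= 2).
#' @param ring_spacing_nm axial ring period in nm.
#' @param chains_per_ring spectrin chains in each inter-ring gap (cannot
#'   exceed the number of ring particles).
#' @param ring_particles,particle_diameter_nm ring discretisation.
#' @param chain_particles,chain_spacing_nm chain discretisation.
#' @param ff force field.
#' @return a \code{particle_system} (cylinder geometry).
#' @export
build_apms <- function(n_rings = 3, ring_spacing_nm = 185,
                       chains_per_ring = 6,
                       ring_particles = 39, particle_diameter_nm = 35,
                       chain_particles = 41, chain_spacing_nm = 5,
                       ff = default_forcefield()) {
  stopifnot(n_rings >= 2)
  if (chains_per_ring > ring_particles)
    stop("chains_per_ring cannot exceed the number of ring particles")
  s <- ff$units$sigma_nm
  spacing <- ring_spacing_nm / s
  lz <- n_rings * spacing
  sys <- NULL
  for (k in seq_len(n_rings)) {
    ring <- build_actin_ring(ring_particles, particle_diameter_nm, ff,
                             center = c(0, 0, (k - 1) * spacing))
    ring$geometry <- list(kind = "cylinder", box = c(0, 0, lz))
    sys <- if (is.null(sys)) ring else merge_systems(sys, ring)
  }
  tp <- sys$topology
  nxt <- c(seq_len(n_rings)[-1], 1L)
  tp$ring_pairs <- cbind(a = seq_len(n_rings), b = nxt,
                         shift = ifelse(nxt == 1L, lz, 0))
  sys$topology <- tp
  # helical spectrin chains between consecutive rings
  radius <- (particle_diameter_nm / s) / (2 * sin(pi / ring_particles))
  gap_off <- ff$req_ag  # 20 nm association offset at each end
  nb <- chain_particles - 1
  dz_tot <- spacing - 2 * gap_off
  if (dz_tot <= 0) stop("ring spacing too small for the association offsets")
  contour <- nb * chain_spacing_nm / s
  arc_circ <- sqrt(max(contour^2 - dz_tot^2, 0))  # circumferential arc length
  # snap the helix twist to the ring's angular grid so both chain ends sit
  # exactly above a ring particle, at the association equilibrium distance
  ring_dth <- 2 * pi / ring_particles
  dtheta_tot <- round((arc_circ / radius) / ring_dth) * ring_dth
  for (k in seq_len(n_rings)) {
    z0 <- (k - 1) * spacing
    for (c in seq_len(chains_per_ring)) {
      # start aligned with a ring particle so the association sits at its
      # equilibrium distance
      a_idx <- 1 + (c - 1) * floor(ring_particles / chains_per_ring)
      th0 <- 2 * pi * (a_idx - 1) / ring_particles
      kk <- 0:nb
      th <- th0 + kk * dtheta_tot / nb
      pos <- cbind(radius * cos(th), radius * sin(th),
                   z0 + gap_off + kk * dz_tot / nb)
      chain <- particle_system(pos,
                               rep(PARTICLE_TYPES[["spectrin"]],
                                   chain_particles),
                               geometry = sys$geometry,
                               sigma_nm = s)
      idx <- seq_len(chain_particles - 1)
      req <- chain_spacing_nm / s
      chain$topology$bonds <- cbind(i = idx, j = idx + 1, k = ff$k0, req = req)
      chain$topology$chains <- list(seq_len(chain_particles))
      first <- nrow(sys$pos) + 1L
      last <- nrow(sys$pos) + chain_particles
      # breakable associations: chain start to a particle of ring k, chain
      # end to the matching particle of ring k+1 (periodic)
      ring_a <- sys$topology$rings[[k]][a_idx]
      kb <- if (k == n_rings) 1L else k + 1L
      end_th <- th[length(th)] %% (2 * pi)
      ring_b_particles <- sys$topology$rings[[kb]]
      bpos <- sys$pos[ring_b_particles, , drop = FALSE]
      bth <- atan2(bpos[, 2], bpos[, 1]) %% (2 * pi)
      dth <- abs((bth - end_th + pi) %% (2 * pi) - pi)
      ring_b <- ring_b_particles[which.min(dth)]
      sys <- merge_systems(sys, chain)
      sys$topology$as_ends <- c(sys$topology$as_ends, first, last)
      sys$topology$as_partner <- c(sys$topology$as_partner, ring_a, ring_b)
    }
  }
  sys
}

hex_sheet <- function(nx, ny, a, jitter) {
  # ny must be even for periodic hexagonal tiling
  xy <- expand.grid(ix = seq_len(nx) - 1, iy = seq_len(ny) - 1)
  x <- (xy$ix + 0.5 * (xy$iy %% 2)) * a
  y <- xy$iy * a * sqrt(3) / 2
  if (jitter > 0) {
    x <- x + stats::runif(length(x), -jitter * a, jitter * a)
    y <- y + stats::runif(length(y), -jitter * a, jitter * a)
  }
  cbind(x, y)
}

#' Build a two-leaflet lipid bilayer
#'
#' Places two near-hexagonally packed layers of lipid particles at the
#' equilibrium lipid spacing, separated by the minimum of the
#' inter-leaflet potential so the bilayer starts relaxed. Outer-leaflet
#' orientations point along +normal (radially outward on a cylinder),
#' inner-leaflet along -normal. A small uniform jitter (default 5% of the
#' spacing) avoids a perfectly crystalline start.
#'
#' @param kind \code{"slab"} (doubly-periodic flat patch in x,y) or
#'   \code{"cylinder"} (axially periodic tube around z).
#' @param lx,ly requested patch extent in sigma (slab; snapped to the
#'   lattice).
#' @param radius_nm,length_nm inner-leaflet radius and axial length
#'   (cylinder; length snapped to the lattice).
#' @param lipid_spacing_nm equilibrium lipid spacing in nm.
#' @param jitter positional jitter as a fraction of the spacing.
#' @param axial_length_sigma optional exact axial period in sigma for the
#'   cylinder (overrides \code{length_nm}); rows are strained slightly to
#'   fit, so the bilayer can share a periodic box with a skeleton.
#' @param ff force field.
#' @return a \code{particle_system} of lipid particles.
#' @export
build_bilayer <- function(kind = c("slab", "cylinder"),
                          lx = 30, ly = 30,
                          radius_nm = 100, length_nm = 100,
                          lipid_spacing_nm = 2.5, jitter = 0.05,
                          axial_length_sigma = NULL,
                          ff = default_forcefield()) {
  kind <- match.arg(kind)
  s <- ff$units$sigma_nm
  a <- lipid_spacing_nm / s
  sep <- ff$rcut_layer  # minimum of the inter-leaflet potential
  if (kind == "slab") {
    nx <- max(2, round(lx / a))
    ny <- max(2, 2 * round(ly / (a * sqrt(3))))
    box <- c(nx * a, ny * a * sqrt(3) / 2, 0)
    pos_list <- list()
    for (leaf in 1:2) {
      xy <- hex_sheet(nx, ny, a, jitter)
      zz <- if (leaf == 1) sep / 2 else -sep / 2
      pos_list[[leaf]] <- cbind(xy, zz)
    }
    pos <- do.call(rbind, pos_list)
    nl <- nx * ny
    type <- rep(c(PARTICLE_TYPES[["lipid_outer"]],
                  PARTICLE_TYPES[["lipid_inner"]]), each = nl)
    orient <- rbind(matrix(rep(c(0, 0, 1), each = nl), ncol = 3),
                    matrix(rep(c(0, 0, -1), each = nl), ncol = 3))
    geometry <- list(kind = "slab", box = box)
  } else {
    r_in <- radius_nm / s
    if (2 * pi * r_in < 8 * a)
      stop("cylinder radius too small for the lipid spacing")
    r_out <- r_in + sep
    if (is.null(axial_length_sigma)) {
      nz <- max(2, 2 * round(length_nm / s / (a * sqrt(3))))
      lz <- nz * a * sqrt(3) / 2
    } else {
      lz <- axial_length_sigma
      nz <- max(2, 2 * round(lz / (a * sqrt(3))))
    }
    mk_leaflet <- function(r, outward) {
      m <- max(8, round(2 * pi * r / a))
      rows <- lapply(seq_len(nz) - 1, function(iz) {
        th <- 2 * pi * ((seq_len(m) - 1) + 0.5 * (iz %% 2)) / m
        if (jitter > 0)
          th <- th + stats::runif(m, -jitter * a / r, jitter * a / r)
        z <- iz * (lz / nz) +
          (if (jitter > 0) stats::runif(m, -jitter * a, jitter * a) else 0)
        cbind(r * cos(th), r * sin(th), z)
      })
      pos <- do.call(rbind, rows)
      nr <- sqrt(pos[, 1]^2 + pos[, 2]^2)
      orient <- cbind(pos[, 1] / nr, pos[, 2] / nr, 0) * outward
      list(pos = pos, orient = orient)
    }
    out <- mk_leaflet(r_out, 1)
    inn <- mk_leaflet(r_in, -1)
    pos <- rbind(out$pos, inn$pos)
    orient <- rbind(out$orient, inn$orient)
    type <- c(rep(PARTICLE_TYPES[["lipid_outer"]], nrow(out$pos)),
              rep(PARTICLE_TYPES[["lipid_inner"]], nrow(inn$pos)))
    geometry <- list(kind = "cylinder", box = c(0, 0, lz))
  }
  sys <- particle_system(pos, type, orient, geometry, sigma_nm = s)
  check_build_spacing(sys, ff)
  sys
}

# build-time guard: no two same-leaflet particles closer than half the
# equilibrium spacing
check_build_spacing <- function(sys, ff) {
  for (leaf in list(c(1L, 3L), c(2L, 4L))) {
    idx <- which(sys$type %in% leaf)
    if (length(idx) < 2) next
    prs <- neighbor_pairs(sys$pos[idx, , drop = FALSE], sys$geometry,
                          cutoff = 0.5 * ff$req_ll)
    if (nrow(prs) > 0)
      stop("build produced overlapping particles within half the ",
           "equilibrium spacing")
  }
  invisible(sys)
}

#' Place membrane proteins in a bilayer
#'
#' Substitutes proteins for lipids at uniformly random positions:
#' monotopic proteins (IMPs) replace a lipid in their leaflet, and
#' transmembrane proteins (TMPs) sit at the bilayer mid-surface. Lipids
#' within the protein contact distance are removed to make room. With
#' \code{anchored = TRUE} each TMP is tethered to its initial position by a
#' spring of stiffness \code{k0} (the immobilised-channel protocol);
#' placement is reproducible for a fixed RNG state (set a seed before
#' calling).
#'
#' @param system a bilayer-containing \code{particle_system}.
#' @param n_tmp,n_imp_outer,n_imp_inner protein counts to place. \code{pprc}
#'   may be given instead of \code{n_tmp}: it is multiplied by
#'   \code{n_corrals}.
#' @param pprc TMP surface density in particles per rectangular corral.
#' @param n_corrals number of skeleton corrals the patch represents.
#' @param anchored tether TMPs to their initial positions.
#' @param ff force field.
#' @return the modified \code{particle_system}.
#' @export
place_proteins <- function(system, n_tmp = 0, n_imp_outer = 0,
                           n_imp_inner = 0, pprc = NULL, n_corrals = 1,
                           anchored = FALSE, ff = default_forcefield()) {
  stopifnot(inherits(system, "particle_system"))
  if (!is.null(pprc)) n_tmp <- pprc * n_corrals
  if (n_tmp + n_imp_outer + n_imp_inner == 0) return(system)
  s <- system
  place_one <- function(s, ptype) {
    leaflets <- switch(type_label(ptype),
                       IMP_outer = 1L, IMP_inner = 2L,
                       TMP = c(1L, 2L), TMP_anchored = c(1L, 2L))
    host_pool <- which(s$type == leaflets[1])
    if (length(host_pool) == 0)
      stop("no lipid available to substitute; placement infeasible")
    host <- host_pool[sample.int(length(host_pool), 1)]
    hp <- s$pos[host, ]
    ho <- s$orient[host, ]
    # carve out lipids too close to the new protein (both leaflets for TMPs)
    clear <- ff$req_lp * 0.95
    cand <- which(s$type %in% leaflets)
    if (length(leaflets) == 2) {
      # TMP sits at the mid-surface
      hp <- hp - ho * ff$rcut_layer / 2
    }
    d <- sweep(s$pos[cand, , drop = FALSE], 2, hp)
    for (dim in 1:3)
      if (bx <- s$geometry$box[dim])
        if (periodic_dim(s$geometry$kind, dim))
          d[, dim] <- d[, dim] - bx * round(d[, dim] / bx)
    drop_idx <- cand[sqrt(rowSums(d^2)) < clear]
    drop_idx <- union(drop_idx, host)
    s <- drop_particles(s, drop_idx)
    prot <- particle_system(matrix(hp, 1, 3), ptype, matrix(ho, 1, 3),
                            s$geometry, sigma_nm = s$sigma_nm)
    if (ptype == PARTICLE_TYPES[["TMP_anchored"]]) {
      prot$topology$tethers <- cbind(i = 1, x = hp[1], y = hp[2], z = hp[3],
                                     k = ff$k0, req = 0)
    }
    merge_systems(s, prot)
  }
  tmp_type <- if (anchored) PARTICLE_TYPES[["TMP_anchored"]] else
    PARTICLE_TYPES[["TMP"]]
  for (q in seq_len(n_tmp)) s <- place_one(s, tmp_type)
  for (q in seq_len(n_imp_outer)) s <- place_one(s, PARTICLE_TYPES[["IMP_outer"]])
  for (q in seq_len(n_imp_inner)) s <- place_one(s, PARTICLE_TYPES[["IMP_inner"]])
  s
}

periodic_dim <- function(kind, dim) {
  (kind == "slab" && dim %in% 1:2) || (kind == "cylinder" && dim == 3)
}

drop_particles <- function(s, idx) {
  if (length(idx) == 0) return(s)
  tp <- s$topology
  refs <- c(tp$bonds[, 1:2], tp$tethers[, 1], tp$angles, unlist(tp$rings),
            tp$as_ends, tp$as_partner)
  if (any(idx %in% refs))
    stop("cannot drop particles referenced by the topology")
  keep <- setdiff(seq_len(nrow(s$pos)), idx)
  remap <- integer(nrow(s$pos))
  remap[keep] <- seq_along(keep)
  remap_m <- function(m, cols) {
    if (nrow(m)) m[, cols] <- remap[m[, cols]]
    m
  }
  tp$bonds <- remap_m(tp$bonds, 1:2)
  tp$tethers <- remap_m(tp$tethers, 1)
  tp$angles <- remap_m(tp$angles, 1:3)
  tp$rings <- lapply(tp$rings, function(r) remap[r])
  tp$chains <- lapply(tp$chains, function(r) remap[r])
  tp$as_ends <- remap[tp$as_ends]
  tp$as_partner <- ifelse(tp$as_partner > 0, remap[tp$as_partner], 0L)
  particle_system(s$pos[keep, , drop = FALSE], s$type[keep],
                  s$orient[keep, , drop = FALSE], s$geometry, tp, s$sigma_nm)
}

#' Attach actin-anchored proteins to the rings
#'
#' Places one 5-nm membrane protein radially outward of selected actin
#' beads at the anchoring rest length (20 nm) and ties it to its bead
#' with a spring of stiffness \code{k0}. These proteins anchor the
#' bilayer to the actin rings and act as obstacles for outer-leaflet
#' diffusion. Lipids overlapping a new anchor are removed.
#'
#' @param system a \code{particle_system} containing rings (and usually a
#'   cylindrical bilayer).
#' @param per_ring anchors per ring, evenly spaced around it.
#' @param ff force field.
#' @return the augmented system.
#' @export
add_actin_anchors <- function(system, per_ring = 6,
                              ff = default_forcefield()) {
  stopifnot(inherits(system, "particle_system"))
  rings <- system$topology$rings
  if (length(rings) == 0) stop("system has no actin rings")
  s <- system
  for (ring in rings) {
    nr <- length(ring)
    picks <- ring[1 + (seq_len(per_ring) - 1) * (nr %/% per_ring)]
    for (ai in picks) {
      ap <- s$pos[ai, ]
      rad <- c(ap[1], ap[2], 0)
      rad <- rad / sqrt(sum(rad^2))
      gp <- ap + rad * ff$req_ag
      s <- carve_lipids(s, gp, ff$req_lg * 0.95)
      prot <- particle_system(matrix(gp, 1, 3),
                              PARTICLE_TYPES[["actin_anchor_protein"]],
                              matrix(rad, 1, 3), s$geometry,
                              sigma_nm = s$sigma_nm)
      gi <- nrow(s$pos) + 1L
      s <- merge_systems(s, prot)
      s$topology$bonds <- rbind(s$topology$bonds,
                                c(gi, ai, ff$k0, ff$req_ag))
    }
  }
  s
}

#' Attach ankyrin-linked channels to the spectrin chains
#'
#' Adds one anchored transmembrane protein per spectrin chain,
#' representing a sodium channel bound through ankyrin to the 20th bead
#' of the tetramer: the channel sits at the bilayer mid-surface radially
#' outward of that bead and is tied to it by a spring of stiffness
#' \code{k0} with the 15 nm ankyrin-complex rest length. Overlapping
#' lipids are removed.
#'
#' @param system a \code{particle_system} with spectrin chains (and
#'   usually a cylindrical bilayer).
#' @param ff force field.
#' @return the augmented system.
#' @export
add_ankyrin_channels <- function(system, ff = default_forcefield()) {
  stopifnot(inherits(system, "particle_system"))
  chains <- system$topology$chains
  if (length(chains) == 0) stop("system has no spectrin chains")
  s <- system
  inner <- s$type == PARTICLE_TYPES[["lipid_inner"]]
  r_mid <- if (any(inner))
    mean(sqrt(s$pos[inner, 1]^2 + s$pos[inner, 2]^2)) + ff$rcut_layer / 2
  else NA_real_
  for (chain in chains) {
    if (length(chain) < 20) stop("chain too short for an ankyrin site")
    bi <- chain[20]
    bp <- s$pos[bi, ]
    rad <- c(bp[1], bp[2], 0)
    rad <- rad / sqrt(sum(rad^2))
    dist <- if (is.na(r_mid)) ff$req_sk else
      max(r_mid - sqrt(bp[1]^2 + bp[2]^2), ff$req_sk)
    tp <- bp + rad * dist
    s <- carve_lipids(s, tp, ff$req_lp * 0.95)
    prot <- particle_system(matrix(tp, 1, 3),
                            PARTICLE_TYPES[["TMP_anchored"]],
                            matrix(rad, 1, 3), s$geometry,
                            sigma_nm = s$sigma_nm)
    ti <- nrow(s$pos) + 1L
    s <- merge_systems(s, prot)
    s$topology$bonds <- rbind(s$topology$bonds,
                              c(ti, bi, ff$k0, ff$req_sk))
  }
  s
}

carve_lipids <- function(s, at, clear) {
  lip <- which(s$type %in% c(PARTICLE_TYPES[["lipid_outer"]],
                             PARTICLE_TYPES[["lipid_inner"]]))
  if (length(lip) == 0) return(s)
  d <- sweep(s$pos[lip, , drop = FALSE], 2, at)
  for (dim in 1:3)
    if (periodic_dim(s$geometry$kind, dim)) {
      bx <- s$geometry$box[dim]
      d[, dim] <- d[, dim] - bx * round(d[, dim] / bx)
    }
  drop_particles(s, lip[sqrt(rowSums(d^2)) < clear])
}

#' Assemble a full axon segment
#'
#' Composes the periodic skeleton ([build_apms()]), a cylindrical
#' two-leaflet bilayer whose inner leaflet clears the rings by the
#' actin-anchor bond length, actin-anchored proteins, ankyrin-linked
#' channels, and optionally mobile or anchored transmembrane and
#' monotopic proteins at a given surface density. With the default
#' full-size geometry (39-bead rings, 185 nm period) the result is the
#' production-scale system (hundreds of thousands of lipids); reduced
#' fixtures are obtained by shrinking the ring and its period together
#' with a force field whose actin steric range matches the smaller beads.
#'
#' @inheritParams build_apms
#' @param anchors_per_ring actin-anchored proteins per ring.
#' @param ankyrin add one ankyrin-linked channel per spectrin chain.
#' @param pprc mobile/anchored TMPs per corral
#'   (corral count = \code{chains_per_ring * n_rings}).
#' @param anchored tether the pprc TMPs to their initial positions.
#' @param ff force field.
#' @return a \code{particle_system}.
#' @export
build_axon <- function(n_rings = 3, ring_spacing_nm = 185,
                       chains_per_ring = 6,
                       ring_particles = 39, particle_diameter_nm = 35,
                       chain_particles = 41, chain_spacing_nm = 5,
                       anchors_per_ring = 6, ankyrin = TRUE,
                       pprc = 0, anchored = FALSE,
                       ff = default_forcefield()) {
  s <- ff$units$sigma_nm
  sk <- build_apms(n_rings, ring_spacing_nm, chains_per_ring,
                   ring_particles, particle_diameter_nm,
                   chain_particles, chain_spacing_nm, ff)
  ring_radius_nm <- particle_diameter_nm / (2 * sin(pi / ring_particles))
  radius_nm <- ring_radius_nm + ff$req_ag * s
  bl <- build_bilayer("cylinder", radius_nm = radius_nm,
                      axial_length_sigma = sk$geometry$box[3], ff = ff)
  sys <- merge_systems(sk, bl)
  if (anchors_per_ring > 0)
    sys <- add_actin_anchors(sys, anchors_per_ring, ff)
  if (ankyrin) sys <- add_ankyrin_channels(sys, ff)
  if (pprc > 0)
    sys <- place_proteins(sys, pprc = pprc,
                          n_corrals = chains_per_ring * n_rings,
                          anchored = anchored, ff = ff)
  sys
}
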