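# Synthetic fixtures: deterministic toy structures, displaced conformers at
# a prescribed RMSD, simulated maps with noise, half-map pairs, and
# spatially varying local-resolution volumes.  All generators are pure
# functions of (spec, seed).

#' Specification of the toy two-domain structure
#'
#' Two idealised three-helix domains joined by a short extended linker.
#' Helix geometry uses standard C-alpha parameters (2.3 A radius, 1.5 A
#' rise, 100 degrees twist per residue, about 3.8 A between consecutive
#' beads).
#'
#' @param residues_per_domain residues in each domain (>= 20; must divide
#'   into the helix count).
#' @param n_helices helices per domain.
#' @param helix_spacing distance between neighbouring helix axes (A).
#' @param linker_residues beads in the inter-domain linker.
#' @param hinge_angle inter-domain hinge angle of the reference geometry
#'   (degrees).
#' @param mass bead mass (amu); the coupling weight equals the mass.
#' @param seed generator seed (the reference construction itself is
#'   deterministic; the seed labels derived fixtures).
#' @return A list of class \code{toy_spec}.
#' @export
toy_spec <- function(residues_per_domain = 60, n_helices = 3,
                     helix_spacing = 14, linker_residues = 4,
                     hinge_angle = 0, mass = 110, seed = 1) {
  if (residues_per_domain < 20)
    stop("need at least 20 residues per domain")
  if (residues_per_domain %% n_helices != 0)
    stop("`residues_per_domain` must be divisible by `n_helices`")
  if (helix_spacing <= 0 || linker_residues < 1 || mass <= 0)
    stop("invalid toy geometry parameters")
  sp <- as.list(environment())
  class(sp) <- "toy_spec"
  sp
}

# ideal helix C-alpha trace: n beads, axis +z from z0, phase offset
helix_trace <- function(n, x0, y0, z0, down = FALSE, radius = 2.3,
                        rise = 1.5, twist = 100 * pi / 180) {
  t <- seq_len(n) - 1
  z <- z0 + (if (down) -1 else 1) * rise * t
  cbind(x0 + radius * cos(twist * t), y0 + radius * sin(twist * t), z)
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle); C <- 1 - c
  matrix(c(a[1]^2 * C + c, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
           a[2] * a[1] * C + a[3] * s, a[2]^2 * C + c, a[2] * a[3] * C - a[1] * s,
           a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3]^2 * C + c),
         nrow = 3, byrow = TRUE)
}

# one three-helix (up-down-up) domain starting at the origin
domain_trace <- function(spec) {
  per <- spec$residues_per_domain / spec$n_helices
  height <- (per - 1) * 1.5
  xyz <- NULL
  for (h in seq_len(spec$n_helices)) {
    down <- h %% 2 == 0
    xyz <- rbind(xyz, helix_trace(per, x0 = (h - 1) * spec$helix_spacing,
                                  y0 = 0, z0 = if (down) height else 0,
                                  down = down))
  }
  xyz
}

#' Build the toy two-domain structure
#'
#' Deterministic construction: domain A at the origin, a short extended
#' linker, then domain B rotated by the spec's hinge angle about the y axis
#' through the linker midpoint.  Helix beads are labelled \code{helix},
#' linker beads \code{coil}.
#'
#' @param spec a \code{\link{toy_spec}}.
#' @return A \code{\link{cg_structure}} with attribute \code{"domains"}
#'   (index lists for domain A, linker, and domain B).
#' @export
make_toy_dimer <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  A <- domain_trace(spec)
  nA <- nrow(A)
  top <- A[nA, ]
  # extended linker continuing along +z
  L <- cbind(rep(top[1], spec$linker_residues), rep(top[2], spec$linker_residues),
             top[3] + 3.5 * seq_len(spec$linker_residues))
  B <- domain_trace(spec)
  # place B beyond the linker, mirrored back along the helix bundle
  B <- sweep(B, 2, c(top[1], top[2] + spec$helix_spacing / 2,
                     L[nrow(L), 3] + 3.5), "+")
  if (spec$hinge_angle != 0) {
    R <- rotation_matrix(c(0, 1, 0), spec$hinge_angle * pi / 180)
    pivot <- L[nrow(L), ]
    B <- sweep(sweep(B, 2, pivot) %*% t(R), 2, pivot, "+")
  }
  xyz <- rbind(A, L, B)
  n <- nrow(xyz)
  ss <- c(rep("helix", nA), rep("coil", spec$linker_residues), rep("helix", nA))
  # mark helix-helix turn beads as coil so SS segments stay per-helix
  per <- spec$residues_per_domain / spec$n_helices
  turn <- as.vector(outer(c(0, 1), per * seq_len(spec$n_helices - 1), "+"))
  ss[turn] <- "coil"
  ss[nA + spec$linker_residues + turn] <- "coil"
  out <- cg_structure(data.frame(
    id = seq_len(n), resid = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = spec$mass, weight = spec$mass, ss = ss,
    stringsAsFactors = FALSE))
  attr(out, "domains") <- list(A = seq_len(nA),
                               linker = nA + seq_len(spec$linker_residues),
                               B = nA + spec$linker_residues + seq_len(nA))
  attr(out, "spec") <- spec
  out
}

# indices of a displacement region given a structure and a region name or
# an explicit index vector
region_indices <- function(structure, region) {
  if (is.numeric(region)) return(as.integer(region))
  dom <- attr(structure, "domains")
  if (is.null(dom) || !region %in% names(dom))
    stop("unknown region: ", region)
  dom[[region]]
}

#' Displace a conformer to a prescribed RMSD
#'
#' Produces a search model at a controlled deviation from a reference
#' structure, emulating hinge motions, thermal unfolding snapshots and
#' locally displaced subunits.  Modes:
#' \describe{
#'   \item{hinge}{rigid rotation of domain B (plus linker relaxation) about
#'     a seed-dependent axis through the linker end; the rotation angle is
#'     solved by bisection so the achieved RMSD is within 0.2 A of the
#'     target.}
#'   \item{heat}{high-temperature (1000 K) unbiased dynamics; the first
#'     recorded snapshot within the tolerance band (after a brief
#'     minimisation to restore bonded geometry) is returned.}
#'   \item{local}{rigid rotation confined to \code{region}; the amplitude
#'     is solved by bisection on the in-region RMSD, leaving the rest of
#'     the structure in place.}
#' }
#'
#' @param structure the reference \code{\link{cg_structure}}.
#' @param target_rmsd desired RMSD in Angstrom (>= 0); for mode
#'   \code{local} this is the in-region RMSD.
#' @param mode one of \code{"hinge"}, \code{"heat"}, \code{"local"}.
#' @param seed RNG seed (axis directions, thermal noise).
#' @param region region name (\code{"A"}, \code{"B"}) or bead indices;
#'   required for mode \code{local}.
#' @return A displaced \code{\link{cg_structure}}.
#' @export
displace_conformer <- function(structure, target_rmsd,
                               mode = c("hinge", "heat", "local"),
                               seed = 1, region = NULL) {
  mode <- match.arg(mode)
  if (target_rmsd < 0) stop("`target_rmsd` must be >= 0")
  if (target_rmsd == 0) return(structure)
  set.seed(seed)
  topo <- build_topology(structure)
  restr <- assign_ss_restraints(structure)
  xyz0 <- bead_coords(structure)
  tol <- 0.2

  relax <- function(xyz, steps = 120) {
    bead_coords(minimize(set_coords(structure, xyz), topo, restr,
                         steps = steps))
  }

  if (mode == "heat") {
    cfg <- sim_config(temperature = 1000, seed = seed, steps = 500,
                      stride = 10, friction_ps = 5)
    cur <- structure
    vel <- NULL
    for (chunk in 1:200) {
      tr <- run_dynamics(cur, topo, restr, NULL, cfg, velocities = vel,
                         set_seed = FALSE)
      cur <- tr$structure
      vel <- tr$velocities
      for (f in seq_len(dim(tr$frames)[1])) {
        cand <- relax(matrix(tr$frames[f, , ], ncol = 3))
        r <- rmsd(cand, xyz0)
        if (abs(r - target_rmsd) <= tol)
          return(set_coords(structure, cand))
        if (r > target_rmsd + tol) break
      }
    }
    stop("heating did not reach the target RMSD within the step budget")
  }

  idx <- if (mode == "hinge") {
    region_indices(structure, "B")
  } else {
    if (is.null(region)) stop("mode 'local' requires `region`")
    region_indices(structure, region)
  }
  dom <- attr(structure, "domains")
  if (mode == "hinge" && !is.null(dom)) {
    pivot <- xyz0[dom$linker[length(dom$linker)], ]
    # bending hinge: rotation axis perpendicular to the inter-domain
    # direction (a twist about that direction is not a hinge motion);
    # the seed picks the azimuth of the bending axis
    inter <- colMeans(xyz0[dom$B, , drop = FALSE]) -
      colMeans(xyz0[dom$A, , drop = FALSE])
    inter <- inter / sqrt(sum(inter^2))
    perp <- cross3(inter, c(1, 0, 0))
    if (sum(perp^2) < 1e-6) perp <- cross3(inter, c(0, 1, 0))
    perp <- perp / sqrt(sum(perp^2))
    perp2 <- cross3(inter, perp)
    psi <- runif(1, 0, 2 * pi)
    axis <- cos(psi) * perp + sin(psi) * perp2
  } else {
    pivot <- colMeans(xyz0[idx, , drop = FALSE])
    axis <- rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
  }

  measure <- function(angle) {
    R <- rotation_matrix(axis, angle)
    xyz <- xyz0
    xyz[idx, ] <- sweep(sweep(xyz0[idx, , drop = FALSE], 2, pivot) %*% t(R),
                        2, pivot, "+")
    xyz <- relax(xyz)
    if (mode == "local") {
      r <- rmsd(xyz[idx, , drop = FALSE], xyz0[idx, , drop = FALSE])
    } else {
      r <- rmsd(xyz, xyz0)
    }
    list(rmsd = r, xyz = xyz)
  }
  hi <- pi
  top <- measure(hi)
  if (top$rmsd + tol < target_rmsd)
    stop(sprintf("target RMSD %.1f A unreachable; maximum achievable about %.1f A",
                 target_rmsd, top$rmsd))
  lo <- 0
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    m <- measure(mid)
    if (abs(m$rmsd - target_rmsd) <= tol)
      return(set_coords(structure, m$xyz))
    if (m$rmsd < target_rmsd) lo <- mid else hi <- mid
  }
  stop("bisection failed to bracket the target RMSD")
}

#' Simulated half-map pair
#'
#' Renders the structure once and adds two independent Gaussian noise
#' fields, emulating reconstructions from independent data halves.
#'
#' @param structure a \code{\link{cg_structure}}.
#' @param resolution rendering resolution (A).
#' @param voxel voxel spacing (A).
#' @param noise_sd standard deviation of the voxel noise (density units,
#'   >= 0).
#' @param seed RNG seed for the two noise fields.
#' @param pad grid padding (A).
#' @return List with \code{half1}, \code{half2}, and the noise-free
#'   \code{signal} map.
#' @export
make_halfmaps <- function(structure, resolution = 3, voxel = 1, noise_sd = 0,
                          seed = 1, pad = 8) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  signal <- render_map(structure, resolution, voxel, pad)
  set.seed(seed)
  d <- dim(signal$values)
  n1 <- array(rnorm(prod(d), 0, noise_sd), d)
  n2 <- array(rnorm(prod(d), 0, noise_sd), d)
  list(half1 = density_map(signal$values + n1, signal$origin, signal$voxel),
       half2 = density_map(signal$values + n2, signal$origin, signal$voxel),
       signal = signal)
}

#' Map with spatially varying resolution plus its local-resolution volume
#'
#' Renders the structure with per-bead Gaussian widths drawn from a radial
#' resolution profile (a sharp core degrading linearly to a blurred
#' periphery between two radii around the structure's centroid) and returns
#' a companion volume storing the nominal local resolution at every voxel.
#'
#' @param structure a \code{\link{cg_structure}}.
#' @param core_resolution,shell_resolution resolutions (A) of the core and
#'   the periphery; the core must be sharper (smaller).
#' @param voxel voxel spacing (A).
#' @param core_radius,shell_radius radii (A) bounding the linear
#'   transition; defaults are fractions of the structure's maximal centroid
#'   distance.
#' @param pad grid padding (A).
#' @return List with \code{map} and \code{localres}
#'   (\code{\link{density_map}} objects on the same grid).
#' @export
make_localres_map <- function(structure, core_resolution = 3,
                              shell_resolution = 6, voxel = 1,
                              core_radius = NULL, shell_radius = NULL,
                              pad = 8) {
  if (core_resolution > shell_resolution)
    stop("inverted resolution profile: the core must not be blurrier than the shell")
  xyz <- bead_coords(structure)
  centre <- colMeans(xyz)
  rad <- sqrt(rowSums(sweep(xyz, 2, centre)^2))
  rmax <- max(rad)
  if (is.null(core_radius)) core_radius <- 0.45 * rmax
  if (is.null(shell_radius)) shell_radius <- 0.55 * rmax
  if (core_radius >= shell_radius)
    stop("`core_radius` must be smaller than `shell_radius`")
  profile <- function(r) {
    t <- pmin(pmax((r - core_radius) / (shell_radius - core_radius), 0), 1)
    core_resolution + t * (shell_resolution - core_resolution)
  }
  widths <- profile(rad) / FWHM_FACTOR
  map <- render_map(structure, core_resolution, voxel, pad, widths = widths)
  d <- dim(map$values)
  ax <- lapply(1:3, function(a) axis_coords(map, a))
  r2 <- outer(outer((ax[[1]] - centre[1])^2, (ax[[2]] - centre[2])^2, "+"),
              (ax[[3]] - centre[3])^2, "+")
  localres <- density_map(array(profile(sqrt(r2)), d), map$origin, map$voxel)
  list(map = map, localres = localres)
}

#' Write the packaged fixture set to a directory
#'
#' Emits target and search structures, the target map, a half-map pair, a
#' local-resolution volume and a JSON manifest recording every parameter.
#'
#' @param dir output directory (created if needed).
#' @param seed fixture seed.
#' @param target_rmsd search-model displacement (A).
#' @param resolution map resolution (A).
#' @param noise_sd half-map noise level.
#' @return Invisibly, the manifest list.
#' @export
make_fixture <- function(dir, seed = 1, target_rmsd = 7, resolution = 3,
                         noise_sd = 0.002) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- toy_spec(seed = seed)
  target <- make_toy_dimer(spec)
  search <- displace_conformer(target, target_rmsd, "hinge", seed = seed + 1)
  map <- render_map(target, resolution)
  halves <- make_halfmaps(target, resolution, noise_sd = noise_sd,
                          seed = seed + 2)
  lr <- make_localres_map(target)
  write_structure(target, file.path(dir, "target.pdb"))
  write_structure(search, file.path(dir, "search.pdb"))
  write_map(map, file.path(dir, "map.mrc"))
  write_map(halves$half1, file.path(dir, "halfmap1.mrc"))
  write_map(halves$half2, file.path(dir, "halfmap2.mrc"))
  write_map(lr$localres, file.path(dir, "localres.mrc"))
  manifest <- list(seed = seed, target_rmsd = target_rmsd,
                   achieved_rmsd = rmsd(search, target),
                   resolution = resolution, noise_sd = noise_sd,
                   residues_per_domain = spec$residues_per_domain,
                   n_beads = nrow(target$beads),
                   package_version = as.character(utils::packageVersion("mapfit")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
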