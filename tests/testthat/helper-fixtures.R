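# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# small toy (46 beads) for fast unit tests
small_toy <- function() {
  cached("small_toy", function() {
    make_toy_dimer(toy_spec(residues_per_domain = 21, n_helices = 3))
  })
}

small_map <- function() {
  cached("small_map", function() render_map(small_toy(), 3))
}

# the packaged study fixture (124 beads) used by the acceptance checks
study_target <- function() cached("study_target", function() {
  make_toy_dimer(toy_spec())
})

study_map <- function() cached("study_map", function() {
  render_map(study_target(), 3)
})

study_search <- function() cached("study_search", function() {
  displace_conformer(study_target(), 7, "hinge", seed = 2)
})

# a straight 5-bead chain: convenient for counting and 1-D checks
straight_chain <- function(n = 5, spacing = 3.8) {
  cg_structure(data.frame(
    id = seq_len(n), resid = seq_len(n), chain = "A",
    x = spacing * (seq_len(n) - 1), y = 0, z = 0,
    mass = 110, weight = 110, ss = "coil"))
}

# a slightly zig-zagged chain (angles/dihedrals well-defined) for force tests
zigzag_chain <- function(n = 8, spacing = 3.8) {
  set.seed(42)
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    step <- c(spacing, 0, 0) + rnorm(3, 0, 0.9)
    xyz[i, ] <- xyz[i - 1, ] + step * spacing / sqrt(sum(step^2))
  }
  cg_structure(data.frame(
    id = seq_len(n), resid = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = 110, weight = 110, ss = "coil"))
}

KB_internal <- function() 0.0019872

scale_potential_1 <- function(pot) mapfit:::scale_potential(pot, 1.0)

# 1-D double-well fitting potential (x axis), harmonically rimmed so a
# diffusing bead cannot reach the flat plateau outside the grid
double_well_potential <- function(dU, depth = 2) {
  x <- seq(-16, 16, by = 0.5)
  y <- seq(-4, 4, by = 1)
  vx <- 3 - depth * exp(-(x + 5)^2 / 8) - (depth + dU) * exp(-(x - 5)^2 / 8) +
    0.02 * x^2
  conf <- 0.3 * y^2
  vals <- outer(outer(vx, conf, "+"), conf, "+")
  pot <- list(values = vals, origin = c(-16, -4, -4), voxel = c(0.5, 1, 1),
              zeta = 8, phi_thr = 0)
  class(pot) <- "mdff_potential"
  pot
}

# central finite-difference forces for an arbitrary energy closure
fd_forces <- function(energy_fn, X, h = 1e-5) {
  F <- matrix(0, nrow(X), 3)
  for (i in seq_len(nrow(X))) {
    for (a in 1:3) {
      Xp <- X; Xp[i, a] <- Xp[i, a] + h
      Xm <- X; Xm[i, a] <- Xm[i, a] - h
      F[i, a] <- -(energy_fn(Xp) - energy_fn(Xm)) / (2 * h)
    }
  }
  F
}

max_rel_force_error <- function(Fa, Fd) {
  scale <- max(abs(Fa), 1)
  max(abs(Fa - Fd)) / scale
}

# topology with a single term class retained (others emptied)
only_term <- function(topo, keep) {
  for (nm in c("bonds", "angles", "dihedrals", "contacts")) {
    if (nm != keep) topo[[nm]] <- topo[[nm]][0, , drop = FALSE]
  }
  if (keep != "ev") topo$ev_pairs <- topo$ev_pairs[0, , drop = FALSE]
  topo
}

# a topology with no internal terms, for single-bead map tests
bead_topology <- function() {
  topo <- list(bonds = matrix(numeric(0), ncol = 4),
               angles = matrix(numeric(0), ncol = 5),
               dihedrals = matrix(numeric(0), ncol = 6),
               contacts = matrix(numeric(0), ncol = 4),
               ev_pairs = matrix(integer(0), ncol = 2),
               ev_sigma = 1, ev_eps = 0, ev_cutoff = 1, n_beads = 1)
  class(topo) <- "cg_topology"
  topo
}

# single bead at position x on the x axis, unit mass and weight
bead_at_x <- function(x) {
  cg_structure(data.frame(id = 1, resid = 1, chain = "A", x = x, y = 0, z = 0,
                          mass = 1, weight = 1))
}

# linear-ramp fitting potential V(x) = slope * x: gives exactly
# controllable Metropolis deltas for single-bead replicas
ramp_potential <- function(slope, zeta = 1) {
  vx <- pmin(slope * (0:20), zeta)
  pot <- list(values = outer(outer(vx, rep(1, 3)), rep(1, 3)),
              origin = c(0, -1, -1), voxel = c(1, 1, 1), zeta = zeta,
              phi_thr = 0)
  class(pot) <- "mdff_potential"
  pot
}
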