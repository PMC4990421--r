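test_that("analytic forces match finite differences for every energy term", {
  s <- small_toy()
  n <- nrow(s$beads)
  topo <- build_topology(s)
  restr <- assign_ss_restraints(s)
  set.seed(21)
  X <- bead_coords(s) + matrix(rnorm(3 * n, 0, 0.25), ncol = 3)
  w <- s$beads$weight

  # excluded-volume pairs start beyond the cutoff by construction, so that
  # term is probed on a uniformly compressed state
  Xev <- sweep(sweep(X, 2, colMeans(X)) * 0.6, 2, colMeans(X), "+")
  for (term in c("bonds", "angles", "dihedrals", "contacts", "ev")) {
    t2 <- only_term(topo, term)
    Xt <- if (term == "ev") Xev else X
    en <- function(Y) energy_forces(Y, t2, weights = w)$U_total
    Fa <- energy_forces(Xt, t2, weights = w)$forces
    expect_gt(max(abs(Fa)), 0) # the term is actually exercised
    expect_lt(max_rel_force_error(Fa, fd_forces(en, Xt)), 1e-4)
  }
  # secondary-structure restraints alone
  t0 <- only_term(topo, "none")
  en <- function(Y) energy_forces(Y, t0, restr, weights = w)$U_total
  Fa <- energy_forces(X, t0, restr, weights = w)$forces
  expect_gt(max(abs(Fa)), 0)
  expect_lt(max_rel_force_error(Fa, fd_forces(en, X)), 1e-4)

  # map coupling alone, beads kept away from voxel-cell faces where the
  # trilinear interpolant's gradient jumps
  z <- zigzag_chain(8)
  m <- render_map(z, 3, voxel = 1, pad = 6)
  pot <- potential_from_map(m, 0.3)
  set.seed(22)
  Xz <- bead_coords(z) + matrix(rnorm(24, 0, 0.35), ncol = 3)
  Xz <- floor(Xz) + 0.5 + matrix(runif(24, -0.3, 0.3), ncol = 3)
  tz <- only_term(build_topology(z), "none")
  wz <- z$beads$weight
  en <- function(Y) energy_forces(Y, tz, potential = pot, weights = wz)$U_total
  Fa <- energy_forces(Xz, tz, potential = pot, weights = wz)$forces
  expect_gt(max(abs(Fa)), 0)
  expect_lt(max_rel_force_error(Fa, fd_forces(en, Xz)), 1e-4)

  # the full potential on the bonded + restrained zigzag
  tzf <- build_topology(z)
  rz <- assign_ss_restraints(z, data.frame(chain = "A", from = 1, to = 8))
  en <- function(Y) energy_forces(Y, tzf, rz, pot, weights = wz)$U_total
  Fa <- energy_forces(Xz, tzf, rz, pot, weights = wz)$forces
  expect_lt(max_rel_force_error(Fa, fd_forces(en, Xz)), 1e-4)
})

test_that("map coupling has a flat plateau and respects zeta = 0", {
  s <- straight_chain(3)
  topo <- build_topology(s)
  m <- small_map()
  pot <- potential_from_map(m, 0.3)
  # beads far outside the grid: V = zeta each, zero force
  X <- matrix(rep(c(500, 500, 500), 3), ncol = 3, byrow = TRUE)
  ef <- energy_forces(X, only_term(topo, "none"), potential = pot,
                      weights = c(1, 1, 1))
  expect_equal(ef$U_em, 3 * 0.3)
  expect_equal(max(abs(ef$forces)), 0)
  # zeta = 0 potential leaves unbiased forces untouched
  pot0 <- potential_from_map(m, 0)
  X2 <- bead_coords(s)
  a <- energy_forces(X2, topo, potential = pot0, weights = s$beads$weight)
  b <- energy_forces(X2, topo, weights = s$beads$weight)
  expect_equal(a$U_em, 0)
  expect_identical(a$forces, b$forces)
  expect_error(energy_forces(matrix(c(NA, 1, 1), 1), topo), "finite")
})

test_that("minimize relaxes a stretched bond to its equilibrium length", {
  s <- straight_chain(2)
  topo <- build_topology(straight_chain(3)) # need >= 3 beads to build
  s3 <- straight_chain(3)
  stretched <- set_coords(s3, rbind(c(0, 0, 0), c(5.2, 0, 0), c(9.0, 0, 0)))
  out <- minimize(stretched, topo, steps = 2000)
  xyz <- bead_coords(out)
  d12 <- sqrt(sum((xyz[1, ] - xyz[2, ])^2))
  expect_equal(d12, 3.8, tolerance = 1e-3)
  expect_error(minimize(s3, topo, steps = 0), ">= 1")
  # an already-minimal structure stays put
  again <- minimize(s3, topo, steps = 100)
  expect_equal(bead_coords(again), bead_coords(s3), tolerance = 1e-9)
})

test_that("zero-friction dynamics conserve energy (NVE limit)", {
  s <- zigzag_chain(6)
  topo <- build_topology(s)
  cfg <- sim_config(timestep_fs = 1, friction_ps = 0, seed = 5, steps = 10000,
                    stride = 50)
  set.seed(5)
  vel <- matrix(rnorm(18, 0, sqrt(KB_internal() * 300 / 110)), ncol = 3)
  tr <- run_dynamics(s, topo, config = cfg, velocities = vel)
  etot <- tr$energies$U_total + tr$energies$E_kin
  expect_lt(diff(range(etot)) / max(abs(etot)), 1e-4)
})

test_that("trajectories are bitwise reproducible for a fixed seed", {
  s <- small_toy()
  topo <- build_topology(s)
  pot <- potential_from_map(small_map(), 0.3)
  cfg <- sim_config(seed = 9, steps = 400, stride = 10)
  t1 <- run_dynamics(s, topo, potential = pot, config = cfg)
  t2 <- run_dynamics(s, topo, potential = pot, config = cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energies, t2$energies)
})

test_that("harmonic dimer fluctuations satisfy equipartition", {
  # two beads, one bond of stiffness k: <(d - d0)^2> = kBT / k
  s <- straight_chain(3)
  topo <- build_topology(s)
  topo$angles <- topo$angles[0, , drop = FALSE]
  topo$dihedrals <- topo$dihedrals[0, , drop = FALSE]
  k <- topo$bonds[1, 4]
  cfg <- sim_config(timestep_fs = 4, friction_ps = 5, temperature = 300,
                    seed = 13, steps = 120000, stride = 20)
  tr <- run_dynamics(s, topo, config = cfg)
  d <- apply(tr$frames, 1, function(f) {
    sqrt(sum((f[1, ] - f[2, ])^2))
  })
  d <- d[-(1:500)]
  expect_equal(mean((d - 3.8)^2), KB_internal() * 300 / k, tolerance = 0.05)
})

test_that("Langevin sampling reproduces Boltzmann well occupancies", {
  # single bead in a 1-D double-well map potential: occupancy of the two
  # wells follows the Boltzmann ratio of their depths (the wells share the
  # same shape, so entropic corrections cancel)
  dU <- 0.55 # kcal/mol depth difference
  pot <- double_well_potential(dU)
  bead <- cg_structure(data.frame(id = 1, resid = 1, chain = "A",
                                  x = 0, y = 0, z = 0, mass = 20, weight = 1))
  topo <- list(bonds = matrix(numeric(0), ncol = 4),
               angles = matrix(numeric(0), ncol = 5),
               dihedrals = matrix(numeric(0), ncol = 6),
               contacts = matrix(numeric(0), ncol = 4),
               ev_pairs = matrix(integer(0), ncol = 2),
               ev_sigma = 1, ev_eps = 0, ev_cutoff = 1, n_beads = 1)
  class(topo) <- "cg_topology"
  cfg <- sim_config(timestep_fs = 8, friction_ps = 2, temperature = 300,
                    seed = 4, steps = 400000, stride = 40)
  tr <- run_dynamics(bead, topo, potential = pot, config = cfg)
  xs <- tr$frames[, 1, 1]
  xs <- xs[-(1:1000)]
  occ_right <- mean(xs > 0)
  ratio <- occ_right / (1 - occ_right)
  expected <- exp(dU / (KB_internal() * 300))
  n_visits <- sum(abs(diff(xs > 0)) > 0) # well-crossing count
  se <- 3 / sqrt(max(n_visits, 1))
  expect_gt(ratio, 1)
  expect_lt(abs(log(ratio) - log(expected)), max(se, 0.5))
})

test_that("energy differences between maps reduce to the map term", {
  s <- small_toy()
  topo <- build_topology(s)
  restr <- assign_ss_restraints(s)
  m <- small_map()
  p1 <- potential_from_map(m, 0.3)
  p2 <- potential_from_map(gaussian_blur(m, 2), 0.3)
  X <- bead_coords(s)
  w <- s$beads$weight
  e1 <- energy_forces(X, topo, restr, p1, w)
  e2 <- energy_forces(X, topo, restr, p2, w)
  expect_equal(e1$U_total - e2$U_total, e1$U_em - e2$U_em, tolerance = 1e-10)
  expect_equal(total_energy_in_map(X, topo, restr, p1, w), e1$U_total)
  # empty coupled selection: E reduces to U_MD + U_SS
  e0 <- energy_forces(X, topo, restr, p1, weights = rep(0, nrow(X)))
  expect_equal(e0$U_em, 0)
  expect_equal(e0$U_total, e0$U_md + e0$U_ss)
})

test_that("anneal_refine is idempotent on an already re-refined structure", {
  s <- small_toy()
  topo <- build_topology(s)
  restr <- assign_ss_restraints(s)
  pot <- potential_from_map(small_map(), 0.3)
  cfg <- sim_config(seed = 2, anneal_ramp_steps = 1000, anneal_hold_steps = 600)
  ref <- anneal_refine(s, topo, restr, pot, cfg)
  out <- anneal_refine(ref, topo, restr, pot, cfg)
  expect_lt(rmsd(out, ref), 0.1)
  # and the total energy never rises across the re-refinement
  u_ref <- total_energy_in_map(bead_coords(ref), topo, restr,
                               scale_potential_1(pot), s$beads$weight)
  u_out <- total_energy_in_map(bead_coords(out), topo, restr,
                               scale_potential_1(pot), s$beads$weight)
  expect_lte(u_out, u_ref + 1e-6)
})

test_that("a zero-length ramp reduces annealing to a quench/minimisation", {
  s <- small_toy()
  topo <- build_topology(s)
  restr <- assign_ss_restraints(s)
  pot <- potential_from_map(small_map(), 0.3)
  start <- set_coords(s, bead_coords(s) +
                        matrix(rnorm(nrow(s$beads) * 3, 0, 0.3), ncol = 3))
  cfg <- sim_config(seed = 2, anneal_ramp_steps = 0, anneal_hold_steps = 0)
  quench <- anneal_refine(start, topo, restr, pot, cfg)
  direct_min <- minimize(start, topo, restr, scale_potential_1(pot), steps = 500)
  expect_equal(bead_coords(quench), bead_coords(direct_min), tolerance = 1e-6)
})
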