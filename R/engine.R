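# R-side interface to the compiled dynamics kernels: configuration,
# energy/force evaluation, minimisation, Langevin dynamics with temperature
# schedules, stationarity detection and annealed re-refinement.

#' Simulation configuration
#'
#' @param timestep_fs integrator timestep in femtoseconds.
#' @param friction_ps Langevin friction in 1/ps (0 gives NVE velocity
#'   Verlet).
#' @param temperature either a scalar temperature in K or a two-column
#'   matrix / data frame of (step, K) pairs interpolated linearly into a
#'   per-step schedule.
#' @param zeta map-coupling scale in kcal/mol.
#' @param coupled integer indices of map-coupled beads (default all).
#' @param seed RNG seed; a fixed seed gives a bitwise-reproducible
#'   trajectory.
#' @param steps number of integrator steps for a plain dynamics run.
#' @param stride trajectory recording stride in steps.
#' @param max_stage_steps hard cap on steps per fitting stage.
#' @param window stationarity window in recorded frames.
#' @param stationary_tol stationarity tolerance (A) on the window range of
#'   the frame-to-window-mean RMSD series.
#' @param thr_percentile percentile (of positive voxels) defining the map
#'   noise threshold.
#' @param resolution nominal map resolution (A) used when rendering the
#'   model for correlation metrics.
#' @param exchange_interval steps between replica-exchange attempts.
#' @param anneal_ramp_steps,anneal_hold_steps length of the 300 K -> 0 K
#'   ramp and the 0 K hold of the re-refinement schedule.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(timestep_fs = 5, friction_ps = 1, temperature = 300,
                       zeta = 0.3, coupled = NULL, seed = 1,
                       steps = 10000, stride = 10,
                       max_stage_steps = 12000, window = 200,
                       stationary_tol = 0.1, thr_percentile = 0.05,
                       resolution = 3, exchange_interval = 500,
                       anneal_ramp_steps = 3000, anneal_hold_steps = 2000) {
  if (timestep_fs <= 0) stop("`timestep_fs` must be > 0")
  if (friction_ps < 0) stop("`friction_ps` must be >= 0")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

as_positions <- function(x) {
  if (inherits(x, "cg_structure")) bead_coords(x) else as.matrix(x)
}

pot_for_cpp <- function(potential) {
  if (is.null(potential)) return(NULL)
  stopifnot(inherits(potential, "mdff_potential"))
  potential[c("values", "origin", "voxel", "zeta")]
}

coupling_weights <- function(structure, coupled = NULL) {
  w <- structure$beads$weight
  if (!is.null(coupled)) {
    keep <- rep(0, length(w))
    keep[coupled] <- w[coupled]
    w <- keep
  }
  w
}

#' Potential energies and forces of a configuration
#'
#' Evaluates \code{U_total = U_MD + U_EM + U_SS} and the analytic forces.
#' The map term is \code{U_EM = sum_i w_i V(r_i)} with \code{V} evaluated by
#' trilinear interpolation; the map force is the exact gradient of the
#' interpolant.  Beads outside the potential grid sit on the flat plateau
#' (\code{V = zeta}) and feel no map force.
#'
#' @param positions N x 3 coordinate matrix or a \code{\link{cg_structure}}.
#' @param topology a \code{\link{build_topology}} result.
#' @param restraints a \code{restraint_set} (default empty).
#' @param potential an \code{mdff_potential} or \code{NULL} for unbiased MD.
#' @param weights per-bead coupling weights; required when \code{positions}
#'   is a bare matrix and a potential is supplied.
#' @return List with \code{U_md}, \code{U_ss}, \code{U_em}, \code{U_total}
#'   (kcal/mol) and \code{forces} (N x 3, kcal/mol/A).
#' @export
energy_forces <- function(positions, topology, restraints = empty_restraints(),
                          potential = NULL, weights = NULL) {
  X <- as_positions(positions)
  if (is.null(weights)) {
    weights <- if (inherits(positions, "cg_structure"))
      positions$beads$weight else rep(1, nrow(X))
  }
  if (!all(is.finite(X))) stop("non-finite bead positions")
  cg_energy_forces_cpp(X, unclass(topology), unclass(restraints),
                       pot_for_cpp(potential), weights)
}

#' Energy minimisation by steepest descent
#'
#' Backtracking steepest descent; the total energy is non-increasing over
#' accepted steps and the procedure is deterministic.
#'
#' @inheritParams energy_forces
#' @param structure a \code{\link{cg_structure}} providing start coordinates
#'   and coupling weights.
#' @param steps maximum number of accepted descent steps (>= 1).
#' @return The structure with minimised coordinates; final energies in
#'   attribute \code{"energies"}.
#' @export
minimize <- function(structure, topology, restraints = empty_restraints(),
                     potential = NULL, steps = 500) {
  stopifnot(inherits(structure, "cg_structure"))
  if (steps < 1) stop("`steps` must be >= 1")
  res <- minimize_cpp(bead_coords(structure), unclass(topology),
                      unclass(restraints), pot_for_cpp(potential),
                      coupling_weights(structure), as.integer(steps))
  out <- set_coords(structure, res$X)
  attr(out, "energies") <- res[c("U_md", "U_ss", "U_em", "U_total")]
  out
}

temperature_schedule <- function(temperature, nsteps) {
  if (is.numeric(temperature) && length(temperature) == 1)
    return(rep(temperature, nsteps))
  tm <- as.matrix(temperature)
  approx(tm[, 1], tm[, 2], xout = seq_len(nsteps), rule = 2)$y
}

draw_velocities <- function(n, mass, temperature) {
  # Maxwell-Boltzmann in internal AKMA velocity units
  sd <- sqrt(KB * max(temperature, 0) / mass)
  matrix(rnorm(3 * n, 0, rep(sd, 3)), ncol = 3)
}

#' Langevin dynamics
#'
#' BAOAB-splitting Langevin integration of a structure under
#' \code{U_MD + U_EM + U_SS}.  With zero friction the scheme reduces to
#' velocity Verlet and conserves energy (NVE); with a fixed seed the
#' trajectory is bitwise reproducible.
#'
#' @inheritParams minimize
#' @param config a \code{\link{sim_config}}.
#' @param velocities optional N x 3 start velocities (internal units);
#'   drawn from the Maxwell-Boltzmann distribution at the initial schedule
#'   temperature when omitted.
#' @param set_seed set the RNG seed from \code{config$seed} before running
#'   (disable when composing longer protocols that manage the seed).
#' @return A \code{cg_trajectory}: recorded \code{frames} (frame x bead x
#'   xyz), an \code{energies} data frame, the final \code{structure} and
#'   final \code{velocities}.
#' @export
run_dynamics <- function(structure, topology, restraints = empty_restraints(),
                         potential = NULL, config = sim_config(),
                         velocities = NULL, set_seed = TRUE) {
  stopifnot(inherits(structure, "cg_structure"))
  if (set_seed) set.seed(config$seed)
  n <- nrow(structure$beads)
  temps <- temperature_schedule(config$temperature, config$steps)
  if (is.null(velocities))
    velocities <- draw_velocities(n, structure$beads$mass, temps[1])
  res <- run_langevin_cpp(
    bead_coords(structure), velocities, structure$beads$mass,
    unclass(topology), unclass(restraints), pot_for_cpp(potential),
    coupling_weights(structure, config$coupled),
    config$timestep_fs / AKMA_FS,
    config$friction_ps * AKMA_FS / 1000,
    temps, as.integer(config$steps), as.integer(config$stride))
  en <- as.data.frame(res$energies)
  en$time_fs <- en$step * config$timestep_fs
  out <- list(frames = res$frames, energies = en,
              structure = set_coords(structure, res$X),
              velocities = res$V, stride = config$stride,
              timestep_fs = config$timestep_fs, sigma = NA_real_)
  class(out) <- "cg_trajectory"
  out
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %d frames x %d beads (stride %d, dt %g fs)\n",
              dim(x$frames)[1], dim(x$frames)[2], x$stride, x$timestep_fs))
  invisible(x)
}

# frame f as an N x 3 matrix
traj_frame <- function(traj, f) {
  matrix(traj$frames[f, , ], ncol = 3)
}

concat_trajectories <- function(trajs) {
  frames <- do.call(abind3, lapply(trajs, `[[`, "frames"))
  en <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    e <- trajs[[i]]$energies
    e$sigma <- trajs[[i]]$sigma
    e
  }))
  last <- trajs[[length(trajs)]]
  structure(list(frames = frames, energies = en, structure = last$structure,
                 velocities = last$velocities, stride = last$stride,
                 timestep_fs = last$timestep_fs, sigma = NA_real_),
            class = "cg_trajectory")
}

abind3 <- function(...) {
  parts <- list(...)
  n <- dim(parts[[1]])[2]
  tot <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(NA_real_, c(tot, n, 3))
  at <- 0
  for (p in parts) {
    nf <- dim(p)[1]
    if (nf > 0) out[at + seq_len(nf), , ] <- p
    at <- at + nf
  }
  out
}

# Stationarity of the last `window` frames: RMSD of each frame to the window
# mean structure; stationary when the range of that series is below tol.
frames_stationary <- function(frames, window, tol) {
  nf <- dim(frames)[1]
  if (nf < window) return(FALSE)
  w <- frames[(nf - window + 1):nf, , , drop = FALSE]
  mean_xyz <- apply(w, c(2, 3), mean)
  r <- vapply(seq_len(window), function(f) {
    sqrt(mean(rowSums((matrix(w[f, , ], ncol = 3) - mean_xyz)^2)))
  }, numeric(1))
  diff(range(r)) < tol
}

# Run dynamics in chunks until the stationarity detector fires or the step
# cap is reached.  Returns the trajectory plus a convergence flag.
run_until_stationary <- function(structure, topology, restraints, potential,
                                 config, velocities = NULL) {
  chunk <- max(config$window * config$stride / 2, 500)
  total <- 0
  trajs <- list()
  frames_all <- NULL
  converged <- FALSE
  cur <- structure
  vel <- velocities
  while (total < config$max_stage_steps) {
    nsteps <- min(chunk, config$max_stage_steps - total)
    cfg <- config
    cfg$steps <- nsteps
    tr <- run_dynamics(cur, topology, restraints, potential, cfg,
                       velocities = vel, set_seed = FALSE)
    trajs[[length(trajs) + 1]] <- tr
    frames_all <- if (is.null(frames_all)) tr$frames else
      abind3(frames_all, tr$frames)
    cur <- tr$structure
    vel <- tr$velocities
    total <- total + nsteps
    if (frames_stationary(frames_all, config$window, config$stationary_tol)) {
      converged <- TRUE
      break
    }
  }
  traj <- concat_trajectories(trajs)
  list(trajectory = traj, structure = cur, velocities = vel,
       steps = total, converged = converged)
}

#' Total energy of a configuration in a (blurred) map
#'
#' Convenience scalar used by the resolution-exchange criterion: the total
#' potential energy of the given coordinates under the given fitting
#' potential.  Internal and restraint terms do not depend on the map, so
#' energy differences between two maps reduce to the map-coupling term.
#'
#' @inheritParams energy_forces
#' @return \code{U_total} in kcal/mol.
#' @export
total_energy_in_map <- function(positions, topology,
                                restraints = empty_restraints(),
                                potential = NULL, weights = NULL) {
  energy_forces(positions, topology, restraints, potential,
                weights = weights)$U_total
}

#' Annealed re-refinement
#'
#' The final re-refinement applied after every fitting protocol: the map
#' coupling is raised to \code{zeta = 1}, the temperature is ramped linearly
#' from 300 K to 0 K over \code{anneal_ramp_steps}, held at 0 K for
#' \code{anneal_hold_steps}, and the result is energy-minimised.  The final
#' total energy never exceeds the starting one: if the annealed candidate
#' ends higher (possible on a pathological landscape), the minimised start
#' is returned instead.
#'
#' @inheritParams run_dynamics
#' @param set_seed see \code{\link{run_dynamics}}.
#' @return The re-refined \code{\link{cg_structure}} with final energies in
#'   attribute \code{"energies"}.
#' @export
anneal_refine <- function(structure, topology, restraints = empty_restraints(),
                          potential = NULL, config = sim_config(),
                          set_seed = TRUE) {
  stopifnot(inherits(structure, "cg_structure"))
  if (set_seed) set.seed(config$seed)
  pot1 <- if (!is.null(potential) && potential$zeta > 0)
    scale_potential(potential, 1.0) else potential
  w <- coupling_weights(structure, config$coupled)
  u_start <- total_energy_in_map(bead_coords(structure), topology, restraints,
                                 pot1, weights = w)
  ramp <- max(as.integer(config$anneal_ramp_steps), 0)
  hold <- max(as.integer(config$anneal_hold_steps), 0)
  cur <- structure
  if (ramp + hold > 0) {
    cfg <- config
    cfg$steps <- ramp + hold
    cfg$temperature <- if (ramp > 0)
      rbind(c(1, 300), c(ramp, 0), c(ramp + hold, 0)) else
      rbind(c(1, 0), c(hold, 0))
    tr <- run_dynamics(cur, topology, restraints, pot1, cfg, set_seed = FALSE)
    cur <- tr$structure
  }
  cur <- minimize(cur, topology, restraints, pot1, steps = 500)
  u_end <- attr(cur, "energies")$U_total
  if (u_end > u_start) {
    cur <- minimize(structure, topology, restraints, pot1, steps = 500)
  }
  cur
}
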