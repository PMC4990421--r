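# Resolution-exchange fitting: one replica per blur-ladder rung, with
# Metropolis swaps of the blur half-width (and associated potential) between
# neighbouring replicas.  Coordinates stay with their replica; swapping the
# maps instead of the coordinates is equivalent and cheaper.

#' Metropolis acceptance probability for a resolution swap
#'
#' For replicas i and j holding maps of blur widths \eqn{\sigma_i} and
#' \eqn{\sigma_j}, the swap is accepted with probability
#' \deqn{p = \min(1, \exp(-[E(x_i,\sigma_j) + E(x_j,\sigma_i)
#'   - E(x_i,\sigma_i) - E(x_j,\sigma_j)] / k_B T)).}
#' Because the internal and restraint energies do not depend on the map,
#' the exponent reduces to map-coupling differences.
#'
#' @param E_i_si,E_i_sj energies of replica i's coordinates in its own and
#'   in the partner's map (kcal/mol).
#' @param E_j_si,E_j_sj same for replica j.
#' @param temperature temperature in K (> 0).
#' @return Acceptance probability in \code{[0, 1]}.
#' @export
exchange_probability <- function(E_i_si, E_i_sj, E_j_si, E_j_sj, temperature) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("`temperature` must be > 0")
  stopifnot(is.finite(c(E_i_si, E_i_sj, E_j_si, E_j_sj)))
  delta <- E_i_sj + E_j_si - E_i_si - E_j_sj
  min(1, exp(-delta / (KB * temperature)))
}

# container for one replica
new_replica <- function(structure, velocities, sigma, potential) {
  list(structure = structure, velocities = velocities, sigma = sigma,
       potential = potential)
}

#' Attempt neighbour swaps across the replica ladder
#'
#' Replicas are ordered by their current blur width; neighbour pairs of the
#' given parity (\code{"even"}: 1-2, 3-4, ...; \code{"odd"}: 2-3, 4-5, ...)
#' are evaluated with \code{\link{exchange_probability}} using the full
#' total energy in each map.  On acceptance the two replicas exchange their
#' \eqn{\sigma} and potentials; the multiset of ladder widths is conserved.
#'
#' @param replicas list of replica records (structure, velocities, sigma,
#'   potential).
#' @param topology,restraints shared topology and restraint set.
#' @param temperature exchange temperature in K.
#' @param parity \code{"even"} or \code{"odd"}.
#' @param coupled optional coupled-bead selection (see
#'   \code{\link{sim_config}}).
#' @return List with updated \code{replicas} and a data frame \code{log} of
#'   attempts (pair, widths, energy difference, probability, accepted).
#' @export
attempt_exchanges <- function(replicas, topology, restraints, temperature,
                              parity = c("even", "odd"), coupled = NULL) {
  parity <- match.arg(parity)
  ord <- order(vapply(replicas, `[[`, numeric(1), "sigma"), decreasing = TRUE)
  first <- if (parity == "even") 1 else 2
  if (length(replicas) < first + 1)
    return(list(replicas = replicas, log = NULL))
  starts <- seq(first, length(replicas) - 1, by = 2)
  log <- NULL
  for (a in starts) {
    ri <- ord[a]; rj <- ord[a + 1]
    xi <- bead_coords(replicas[[ri]]$structure)
    xj <- bead_coords(replicas[[rj]]$structure)
    wi <- coupling_weights(replicas[[ri]]$structure, coupled)
    E_i_si <- total_energy_in_map(xi, topology, restraints,
                                  replicas[[ri]]$potential, weights = wi)
    E_i_sj <- total_energy_in_map(xi, topology, restraints,
                                  replicas[[rj]]$potential, weights = wi)
    E_j_si <- total_energy_in_map(xj, topology, restraints,
                                  replicas[[ri]]$potential, weights = wi)
    E_j_sj <- total_energy_in_map(xj, topology, restraints,
                                  replicas[[rj]]$potential, weights = wi)
    p <- exchange_probability(E_i_si, E_i_sj, E_j_si, E_j_sj, temperature)
    si <- replicas[[ri]]$sigma; sj <- replicas[[rj]]$sigma
    accepted <- runif(1) < p
    if (accepted) {
      tmp_p <- replicas[[ri]]$potential
      replicas[[ri]]$sigma <- sj
      replicas[[ri]]$potential <- replicas[[rj]]$potential
      replicas[[rj]]$sigma <- si
      replicas[[rj]]$potential <- tmp_p
    }
    delta <- E_i_sj + E_j_si - E_i_si - E_j_sj
    log <- rbind(log, data.frame(
      replica_i = ri, replica_j = rj, sigma_i = si, sigma_j = sj,
      delta = delta, p = p, accepted = accepted))
  }
  list(replicas = replicas, log = log)
}

# trend test on the sigma = 0 replica's recorded total energies: stationary
# when the linear drift over the window is indistinguishable from noise
energy_stationary <- function(u, window) {
  if (length(u) < window) return(FALSE)
  y <- utils::tail(u, window)
  x <- seq_along(y)
  fit <- summary(lm(y ~ x))$coefficients
  abs(fit[2, 1]) < 2 * fit[2, 2]
}

#' Resolution-exchange map fitting
#'
#' Runs one replica per ladder rung, all started from the minimised search
#' model.  Replicas advance by \code{exchange_interval} integrator steps
#' between exchange rounds; neighbour swaps alternate even/odd parity.  The
#' run ends when the recorded total energy of every replica is stationary
#' (exchanges naturally cease as the ensemble settles), or at the round cap
#' (recorded as a convergence warning).  The final model is the best-fit
#' member of the replica ensemble -- each replica's end structure scored by
#' global cross-correlation -- annealed against the unblurred map.
#'
#' @inheritParams run_cmdff
#' @return List with \code{result} (a \code{fit_result}; its trajectory is
#'   the \eqn{\sigma = 0} segment record) and \code{exchange_log} (one row
#'   per attempted swap, with per-pair acceptance statistics as attribute
#'   \code{"rates"}).
#' @export
run_remdff <- function(search, map, schedule, config = sim_config(),
                       reference = NULL, topology = NULL, restraints = NULL) {
  stopifnot(inherits(search, "cg_structure"), inherits(map, "density_map"))
  sched <- as_schedule(schedule)
  if (is.null(topology)) topology <- build_topology(search)
  if (is.null(restraints)) restraints <- assign_ss_restraints(search)
  set.seed(config$seed)
  start <- minimize(search, topology, restraints, NULL, steps = 500)
  temps <- temperature_schedule(config$temperature, 1)
  pots <- lapply(sched, function(sg) stage_potential(map, sg, config))
  replicas <- lapply(seq_along(sched), function(i) {
    new_replica(start,
                draw_velocities(nrow(start$beads), start$beads$mass, temps[1]),
                sched[i], pots[[i]])
  })
  interval <- as.integer(config$exchange_interval)
  # per-replica round budget; keeps every replica's step count below the
  # cascade's cumulative (L stages x stage cap) budget
  max_rounds <- max(2, ceiling(4 * config$max_stage_steps / interval))
  cfg <- config
  cfg$steps <- interval
  log <- NULL
  sigma0_frames <- NULL
  sigma0_energy <- numeric(0)
  sigma0_steps <- 0
  rep_energy <- vector("list", length(replicas))
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    for (ri in seq_along(replicas)) {
      tr <- run_dynamics(replicas[[ri]]$structure, topology, restraints,
                         replicas[[ri]]$potential, cfg,
                         velocities = replicas[[ri]]$velocities,
                         set_seed = FALSE)
      replicas[[ri]]$structure <- tr$structure
      replicas[[ri]]$velocities <- tr$velocities
      rep_energy[[ri]] <- c(rep_energy[[ri]], tr$energies$U_total)
      if (replicas[[ri]]$sigma == 0) {
        sigma0_frames <- if (is.null(sigma0_frames)) tr$frames else
          abind3(sigma0_frames, tr$frames)
        sigma0_energy <- c(sigma0_energy, tr$energies$U_total)
        sigma0_steps <- sigma0_steps + interval
      }
    }
    parity <- if (round %% 2 == 1) "even" else "odd"
    ex <- attempt_exchanges(replicas, topology, restraints, temps[1],
                            parity, config$coupled)
    replicas <- ex$replicas
    if (!is.null(ex$log)) {
      ex$log$round <- round
      ex$log$step <- round * interval
      log <- rbind(log, ex$log)
    }
    if (all(vapply(rep_energy, energy_stationary, logical(1),
                   window = config$window))) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("resolution exchange hit the round cap before energy stationarity")
  # best-fit member of the replica ensemble, by GCC
  scores <- vapply(replicas, function(r) {
    gcc(map, r$structure, config$resolution)
  }, numeric(1))
  best <- replicas[[which.max(scores)]]$structure
  pot0 <- pots[[which(sched == 0)[1]]]
  final <- anneal_refine(best, topology, restraints, pot0, config,
                         set_seed = FALSE)
  # steps until the sigma = 0 holder's own energy became stationary
  rec_per_round <- max(1, interval %/% config$stride)
  sigma0_stationary_steps <- sigma0_steps
  nrec <- length(sigma0_energy)
  for (k in seq_len(max(0, nrec - config$window))) {
    if (energy_stationary(sigma0_energy[seq_len(config$window + k - 1)],
                          config$window)) {
      sigma0_stationary_steps <-
        ceiling((config$window + k - 1) / rec_per_round) * interval
      break
    }
  }
  stages <- data.frame(
    sigma = 0, steps = sigma0_steps, converged = converged,
    rmsd = if (is.null(reference)) NA_real_ else rmsd(final, reference),
    gcc = gcc(map, final, config$resolution),
    U_md = NA_real_, U_ss = NA_real_, U_em = NA_real_,
    U_total = utils::tail(sigma0_energy, 1))
  result <- list(structure = final, stages = stages,
                 trajectory = list(frames = sigma0_frames,
                                   energies = data.frame(U_total = sigma0_energy)),
                 final_rmsd = if (is.null(reference)) NA_real_ else
                   rmsd(final, reference),
                 sigma0_steps = sigma0_steps,
                 sigma0_stationary_steps = sigma0_stationary_steps,
                 replica_scores = scores,
                 topology = topology, restraints = restraints, config = config)
  class(result) <- "fit_result"
  if (!is.null(log)) {
    key <- paste(pmin(log$replica_i, log$replica_j),
                 pmax(log$replica_i, log$replica_j))
    rates <- do.call(rbind, lapply(split(log, key), function(g) {
      data.frame(pair = g$replica_i[1] * 1000 + g$replica_j[1],
                 attempts = nrow(g), accepted = sum(g$accepted),
                 mean_p = mean(g$p))
    }))
    attr(log, "rates") <- rates
  }
  list(result = result, exchange_log = log)
}

#' Write an exchange log as TSV
#' @param log exchange log data frame from \code{\link{run_remdff}}.
#' @param path output path.
#' @export
write_exchange_log <- function(log, path) {
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
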