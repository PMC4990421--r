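# Cascade fitting: sequential refinement through a ladder of progressively
# less blurred maps, each stage seeding the next with its final structure.

#' Blur schedule for cascade / resolution-exchange fitting
#'
#' Arithmetic descent of blur half-widths from \code{sigma_start} down to 0
#' inclusive.  \code{make_schedule(5, 1)} gives the canonical 6-rung ladder
#' 5, 4, 3, 2, 1, 0 A; \code{make_schedule(5, 0.5)} gives the 11-rung
#' half-step ladder.
#'
#' @param sigma_start largest blur half-width (A, > 0).
#' @param step decrement per rung (A, \code{0 < step <= sigma_start}).
#' @return Numeric vector of class \code{blur_schedule}, strictly
#'   decreasing, ending at 0.
#' @export
make_schedule <- function(sigma_start, step) {
  if (!is.finite(sigma_start) || sigma_start <= 0)
    stop("`sigma_start` must be > 0")
  if (!is.finite(step) || step <= 0 || step > sigma_start)
    stop("`step` must satisfy 0 < step <= sigma_start")
  s <- seq(sigma_start, 0, by = -step)
  if (utils::tail(s, 1) > 1e-9) s <- c(s, 0)
  s[abs(s) < 1e-9] <- 0
  class(s) <- "blur_schedule"
  s
}

as_schedule <- function(x) {
  s <- as.numeric(x)
  if (length(s) == 0) stop("empty blur schedule")
  if (length(s) > 1 && any(diff(s) >= 0))
    stop("blur schedule must be strictly decreasing")
  if (utils::tail(s, 1) < 0) stop("blur half-widths must be >= 0")
  s
}

# Potential for one ladder rung: the unblurred fitting potential is built
# once from the map (noise threshold at the configured percentile) and the
# rung potentials are Gaussian blurs of that potential grid, without
# renormalisation.  Blurring the potential rather than re-deriving it from a
# blurred density keeps the energy scales of neighbouring rungs close (the
# blur only smooths V), which both softens the blurred-stage forces and
# gives resolution-exchange swaps a usable acceptance rate.  The background
# plateau (V = zeta) is held fixed by blurring V - zeta, which decays to
# zero away from the density.
stage_potential <- function(map, sigma, config) {
  pot <- potential_from_map(map, config$zeta,
                            map_threshold(map, config$thr_percentile))
  if (sigma == 0) return(pot)
  well <- density_map(pot$values - pot$zeta, pot$origin, pot$voxel)
  blurred <- gaussian_blur(well, sigma)
  pot$values <- pmin(pmax(blurred$values + pot$zeta, 0), pot$zeta)
  pot
}

stage_record <- function(sigma, steps, converged, stg, map, reference, config) {
  st <- stg$structure
  en <- utils::tail(stg$trajectory$energies, 1)
  data.frame(
    sigma = sigma, steps = steps, converged = converged,
    rmsd = if (is.null(reference)) NA_real_ else rmsd(st, reference),
    gcc = gcc(map, st, config$resolution),
    U_md = en$U_md, U_ss = en$U_ss, U_em = en$U_em, U_total = en$U_total)
}

#' Cascade (multi-resolution) map fitting
#'
#' Fits a search model through the blur ladder: for each half-width the map
#' is blurred, converted to a fitting potential, and dynamics are run until
#' the stationarity detector fires (or the per-stage step cap is reached,
#' which is recorded as a convergence warning, not an error); the resulting
#' structure seeds the next stage.  The final stage uses the unblurred map
#' and is followed by the annealed re-refinement
#' (\code{\link{anneal_refine}}).  Velocities are re-drawn at the stage
#' temperature when each stage starts.
#'
#' @param search the search-model \code{\link{cg_structure}}; the internal
#'   topology is built from this conformation, so fitting genuinely deforms
#'   the model against its own internal energy.
#' @param map the target \code{\link{density_map}}.
#' @param schedule a \code{\link{make_schedule}} ladder (or numeric vector).
#' @param config a \code{\link{sim_config}}.
#' @param reference optional target structure for per-stage RMSD records.
#' @param topology,restraints optional pre-built topology / restraint set;
#'   derived from \code{search} when omitted.
#' @return A \code{fit_result}: final \code{structure}, per-stage
#'   \code{stages} records (sigma, steps, convergence, RMSD, GCC, energy
#'   components), the concatenated \code{trajectory} and the \code{config}.
#' @export
run_cmdff <- function(search, map, schedule, config = sim_config(),
                      reference = NULL, topology = NULL, restraints = NULL) {
  stopifnot(inherits(search, "cg_structure"), inherits(map, "density_map"))
  sched <- as_schedule(schedule)
  if (is.null(topology)) topology <- build_topology(search)
  if (is.null(restraints)) restraints <- assign_ss_restraints(search)
  set.seed(config$seed)
  cur <- minimize(search, topology, restraints, NULL, steps = 500)
  stages <- NULL
  trajs <- list()
  for (sigma in sched) {
    pot <- stage_potential(map, sigma, config)
    stg <- run_until_stationary(cur, topology, restraints, pot, config)
    stg$trajectory$sigma <- sigma
    trajs[[length(trajs) + 1]] <- stg$trajectory
    cur <- stg$structure
    stages <- rbind(stages,
                    stage_record(sigma, stg$steps, stg$converged, stg,
                                 map, reference, config))
  }
  if (any(!stages$converged))
    warning("some cascade stages hit the step cap before stationarity")
  pot0 <- stage_potential(map, 0, config)
  final <- anneal_refine(cur, topology, restraints, pot0, config,
                         set_seed = FALSE)
  out <- list(structure = final, stages = stages,
              trajectory = concat_trajectories(trajs),
              final_rmsd = if (is.null(reference)) NA_real_ else
                rmsd(final, reference),
              topology = topology, restraints = restraints, config = config)
  class(out) <- "fit_result"
  out
}

#' Direct (single-map) fitting
#'
#' The classic one-stage protocol: dynamics against the unblurred map's
#' potential followed by the annealed re-refinement.  Equivalent to a
#' cascade with the degenerate schedule \code{c(0)}.
#'
#' @inheritParams run_cmdff
#' @return A \code{fit_result}; see \code{\link{run_cmdff}}.
#' @export
run_direct <- function(search, map, config = sim_config(), reference = NULL,
                       topology = NULL, restraints = NULL) {
  run_cmdff(search, map, c(0), config, reference,
            topology = topology, restraints = restraints)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d stage(s); final RMSD %s A\n",
              nrow(x$stages),
              ifelse(is.na(x$final_rmsd), "n/a", sprintf("%.2f", x$final_rmsd))))
  print(x$stages[, c("sigma", "steps", "converged", "rmsd", "gcc")],
        row.names = FALSE)
  invisible(x)
}

#' Write per-stage fitting metrics as TSV
#' @param result a \code{fit_result}.
#' @param path output path.
#' @export
write_stage_metrics <- function(result, path) {
  write.table(result$stages, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' Write a trajectory as multi-model PDB plus an energy table
#'
#' @param trajectory a \code{cg_trajectory}.
#' @param prefix output path prefix; writes \code{<prefix>.pdb} and
#'   \code{<prefix>_energies.tsv}.
#' @param every keep every \code{every}-th frame in the PDB.
#' @export
write_trajectory <- function(trajectory, prefix, every = 1) {
  pdb_path <- paste0(prefix, ".pdb")
  cat("", file = pdb_path)
  tmpl <- trajectory$structure
  keep <- seq(1, dim(trajectory$frames)[1], by = every)
  for (m in seq_along(keep)) {
    write_model(set_coords(tmpl, traj_frame(trajectory, keep[m])),
                pdb_path, model = m)
  }
  cat("END\n", file = pdb_path, append = TRUE)
  write.table(trajectory$energies, paste0(prefix, "_energies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
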