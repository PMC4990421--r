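# Map-model quality metrics: global/local cross-correlation, Fourier shell
# correlation and its resolution-range integral, half-map cross-validation,
# RMSF profiles, RMSF-derived B-factors, sharpening scans and
# local-resolution binning.

#' Global cross-correlation between a map and a model
#'
#' The model is rendered onto the experimental map's grid at the stated
#' resolution; the Pearson correlation is computed over the union of the
#' voxels where either map exceeds its own noise threshold (the same
#' positive-voxel percentile rule used for fitting potentials).
#'
#' @param exp_map a \code{\link{density_map}}.
#' @param model a \code{\link{cg_structure}}.
#' @param resolution rendering resolution in Angstrom.
#' @param thr_percentile threshold percentile (see
#'   \code{\link{map_threshold}}).
#' @return Correlation in \code{[-1, 1]}.
#' @export
gcc <- function(exp_map, model, resolution, thr_percentile = 0.05) {
  sim <- render_on_grid(model, exp_map, resolution)
  mask <- exp_map$values > map_threshold(exp_map, thr_percentile) |
    sim$values > map_threshold(sim, thr_percentile)
  if (!any(mask)) stop("empty correlation mask")
  a <- exp_map$values[mask]
  b <- sim$values[mask]
  # a model rendered entirely outside the masked region carries no signal
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' Local (per-residue) cross-correlation
#'
#' \code{\link{gcc}} restricted to the voxels within \code{radius} of the
#' residue's beads (intersected with the union threshold mask).
#'
#' @inheritParams gcc
#' @param residue_id residue index (with optional \code{chain} to
#'   disambiguate).
#' @param chain chain id; default first chain containing the residue.
#' @param radius sphere radius in Angstrom around the residue's beads.
#' @return Correlation in \code{[-1, 1]}.
#' @export
lcc <- function(exp_map, model, resolution, residue_id, chain = NULL,
                radius = 5, thr_percentile = 0.05) {
  b <- model$beads
  sel <- b$resid == residue_id & (if (is.null(chain)) TRUE else b$chain == chain)
  if (!any(sel)) stop("residue ", residue_id, " not found")
  sim <- render_on_grid(model, exp_map, resolution)
  d <- dim(exp_map$values)
  ax <- lapply(1:3, function(a) axis_coords(exp_map, a))
  near <- array(FALSE, d)
  for (i in which(sel)) {
    p <- as.numeric(b[i, c("x", "y", "z")])
    ix <- lapply(1:3, function(a) which(abs(ax[[a]] - p[a]) <= radius))
    if (any(lengths(ix) == 0)) next
    sub <- array(FALSE, lengths(ix))
    dx2 <- outer(outer((ax[[1]][ix[[1]]] - p[1])^2,
                       (ax[[2]][ix[[2]]] - p[2])^2, "+"),
                 (ax[[3]][ix[[3]]] - p[3])^2, "+")
    near[ix[[1]], ix[[2]], ix[[3]]] <-
      near[ix[[1]], ix[[2]], ix[[3]]] | (dx2 <= radius^2)
  }
  mask <- near & (exp_map$values > map_threshold(exp_map, thr_percentile) |
                    sim$values > map_threshold(sim, thr_percentile))
  if (!any(mask)) stop("empty local correlation mask for residue ", residue_id)
  cor(exp_map$values[mask], sim$values[mask])
}

#' Fourier shell correlation between two maps
#'
#' Per-shell normalised cross-correlation of the Fourier coefficients of
#' two maps on identical grids.  Shells are one reciprocal-grid unit wide
#' (spacing = 1 / largest grid extent).  Real input makes the coefficients
#' conjugate-symmetric; both halves enter every sum, which leaves the
#' correlation unchanged, and the reported per-shell count is the number of
#' independent coefficients.
#'
#' @param map1,map2 \code{\link{density_map}} objects on identical grids.
#' @return An \code{fsc_curve} data frame: \code{s} (1/A), \code{d} (A),
#'   \code{fsc}, \code{n} (independent coefficients per shell).
#' @export
fsc <- function(map1, map2) {
  stopifnot(inherits(map1, "density_map"), inherits(map2, "density_map"))
  if (!same_grid(map1, map2)) stop("maps are not on identical grids")
  d <- dim(map1$values)
  F1 <- fft(map1$values)
  F2 <- fft(map2$values)
  ds <- 1 / max(d * map1$voxel)
  shell <- as.integer(round(sqrt(freq_sq_grid(d, map1$voxel)) / ds))
  keep <- shell > 0
  num <- tapply(Re(F1[keep] * Conj(F2[keep])), shell[keep], sum)
  d1 <- tapply(Mod(F1[keep])^2, shell[keep], sum)
  d2 <- tapply(Mod(F2[keep])^2, shell[keep], sum)
  cnt <- tapply(shell[keep], shell[keep], length)
  idx <- as.integer(names(num))
  curve <- data.frame(s = idx * ds, d = 1 / (idx * ds),
                      fsc = as.numeric(num / sqrt(d1 * d2)),
                      n = as.integer(ceiling(cnt / 2)))
  curve <- curve[is.finite(curve$fsc), ]
  class(curve) <- c("fsc_curve", "data.frame")
  curve
}

#' Construct an FSC curve from values
#'
#' Builds an \code{fsc_curve} directly from frequencies and correlations,
#' for synthetic curves and closed-form checks.
#'
#' @param s spatial frequencies in 1/A (strictly increasing).
#' @param fsc correlations in \code{[-1, 1]}.
#' @return An \code{fsc_curve}.
#' @export
fsc_curve <- function(s, fsc) {
  stopifnot(length(s) == length(fsc), all(diff(s) > 0), all(s > 0))
  curve <- data.frame(s = s, d = 1 / s, fsc = fsc, n = NA_integer_)
  class(curve) <- c("fsc_curve", "data.frame")
  curve
}

#' Integrated FSC over a resolution range
#'
#' Trapezoidal integral of the FSC as a function of resolution \code{d}
#' over \code{[d_min, d_max]}, in Angstrom; a curve pinned at 1 integrates
#' to \code{d_max - d_min}.  The curve is linearly interpolated at the
#' range endpoints.
#'
#' @param curve an \code{fsc_curve}.
#' @param d_min,d_max resolution range (A), within the curve's support.
#' @return Integral in Angstrom.
#' @export
integrated_fsc <- function(curve, d_min, d_max) {
  stopifnot(inherits(curve, "fsc_curve"))
  if (!(d_min < d_max)) stop("`d_min` must be smaller than `d_max`")
  dd <- curve$d
  if (d_min < min(dd) || d_max > max(dd))
    stop("requested range extends beyond the FSC curve's support")
  o <- order(dd)
  xs <- dd[o]; ys <- curve$fsc[o]
  grid <- sort(unique(c(d_min, d_max, xs[xs > d_min & xs < d_max])))
  yg <- approx(xs, ys, xout = grid)$y
  sum(diff(grid) * (utils::head(yg, -1) + utils::tail(yg, -1)) / 2)
}

#' Half-map cross-validation of a fitted model
#'
#' Renders the fitted model and compares its FSC against the half-map used
#' for fitting (direct) and the held-out half-map (cross) over one or more
#' resolution ranges.  A model that fit signal rather than noise gives
#' nearly identical integrated FSC values; \code{direct - cross} is the
#' overfitting indicator.
#'
#' @param model the structure fitted against \code{half1}.
#' @param half1,half2 half-maps on identical grids.
#' @param resolution rendering resolution (A).
#' @param d_ranges list of \code{c(d_min, d_max)} resolution ranges (A).
#' @return Data frame with one row per range: \code{d_min}, \code{d_max},
#'   \code{ifsc_direct}, \code{ifsc_cross}, \code{overfit}.
#' @export
halfmap_crossvalidate <- function(model, half1, half2, resolution,
                                  d_ranges = list(c(5, 10))) {
  if (!same_grid(half1, half2)) stop("half-maps are not on identical grids")
  sim <- render_on_grid(model, half1, resolution)
  c1 <- fsc(sim, half1)
  c2 <- fsc(sim, half2)
  out <- lapply(d_ranges, function(r) {
    dir <- integrated_fsc(c1, r[1], r[2])
    crs <- integrated_fsc(c2, r[1], r[2])
    data.frame(d_min = r[1], d_max = r[2], ifsc_direct = dir,
               ifsc_cross = crs, overfit = dir - crs)
  })
  do.call(rbind, out)
}

#' RMSF profile of a trajectory window
#'
#' Per-bead root-mean-square fluctuation about the window-averaged
#' positions, without superposition (the map fixes the frame).  The default
#' window is the last 80\% of frames.
#'
#' @param trajectory a \code{cg_trajectory} (or any list with a
#'   \code{frames} array of dimension frame x bead x xyz).
#' @param selection integer bead indices (default all).
#' @param window fraction of trailing frames (scalar in (0, 1]) or an
#'   explicit integer vector of frame indices; at least 2 frames.
#' @return An \code{rmsf_profile}: per-bead \code{rmsf} (A), \code{overall}
#'   RMSF (root mean square of the per-bead values), and a
#'   \code{per_residue} table with RMSF and RMSF^2.
#' @export
rmsf_profile <- function(trajectory, selection = NULL, window = 0.8) {
  frames <- trajectory$frames
  nf <- dim(frames)[1]
  idx <- if (length(window) == 1 && window <= 1) {
    seq(max(1, nf - ceiling(window * nf) + 1), nf)
  } else as.integer(window)
  if (length(idx) < 2) stop("RMSF window must contain at least 2 frames")
  sel <- if (is.null(selection)) seq_len(dim(frames)[2]) else selection
  w <- frames[idx, sel, , drop = FALSE]
  mean_xyz <- apply(w, c(2, 3), mean)
  dev2 <- sweep(w, c(2, 3), mean_xyz)^2
  rmsf <- sqrt(apply(dev2, 2, mean) * 3) # mean over frames and xyz, times 3
  per_res <- NULL
  if (!is.null(trajectory$structure)) {
    b <- trajectory$structure$beads[sel, ]
    agg <- tapply(rmsf, paste(b$chain, b$resid), mean)
    per_res <- data.frame(residue = names(agg), rmsf = as.numeric(agg),
                          rmsf2 = as.numeric(agg)^2)
  }
  out <- list(rmsf = rmsf, selection = sel,
              overall = sqrt(mean(rmsf^2)), per_residue = per_res)
  class(out) <- "rmsf_profile"
  out
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("<rmsf_profile> %d beads, overall RMSF %.3f A\n",
              length(x$rmsf), x$overall))
  invisible(x)
}

#' B-factors from RMSF
#'
#' The quadratic displacement relation \code{B = 8 pi^2 / 3 * RMSF^2}
#' (exact constant 26.3189...).
#'
#' @param profile an \code{rmsf_profile} or a numeric vector of RMSF values
#'   in Angstrom.
#' @return Per-bead B-factors in Angstrom^2.
#' @export
bfactor_from_rmsf <- function(profile) {
  r <- if (inherits(profile, "rmsf_profile")) profile$rmsf else profile
  (8 * pi^2 / 3) * r^2
}

#' Sharpening scan: overall RMSF as a function of map B-factor
#'
#' For each B-factor the map is sharpened, converted to a fitting
#' potential, and a short fixed-seed dynamics run of the prefitted model is
#' performed; the overall RMSF of the trailing window is recorded.  The
#' RMSF-vs-B curve is parabolic: too little sharpening leaves a blurred,
#' shallow potential, too much amplifies noise until the potential's
#' effective minima flatten, and the minimum marks the optimal sharpening,
#' coinciding with the Guinier estimate.
#'
#' @param model the prefitted \code{\link{cg_structure}}.
#' @param map the unsharpened \code{\link{density_map}}.
#' @param B_list numeric vector of B-factors to scan (A^2).
#' @param config a \code{\link{sim_config}}; \code{config$steps} sets the
#'   per-B run length and \code{config$seed} is reset before each run so
#'   every B sees the same noise realisation.
#' @param topology,restraints optional pre-built mechanics.
#' @return List with \code{table} (B, overall RMSF; failed runs get NA) and
#'   \code{argmin_B}.
#' @export
sharpen_scan <- function(model, map, B_list, config = sim_config(),
                         topology = NULL, restraints = NULL) {
  if (length(B_list) < 1) stop("`B_list` must contain at least one value")
  if (is.null(topology)) topology <- build_topology(model)
  if (is.null(restraints)) restraints <- assign_ss_restraints(model)
  rmsfs <- vapply(B_list, function(B) {
    tryCatch({
      m2 <- sharpen(map, B)
      pot <- potential_from_map(m2, config$zeta,
                                map_threshold(m2, config$thr_percentile))
      tr <- run_dynamics(model, topology, restraints, pot, config)
      rmsf_profile(tr)$overall
    }, error = function(e) NA_real_)
  }, numeric(1))
  tab <- data.frame(B = B_list, rmsf = rmsfs)
  list(table = tab, argmin_B = B_list[which.min(rmsfs)])
}

# trilinear interpolation of a map at arbitrary points (R side, plumbing
# for local-resolution lookups)
interp_map <- function(map, xyz) {
  d <- dim(map$values)
  fr <- sweep(sweep(xyz, 2, map$origin), 2, map$voxel, "/")
  vapply(seq_len(nrow(xyz)), function(i) {
    f <- fr[i, ]
    i0 <- floor(f)
    if (any(i0 < 0) || any(i0 >= d - 1)) return(NA_real_)
    t <- f - i0
    i0 <- i0 + 1 # 1-based corner
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wgt <- (if (dx) t[1] else 1 - t[1]) * (if (dy) t[2] else 1 - t[2]) *
        (if (dz) t[3] else 1 - t[3])
      acc <- acc + wgt * map$values[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    acc
  }, numeric(1))
}

#' Bin RMSF by local resolution
#'
#' Each bead is assigned the interpolated local-resolution value at its
#' position; beads are grouped into fixed-width resolution bins,
#' under-populated bins are dropped, and a least-squares line of mean RMSF
#' against bin resolution is fitted.  Worse (larger) local resolution is
#' expected to carry larger fluctuations.
#'
#' @param profile an \code{rmsf_profile}.
#' @param localres a \code{\link{density_map}} whose voxel values are local
#'   resolutions in Angstrom.
#' @param model the \code{\link{cg_structure}} the profile refers to.
#' @param min_population bins with fewer beads are dropped (default 20).
#' @param bin_width resolution bin width in Angstrom (default 0.25).
#' @return List with \code{table} (bin centre, population, mean RMSF),
#'   \code{slope}, \code{r2} (both NA when fewer than 2 populated bins
#'   remain).
#' @export
bin_rmsf_by_local_resolution <- function(profile, localres, model,
                                         min_population = 20,
                                         bin_width = 0.25) {
  stopifnot(inherits(profile, "rmsf_profile"))
  xyz <- bead_coords(model)[profile$selection, , drop = FALSE]
  res <- interp_map(localres, xyz)
  ok <- is.finite(res)
  res <- res[ok]
  rms <- profile$rmsf[ok]
  bins <- floor(res / bin_width) * bin_width + bin_width / 2
  tab <- do.call(rbind, lapply(split(seq_along(bins), bins), function(ii) {
    data.frame(resolution = bins[ii[1]], population = length(ii),
               mean_rmsf = mean(rms[ii]))
  }))
  tab <- tab[order(tab$resolution), ]
  rownames(tab) <- NULL
  kept <- tab[tab$population >= min_population, ]
  if (nrow(kept) == 0)
    stop("all resolution bins are below the population threshold")
  if (nrow(kept) < 2)
    return(list(table = tab, kept = kept, slope = NA_real_, r2 = NA_real_))
  fit <- lm(mean_rmsf ~ resolution, data = kept)
  list(table = tab, kept = kept, slope = unname(coef(fit)[2]),
       r2 = summary(fit)$r.squared)
}

#' Write a validation report as JSON
#'
#' @param report a named list of metrics (numbers, tables as data frames).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(NULL)
}

#' Write per-bead B-factors into a PDB file
#'
#' @param model a \code{\link{cg_structure}}.
#' @param B per-bead B-factors (A^2); values above 999.99 are clipped to
#'   the PDB column limit with a warning.
#' @param path output path.
#' @export
write_bfactors_to_pdb <- function(model, B, path) {
  write_structure(model, path, bfactor = B)
}
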