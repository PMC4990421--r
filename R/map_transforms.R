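# Fourier-space map transforms: Gaussian blurring, B-factor sharpening,
# synthetic rendering and Guinier analysis.

# signed DFT sample frequencies for one axis, in 1/Angstrom
fft_freqs <- function(n, spacing) {
  k <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1))
  k / (n * spacing)
}

# |s|^2 over the full 3-D reciprocal grid of a map-sized array
freq_sq_grid <- function(dims, voxel) {
  fx <- fft_freqs(dims[1], voxel[1])
  fy <- fft_freqs(dims[2], voxel[2])
  fz <- fft_freqs(dims[3], voxel[3])
  outer(outer(fx^2, fy^2, "+"), fz^2, "+")
}

# Multiply the map's Fourier transform by a radially symmetric transfer
# function of |s|^2.  Convolution is periodic on the map's own grid: the
# DC coefficient is untouched, so total density is conserved exactly, and
# successive diagonal transfers compose exactly (blur semigroup,
# blur/sharpen inverse).  Maps rendered with an adequate zero margin (the
# generators pad by >= 8 A) make the wrap-around contribution negligible.
apply_transfer <- function(map, transfer) {
  d <- dim(map$values)
  s2 <- freq_sq_grid(d, map$voxel)
  out <- Re(fft(fft(map$values) * transfer(s2), inverse = TRUE)) / prod(d)
  density_map(out, origin = map$origin, voxel = map$voxel)
}

#' Gaussian blur of a density map
#'
#' Convolves the map with an isotropic Gaussian kernel of standard deviation
#' \code{sigma} (the blur "half-width" of the ladder construction).  The
#' convolution is applied in Fourier space, periodically on the map's own
#' grid: total density is conserved exactly and repeated blurs compose
#' exactly as \code{sqrt(a^2 + b^2)}.  Maps should carry an adequate zero
#' margin (the rendering utilities pad by 8 A or more) so that wrap-around
#' between opposite faces is negligible.
#'
#' @param map a \code{\link{density_map}}.
#' @param sigma kernel standard deviation in Angstrom, \code{>= 0};
#'   \code{sigma = 0} returns the input unchanged.
#' @return A blurred \code{\link{density_map}} on the same grid.
#' @export
gaussian_blur <- function(map, sigma) {
  stopifnot(inherits(map, "density_map"))
  if (!is.finite(sigma) || sigma < 0) stop("`sigma` must be >= 0")
  if (sigma == 0) return(map)
  apply_transfer(map, function(s2) exp(-2 * pi^2 * sigma^2 * s2))
}

#' Sharpen (or dampen) a map by a B-factor
#'
#' Scales Fourier amplitudes by \code{exp(-B s^2 / 4)} with \code{s} the
#' spatial frequency in 1/Angstrom.  Negative \code{B} sharpens (amplifies
#' high-frequency amplitudes and restores contrast), positive \code{B}
#' dampens; \code{B = 0} is the identity.  Sharpening by \code{-8 pi^2
#' sigma^2} undoes a Gaussian blur of width \code{sigma}.
#'
#' @param map a \code{\link{density_map}}.
#' @param B B-factor in Angstrom^2 (any sign).
#' @return A \code{\link{density_map}} on the same grid.
#' @export
sharpen <- function(map, B) {
  stopifnot(inherits(map, "density_map"))
  if (!is.finite(B)) stop("`B` must be finite")
  if (B == 0) return(map)
  apply_transfer(map, function(s2) exp(-B * s2 / 4))
}

#' Render a synthetic density map from a structure
#'
#' Each bead is rendered as an isotropic 3-D Gaussian of integrated density
#' equal to its coupling weight and standard deviation \code{resolution /
#' (2 sqrt(2 log 2))}, i.e. the full width at half maximum of the Gaussian
#' equals the nominal resolution.  The grid covers the structure's bounding
#' box plus \code{pad} on every side.
#'
#' @param structure a \code{\link{cg_structure}}.
#' @param resolution nominal resolution in Angstrom (> 0).
#' @param voxel voxel spacing in Angstrom (> 0).
#' @param pad padding around the structure in Angstrom (> 0).
#' @param widths optional per-bead Gaussian standard deviations (Angstrom)
#'   overriding the single-resolution rule (used for spatially varying
#'   resolution fixtures).
#' @return A \code{\link{density_map}}.
#' @export
render_map <- function(structure, resolution, voxel = 1, pad = 8, widths = NULL) {
  stopifnot(inherits(structure, "cg_structure"))
  if (nrow(structure$beads) == 0) stop("cannot render an empty structure")
  if (resolution <= 0 || voxel <= 0 || pad <= 0)
    stop("`resolution`, `voxel` and `pad` must be > 0")
  xyz <- bead_coords(structure)
  lo <- unname(floor(apply(xyz, 2, min) - pad))
  hi <- unname(ceiling(apply(xyz, 2, max) + pad))
  dims <- pmax(ceiling((hi - lo) / voxel) + 1, 2)
  empty <- density_map(array(0, dims), origin = lo, voxel = rep(voxel, 3))
  render_on_grid(structure, empty, resolution, widths = widths, add = FALSE)
}

# render beads as Gaussians onto the grid of `template`; the workhorse behind
# render_map(), gcc() and the synthetic-map generators
render_on_grid <- function(structure, template, resolution, widths = NULL,
                           add = FALSE) {
  xyz <- bead_coords(structure)
  w <- structure$beads$weight
  n <- nrow(xyz)
  s <- if (is.null(widths)) rep(resolution / FWHM_FACTOR, n) else widths
  stopifnot(length(s) == n, all(s > 0))
  d <- dim(template$values)
  out <- if (add) template$values else array(0, d)
  ax <- lapply(1:3, function(a) axis_coords(template, a))
  for (i in seq_len(n)) {
    rad <- 4.5 * s[i]
    idx <- lapply(1:3, function(a) {
      which(ax[[a]] >= xyz[i, a] - rad & ax[[a]] <= xyz[i, a] + rad)
    })
    if (any(lengths(idx) == 0)) next
    amp <- w[i] / ((2 * pi)^1.5 * s[i]^3)
    gx <- exp(-(ax[[1]][idx[[1]]] - xyz[i, 1])^2 / (2 * s[i]^2))
    gy <- exp(-(ax[[2]][idx[[2]]] - xyz[i, 2])^2 / (2 * s[i]^2))
    gz <- exp(-(ax[[3]][idx[[3]]] - xyz[i, 3])^2 / (2 * s[i]^2))
    out[idx[[1]], idx[[2]], idx[[3]]] <-
      as.vector(out[idx[[1]], idx[[2]], idx[[3]]]) +
      amp * as.vector(outer(outer(gx, gy), gz))
  }
  density_map(out, origin = template$origin, voxel = template$voxel)
}

#' Density threshold at a percentile of the positive voxels
#'
#' The noise threshold used when deriving fitting potentials and correlation
#' masks: the given quantile of the strictly positive voxel values (default
#' the 5th percentile).  Falls back to the quantile of all values when no
#' voxel is positive.
#'
#' @param map a \code{\link{density_map}}.
#' @param percentile quantile in \code{[0, 1)}.
#' @return Scalar threshold in density units.
#' @export
map_threshold <- function(map, percentile = 0.05) {
  v <- as.numeric(map$values)
  pos <- v[v > 0]
  if (length(pos) == 0) pos <- v
  unname(quantile(pos, percentile))
}

#' Convert a density map into an MDFF fitting potential
#'
#' Builds the per-voxel fitting energy
#' \deqn{V(r) = \zeta [1 - (\Phi(r) - \Phi_{thr}) / (\Phi_{max} - \Phi_{thr})]}
#' for \eqn{\Phi \ge \Phi_{thr}} and \eqn{V = \zeta} below the threshold, so
#' that density maxima are energy minima (V = 0) and sub-threshold noise sits
#' on a flat plateau of height \eqn{\zeta}.  This is the sign-inverted,
#' threshold-continuous reading of the usual printed form
#' \eqn{\zeta(\Phi - \Phi_{thr})/(\Phi_{max} - \Phi_{thr})}, which as printed
#' would rise with density; the potential must be proportional to the
#' sign-inverse of the map for fitting forces to point into the density.
#'
#' @param map a \code{\link{density_map}}.
#' @param zeta coupling scale in kcal/mol, \code{>= 0}.
#' @param phi_thr density threshold; defaults to
#'   \code{\link{map_threshold}(map)}.  Must not exceed the map maximum.
#' @return An object of class \code{mdff_potential}: fields \code{values}
#'   (grid of energies in \code{[0, zeta]}), \code{origin}, \code{voxel},
#'   \code{zeta}, \code{phi_thr}.
#' @export
potential_from_map <- function(map, zeta, phi_thr = map_threshold(map)) {
  stopifnot(inherits(map, "density_map"))
  if (!is.finite(zeta) || zeta < 0) stop("`zeta` must be >= 0")
  phi_max <- max(map$values)
  if (phi_thr > phi_max) stop("`phi_thr` exceeds the map maximum")
  if (phi_max == phi_thr)
    stop("degenerate flat map: max density equals the threshold")
  frac <- (map$values - phi_thr) / (phi_max - phi_thr)
  v <- zeta * (1 - pmin(pmax(frac, 0), 1))
  structure(list(values = array(v, dim(map$values)), origin = map$origin,
                 voxel = map$voxel, zeta = zeta, phi_thr = phi_thr),
            class = "mdff_potential")
}

#' @export
print.mdff_potential <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<mdff_potential> %d x %d x %d voxels, zeta = %g kcal/mol, threshold = %g\n",
              d[1], d[2], d[3], x$zeta, x$phi_thr))
  invisible(x)
}

# rescale a potential to a new coupling strength (shape preserved)
scale_potential <- function(potential, zeta) {
  stopifnot(inherits(potential, "mdff_potential"), zeta >= 0)
  if (potential$zeta == 0) stop("cannot rescale a zero-strength potential")
  potential$values <- potential$values * (zeta / potential$zeta)
  potential$zeta <- zeta
  potential
}

# spherically averaged Fourier amplitudes: one shell per integer radius in
# reciprocal-grid units (shell spacing = 1 / largest grid extent)
radial_amplitudes <- function(map) {
  d <- dim(map$values)
  s2 <- freq_sq_grid(d, map$voxel)
  amp <- Mod(fft(map$values))
  ds <- 1 / max(d * map$voxel)
  shell <- as.integer(round(sqrt(s2) / ds))
  keep <- shell > 0
  mean_amp <- tapply(amp[keep], shell[keep], mean)
  idx <- as.integer(names(mean_amp))
  data.frame(shell = idx, s = idx * ds, d = 1 / (idx * ds),
             amplitude = as.numeric(mean_amp))
}

#' Estimate a map's overall B-factor by Guinier analysis
#'
#' Fits a least-squares line to the log spherically averaged Fourier
#' amplitude against squared spatial frequency over the resolution band
#' \code{[d_min, d_max]} and reports \code{B = -4 * slope}.  Applying
#' \code{\link{sharpen}} with \code{-B} flattens the amplitude falloff over
#' that band.
#'
#' @param map a \code{\link{density_map}}.
#' @param d_min,d_max resolution range in Angstrom, \code{d_min < d_max};
#'   \code{d_min} must respect the Nyquist limit \code{2 * max(voxel)}.
#' @return B-factor in Angstrom^2.
#' @export
guinier_bfactor <- function(map, d_min, d_max) {
  stopifnot(inherits(map, "density_map"))
  if (!(d_min < d_max)) stop("`d_min` must be smaller than `d_max`")
  if (d_min < 2 * max(map$voxel))
    stop("`d_min` is beyond the Nyquist limit of this grid")
  ra <- radial_amplitudes(map)
  sel <- ra[ra$d >= d_min & ra$d <= d_max & ra$amplitude > 0, ]
  if (nrow(sel) < 3)
    stop("fewer than 3 Fourier shells in the requested resolution range")
  fit <- lm(log(amplitude) ~ I(s^2), data = sel)
  unname(-4 * coef(fit)[2])
}

#' Fit the width of an isotropic Gaussian blob in a map
#'
#' Least-squares fit of a single isotropic Gaussian (amplitude, centre,
#' standard deviation) to the map values, initialised from density moments.
#' Used as the measurement behind blur-width composition checks.
#'
#' @param map a \code{\link{density_map}} containing one dominant blob.
#' @return Fitted standard deviation in Angstrom.
#' @export
fit_gaussian_width <- function(map) {
  stopifnot(inherits(map, "density_map"))
  v <- map$values
  d <- dim(v)
  ax <- lapply(1:3, function(a) axis_coords(map, a))
  w <- pmax(as.numeric(v), 0)
  tot <- sum(w)
  gx <- array(rep(ax[[1]], times = d[2] * d[3]), d)
  gy <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
  gz <- array(rep(ax[[3]], each = d[1] * d[2]), d)
  mu <- c(sum(gx * w), sum(gy * w), sum(gz * w)) / tot
  var0 <- (sum(((gx - mu[1])^2 + (gy - mu[2])^2 + (gz - mu[3])^2) * w)) / (3 * tot)
  p0 <- c(log(max(v)), mu, log(sqrt(var0)))
  obj <- function(p) {
    s <- exp(p[5])
    pred <- exp(p[1]) * exp(-((gx - p[2])^2 + (gy - p[3])^2 + (gz - p[4])^2) / (2 * s^2))
    sum((pred - v)^2)
  }
  fit <- optim(p0, obj, method = "BFGS", control = list(maxit = 200))
  exp(fit$par[5])
}
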