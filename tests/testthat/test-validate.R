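test_that("global cross-correlation: self-fit, null overlap, negation", {
  target <- small_toy()
  map <- small_map()
  expect_gte(gcc(map, target, 3), 0.99)
  far <- set_coords(target, sweep(bead_coords(target), 2, c(500, 0, 0), "+"))
  expect_lt(abs(gcc(map, far, 3)), 0.05)
  neg <- density_map(-map$values, map$origin, map$voxel)
  expect_equal(gcc(neg, target, 3), -gcc(map, target, 3), tolerance = 1e-6)
})

test_that("gcc is invariant under affine rescaling of the map", {
  target <- small_toy()
  map <- small_map()
  g1 <- gcc(map, target, 3)
  scaled <- density_map(map$values * 2.5, map$origin, map$voxel)
  expect_equal(gcc(scaled, target, 3), g1, tolerance = 1e-9)
})

test_that("local cross-correlation tracks per-residue fit", {
  target <- small_toy()
  map <- small_map()
  expect_gte(lcc(map, target, 3, residue_id = 5), 0.95)
  # displace one residue 10 A out of its density
  bad <- target
  mid <- 11
  xyz <- bead_coords(bad)
  xyz[mid, ] <- xyz[mid, ] + c(0, 10, 0)
  bad <- set_coords(bad, xyz)
  expect_lt(lcc(map, bad, 3, residue_id = mid), 0.3)
  expect_error(lcc(map, target, 3, residue_id = 9999), "not found")
})

test_that("all-residue LCC of a perfect fit stays near the GCC", {
  target <- small_toy()
  map <- small_map()
  g <- gcc(map, target, 3)
  lccs <- vapply(target$beads$resid, function(r) lcc(map, target, 3, r),
                 numeric(1))
  expect_gt(min(lccs), g - 0.1)
})

test_that("FSC of a map with itself is 1 in every shell", {
  m <- small_map()
  curve <- fsc(m, m)
  expect_true(all(abs(curve$fsc - 1) < 1e-9))
  expect_true(all(diff(curve$s) > 0))
  expect_error(fsc(m, density_map(array(1, c(4, 4, 4)))), "identical grids")
})

test_that("independent white-noise maps decorrelate by shell count", {
  set.seed(31)
  d <- c(32, 32, 32)
  m1 <- density_map(array(rnorm(prod(d)), d))
  m2 <- density_map(array(rnorm(prod(d)), d))
  curve <- fsc(m1, m2)
  hi <- curve[curve$s > 0.25, ]
  expect_true(all(abs(hi$fsc) < 3 / sqrt(hi$n)))
})

test_that("a one-voxel shift damps FSC like the analytic phase ramp", {
  target <- small_toy()
  m <- small_map()
  shifted <- m
  v <- m$values
  d <- dim(v)
  shifted$values <- v[c(d[1], 1:(d[1] - 1)), , ] # circular shift along x
  curve <- fsc(m, shifted)
  # exact closed form: the shift multiplies each coefficient by the phase
  # ramp exp(-2 pi i fx dx), so per shell the FSC is the amplitude-weighted
  # mean of cos(2 pi fx dx)
  Fm <- fft(v)
  P <- Mod(Fm)^2
  fx <- mapfit:::fft_freqs(d[1], m$voxel[1])
  cosr <- array(rep(cos(2 * pi * fx * 1), times = d[2] * d[3]), d)
  ds <- 1 / max(d * m$voxel)
  shell <- as.integer(round(sqrt(mapfit:::freq_sq_grid(d, m$voxel)) / ds))
  keep <- shell > 0
  pred <- tapply(P[keep] * cosr[keep], shell[keep], sum) /
    tapply(P[keep], shell[keep], sum)
  pred <- as.numeric(pred[as.character(round(curve$s / ds))])
  sel <- curve$s < 0.4
  expect_equal(curve$fsc[sel], pred[sel], tolerance = 0.02)
})

test_that("integrated FSC reproduces closed forms and monotonicity", {
  s_grid <- seq(0.05, 0.5, by = 0.005)
  ones <- fsc_curve(s_grid, rep(1, length(s_grid)))
  expect_equal(integrated_fsc(ones, 5, 10), 5.0, tolerance = 1e-9)
  zeros <- fsc_curve(s_grid, rep(0, length(s_grid)))
  expect_equal(integrated_fsc(zeros, 5, 10), 0)
  halves <- fsc_curve(s_grid, rep(0.5, length(s_grid)))
  expect_equal(integrated_fsc(halves, 3.4, 10), 3.3, tolerance = 1e-9)
  expect_error(integrated_fsc(ones, 10, 5), "smaller")
  expect_error(integrated_fsc(ones, 1, 10), "support")
  # monotonicity: pointwise-larger curves give larger integrals
  set.seed(32)
  for (i in 1:10) {
    lo <- runif(length(s_grid), 0, 0.8)
    hi <- lo + runif(length(s_grid), 0, 0.2)
    expect_gte(integrated_fsc(fsc_curve(s_grid, hi), 4, 12) + 1e-12,
               integrated_fsc(fsc_curve(s_grid, lo), 4, 12))
  }
})

test_that("RMSF profiles: frozen, two-frame, and aggregate identities", {
  frames <- array(0, c(5, 3, 3))
  traj <- list(frames = frames, structure = straight_chain(3))
  prof <- rmsf_profile(traj, window = 1)
  expect_equal(prof$rmsf, rep(0, 3))
  expect_equal(prof$overall, 0)
  # two frames, one bead at +d / -d along x
  frames2 <- array(0, c(2, 2, 3))
  frames2[1, 1, 1] <- 1.5
  frames2[2, 1, 1] <- -1.5
  prof2 <- rmsf_profile(list(frames = frames2), window = 1)
  expect_equal(prof2$rmsf[1], 1.5)
  expect_equal(prof2$rmsf[2], 0)
  expect_equal(prof2$overall, sqrt(mean(c(1.5, 0)^2)))
  expect_error(rmsf_profile(list(frames = frames2[1, , , drop = FALSE])),
               "2 frames")
})

test_that("RMSF of a map-confined bead satisfies equipartition", {
  # single bead in its own rendered map: near the density maximum the
  # potential is harmonic with k = zeta * w / S^2 per axis
  bead <- cg_structure(data.frame(id = 1, resid = 1, chain = "A", x = 0,
                                  y = 0, z = 0, mass = 110, weight = 110))
  m <- render_map(bead, 3, voxel = 0.25, pad = 8)
  pot <- potential_from_map(m, 0.3, 0)
  S2 <- (3 / (2 * sqrt(2 * log(2))))^2
  k <- 0.3 * 110 / S2
  topo <- bead_topology()
  cfg <- sim_config(timestep_fs = 4, friction_ps = 5, seed = 17,
                    steps = 150000, stride = 20)
  tr <- run_dynamics(bead, topo, potential = pot, config = cfg)
  prof <- rmsf_profile(list(frames = tr$frames), window = 0.8)
  # 3-D harmonic fluctuation: RMSF^2 = 3 kBT / k (mild anharmonic excess)
  expect_equal(prof$rmsf[1]^2, 3 * KB_internal() * 300 / k, tolerance = 0.08)
})

test_that("B-factors follow the 8 pi^2 / 3 quadratic rule", {
  expect_equal(bfactor_from_rmsf(0), 0)
  expect_equal(bfactor_from_rmsf(1), 8 * pi^2 / 3, tolerance = 1e-12)
  expect_equal(signif(bfactor_from_rmsf(1), 5), 26.319)
  expect_equal(bfactor_from_rmsf(sqrt(1.73)), 8 * pi^2 / 3 * 1.73,
               tolerance = 1e-12)
  # exactly quadratic
  r <- c(0.2, 0.7, 1.9)
  expect_equal(bfactor_from_rmsf(2 * r), 4 * bfactor_from_rmsf(r))
})

test_that("half-map cross-validation: identical halves agree exactly", {
  target <- small_toy()
  halves <- make_halfmaps(target, 3, noise_sd = 0, seed = 1)
  tab <- halfmap_crossvalidate(target, halves$half1, halves$half2, 3,
                               d_ranges = list(c(5, 10), c(3.4, 10)))
  expect_equal(tab$ifsc_direct, tab$ifsc_cross)
  expect_equal(tab$overfit, c(0, 0))
})

test_that("local-resolution binning orders fluctuation by resolution", {
  target <- study_target()
  lr <- make_localres_map(target)
  topo <- build_topology(target)
  restr <- assign_ss_restraints(target)
  pot <- potential_from_map(lr$map, 0.3)
  cfg <- sim_config(seed = 19, steps = 6000, stride = 10)
  tr <- run_dynamics(target, topo, restr, pot, cfg)
  prof <- rmsf_profile(tr)
  out <- bin_rmsf_by_local_resolution(prof, lr$localres, target,
                                      min_population = 20)
  expect_gte(nrow(out$kept), 2)
  expect_gt(out$slope, 0)
  # populations account for every bead
  expect_equal(sum(out$table$population), nrow(target$beads))
  # shell (worse resolution) beads fluctuate more than core beads
  expect_gt(out$kept$mean_rmsf[nrow(out$kept)], out$kept$mean_rmsf[1])
})

test_that("uniform local resolution degenerates to a single bin", {
  target <- small_toy()
  lr <- make_localres_map(target, core_resolution = 4, shell_resolution = 4)
  prof <- rmsf_profile(list(frames = array(rnorm(2 * nrow(target$beads) * 3,
                                                 0, 0.1),
                                           c(2, nrow(target$beads), 3))),
                       window = 1)
  out <- bin_rmsf_by_local_resolution(prof, lr$localres, target,
                                      min_population = 20)
  expect_true(is.na(out$slope))
  expect_equal(nrow(out$kept), 1)
  expect_error(bin_rmsf_by_local_resolution(prof, lr$localres, target,
                                            min_population = 1e6),
               "population")
})

test_that("validation reports serialise to JSON", {
  rep <- list(gcc = 0.87, ifsc = data.frame(range = "5-10", value = 4.2))
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$gcc, 0.87)
})
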