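test_that("MRC round trip preserves geometry and values", {
  ramp <- density_map(array(seq_len(512) / 64, c(8, 8, 8)),
                      origin = c(-4.5, 2, 11), voxel = c(1.25, 1, 0.8))
  path <- tempfile(fileext = ".mrc")
  write_map(ramp, path)
  back <- read_map(path)
  expect_equal(dim(back), dim(ramp))
  expect_equal(back$origin, ramp$origin, tolerance = 1e-6)
  expect_equal(back$voxel, ramp$voxel, tolerance = 1e-6)
  # float32 storage
  expect_equal(back$values, ramp$values, tolerance = 1e-6)
})

test_that("read_map matches render_map generator arguments", {
  m <- render_map(straight_chain(), 3, voxel = 1, pad = 5)
  path <- tempfile(fileext = ".mrc")
  write_map(m, path)
  back <- read_map(path)
  expect_identical(dim(back), dim(m))
  expect_equal(back$origin, m$origin, tolerance = 1e-5)
})

test_that("malformed MRC headers are rejected with a named field", {
  m <- density_map(array(1, c(4, 4, 4)))
  path <- tempfile(fileext = ".mrc")
  write_map(m, path)
  # zero out MX/MY/MZ (words 8-10) -> voxel spacing 0
  con <- file(path, "r+b")
  seek(con, 28, rw = "write")
  writeBin(integer(3), con, size = 4, endian = "little")
  close(con)
  expect_error(read_map(path), "MX")
  # non-orthogonal cell: set a cell angle to 80 degrees
  write_map(m, path)
  con <- file(path, "r+b")
  seek(con, 52, rw = "write")
  writeBin(80, con, size = 4, endian = "little")
  close(con)
  expect_error(read_map(path), "orthogonal")
  expect_error(read_map(tempfile()), "exist")
})

test_that("density_map validates invariants", {
  expect_error(density_map(array(1, c(2, 2, 2)), voxel = c(1, 0, 1)), "positive")
  expect_error(density_map(array(c(1, NA), c(2, 1, 1))), "finite")
  expect_error(density_map(matrix(1, 2, 2)), "3-D")
})

test_that("gaussian_blur: identity at sigma 0, mass conservation, errors", {
  m <- small_map()
  expect_identical(gaussian_blur(m, 0)$values, m$values)
  b <- gaussian_blur(m, 2)
  expect_equal(sum(b$values), sum(m$values), tolerance = 1e-6)
  expect_identical(dim(b), dim(m))
  expect_error(gaussian_blur(m, -1), ">= 0")
})

test_that("blur widths compose as sqrt(s^2 + sigma^2)", {
  # single Gaussian blob rendered as a one-bead structure
  bead <- straight_chain(1)
  for (case in list(c(2, 1.5), c(3, 2))) {
    s <- case[1]; sigma <- case[2]
    # nominal resolution chosen so the rendered width is exactly s
    m <- render_map(bead, s * 2 * sqrt(2 * log(2)), voxel = 0.5, pad = 6 * s)
    w <- fit_gaussian_width(gaussian_blur(m, sigma))
    expect_equal(w, sqrt(s^2 + sigma^2), tolerance = 0.02)
  }
})

test_that("blur semigroup: successive blurs compose in quadrature", {
  m <- small_map()
  ab <- gaussian_blur(gaussian_blur(m, 1.5), 2)
  once <- gaussian_blur(m, sqrt(1.5^2 + 2^2))
  expect_equal(ab$values, once$values, tolerance = 1e-5)
})

test_that("potential_from_map implements the inverted thresholded form", {
  m <- small_map()
  thr <- map_threshold(m)
  pot <- potential_from_map(m, zeta = 0.3, phi_thr = thr)
  expect_true(all(pot$values >= 0 & pot$values <= 0.3))
  expect_equal(pot$values[which.max(m$values)], 0)
  expect_true(all(pot$values[m$values < thr] == 0.3))
  # continuity at the threshold: just above thr the value is ~zeta
  eps_above <- m$values >= thr & m$values < thr + 0.02 * max(m$values)
  expect_true(all(pot$values[eps_above] > 0.3 * 0.95))
  # monotone non-increasing in density above the threshold
  o <- order(m$values)
  vo <- pot$values[o][m$values[o] >= thr]
  expect_true(all(diff(vo) <= 1e-12))
})

test_that("potential is invariant under affine rescaling of the density", {
  m <- small_map()
  thr <- map_threshold(m)
  p1 <- potential_from_map(m, 0.3, thr)
  m2 <- density_map(m$values * 3.7, m$origin, m$voxel)
  p2 <- potential_from_map(m2, 0.3, thr * 3.7)
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
  flat <- density_map(array(2, c(4, 4, 4)))
  expect_error(potential_from_map(flat, 0.3, 2), "degenerate")
  expect_error(potential_from_map(m, -1), ">= 0")
})

test_that("sharpen: identity, exact inverse, equivalence to blur", {
  m <- small_map()
  expect_identical(sharpen(m, 0)$values, m$values)
  back <- sharpen(sharpen(m, 60), -60)
  expect_equal(back$values, m$values, tolerance = 1e-6)
  # blur by sigma then sharpen with B = -8 pi^2 sigma^2 restores the map
  sigma <- 1.2
  restored <- sharpen(gaussian_blur(m, sigma), -8 * pi^2 * sigma^2)
  d <- dim(m$values)
  core <- list(8:(d[1] - 8), 8:(d[2] - 8), 8:(d[3] - 8))
  expect_equal(restored$values[core[[1]], core[[2]], core[[3]]],
               m$values[core[[1]], core[[2]], core[[3]]],
               tolerance = 0.01)
})

test_that("sharpen and blur commute", {
  m <- small_map()
  a <- sharpen(gaussian_blur(m, 1.5), -40)
  b <- gaussian_blur(sharpen(m, -40), 1.5)
  expect_equal(a$values, b$values, tolerance = 1e-6)
})

test_that("guinier_bfactor: flat spectrum, additive shifts, errors", {
  set.seed(7)
  # white noise has a flat spherically averaged spectrum -> B ~ 0
  noise <- density_map(array(rnorm(40^3), c(40, 40, 40)))
  b0 <- guinier_bfactor(noise, 2.5, 8)
  expect_lt(abs(b0), 5)
  for (dB in c(-120, -40, 40, 120)) {
    b <- guinier_bfactor(sharpen(noise, dB), 2.5, 8)
    expect_lt(abs((b - b0) - dB), 5)
  }
  expect_error(guinier_bfactor(noise, 8, 2.5), "smaller")
  expect_error(guinier_bfactor(noise, 1, 8), "Nyquist")
})

test_that("render_map: normalisation, maxima, additivity", {
  bead <- straight_chain(1)
  bead$beads$weight <- 1
  m <- render_map(bead, 3, voxel = 0.5, pad = 8)
  expect_equal(sum(m$values) * prod(m$voxel), 1, tolerance = 0.01)
  peak <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
  world <- m$origin + (peak - 1) * m$voxel
  expect_true(all(abs(world - c(0, 0, 0)) <= m$voxel / 2 + 1e-9))

  # two beads 20 A apart -> two local maxima along the connecting axis
  two <- straight_chain(2, spacing = 20)
  m2 <- render_map(two, 3, voxel = 1, pad = 8)
  j0 <- which.min(abs((seq_len(dim(m2)[2]) - 1) * m2$voxel[2] + m2$origin[2]))
  k0 <- which.min(abs((seq_len(dim(m2)[3]) - 1) * m2$voxel[3] + m2$origin[3]))
  profile <- m2$values[, j0, k0]
  peaks <- sum(diff(sign(diff(profile))) == -2)
  expect_equal(peaks, 2)

  # integrated density is additive over beads
  many <- straight_chain(6)
  mm <- render_map(many, 3, voxel = 1, pad = 8)
  expect_equal(sum(mm$values) * prod(mm$voxel),
               sum(many$beads$weight), tolerance = 0.01)
  expect_error(render_map(bead, -3, 1, 1), "> 0")
})
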