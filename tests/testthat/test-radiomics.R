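# Volume LBP, 3D HOG, 3D GLCM against brute-force oracles

test_that("constant volume concentrates LBP mass on the all-ones pattern", {
  h <- lbp3d_histogram(array(0.3, dim = c(6, 6, 4)))
  expect_equal(sum(h), 1)
  expect_equal(unname(h[16384]), 1)   # pattern 2^14 - 1 = 16383 (B(0) = 1)
})

test_that("LBP matches a per-voxel bit-enumeration oracle", {
  # single bright center voxel in a 3-slice toy volume
  toy <- array(0, dim = c(3, 3, 3))
  toy[2, 2, 2] <- 1
  expect_equal(unname(lbp3d_histogram(toy)), oracle_lbp(toy))
  # random small volumes
  for (s in 1:3) {
    v <- random_volume(c(8, 8, 3), seed = 100 + s)
    expect_equal(unname(lbp3d_histogram(v)), oracle_lbp(v))
  }
})

test_that("LBP is invariant under strictly increasing intensity maps", {
  v <- random_volume(c(10, 10, 5), seed = 42)
  expect_identical(lbp3d_histogram(v), lbp3d_histogram(v^3 + 2 * v + 1))
  expect_identical(lbp3d_histogram(v), lbp3d_histogram(exp(v)))
  expect_error(lbp3d_histogram(array(0, dim = c(5, 5, 2))), "slices")
})

test_that("HOG handles constant and ramp volumes analytically", {
  expect_true(all(hog3d_descriptor(array(1, dim = c(32, 32, 4)),
                                   hog_params(c(16, 16, 2))) == 0))
  # ramp along x: gradient (1, 0, 0) -> azimuth 0, elevation 0 everywhere
  d <- c(16, 16, 8)
  ramp <- array(rep(seq_len(d[1]), times = prod(d[2:3])), dim = d)
  p <- hog_params(cell_shape = c(8, 8, 4), inplane_bins = 8, elevation_bins = 4)
  h <- hog3d_descriptor(ramp, p)
  nz <- which(h > 0)
  # the bin containing (azimuth 0, elevation 0) is azimuth bin 1, elevation
  # bin 3 of each cell (elevation bins split [-pi/2, pi/2] into 4)
  expect_true(all(grepl("_e2_a0$", names(h)[nz])))
  expect_equal(sum(h^2), 1)
})

test_that("HOG matches a per-voxel vote-loop oracle", {
  v <- random_volume(c(16, 16, 8), seed = 7)
  p <- hog_params(cell_shape = c(8, 8, 4))
  expect_equal(unname(hog3d_descriptor(v, p)), oracle_hog(v), tolerance = 1e-6)
  expect_error(hog3d_descriptor(v, hog_params(c(7, 8, 4))), "cell_shape")
})

test_that("GLCM reduces to the trivial matrix on constant volumes", {
  f <- suppressWarnings(glcm3d_features(array(0.4, dim = c(9, 9, 5))))
  expect_equal(unname(f[grepl("_energy$", names(f))]), rep(1, 52))
  expect_equal(unname(f[grepl("_entropy$", names(f))]), rep(0, 52))
  expect_equal(unname(f[grepl("_contrast$", names(f))]), rep(0, 52))
  expect_equal(unname(f[grepl("_homogeneity$", names(f))]), rep(1, 52))
})

test_that("GLCM matches the hand-counted plane example", {
  # 2x2 plane with columns (0, 0) and (1, 1); direction (0,1,0), d = 1:
  # symmetric counts {(0,1): 2, (1,0): 2} -> p = 0.5 each
  plane <- array(c(0, 0, 1, 1), dim = c(2, 2, 1))
  pars <- glcm_params(gray_levels = 2, z_direction_distances = 1,
                      inplane_distances = 1)
  f <- suppressWarnings(glcm3d_features(plane, pars))
  expect_equal(unname(f["glcm_0.1.0_d1_energy"]), 0.5)
  expect_equal(unname(f["glcm_0.1.0_d1_contrast"]), 1.0)
  expect_equal(unname(f["glcm_0.1.0_d1_homogeneity"]), 0.5)
  expect_equal(unname(f["glcm_0.1.0_d1_entropy"]), -2 * 0.5 * log(0.5))
})

test_that("GLCM matches a per-pair loop oracle on random volumes", {
  v <- random_volume(c(12, 12, 6), seed = 9)
  pars <- glcm_params(gray_levels = 8, z_direction_distances = c(1, 2),
                      inplane_distances = c(1, 3))
  f <- glcm3d_features(v, pars)
  cases <- list(list(dir = c(1, 0, 0), dist = 1, tag = "glcm_1.0.0_d1"),
                list(dir = c(1, -1, 0), dist = 3, tag = "glcm_1.-1.0_d3"),
                list(dir = c(0, 0, 1), dist = 2, tag = "glcm_0.0.1_d2"),
                list(dir = c(-1, -1, 1), dist = 1, tag = "glcm_-1.-1.1_d1"))
  for (cs in cases) {
    want <- oracle_glcm(v, 8, cs$dir, cs$dist)
    got <- f[paste0(cs$tag, "_", names(want))]
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("GLCM probabilities are normalized, symmetric and bounded", {
  v <- random_volume(c(10, 10, 5), seed = 21)
  G <- 8
  q <- rgdfusion:::quantize_volume(v, G)
  lev <- seq_len(G)
  imj <- outer(lev, lev, `-`)
  m <- rgdfusion:::glcm_one(q, G, c(1, 0, 0), imj, 1 / (1 + abs(imj)))
  expect_true(m["energy"] > 0 && m["energy"] <= 1)
  expect_true(m["entropy"] >= 0 && m["entropy"] <= 2 * log(G))
  f <- glcm3d_features(v, glcm_params(gray_levels = G))
  expect_true(all(f[grepl("_energy$", names(f))] <= 1))
  expect_true(all(f[grepl("_entropy$", names(f))] <= 2 * log(G)))
  # degenerate distance: all-zero block with a warning (one per direction)
  warns <- capture_warnings(
    fdeg <- glcm3d_features(random_volume(c(6, 6, 3), 1),
                            glcm_params(inplane_distances = 8,
                                        z_direction_distances = 1)))
  expect_true(all(grepl("degenerate", warns)))
  expect_length(warns, 4)   # the four in-plane directions at distance 8
  expect_true(all(fdeg[grepl("^glcm_1\\.0\\.0_d8", names(fdeg))] == 0))
})

test_that("90-degree in-plane rotation permutes the in-plane directions", {
  v <- random_volume(c(10, 10, 4), seed = 33)
  vr <- array(0, dim = dim(v))          # (i, j) -> (j, n - i + 1)
  n <- dim(v)[1]
  for (k in seq_len(dim(v)[3])) vr[, , k] <- t(v[n:1, , k])
  pars <- glcm_params(gray_levels = 8, inplane_distances = c(1, 2),
                      z_direction_distances = 1)
  f1 <- glcm3d_features(v, pars)
  f2 <- glcm3d_features(vr, pars)
  inplane <- function(f) {
    keep <- grepl("^glcm_(1\\.0\\.0|0\\.1\\.0|1\\.1\\.0|1\\.-1\\.0)_", names(f))
    m <- matrix(f[keep], nrow = 4, byrow = TRUE)   # one row per direction
    m[order(m[, 1], m[, 2]), ]                      # compare as a multiset
  }
  expect_equal(inplane(f1), inplane(f2), tolerance = 1e-12)
})

test_that("the radiomics vector FR concatenates the three blocks stably", {
  v1 <- random_volume(c(16, 16, 8), seed = 1)
  v2 <- random_volume(c(16, 16, 8), seed = 2)
  p_hog <- hog_params(cell_shape = c(8, 8, 4))
  r1 <- radiomics_vector(v1, hog = p_hog)
  r2 <- radiomics_vector(v2, hog = p_hog)
  expect_length(r1$glcm, 4 * (9 * 4 + 4 * 4))    # 208 with default distances
  expect_equal(length(r1$fr), length(r1$lbp) + length(r1$hog) + length(r1$glcm))
  expect_identical(length(r1$fr), length(r2$fr))
  expect_identical(radiomics_vector(v1, hog = p_hog)$fr, r1$fr)
  expect_true(all(is.finite(r1$fr)))
  m <- radiomics_matrix(list(nodule_volume(v1), nodule_volume(v2)), hog = p_hog)
  expect_equal(dim(m), c(2L, length(r1$fr)))
  expect_equal(unname(m[1, ]), unname(r1$fr))
})
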