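# 3D texture radiomics ---------------------------------------------------------
#
# The radiomics vector FR concatenates three descriptors of a nodule volume:
#   * volume local binary patterns: a (3P+2)-bit pattern per voxel built from
#     thresholded intensity differences against the center voxel, using the
#     center pixels of the slices L above/below plus P circular neighbors at
#     radius R in the three slices; histogram over all 2^(3P+2) patterns.
#   * a 3D histogram of oriented gradients: central-difference gradients, an
#     in-plane azimuth and an elevation angle, per-cell magnitude-weighted 2D
#     orientation histograms, globally L2-normalized.
#   * 3D gray-level co-occurrence features: 13 unique directions of the
#     26-neighborhood (opposite directions merged by symmetric accumulation),
#     distances 1,2,3,4 for directions with a through-plane component and
#     1,2,4,8 in-plane; energy, entropy, contrast and homogeneity per matrix.

#' Volume LBP parameters
#'
#' @param L slice interval between the center slice and the previous/posterior
#'   neighboring slices.
#' @param P number of circular neighbors per slice.
#' @param R neighbor radius in pixels.
#' @return An object of class `lbp_params`. The pattern width is `3P + 2` bits.
#' @export
lbp_params <- function(L = 1L, P = 4L, R = 1) {
  L <- check_count(L, "L", 1L)
  P <- check_count(P, "P", 1L)
  R <- check_number(R, "R", min = 1e-9)
  structure(list(L = L, P = P, R = R), class = "lbp_params")
}

#' 3D HOG parameters
#'
#' @param cell_shape voxel triple; cells must tile the volume exactly.
#' @param inplane_bins unsigned azimuth bins over `[0, pi)`.
#' @param elevation_bins elevation bins over `[-pi/2, pi/2]`.
#' @return An object of class `hog_params`.
#' @export
hog_params <- function(cell_shape = c(32L, 32L, 4L), inplane_bins = 8L,
                       elevation_bins = 4L) {
  check_flag(length(cell_shape) == 3L && all(cell_shape >= 1), "cell_shape",
             "must be three positive integers")
  inplane_bins <- check_count(inplane_bins, "inplane_bins", 2L)
  elevation_bins <- check_count(elevation_bins, "elevation_bins", 2L)
  structure(list(cell_shape = as.integer(cell_shape),
                 inplane_bins = inplane_bins, elevation_bins = elevation_bins),
            class = "hog_params")
}

#' 3D GLCM parameters
#'
#' @param gray_levels number of equal-width quantization levels (>= 2).
#' @param z_direction_distances distances used for the 9 directions with a
#'   through-plane component.
#' @param inplane_distances distances used for the 4 in-plane directions.
#' @return An object of class `glcm_params`.
#' @export
glcm_params <- function(gray_levels = 32L,
                        z_direction_distances = c(1L, 2L, 3L, 4L),
                        inplane_distances = c(1L, 2L, 4L, 8L)) {
  gray_levels <- check_count(gray_levels, "gray_levels", 2L)
  check_flag(all(z_direction_distances >= 1) && all(inplane_distances >= 1),
             "distances", "must be positive integers")
  structure(list(gray_levels = gray_levels,
                 z_direction_distances = as.integer(z_direction_distances),
                 inplane_distances = as.integer(inplane_distances)),
            class = "glcm_params")
}

# in-plane circular neighbor offsets (d_row, d_col) for angle 2*pi*p/P
lbp_offsets <- function(P, R) {
  th <- 2 * pi * (seq_len(P) - 1) / P
  off <- cbind(dr = R * cos(th), dc = R * sin(th))
  off[abs(off) < 1e-9] <- 0
  off
}

# extract the block v[rows+dr, cols+dc, slices+ds] with bilinear in-plane
# interpolation for fractional (dr, dc); rows/cols/slices are integer ranges
shift_block <- function(v, rows, cols, slices, dr, dc, ds) {
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0;  fc <- dc - c0
  blk <- function(a, b) v[rows + r0 + a, cols + c0 + b, slices + ds, drop = FALSE]
  if (fr < 1e-12 && fc < 1e-12) return(blk(0L, 0L))
  (1 - fr) * (1 - fc) * blk(0L, 0L) + (1 - fr) * fc * blk(0L, 1L) +
    fr * (1 - fc) * blk(1L, 0L) + fr * fc * blk(1L, 1L)
}

#' Volume LBP histogram
#'
#' For every interior voxel a `(3P+2)`-bit pattern is assembled from the
#' thresholded differences `B(g - g_center)` (with `B(x) = 1` iff `x >= 0`),
#' in the order: center of the previous slice, the P neighbors of the previous
#' slice, the P neighbors of the center slice, the P neighbors of the
#' posterior slice, the center of the posterior slice. The histogram over the
#' `2^(3P+2)` pattern values is L1-normalized. Monotone increasing intensity
#' maps leave the histogram unchanged.
#'
#' @param vol a [nodule_volume()] or 3D numeric array.
#' @param params an [lbp_params()].
#' @return A numeric vector of length `2^(3P+2)` summing to 1.
#' @export
lbp3d_histogram <- function(vol, params = lbp_params()) {
  v <- if (inherits(vol, "nodule_volume")) vol$voxels else vol
  check_flag(is.array(v) && length(dim(v)) == 3L, "vol", "must be a 3D array")
  L <- params$L; P <- params$P; R <- params$R
  d <- dim(v)
  check_flag(d[3] >= 2 * L + 1, "vol",
             sprintf("needs at least %d slices for L = %d", 2 * L + 1, L))
  m <- as.integer(ceiling(R))
  check_flag(d[1] > 2 * m && d[2] > 2 * m, "vol", "too small for radius R")
  rows <- (m + 1L):(d[1] - m)
  cols <- (m + 1L):(d[2] - m)
  slices <- (L + 1L):(d[3] - L)
  gc <- v[rows, cols, slices, drop = FALSE]
  off <- lbp_offsets(P, R)
  nbits <- 3L * P + 2L
  pattern <- array(0, dim = dim(gc))
  q <- 0L
  add_bit <- function(pattern, g, q) pattern + (g >= gc) * 2^q
  pattern <- add_bit(pattern, shift_block(v, rows, cols, slices, 0, 0, -L), 0L)
  q <- 1L
  for (ds in c(-L, 0L, L)) {
    for (p in seq_len(P)) {
      pattern <- add_bit(pattern,
                         shift_block(v, rows, cols, slices, off[p, 1], off[p, 2], ds), q)
      q <- q + 1L
    }
  }
  pattern <- add_bit(pattern, shift_block(v, rows, cols, slices, 0, 0, L), q)
  h <- tabulate(as.integer(pattern) + 1L, nbins = 2^nbits)
  h <- h / sum(h)
  names(h) <- sprintf("lbp_%05d", seq_along(h) - 1L)
  h
}

#' 3D HOG descriptor
#'
#' Central-difference gradients (zero on boundary faces) are converted to an
#' unsigned in-plane azimuth in `[0, pi)` and an elevation in
#' `[-pi/2, pi/2]`; each voxel votes its gradient magnitude into its cell's
#' 2D orientation histogram, and the concatenated cell histograms are
#' L2-normalized globally (an all-zero descriptor is left unnormalized).
#'
#' @param vol a [nodule_volume()] or 3D numeric array, at least 3 voxels per
#'   axis.
#' @param params a [hog_params()]; `cell_shape` must divide the volume shape.
#' @return A numeric vector of length
#'   `n_cells * inplane_bins * elevation_bins` with unit L2 norm (or all
#'   zeros for a constant volume).
#' @export
hog3d_descriptor <- function(vol, params = hog_params()) {
  v <- if (inherits(vol, "nodule_volume")) vol$voxels else vol
  check_flag(is.array(v) && length(dim(v)) == 3L, "vol", "must be a 3D array")
  d <- dim(v)
  check_flag(all(d >= 3), "vol", "needs at least 3 voxels per axis")
  cs <- params$cell_shape
  check_flag(all(d %% cs == 0), "params",
             "cell_shape must divide the volume shape exactly")
  ib <- params$inplane_bins; eb <- params$elevation_bins

  # one-axis central differences; boundary faces keep zero gradient
  gx <- array(0, dim = d); gy <- array(0, dim = d); gz <- array(0, dim = d)
  gx[2:(d[1] - 1), , ] <- (v[3:d[1], , ] - v[1:(d[1] - 2), , ]) / 2
  gy[, 2:(d[2] - 1), ] <- (v[, 3:d[2], ] - v[, 1:(d[2] - 2), ]) / 2
  gz[, , 2:(d[3] - 1)] <- (v[, , 3:d[3]] - v[, , 1:(d[3] - 2)]) / 2

  mag <- sqrt(gx^2 + gy^2 + gz^2)
  az <- atan2(gy, gx) %% pi                       # unsigned, [0, pi)
  el <- atan2(gz, sqrt(gx^2 + gy^2))              # [-pi/2, pi/2]
  azb <- pmin(floor(az / (pi / ib)), ib - 1L)
  elb <- pmin(floor((el + pi / 2) / (pi / eb)), eb - 1L)

  ncell <- d %/% cs
  ci <- (slice.index(v, 1) - 1L) %/% cs[1]
  cj <- (slice.index(v, 2) - 1L) %/% cs[2]
  ck <- (slice.index(v, 3) - 1L) %/% cs[3]
  cell <- ci + ncell[1] * (cj + ncell[2] * ck)
  idx <- 1L + azb + ib * (elb + eb * cell)
  nbin <- ib * eb * prod(ncell)
  h <- numeric(nbin)
  acc <- rowsum(as.numeric(mag), as.integer(idx))
  h[as.integer(rownames(acc))] <- acc
  nrm <- sqrt(sum(h^2))
  if (nrm > 0) h <- h / nrm
  names(h) <- sprintf("hog_c%03d_e%d_a%d",
                      rep(seq_len(prod(ncell)) - 1L, each = ib * eb),
                      rep(rep(seq_len(eb) - 1L, each = ib), prod(ncell)),
                      rep(seq_len(ib) - 1L, eb * prod(ncell)))
  h
}

# the 13 unique 26-neighborhood directions; in-plane first, then z-component
glcm_directions <- function() {
  list(inplane = rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0)),
       zdir = rbind(c(0, 0, 1), c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1), c(0, -1, 1),
                    c(1, 1, 1), c(1, -1, 1), c(-1, 1, 1), c(-1, -1, 1)))
}

quantize_volume <- function(v, G) {
  lo <- min(v); hi <- max(v)
  if (lo >= -1e-9 && hi <= 1 + 1e-9) { lo <- 0; hi <- 1 }
  if (hi - lo < 1e-12) return(array(1L, dim = dim(v)))
  q <- floor((v - lo) / (hi - lo) * G) + 1L
  array(pmin(as.integer(q), G), dim = dim(v))
}

# symmetric co-occurrence features for one integer offset on a quantized array
glcm_one <- function(q, G, offset, i_minus_j, inv_abs) {
  d <- dim(q)
  if (any(abs(offset) >= d)) return(NULL)
  rs <- if (offset[1] >= 0) 1:(d[1] - offset[1]) else (1 - offset[1]):d[1]
  cs <- if (offset[2] >= 0) 1:(d[2] - offset[2]) else (1 - offset[2]):d[2]
  ss <- if (offset[3] >= 0) 1:(d[3] - offset[3]) else (1 - offset[3]):d[3]
  a <- q[rs, cs, ss]
  b <- q[rs + offset[1], cs + offset[2], ss + offset[3]]
  cnt <- matrix(tabulate(a + G * (b - 1L), nbins = G * G), G, G)
  cnt <- cnt + t(cnt)                                      # symmetric
  p <- cnt / sum(cnt)
  nz <- p > 0
  c(energy = sum(p^2),
    entropy = -sum(p[nz] * log(p[nz])),
    contrast = sum(i_minus_j^2 * p),
    homogeneity = sum(inv_abs * p))
}

#' 3D GLCM texture features
#'
#' Intensities are quantized into `gray_levels` equal-width bins (over
#' `[0, 1]` for unit-scaled data, otherwise over the volume's range); for each
#' of the 13 unique 26-neighborhood directions and each of its distances,
#' symmetric co-occurrence counts are normalized to probabilities and reduced
#' to energy, entropy (natural log, `0 log 0 := 0`), contrast and homogeneity.
#' Feature order is direction-major (the 4 in-plane directions, then the 9
#' with a through-plane component), distance-minor, with the four statistics
#' per matrix. A distance that exceeds the volume extent yields an all-zero
#' degenerate block with a warning.
#'
#' @param vol a [nodule_volume()] or 3D numeric array.
#' @param params a [glcm_params()].
#' @return A named numeric vector of length
#'   `4 * (4 * length(inplane_distances) + 9 * length(z_direction_distances))`.
#' @export
glcm3d_features <- function(vol, params = glcm_params()) {
  v <- if (inherits(vol, "nodule_volume")) vol$voxels else vol
  check_flag(is.array(v) && length(dim(v)) == 3L, "vol", "must be a 3D array")
  G <- params$gray_levels
  q <- quantize_volume(v, G)
  lev <- seq_len(G)
  i_minus_j <- outer(lev, lev, `-`)
  inv_abs <- 1 / (1 + abs(i_minus_j))
  dirs <- glcm_directions()
  out <- numeric(0)
  emit <- function(dir, dist, tag) {
    f <- glcm_one(q, G, dir * dist, i_minus_j, inv_abs)
    if (is.null(f)) {
      warning(sprintf("degenerate GLCM for direction (%s) at distance %d",
                      paste(dir, collapse = ","), dist), call. = FALSE)
      f <- c(energy = 0, entropy = 0, contrast = 0, homogeneity = 0)
    }
    names(f) <- sprintf("glcm_%s_d%d_%s", tag, dist, names(f))
    f
  }
  for (i in seq_len(nrow(dirs$inplane))) {
    dir <- dirs$inplane[i, ]
    tag <- paste(dir, collapse = ".")
    for (dist in params$inplane_distances) out <- c(out, emit(dir, dist, tag))
  }
  for (i in seq_len(nrow(dirs$zdir))) {
    dir <- dirs$zdir[i, ]
    tag <- paste(dir, collapse = ".")
    for (dist in params$z_direction_distances) out <- c(out, emit(dir, dist, tag))
  }
  out
}

#' The radiomics vector FR
#'
#' Concatenates the volume LBP histogram, the 3D HOG descriptor and the 3D
#' GLCM features of one nodule volume. The length is constant across volumes
#' for fixed parameters.
#'
#' @param vol a [nodule_volume()] or 3D numeric array.
#' @param lbp an [lbp_params()].
#' @param hog a [hog_params()].
#' @param glcm a [glcm_params()].
#' @return An object of class `radiomics_vector`: list with the three blocks
#'   and their concatenation `fr`.
#' @export
radiomics_vector <- function(vol, lbp = lbp_params(), hog = hog_params(),
                             glcm = glcm_params()) {
  l <- lbp3d_histogram(vol, lbp)
  h <- hog3d_descriptor(vol, hog)
  g <- glcm3d_features(vol, glcm)
  structure(list(lbp = l, hog = h, glcm = g, fr = c(l, h, g)),
            class = "radiomics_vector")
}

#' @export
print.radiomics_vector <- function(x, ...) {
  cat(sprintf("<radiomics_vector> |FR| = %d (LBP %d + HOG %d + GLCM %d)\n",
              length(x$fr), length(x$lbp), length(x$hog), length(x$glcm)))
  invisible(x)
}

#' Radiomics feature matrix for a set of volumes
#'
#' @param volumes list of [nodule_volume()] (or a `phantom_cohort`).
#' @inheritParams radiomics_vector
#' @param file optional CSV path; if given, the matrix is written with one row
#'   per nodule and stable column names.
#' @return Numeric matrix, one row per volume, with descriptor column names.
#' @export
radiomics_matrix <- function(volumes, lbp = lbp_params(), hog = hog_params(),
                             glcm = glcm_params(), file = NULL) {
  if (inherits(volumes, "phantom_cohort")) volumes <- volumes$volumes
  rows <- lapply(volumes, function(v) radiomics_vector(v, lbp, hog, glcm)$fr)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(volumes, function(v) v$patient_id, character(1))
  if (!is.null(file)) utils::write.csv(m, file)
  m
}
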