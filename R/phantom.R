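# Synthetic nodule phantoms --------------------------------------------------
#
# Two texture/shape classes emulating the cues radiologists and texture
# radiomics rely on: benign nodules are smooth, homogeneous, blurred
# ellipsoids; malignant nodules carry radial spicules and superimposed
# band-limited intensity texture (increased within-lesion heterogeneity).

#' Construct a nodule volume
#'
#' Container for one voxel grid with spacing and provenance metadata.
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing_mm numeric triple, voxel spacing in mm (x, y, z).
#' @param patient_id character scalar.
#' @return An object of class `nodule_volume`.
#' @export
nodule_volume <- function(voxels, spacing_mm = c(1, 1, 1), patient_id = NA_character_) {
  check_flag(is.array(voxels) && length(dim(voxels)) == 3L && is.numeric(voxels),
             "voxels", "must be a numeric 3D array")
  check_flag(length(spacing_mm) == 3L && all(spacing_mm > 0),
             "spacing_mm", "must be three positive numbers")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 patient_id = as.character(patient_id)),
            class = "nodule_volume")
}

#' @export
print.nodule_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<nodule_volume> %dx%dx%d voxels, spacing %.2fx%.2fx%.2f mm, patient %s\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              x$patient_id))
  cat(sprintf("  intensity range [%.3f, %.3f]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Specify a synthetic phantom cohort
#'
#' @param n_per_class number of nodules per class (>= 1).
#' @param crop_shape voxel triple of each generated volume; every entry >= 4.
#' @param benign_smoothness in-plane Gaussian blur scale (voxels) applied to
#'   benign nodules; larger is smoother.
#' @param malignant_spike_count number of radial spicules per malignant nodule.
#' @param malignant_texture_amplitude standard deviation (as a fraction of the
#'   intensity range) of the band-limited texture added inside malignant
#'   nodules; in `[0, 1]`.
#' @param noise_sd acquisition-noise standard deviation (intensity fraction).
#' @param seed integer seed; identical specs yield bit-identical cohorts.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(n_per_class = 2, seed = 7)
phantom_spec <- function(n_per_class,
                         crop_shape = c(56L, 56L, 8L),
                         benign_smoothness = 2,
                         malignant_spike_count = 8L,
                         malignant_texture_amplitude = 0.3,
                         noise_sd = 0.02,
                         seed = 1L) {
  n_per_class <- check_count(n_per_class, "n_per_class", min = 1L)
  check_flag(length(crop_shape) == 3L && all(crop_shape >= 4) &&
               all(crop_shape == round(crop_shape)),
             "crop_shape", "must be three integers, each >= 4")
  benign_smoothness <- check_number(benign_smoothness, "benign_smoothness", min = 0)
  malignant_spike_count <- check_count(malignant_spike_count, "malignant_spike_count", min = 0L)
  malignant_texture_amplitude <- check_number(malignant_texture_amplitude,
                                              "malignant_texture_amplitude", 0, 1)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(n_per_class = n_per_class,
                 crop_shape = as.integer(crop_shape),
                 benign_smoothness = benign_smoothness,
                 malignant_spike_count = malignant_spike_count,
                 malignant_texture_amplitude = malignant_texture_amplitude,
                 noise_sd = noise_sd,
                 seed = seed),
            class = "phantom_spec")
}

# separable Gaussian blur along the three axes; sigma may be a triple
blur3d <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 1e-8) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    a <- conv1d_axis(a, k, ax)
  }
  a
}

# zero-phase 1D convolution along one axis with replicate padding
conv1d_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  p <- aperm(a, perm)
  n <- d[axis]
  m <- matrix(p, nrow = n)
  r <- (length(k) - 1L) %/% 2L
  padded <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  out <- stats::filter(padded, k, sides = 2)
  out <- matrix(out[(r + 1L):(r + n), ], nrow = n)
  arr <- array(out, dim = d[perm])
  aperm(arr, order(perm))
}

# one phantom volume; everything below consumes the supplied RNG stream
phantom_volume <- function(spec, malignant) {
  d <- spec$crop_shape
  cx <- (d + 1) / 2 + c(stats::runif(2, -2, 2), stats::runif(1, -0.4, 0.4))
  # in-plane radii scale with crop size; z radii with slab thickness
  rin <- stats::runif(2, 0.16, 0.26) * d[1:2]
  rz <- stats::runif(1, 0.28, 0.42) * d[3]
  gx <- (seq_len(d[1]) - cx[1]) / rin[1]
  gy <- (seq_len(d[2]) - cx[2]) / rin[2]
  gz <- (seq_len(d[3]) - cx[3]) / rz
  m2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)   # squared ellipsoid coord
  core <- 0.75 * (m2 <= 1)

  if (malignant) {
    # radial spicules: thin decaying rays from the surface outward
    vx <- outer(outer((seq_len(d[1]) - cx[1]), rep(1, d[2]), `*`), rep(1, d[3]), `*`)
    vy <- outer(outer(rep(1, d[1]), (seq_len(d[2]) - cx[2]), `*`), rep(1, d[3]), `*`)
    vz <- outer(outer(rep(1, d[1]), rep(1, d[2]), `*`), (seq_len(d[3]) - cx[3]), `*`)
    r2 <- vx^2 + vy^2 + vz^2
    rbase <- mean(rin)
    for (s in seq_len(spec$malignant_spike_count)) {
      phi <- stats::runif(1, 0, 2 * pi)
      elev <- stats::runif(1, -0.25, 0.25)        # near in-plane (thin slab)
      u <- c(cos(elev) * cos(phi), cos(elev) * sin(phi), sin(elev))
      len <- stats::runif(1, 0.45, 0.9) * rbase
      t <- vx * u[1] + vy * u[2] + vz * u[3]
      perp2 <- pmax(r2 - t^2, 0)
      along <- (t - 0.55 * rbase) / len
      prof <- exp(-perp2 / (2 * 1.1^2)) * (along > 0) * (along < 1) * (1 - along)
      core <- pmax(core, 0.7 * prof)
    }
    vol <- blur3d(core, c(0.8, 0.8, 0.5))
    if (spec$malignant_texture_amplitude > 0) {
      tex <- array(stats::rnorm(prod(d)), dim = d)
      tex <- blur3d(tex, c(1.1, 1.1, 0.7))
      tex <- tex / max(stats::sd(tex), 1e-12) * spec$malignant_texture_amplitude
      vol <- vol + tex * (m2 <= 1.25)
    }
  } else {
    s <- spec$benign_smoothness
    vol <- blur3d(core, c(s, s, max(0.5, s / 2)))
  }

  vol <- vol + 0.08
  if (spec$noise_sd > 0) vol <- vol + stats::rnorm(prod(d), sd = spec$noise_sd)
  array(clamp(vol, 0, 1), dim = d)
}

#' Generate a labeled phantom cohort
#'
#' Produces `2 * n_per_class` volumes with exactly balanced labels
#' (0 = benign, 1 = malignant) and one nodule per synthetic patient, so
#' patient-disjoint fold splitting is always satisfiable.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_cohort`: a list with `volumes` (list of
#'   [nodule_volume()]), integer `labels`, character `patient_ids`, and `spec`.
#' @export
#' @examples
#' cohort <- generate_cohort(phantom_spec(n_per_class = 2, seed = 7))
#' table(cohort$labels)
generate_cohort <- function(spec) {
  check_flag(inherits(spec, "phantom_spec"), "spec", "must be a phantom_spec")
  n <- 2L * spec$n_per_class
  labels <- rep(c(0L, 1L), each = spec$n_per_class)
  volumes <- vector("list", n)
  patient_ids <- sprintf("P%05d", seq_len(n))
  for (i in seq_len(n)) {
    volumes[[i]] <- with_seed(derive_seed(spec$seed, 101L, i), {
      nodule_volume(phantom_volume(spec, malignant = labels[i] == 1L),
                    spacing_mm = c(0.7, 0.7, 1),
                    patient_id = patient_ids[i])
    })
  }
  structure(list(volumes = volumes, labels = labels,
                 patient_ids = patient_ids, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d volumes (%d benign, %d malignant), %dx%dx%d voxels\n",
              length(x$volumes), sum(x$labels == 0), sum(x$labels == 1),
              x$spec$crop_shape[1], x$spec$crop_shape[2], x$spec$crop_shape[3]))
  invisible(x)
}

#' Export a cohort as NIfTI volumes with a CSV manifest
#'
#' @param cohort a `phantom_cohort` (or compatible list).
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data frame (patient_id, label, file).
#' @export
write_cohort_nifti <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort$volumes))
  for (i in seq_along(cohort$volumes)) {
    v <- cohort$volumes[[i]]
    files[i] <- file.path(dir, paste0(v$patient_id, ".nii.gz"))
    img <- RNifti::asNifti(v$voxels)
    RNifti::pixdim(img) <- v$spacing_mm
    RNifti::writeNifti(img, files[i])
  }
  manifest <- data.frame(patient_id = cohort$patient_ids,
                         label = cohort$labels, file = basename(files),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Export a cohort as raw numeric arrays with a CSV manifest
#'
#' Each volume is written as little-endian doubles; the manifest records the
#' grid dimensions and spacing needed to read it back with [read_cohort_raw()].
#'
#' @inheritParams write_cohort_nifti
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort_raw <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort$volumes))
  dims <- matrix(0L, length(cohort$volumes), 3)
  sp <- matrix(0, length(cohort$volumes), 3)
  for (i in seq_along(cohort$volumes)) {
    v <- cohort$volumes[[i]]
    files[i] <- paste0(v$patient_id, ".raw")
    con <- file(file.path(dir, files[i]), "wb")
    writeBin(as.numeric(v$voxels), con, size = 8, endian = "little")
    close(con)
    dims[i, ] <- dim(v$voxels)
    sp[i, ] <- v$spacing_mm
  }
  manifest <- data.frame(patient_id = cohort$patient_ids, label = cohort$labels,
                         file = files,
                         dim1 = dims[, 1], dim2 = dims[, 2], dim3 = dims[, 3],
                         sp1 = sp[, 1], sp2 = sp[, 2], sp3 = sp[, 3],
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
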