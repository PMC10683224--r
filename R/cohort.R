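# Cohort preparation ----------------------------------------------------------
#
# Label derivation from radiologist malignancy ratings (1-5 scale),
# preprocessing of raw sub-volumes to the 128x128x8 network input, and
# patient-disjoint k-fold splits.

#' Derive a benign/malignant/uncertain label from malignancy ratings
#'
#' The mean rating decides the class: mean <= 2.75 is benign, mean >= 3.125 is
#' malignant, anything in between is uncertain and excluded downstream. The
#' 2.75 boundary goes to benign and the 3.125 boundary to malignant.
#'
#' @param ratings numeric vector of malignancy scores, each in `[1, 5]`.
#' @return `"benign"`, `"malignant"` or `"uncertain"`.
#' @export
#' @examples
#' derive_label(c(2, 2, 2, 2))  # benign
#' derive_label(c(4, 4, 3, 3))  # malignant
#' derive_label(c(3, 3, 3, 3))  # uncertain
derive_label <- function(ratings) {
  check_flag(length(ratings) >= 1 && is.numeric(ratings) && all(is.finite(ratings)),
             "ratings", "must be at least one finite numeric score")
  check_flag(all(ratings >= 1 & ratings <= 5), "ratings",
             "every score must lie in [1, 5]")
  m <- mean(ratings)
  if (m <= 2.75) "benign" else if (m >= 3.125) "malignant" else "uncertain"
}

#' Construct a rated nodule record
#'
#' @param patient_id character scalar.
#' @param ratings numeric malignancy scores in `[1, 5]`.
#' @param nodule_id optional identifier.
#' @return An object of class `rated_nodule` with the mean rating, derived
#'   label, and an `included` flag (at least three raters and a decided label).
#' @export
rated_nodule <- function(patient_id, ratings, nodule_id = NA_character_) {
  label <- derive_label(ratings)
  structure(list(patient_id = as.character(patient_id),
                 nodule_id = as.character(nodule_id),
                 ratings = as.numeric(ratings),
                 mean_rating = mean(ratings),
                 label = label,
                 included = length(ratings) >= 3L && label != "uncertain"),
            class = "rated_nodule")
}

#' Read rated nodules from a ratings CSV
#'
#' Expects columns `patient_id`, `nodule_id`, and `rating_1`, `rating_2`, ...;
#' missing ratings (`NA`) are dropped per nodule.
#'
#' @param path CSV file path.
#' @return A list of [rated_nodule()] records.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rcols <- grep("^rating_", names(df), value = TRUE)
  check_flag(length(rcols) >= 1 && all(c("patient_id", "nodule_id") %in% names(df)),
             "path", "CSV must have patient_id, nodule_id and rating_* columns")
  lapply(seq_len(nrow(df)), function(i) {
    r <- as.numeric(df[i, rcols])
    rated_nodule(df$patient_id[i], r[!is.na(r)], df$nodule_id[i])
  })
}

# 1D linear interpolation matrix mapping n_in samples at spacing `sp` onto a
# 1-unit grid covering the same physical extent
resample_matrix_linear <- function(n_in, sp) {
  extent <- (n_in - 1) * sp
  n_out <- floor(extent + 1e-9) + 1L
  pos <- (seq_len(n_out) - 1) / sp + 1   # fractional input index
  lo <- clamp(floor(pos), 1, n_in)
  hi <- clamp(lo + 1, 1, n_in)
  w <- pos - lo
  B <- matrix(0, n_out, n_in)
  B[cbind(seq_len(n_out), lo)] <- B[cbind(seq_len(n_out), lo)] + (1 - w)
  B[cbind(seq_len(n_out), hi)] <- B[cbind(seq_len(n_out), hi)] + w
  B
}

# Keys cubic-convolution kernel (a = -0.5)
cubic_kernel <- function(x) {
  x <- abs(x)
  ifelse(x <= 1, 1.5 * x^3 - 2.5 * x^2 + 1,
         ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
}

# 1D cubic interpolation matrix from n_in to n_out (pixel-center convention,
# edge-clamped support)
resample_matrix_cubic <- function(n_in, n_out) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  B <- matrix(0, n_out, n_in)
  base <- floor(pos)
  for (o in -1:2) {
    idx <- base + o
    w <- cubic_kernel(pos - idx)
    idxc <- clamp(idx, 1, n_in)
    B[cbind(seq_len(n_out), idxc)] <- B[cbind(seq_len(n_out), idxc)] + w
  }
  B / rowSums(B)
}

#' Preprocess a raw nodule volume to the network input grid
#'
#' Resamples the through-plane axis to 1 mm spacing (linear interpolation),
#' extracts a zero-padded crop (default 56x56x8 voxels) centered on the nodule,
#' upsamples in-plane to 128x128 (cubic interpolation), applies a lung
#' intensity window of `[-1000, 400]` HU when the input looks like Hounsfield
#' units (identity for data already in `[0, 1]`), and min-max normalizes to
#' `[0, 1]`; a constant crop maps to all zeros.
#'
#' @param raw a [nodule_volume()].
#' @param center voxel coordinate triple (in the raw grid) of the nodule
#'   center; defaults to the volume center.
#' @param crop_shape voxel triple of the crop taken around the center.
#' @param out_shape voxel triple of the output grid.
#' @return A [nodule_volume()] of shape `out_shape` with intensities in
#'   `[0, 1]`.
#' @export
preprocess_volume <- function(raw, center = NULL,
                              crop_shape = c(56L, 56L, 8L),
                              out_shape = c(128L, 128L, 8L)) {
  check_flag(inherits(raw, "nodule_volume"), "raw", "must be a nodule_volume")
  v <- raw$voxels
  d <- dim(v)
  check_flag(prod(d) > 0, "raw", "volume is empty")
  check_flag(crop_shape[3] == out_shape[3], "out_shape",
             "through-plane extent must match crop_shape")
  if (is.null(center)) center <- (d + 1) / 2
  check_flag(length(center) == 3L && all(is.finite(center)), "center",
             "must be a finite voxel triple")

  # z-resample to 1 mm
  sz <- raw$spacing_mm[3]
  if (abs(sz - 1) > 1e-9 && d[3] > 1) {
    Bz <- resample_matrix_linear(d[3], sz)
    m <- matrix(aperm(v, c(3, 1, 2)), nrow = d[3])
    v <- aperm(array(Bz %*% m, dim = c(nrow(Bz), d[1], d[2])), c(2, 3, 1))
    center[3] <- (center[3] - 1) * sz + 1
    d <- dim(v)
  }

  # zero-padded centered crop
  crop <- array(0, dim = crop_shape)
  start <- round(center - crop_shape / 2)
  src_lo <- clamp(start + 1, 1, d)
  src_hi <- clamp(start + crop_shape, 0, d)
  if (all(src_hi >= src_lo)) {
    dst_lo <- src_lo - start
    dst_hi <- src_hi - start
    crop[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      v[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }

  # in-plane cubic upsampling
  Bx <- resample_matrix_cubic(crop_shape[1], out_shape[1])
  By <- resample_matrix_cubic(crop_shape[2], out_shape[2])
  a1 <- array(Bx %*% matrix(crop, nrow = crop_shape[1]),
              dim = c(out_shape[1], crop_shape[2], crop_shape[3]))
  a1 <- aperm(a1, c(2, 1, 3))
  a2 <- array(By %*% matrix(a1, nrow = crop_shape[2]),
              dim = c(out_shape[2], out_shape[1], crop_shape[3]))
  out <- aperm(a2, c(2, 1, 3))

  # HU window (identity for data already on a unit scale), then min-max
  if (min(out) < -5 || max(out) > 5) out <- clamp(out, -1000, 400)
  rng <- max(out) - min(out)
  out <- if (rng < 1e-12) array(0, dim = out_shape) else (out - min(out)) / rng

  sp_in <- raw$spacing_mm[1:2] * crop_shape[1:2] / out_shape[1:2]
  nodule_volume(out, spacing_mm = c(sp_in, 1), patient_id = raw$patient_id)
}

#' Build a patient-disjoint k-fold split
#'
#' All nodules from one patient land in the same fold; fold nodule counts are
#' kept as even as the patient grouping allows (greedy largest-first
#' assignment to the currently smallest fold, with a seeded shuffle for
#' determinism and tie-breaking).
#'
#' @param patient_ids character vector, one entry per nodule.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return An object of class `fold_split`: list with `fold_of_patient`
#'   (named integer vector of fold indices in `0..k-1`), `fold_of_nodule`
#'   (integer vector aligned with `patient_ids`), and `k`.
#' @export
#' @examples
#' make_folds(sprintf("P%02d", 1:10), k = 10, seed = 1)
make_folds <- function(patient_ids, k = 10L, seed = 1L) {
  k <- check_count(k, "k", min = 2L)
  check_flag(length(patient_ids) >= 1, "patient_ids", "must be nonempty")
  patient_ids <- as.character(patient_ids)
  counts <- table(patient_ids)
  patients <- names(counts)
  check_flag(length(patients) >= k, "k",
             sprintf("needs at least k = %d distinct patients, found %d",
                     k, length(patients)))
  ord <- with_seed(derive_seed(seed, 577L), sample(length(patients)))
  patients <- patients[ord]
  counts <- as.integer(counts)[ord]
  ord2 <- order(-counts)   # largest first; seeded order breaks ties
  fold_sizes <- numeric(k)
  fold_of_patient <- stats::setNames(integer(length(patients)), patients)
  for (i in ord2) {
    f <- which.min(fold_sizes)
    fold_of_patient[patients[i]] <- f - 1L
    fold_sizes[f] <- fold_sizes[f] + counts[i]
  }
  structure(list(fold_of_patient = fold_of_patient,
                 fold_of_nodule = unname(fold_of_patient[patient_ids]),
                 k = k),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> %d folds over %d patients; nodules per fold: %s\n",
              x$k, length(x$fold_of_patient),
              paste(tabulate(x$fold_of_nodule + 1L, x$k), collapse = " ")))
  invisible(x)
}

#' Read a cohort back from a raw-array export
#'
#' Counterpart of [write_cohort_raw()].
#'
#' @param dir directory containing `manifest.csv` and the `.raw` files.
#' @return A list with `volumes`, `labels`, `patient_ids` (phantom-cohort
#'   layout).
#' @export
read_cohort_raw <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  volumes <- lapply(seq_len(nrow(manifest)), function(i) {
    dims <- c(manifest$dim1[i], manifest$dim2[i], manifest$dim3[i])
    con <- file(file.path(dir, manifest$file[i]), "rb")
    x <- readBin(con, "numeric", n = prod(dims), size = 8, endian = "little")
    close(con)
    nodule_volume(array(x, dim = dims),
                  spacing_mm = c(manifest$sp1[i], manifest$sp2[i], manifest$sp3[i]),
                  patient_id = manifest$patient_id[i])
  })
  structure(list(volumes = volumes, labels = as.integer(manifest$label),
                 patient_ids = manifest$patient_id),
            class = "phantom_cohort")
}

#' Read one NIfTI volume as a nodule volume
#'
#' @param path NIfTI file path.
#' @param patient_id identifier attached to the volume.
#' @return A [nodule_volume()].
#' @export
read_volume_nifti <- function(path, patient_id = NA_character_) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  nodule_volume(array(as.numeric(img), dim = dim(img)[1:3]),
                spacing_mm = rep(sp, length.out = 3)[1:3],
                patient_id = patient_id)
}
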