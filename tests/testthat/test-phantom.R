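# Synthetic phantom generator

test_that("cohorts are balanced, patient-unique and seed-deterministic", {
  spec <- phantom_spec(n_per_class = 5, seed = 7)
  cohort <- generate_cohort(spec)
  expect_length(cohort$volumes, 10)
  expect_equal(sum(cohort$labels == 0), 5)
  expect_equal(sum(cohort$labels == 1), 5)
  expect_equal(anyDuplicated(cohort$patient_ids), 0L)
  for (v in cohort$volumes) {
    expect_equal(dim(v$voxels), c(56L, 56L, 8L))
    expect_true(min(v$voxels) >= 0 && max(v$voxels) <= 1)
  }
  again <- generate_cohort(phantom_spec(n_per_class = 5, seed = 7))
  expect_identical(lapply(cohort$volumes, `[[`, "voxels"),
                   lapply(again$volumes, `[[`, "voxels"))
  different <- generate_cohort(phantom_spec(n_per_class = 5, seed = 8))
  expect_false(identical(cohort$volumes[[1]]$voxels,
                         different$volumes[[1]]$voxels))
})

test_that("malignant phantoms carry more within-volume intensity variance", {
  cohort <- generate_cohort(phantom_spec(n_per_class = 15, seed = 11,
                                         noise_sd = 0,
                                         malignant_texture_amplitude = 0.4))
  vars <- vapply(cohort$volumes, function(v) stats::var(as.numeric(v$voxels)),
                 numeric(1))
  expect_gt(mean(vars[cohort$labels == 1]), mean(vars[cohort$labels == 0]))
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(0), "n_per_class")
  expect_error(phantom_spec(2, noise_sd = -0.1), "noise_sd")
  expect_error(phantom_spec(2, crop_shape = c(56, 56, 2)), "crop_shape")
  expect_error(phantom_spec(2, malignant_texture_amplitude = 1.5),
               "malignant_texture_amplitude")
  expect_error(generate_cohort(list()), "spec")
})

test_that("a GLCM-contrast threshold separates the classes (accuracy > 0.9)", {
  cohort <- cached_cohort(100, 0)
  params <- glcm_params(gray_levels = 32, z_direction_distances = 1,
                        inplane_distances = 1)
  contrast <- vapply(cohort$volumes, function(v) {
    f <- glcm3d_features(v, params)
    f[["glcm_1.0.0_d1_contrast"]]
  }, numeric(1))
  y <- cohort$labels
  # best single-threshold classifier on the contrast value
  cuts <- sort(unique(contrast))
  cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
  acc <- max(vapply(cuts, function(th)
    max(mean((contrast >= th) == (y == 1)),
        mean((contrast < th) == (y == 1))), numeric(1)))
  expect_gt(acc, 0.9)
})

test_that("cohort export round-trips through raw arrays and NIfTI", {
  cohort <- generate_cohort(phantom_spec(n_per_class = 2, seed = 3))
  d_raw <- withr::local_tempdir()
  d_nii <- withr::local_tempdir()
  write_cohort_raw(cohort, d_raw)
  back <- read_cohort_raw(d_raw)
  expect_identical(back$labels, cohort$labels)
  expect_identical(back$volumes[[4]]$voxels, cohort$volumes[[4]]$voxels)
  manifest <- write_cohort_nifti(cohort, d_nii)
  expect_setequal(manifest$patient_id, cohort$patient_ids)
  nv <- read_volume_nifti(file.path(d_nii, manifest$file[2]),
                          manifest$patient_id[2])
  expect_equal(nv$voxels, cohort$volumes[[2]]$voxels, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(nv$spacing_mm, cohort$volumes[[2]]$spacing_mm,
               tolerance = 1e-6)   # NIfTI stores pixdim as float32
})
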