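# Label derivation, preprocessing, fold construction

test_that("mean malignancy rating maps to the three-way label rule", {
  expect_equal(derive_label(c(2, 2, 2, 2)), "benign")
  expect_equal(derive_label(c(4, 4, 3, 3)), "malignant")
  expect_equal(derive_label(c(3, 3, 3, 3)), "uncertain")
  # boundaries: 2.75 goes to benign, 3.125 to malignant
  expect_equal(derive_label(c(2.75)), "benign")
  expect_equal(derive_label(c(3.125)), "malignant")
  expect_equal(derive_label(c(3.0)), "uncertain")
  expect_error(derive_label(c(0.5, 3)), "\\[1, 5\\]")
  expect_error(derive_label(numeric(0)), "ratings")
  # partition over the rating range is exhaustive and mutually exclusive
  for (m in seq(1, 5, by = 0.125)) {
    lab <- derive_label(m)
    expect_true(lab %in% c("benign", "malignant", "uncertain"))
    expect_equal(lab, if (m <= 2.75) "benign"
                      else if (m >= 3.125) "malignant" else "uncertain")
  }
})

test_that("rated nodules need three raters and a decided label for inclusion", {
  expect_true(rated_nodule("p1", c(1, 2, 1))$included)
  expect_false(rated_nodule("p1", c(1, 2))$included)       # too few raters
  expect_false(rated_nodule("p1", c(3, 3, 3))$included)    # uncertain
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,nodule_id,rating_1,rating_2,rating_3,rating_4",
               "p1,n1,2,2,2,2", "p2,n1,4,4,3,NA"), f)
  nods <- read_ratings(f)
  expect_length(nods, 2)
  expect_equal(nods[[1]]$label, "benign")
  expect_equal(nods[[2]]$mean_rating, mean(c(4, 4, 3)))
  expect_equal(nods[[2]]$label, "malignant")
})

test_that("preprocessing yields a normalized 128x128x8 grid", {
  const <- nodule_volume(array(0.5, dim = c(80, 80, 20)))
  out <- preprocess_volume(const, center = c(40, 40, 10))
  expect_equal(dim(out$voxels), c(128L, 128L, 8L))
  expect_true(all(out$voxels == 0))          # constant maps to zeros

  cohort <- generate_cohort(phantom_spec(n_per_class = 1, seed = 2))
  ph <- preprocess_volume(cohort$volumes[[2]])
  expect_equal(dim(ph$voxels), c(128L, 128L, 8L))
  expect_equal(min(ph$voxels), 0)
  expect_equal(max(ph$voxels), 1)

  # crop centered at a volume corner is zero-padded, shape preserved
  corner <- preprocess_volume(cohort$volumes[[1]], center = c(1, 1, 1))
  expect_equal(dim(corner$voxels), c(128L, 128L, 8L))

  # HU-scaled input passes through the lung window before scaling
  hu <- nodule_volume(array(seq(-1200, 600, length.out = 60 * 60 * 10),
                            dim = c(60, 60, 10)))
  whu <- preprocess_volume(hu, center = c(30, 30, 5))
  expect_true(all(whu$voxels >= 0 & whu$voxels <= 1))
})

test_that("through-plane resampling brings spacing to 1 mm", {
  set.seed(4)
  raw <- nodule_volume(array(runif(60 * 60 * 6), dim = c(60, 60, 6)),
                       spacing_mm = c(0.7, 0.7, 2.5))
  out <- preprocess_volume(raw, center = c(30, 30, 3))
  expect_equal(dim(out$voxels), c(128L, 128L, 8L))
  expect_equal(out$spacing_mm[3], 1)
})

test_that("folds are patient-disjoint, even, and reproducible", {
  split <- make_folds(sprintf("P%02d", 1:10), k = 10, seed = 1)
  expect_equal(sort(unname(split$fold_of_patient)), 0:9)

  # all nodules of a multi-nodule patient share a fold
  ids <- c(rep("pA", 3), sprintf("p%02d", 1:9))
  s2 <- make_folds(ids, k = 4, seed = 2)
  expect_length(unique(s2$fold_of_nodule[ids == "pA"]), 1)

  # 798 nodules from 600 patients with 1-2 nodules: folds within 78..82
  set.seed(5)
  sizes <- c(rep(2L, 198), rep(1L, 402))
  roster <- rep(sprintf("q%03d", 1:600), times = sizes)
  s3 <- make_folds(roster, k = 10, seed = 3)
  per_fold <- tabulate(s3$fold_of_nodule + 1L, 10)
  expect_equal(sum(per_fold), 798)
  expect_true(all(per_fold >= 78 & per_fold <= 82))
  # disjointness: every patient in exactly one fold
  expect_true(all(tapply(s3$fold_of_nodule, roster,
                         function(f) length(unique(f))) == 1))

  expect_identical(make_folds(roster, k = 10, seed = 3), s3)
  expect_false(identical(make_folds(roster, k = 10, seed = 4)$fold_of_nodule,
                         s3$fold_of_nodule))
  expect_error(make_folds(c("a", "b"), k = 3), "patients")
})
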