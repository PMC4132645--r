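test_that("masks are binarized: nonzero -> 1, zero and NaN -> 0", {
  g <- voxel_grid(c(4L, 4L, 4L), spacing = c(2, 2, 2))
  arr <- array(0, g$dims)
  arr[1, 1, 1] <- 0.4
  arr[2, 1, 1] <- 1
  arr[3, 1, 1] <- 2
  arr[4, 1, 1] <- NaN
  m <- lesion_mask(arr, g)
  expect_identical(sort(unique(as.vector(m$voxels))), c(0L, 1L))
  expect_identical(m$voxels[cbind(1:4, 1, 1)], c(1L, 1L, 1L, 0L))
})

test_that("minimum-volume rule excludes 26 voxels and accepts 27 at 2 mm", {
  g <- voxel_grid(c(10L, 10L, 10L), spacing = c(2, 2, 2))
  make <- function(n) {
    arr <- array(0L, g$dims)
    arr[seq_len(n) + 100L] <- 1L
    lesion_mask(arr, g)
  }
  # 26 x 8 mm^3 = 208 mm^3 < 216 mm^3
  expect_error(check_min_volume(make(26)), class = "lesionmapr_min_volume")
  expect_silent(check_min_volume(make(27)))  # 216 >= 216, inclusive
})

test_that("NIfTI mask round-trip preserves voxels and grid", {
  g <- voxel_grid(c(6L, 5L, 4L), spacing = c(2, 2, 2), origin = c(-4, 0, 2))
  arr <- array(0L, g$dims)
  arr[2:4, 2:4, 2:4] <- 1L
  m <- lesion_mask(arr, g, "rt")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask_volume(m, path)
  m2 <- read_mask_volume(path, min_volume_mm3 = 0, subject_id = "rt")
  expect_identical(m2$voxels, m$voxels)
  expect_equal(m2$grid$spacing, g$spacing)
  expect_equal(m2$grid$origin, g$origin)
  # reading back what was written is idempotent (binarization fixed point)
  path2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask_volume(m2, path2)
  expect_identical(read_mask_volume(path2, min_volume_mm3 = 0)$voxels,
                   m$voxels)
  # grid policy: mismatching reference grid is a hard error
  expect_error(read_mask_volume(path, reference_grid = voxel_grid(c(6L, 5L, 5L)),
                                min_volume_mm3 = 0),
               "does not match")
})

test_that("collapse_to_hemisphere keeps, mirrors, and projects correctly", {
  g <- voxel_grid(c(8L, 4L, 4L), spacing = c(2, 2, 2))
  mk <- function(ijk) {
    arr <- array(0L, g$dims)
    arr[ijk] <- 1L
    lesion_mask(arr, g)
  }
  # entirely canonical: identity
  left <- mk(cbind(2:3, 2, 2))
  expect_identical(collapse_to_hemisphere(left)$voxels, left$voxels)
  # entirely contralateral: mirrored to (d + 1 - i, j, k)
  right <- mk(cbind(7, 3, 2))
  out <- collapse_to_hemisphere(right)
  expect_identical(which_voxels(out$voxels), which_voxels(mk(cbind(2, 3, 2))$voxels))
  # bilateral 5 left / 30 right: right wins, left voxels discarded
  arr <- array(0L, g$dims)
  arr[1, 1:3, 1:2] <- 1L                      # 6 canonical voxels
  arr[6:8, 1:4, 1:3] <- 1L                    # 36 contralateral voxels
  bil <- collapse_to_hemisphere(lesion_mask(arr, g))
  expect_equal(sum(bil$voxels), 36)
  expect_true(all(which_voxels(bil$voxels)[, 1] <= 4))
  # projection: applying twice equals applying once
  expect_identical(collapse_to_hemisphere(bil)$voxels, bil$voxels)
  # exact tie keeps canonical side with a warning
  tie <- array(0L, g$dims)
  tie[4, 2, 2] <- 1L
  tie[5, 2, 2] <- 1L
  expect_warning(tied <- collapse_to_hemisphere(lesion_mask(tie, g)), "equal")
  expect_identical(which_voxels(tied$voxels),
                   which_voxels(mk(cbind(4, 2, 2))$voxels))
  # empty mask is rejected
  expect_error(collapse_to_hemisphere(mk(cbind(integer(0), integer(0), integer(0)))),
               class = "lesionmapr_empty_mask")
})

test_that("overlap map is additive and conserves total lesion volume", {
  ds <- staircase_dataset()
  ov <- overlap_map(ds)
  expect_identical(ov, ds$hit_count)
  expect_identical(ov[cbind(1:6, 2, 2)], 6:1)
  expect_equal(sum(ov), sum(vapply(ds$masks, function(m) sum(m$voxels), integer(1))))
  ds2 <- small_independent()
  expect_identical(overlap_map(ds2), ds2$hit_count)
})

test_that("vector field export: tsv rows and bit-exact NIfTI round-trip", {
  g <- voxel_grid(c(6L, 6L, 6L), spacing = c(2, 2, 2))
  f <- error_vector_field(g, matrix(c(2L, 3L, 4L), 1L),
                          matrix(c(3, 4, 0), 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_vector_field(f, path, "tsv")
  tab <- read.delim(path)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$magnitude_mm, 5)            # 3-4-5 triangle
  expect_equal(tab$x_mm, 2)
  # empty field: header-only file
  ef <- error_vector_field(g, matrix(integer(0), 0L, 3L),
                           matrix(numeric(0), 0L, 3L))
  path0 <- withr::local_tempfile(fileext = ".tsv")
  export_vector_field(ef, path0, "tsv")
  expect_equal(nrow(read.delim(path0)), 0L)
  expect_equal(length(readLines(path0)), 1L)
  # nifti-triplet round trip reproduces the vectors bit-exactly
  set.seed(9)
  vox <- unique(cbind(sample(6, 20, TRUE), sample(6, 20, TRUE),
                      sample(6, 20, TRUE)))
  storage.mode(vox) <- "integer"
  colnames(vox) <- c("i", "j", "k")
  vf <- error_vector_field(g, vox, matrix(rnorm(3 * nrow(vox)), ncol = 3L))
  prefix <- file.path(withr::local_tempdir(), "field")
  export_vector_field(vf, prefix, "nifti-triplet")
  back <- read_vector_field_nifti(prefix)
  ord_a <- order(linear_index(vf$voxels, g$dims))
  expect_identical(back$vectors, vf$vectors[ord_a, , drop = FALSE])
  expect_identical(back$voxels, vf$voxels[ord_a, , drop = FALSE])
})

test_that("cohort write/read round-trips and applies load-time exclusion", {
  ds <- small_stereotyped()
  dir <- withr::local_tempdir()
  write_cohort(ds, dir)
  back <- read_cohort(dir, min_volume_mm3 = 0)
  expect_equal(n_subjects(back), n_subjects(ds))
  expect_identical(back$hit_count, ds$hit_count)
  # a high floor excludes small lesions with a message, not an error
  vols <- vapply(ds$masks, lesion_volume_mm3, numeric(1))
  floor_mm3 <- as.numeric(stats::quantile(vols, 0.25))
  expect_message(sub <- read_cohort(dir, min_volume_mm3 = floor_mm3))
  expect_equal(n_subjects(sub), sum(vols >= floor_mm3))
})
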