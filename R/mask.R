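#' Binary lesion mask
#'
#' A single subject's lesion on a [voxel_grid()]. Input volumes are binarized
#' on construction: any nonzero, non-`NA` value marks damage; `NA`/`NaN` are
#' treated as undamaged (masks are binary by contract).
#'
#' @param voxels Numeric or logical 3-D array matching `grid$dims`.
#' @param grid A [voxel_grid()].
#' @param subject_id Opaque subject identifier.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(voxels, grid, subject_id = "subject") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(as.integer(dim(voxels)), grid$dims)) {
    stop("mask array dimensions do not match the grid")
  }
  v <- array(0L, grid$dims)
  v[!is.na(voxels) & voxels != 0] <- 1L
  structure(list(grid = grid, voxels = v, subject_id = as.character(subject_id)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> '%s': %d voxels (%.0f mm^3) on %d x %d x %d grid\n",
              x$subject_id, sum(x$voxels), lesion_volume_mm3(x),
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

#' Lesion volume in mm^3
#'
#' @param mask A [lesion_mask()].
#' @return Numeric volume: voxel count times voxel volume.
#' @export
lesion_volume_mm3 <- function(mask) {
  sum(mask$voxels) * prod(mask$grid$spacing)
}

#' Signal exclusion of an undersized lesion
#'
#' Lesions below the minimum volume (default 216 mm^3, i.e. 27 voxels at
#' 2 mm isotropic) are excluded from cohorts. The condition class
#' `lesionmapr_min_volume` lets callers distinguish exclusion from a hard
#' read failure.
#'
#' @param mask A [lesion_mask()].
#' @param min_volume_mm3 Minimum admissible lesion volume in mm^3.
#' @return `mask`, invisibly, if admissible.
#' @export
check_min_volume <- function(mask, min_volume_mm3 = 216) {
  vol <- lesion_volume_mm3(mask)
  if (vol < min_volume_mm3) {
    stop(errorCondition(
      sprintf("lesion '%s' excluded: volume %.0f mm^3 below minimum %.0f mm^3",
              mask$subject_id, vol, min_volume_mm3),
      class = c("lesionmapr_min_volume", "lesionmapr_error")))
  }
  invisible(mask)
}

#' Collapse a lesion onto the canonical hemisphere
#'
#' Unilateral stroke cohorts are conventionally pooled onto one hemisphere
#' before group analysis: the hemisphere containing the larger lesion
#' fraction is retained and, if it is the non-canonical side, the volume is
#' mirrored about the mid-sagittal plane. Mirroring reflects first-axis index
#' `i` to `d + 1 - i` (the inter-voxel midplane for even `d`), preserving the
#' grid without interpolation. Any voxels remaining on the non-canonical side
#' after the choice are discarded. An exact volume tie keeps the canonical
#' side unflipped with a warning; an empty mask is rejected.
#'
#' Applying the operation twice equals applying it once (projection).
#'
#' @param mask A [lesion_mask()].
#' @param midline_index Last first-axis index of the canonical hemisphere.
#' @return A [lesion_mask()] occupying only the canonical hemisphere.
#' @export
collapse_to_hemisphere <- function(mask,
                                   midline_index = default_midline(mask$grid)) {
  d <- mask$grid$dims[1L]
  stopifnot(is_count(midline_index), midline_index >= 1, midline_index < d)
  v <- mask$voxels
  n_left <- sum(v[seq_len(midline_index), , ])
  n_right <- sum(v) - n_left
  if (n_left + n_right == 0L) {
    stop(errorCondition(
      sprintf("lesion '%s' is empty: cannot assign a hemisphere",
              mask$subject_id),
      class = c("lesionmapr_empty_mask", "lesionmapr_error")))
  }
  if (n_right > n_left) {
    v <- v[rev(seq_len(d)), , , drop = FALSE]  # i <-> d + 1 - i
  } else if (n_right == n_left && n_right > 0L) {
    warning(sprintf("lesion '%s': equal volume in both hemispheres; %s",
                    mask$subject_id, "keeping the canonical side unflipped"))
  }
  v[seq.int(midline_index + 1L, d), , ] <- 0L
  out <- mask
  out$voxels <- v
  out
}

#' Lesion dataset: a cohort of co-registered masks
#'
#' Validates that all masks share one grid and stores the per-voxel hit
#' count (the overlap map), the core bookkeeping object for every analysis.
#'
#' @param masks List of [lesion_mask()] objects (length >= 1).
#' @return An object of class `lesion_dataset` with fields `grid`, `masks`,
#'   `hit_count`.
#' @export
lesion_dataset <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L,
            all(vapply(masks, inherits, logical(1L), "lesion_mask")))
  grid <- masks[[1L]]$grid
  for (m in masks) stop_if_grid_mismatch(grid, m$grid, m$subject_id)
  hit <- array(0L, grid$dims)
  for (m in masks) hit <- hit + m$voxels
  structure(list(grid = grid, masks = masks, hit_count = hit),
            class = "lesion_dataset")
}

#' @export
print.lesion_dataset <- function(x, ...) {
  cat(sprintf("<lesion_dataset> %d masks on %d x %d x %d grid; %d voxels hit at least once\n",
              length(x$masks), x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              sum(x$hit_count > 0L)))
  invisible(x)
}

#' Number of subjects in a dataset
#' @param dataset A [lesion_dataset()].
#' @return Integer count.
#' @export
n_subjects <- function(dataset) length(dataset$masks)

#' Overlap map of a cohort
#'
#' Recomputes the per-voxel count of masks damaged at each voxel by direct
#' summation (always equal to the stored `hit_count`; the recomputation is
#' the conservation check).
#'
#' @param dataset A [lesion_dataset()].
#' @return Integer 3-D array of per-voxel hit counts.
#' @export
overlap_map <- function(dataset) {
  stopifnot(inherits(dataset, "lesion_dataset"), length(dataset$masks) >= 1L)
  hit <- array(0L, dataset$grid$dims)
  for (m in dataset$masks) hit <- hit + m$voxels
  hit
}

#' Damage matrix restricted to a voxel set
#'
#' Builds the `V x N` binary matrix whose entry `(v, i)` indicates damage of
#' subject `i` at the `v`-th voxel of `voxels` (rows follow the canonical
#' voxel order of `voxels`). This is the workhorse representation for the
#' mass-univariate and multivariate engines.
#'
#' @param dataset A [lesion_dataset()].
#' @param voxels `n x 3` integer matrix of voxel indices.
#' @return Integer matrix, `nrow(voxels) x n_subjects(dataset)`.
#' @export
lesion_matrix <- function(dataset, voxels) {
  stopifnot(is.matrix(voxels), ncol(voxels) == 3L)
  lin <- linear_index(voxels, dataset$grid$dims)
  out <- vapply(dataset$masks, function(m) m$voxels[lin],
                integer(nrow(voxels)))
  # vapply simplifies to a bare vector when there is exactly one voxel
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(voxels))
  out
}
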