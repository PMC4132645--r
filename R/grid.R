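#' Voxel grid geometry
#'
#' A `voxel_grid` fixes the geometry every map in the package lives on: the
#' number of voxels per axis, the voxel spacing in mm, and the world (mm)
#' coordinate of the centre of voxel `(1,1,1)`. The world coordinate of voxel
#' `(i,j,k)` is `origin + (c(i,j,k) - 1) * spacing`; the mapping is exact and
#' invertible, no interpolation is ever performed.
#'
#' @param dims Integer triple, voxels per axis (all >= 1).
#' @param spacing Positive real triple, mm per voxel along each axis.
#' @param origin Real triple, mm coordinate of the first voxel centre.
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' g <- voxel_grid(c(32, 32, 32), spacing = c(2, 2, 2))
#' voxel_to_world(g, rbind(c(1, 1, 1), c(2, 3, 4)))
voxel_grid <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(dims) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(dims < 1L)) stop("all grid dims must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("all grid spacings must be positive")
  }
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Convert voxel indices to world (mm) coordinates
#'
#' @param grid A [voxel_grid()].
#' @param idx Integer vector of length 3 or an `n x 3` matrix of 1-based
#'   voxel indices.
#' @return A numeric vector or `n x 3` matrix of mm coordinates.
#' @export
voxel_to_world <- function(grid, idx) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1L)
  sweep(sweep(idx - 1, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
}

#' Convert world (mm) coordinates to the nearest voxel index
#'
#' @inheritParams voxel_to_world
#' @param mm Numeric vector of length 3 or `n x 3` matrix of mm coordinates.
#' @return Integer voxel indices (1-based); errors if outside the grid.
#' @export
world_to_voxel <- function(grid, mm) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(dim(mm))) mm <- matrix(mm, nrow = 1L)
  idx <- round(sweep(sweep(mm, 2L, grid$origin, "-"), 2L, grid$spacing, "/")) + 1
  if (any(idx < 1) || any(sweep(idx, 2L, grid$dims, ">"))) {
    stop("world coordinate falls outside the grid")
  }
  storage.mode(idx) <- "integer"
  idx
}

grids_equal <- function(a, b, tol = 1e-8) {
  identical(a$dims, b$dims) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volume") {
  if (!grids_equal(a, b)) {
    stop(sprintf("%s grid does not match the reference grid", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Default mid-sagittal plane index for a grid
#'
#' Synthetic grids carry no anatomical template, so the midline must be
#' declared: the canonical hemisphere is the first-axis slab `1..midline`.
#' The default splits the first axis in half.
#'
#' @inheritParams voxel_to_world
#' @return Integer midline index.
#' @export
default_midline <- function(grid) {
  as.integer(grid$dims[1L] %/% 2L)
}

#' Logical mask of the canonical hemisphere
#'
#' @inheritParams voxel_to_world
#' @param midline_index Last first-axis index belonging to the canonical
#'   hemisphere.
#' @return A logical 3-D array, `TRUE` inside the canonical hemisphere.
#' @export
hemisphere_mask <- function(grid, midline_index = default_midline(grid)) {
  stopifnot(is_count(midline_index), midline_index >= 1,
            midline_index <= grid$dims[1L])
  m <- array(FALSE, grid$dims)
  m[seq_len(midline_index), , ] <- TRUE
  m
}

# n x 3 index matrix of hemisphere voxels, canonical (column-major) order
hemisphere_voxels <- function(grid, midline_index = default_midline(grid)) {
  which_voxels(hemisphere_mask(grid, midline_index))
}

# logical/0-1 array -> n x 3 index matrix in canonical column-major order
which_voxels <- function(arr) {
  w <- which(arr != 0)
  idx <- arrayInd(w, dim(arr))
  storage.mode(idx) <- "integer"
  colnames(idx) <- c("i", "j", "k")
  idx
}
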