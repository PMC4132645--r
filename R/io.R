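#' @importFrom RNifti readNifti writeNifti asNifti xform pixdim sform<- pixdim<-
NULL

# extract an axis-aligned voxel_grid from a NIfTI header
grid_from_nifti <- function(img, path = "<volume>") {
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4) {
    warning(sprintf("%s: non-axis-aligned orientation; %s", path,
                    "using voxel spacings and offset only"))
  }
  spacing <- abs(diag(rot))
  if (any(spacing <= 0)) spacing <- abs(RNifti::pixdim(img))[1:3]
  voxel_grid(dim(img)[1:3], spacing = spacing, origin = xf[1:3, 4])
}

# write a numeric 3-D array on a grid as NIfTI-1
write_nifti_volume <- function(arr, grid, path, datatype = "auto") {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary lesion mask from a NIfTI volume
#'
#' Nonzero voxels map to 1, zero and `NaN` to 0. The grid is extracted from
#' the header (axis-aligned orientation assumed). If `reference_grid` is
#' given, a mismatching grid is a hard error: volumes are never resampled.
#' Lesions below `min_volume_mm3` raise a `lesionmapr_min_volume` condition
#' (exclusion, distinct from an unreadable file).
#'
#' @param path Path to a NIfTI volume.
#' @param reference_grid Optional [voxel_grid()] every loaded mask must match.
#' @param min_volume_mm3 Minimum lesion volume (default 216 mm^3); `0`
#'   disables the check.
#' @param subject_id Subject identifier; defaults to the file base name.
#' @return A [lesion_mask()].
#' @export
read_mask_volume <- function(path, reference_grid = NULL,
                             min_volume_mm3 = 216,
                             subject_id = sub("\\.nii(\\.gz)?$", "",
                                              basename(path))) {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img, path)
  if (!is.null(reference_grid)) stop_if_grid_mismatch(reference_grid, grid, path)
  mask <- lesion_mask(as.array(img), grid, subject_id)
  check_min_volume(mask, min_volume_mm3)
  mask
}

#' Write a lesion mask as NIfTI-1
#'
#' @param mask A [lesion_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_mask_volume <- function(mask, path) {
  write_nifti_volume(mask$voxels, mask$grid, path, datatype = "uint8")
}

#' Integer-labelled parcellation
#'
#' @param labels Non-negative integer 3-D array (0 = unassigned).
#' @param grid A [voxel_grid()] matching `dim(labels)`.
#' @return An object of class `parcellation` with fields `grid`, `labels`,
#'   `area_ids`.
#' @export
parcellation <- function(labels, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(as.integer(dim(labels)), grid$dims)) {
    stop("parcellation array dimensions do not match the grid")
  }
  lab <- array(as.integer(round(labels)), grid$dims)
  if (any(is.na(lab)) || any(lab < 0L)) {
    stop("parcellation labels must be non-negative integers (0 = unassigned)")
  }
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) stop("parcellation contains no labelled area")
  structure(list(grid = grid, labels = lab, area_ids = ids),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d areas on %d x %d x %d grid (%d labelled voxels)\n",
              length(x$area_ids), x$grid$dims[1], x$grid$dims[2],
              x$grid$dims[3], sum(x$labels > 0L)))
  invisible(x)
}

#' Voxel indices of one parcellation area
#'
#' @param parc A [parcellation()].
#' @param area Area id.
#' @return `n x 3` integer index matrix in canonical order.
#' @export
area_voxels <- function(parc, area) {
  if (!area %in% parc$area_ids) stop(sprintf("area %s not in parcellation", area))
  which_voxels(parc$labels == area)
}

#' Centre of mass (mm) of a voxel set
#'
#' The unweighted mean of the member voxels' world coordinates.
#'
#' @param grid A [voxel_grid()].
#' @param voxels `n x 3` integer index matrix.
#' @return Length-3 numeric mm coordinate.
#' @export
centre_of_mass <- function(grid, voxels) {
  stopifnot(is.matrix(voxels), nrow(voxels) >= 1L)
  colMeans(voxel_to_world(grid, voxels))
}

#' Read a parcellation from a NIfTI volume
#'
#' @inheritParams read_mask_volume
#' @return A [parcellation()].
#' @export
read_parcellation <- function(path, reference_grid = NULL) {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img, path)
  if (!is.null(reference_grid)) stop_if_grid_mismatch(reference_grid, grid, path)
  parcellation(as.array(img), grid)
}

#' Write a parcellation as NIfTI-1
#' @param parc A [parcellation()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_parcellation <- function(parc, path) {
  write_nifti_volume(parc$labels, parc$grid, path, datatype = "int16")
}

#' Error vector field
#'
#' Per-voxel displacement vectors (mm) from the true locus of each evaluated
#' model to its inferred locus, plus the evaluated voxels whose significance
#' result was empty (failures). `vectors` and `failures` partition the
#' evaluated voxel set.
#'
#' @param grid A [voxel_grid()].
#' @param voxels `n x 3` integer index matrix of evaluated voxels with a
#'   defined vector.
#' @param vectors `n x 3` numeric matrix of displacement vectors in mm.
#' @param failures `m x 3` integer index matrix of evaluated voxels with an
#'   empty significance result.
#' @return An object of class `error_vector_field`.
#' @export
error_vector_field <- function(grid, voxels, vectors,
                               failures = matrix(integer(0), 0L, 3L)) {
  stopifnot(inherits(grid, "voxel_grid"),
            is.matrix(voxels), ncol(voxels) == 3L,
            is.matrix(vectors), ncol(vectors) == 3L,
            nrow(voxels) == nrow(vectors),
            is.matrix(failures), ncol(failures) == 3L)
  if (nrow(voxels) > 0L && nrow(failures) > 0L) {
    if (length(intersect(linear_index(voxels, grid$dims),
                         linear_index(failures, grid$dims))) > 0L) {
      stop("a voxel cannot both carry a vector and be a failure")
    }
  }
  structure(list(grid = grid, voxels = voxels, vectors = vectors,
                 failures = failures),
            class = "error_vector_field")
}

#' @export
print.error_vector_field <- function(x, ...) {
  mags <- sqrt(rowSums(x$vectors^2))
  cat(sprintf("<error_vector_field> %d vectors (%d failures); mean magnitude %.2f mm\n",
              nrow(x$voxels), nrow(x$failures),
              if (length(mags)) mean(mags) else NA_real_))
  invisible(x)
}

#' Export an error vector field
#'
#' The `tsv` dialect writes one row per evaluated voxel with columns
#' `i j k x_mm y_mm z_mm dx_mm dy_mm dz_mm magnitude_mm` (tab-separated,
#' header row, `.` decimal; an empty field yields a header-only file). The
#' `nifti-triplet` dialect writes four scalar volumes, `<path>_dx.nii.gz`,
#' `_dy`, `_dz` (mm) and `_magnitude`, with `NaN` outside the evaluated set.
#'
#' @param field An [error_vector_field()].
#' @param path Output file (tsv) or path prefix (nifti-triplet).
#' @param format `"tsv"` or `"nifti-triplet"`.
#' @return The path(s) written, invisibly.
#' @export
export_vector_field <- function(field, path, format = c("tsv", "nifti-triplet")) {
  format <- match.arg(format)
  stopifnot(inherits(field, "error_vector_field"))
  if (format == "tsv") {
    mm <- voxel_to_world(field$grid, field$voxels)
    df <- data.frame(
      i = field$voxels[, 1L], j = field$voxels[, 2L], k = field$voxels[, 3L],
      x_mm = mm[, 1L], y_mm = mm[, 2L], z_mm = mm[, 3L],
      dx_mm = field$vectors[, 1L], dy_mm = field$vectors[, 2L],
      dz_mm = field$vectors[, 3L],
      magnitude_mm = sqrt(rowSums(field$vectors^2)))
    if (nrow(field$voxels) == 0L) df <- df[0L, ]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  comp <- c("dx", "dy", "dz", "magnitude")
  mags <- sqrt(rowSums(field$vectors^2))
  vals <- cbind(field$vectors, mags)
  lin <- linear_index(field$voxels, field$grid$dims)
  paths <- character(4L)
  for (c_i in seq_along(comp)) {
    arr <- array(NaN, field$grid$dims)
    arr[lin] <- vals[, c_i]
    paths[c_i] <- paste0(path, "_", comp[c_i], ".nii.gz")
    write_nifti_volume(arr, field$grid, paths[c_i], datatype = "double")
  }
  invisible(paths)
}

#' Read an error vector field written as a NIfTI triplet
#'
#' Inverse of [export_vector_field()] with `format = "nifti-triplet"`:
#' voxels that are `NaN` in all components are outside the evaluated set.
#'
#' @param path The path prefix used at export time.
#' @return An [error_vector_field()] (failure set not recoverable; empty).
#' @export
read_vector_field_nifti <- function(path) {
  comp <- c("dx", "dy", "dz")
  imgs <- lapply(comp, function(cc) RNifti::readNifti(paste0(path, "_", cc, ".nii.gz")))
  grid <- grid_from_nifti(imgs[[1L]], path)
  arrs <- lapply(imgs, as.array)
  defined <- !is.nan(arrs[[1L]])
  voxels <- which_voxels(defined)
  lin <- linear_index(voxels, grid$dims)
  vectors <- cbind(arrs[[1L]][lin], arrs[[2L]][lin], arrs[[3L]][lin])
  if (nrow(voxels) == 0L) vectors <- matrix(numeric(0), 0L, 3L)
  error_vector_field(grid, voxels, vectors)
}

#' Write a cohort as a NIfTI mask stack plus manifest
#'
#' One `.nii.gz` per subject under `dir`, plus `manifest.tsv` with columns
#' `subject_id`, `file`, `n_voxels`, `volume_mm3`.
#'
#' @param dataset A [lesion_dataset()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(dataset$masks))
  for (i in seq_along(dataset$masks)) {
    m <- dataset$masks[[i]]
    files[i] <- sprintf("%s.nii.gz", m$subject_id)
    write_mask_volume(m, file.path(dir, files[i]))
  }
  manifest <- data.frame(
    subject_id = vapply(dataset$masks, `[[`, character(1L), "subject_id"),
    file = files,
    n_voxels = vapply(dataset$masks, function(m) sum(m$voxels), integer(1L)),
    volume_mm3 = vapply(dataset$masks, lesion_volume_mm3, numeric(1L)))
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' Masks failing the minimum-volume check are excluded with a message;
#' unreadable files remain hard errors.
#'
#' @param dir Cohort directory containing `manifest.tsv`.
#' @param min_volume_mm3 Minimum lesion volume applied at load time.
#' @return A [lesion_dataset()].
#' @export
read_cohort <- function(dir, min_volume_mm3 = 216) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  masks <- list()
  ref <- NULL
  for (i in seq_len(nrow(manifest))) {
    m <- tryCatch(
      read_mask_volume(file.path(dir, manifest$file[i]), reference_grid = ref,
                       min_volume_mm3 = min_volume_mm3,
                       subject_id = manifest$subject_id[i]),
      lesionmapr_min_volume = function(e) {
        message(conditionMessage(e))
        NULL
      })
    if (!is.null(m)) {
      masks[[length(masks) + 1L]] <- m
      if (is.null(ref)) ref <- m$grid
    }
  }
  if (length(masks) == 0L) stop("no admissible masks in cohort")
  lesion_dataset(masks)
}
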