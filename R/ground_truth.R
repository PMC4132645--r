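#' Hypothetical ground-truth lesion-deficit model
#'
#' A rule assigning each subject an 'affected'/'unaffected' label from
#' lesion anatomy alone. Two kinds: `single-voxel` (a one-voxel critical
#' locus; the label is damage at that voxel, deterministic) and `area-set`
#' (the deficit occurs, with probability `deficit_probability`, when at
#' least `damage_fraction` of the voxels of *any* target area are damaged —
#' union rule across areas). The defaults (20% damage fraction, 90% deficit
#' probability) are the conventional stochastic area model.
#'
#' @param kind `"single-voxel"` or `"area-set"`.
#' @param target Length-3 voxel index (single-voxel) or a non-empty vector
#'   of parcellation area ids (area-set).
#' @param damage_fraction Fraction of an area's voxels that must be damaged,
#'   in `(0, 1]`. Ignored for single-voxel models.
#' @param deficit_probability Probability of a deficit when the damage
#'   criterion is met, in `(0, 1]`; `1` gives a deterministic model.
#'   Single-voxel models are deterministic unless overridden.
#' @param seed Integer seed for the per-subject deficit coin.
#' @return An object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(kind = c("single-voxel", "area-set"), target,
                              damage_fraction = 0.20,
                              deficit_probability = if (kind[1L] == "single-voxel") 1 else 0.90,
                              seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(damage_fraction > 0, damage_fraction <= 1,
            deficit_probability > 0, deficit_probability <= 1)
  if (kind == "single-voxel") {
    stopifnot(length(target) == 3L)
    target <- as.integer(target)
  } else {
    stopifnot(length(target) >= 1L)
    target <- as.integer(target)
  }
  structure(list(kind = kind, target = target,
                 damage_fraction = damage_fraction,
                 deficit_probability = deficit_probability,
                 seed = as.integer(seed)),
            class = "ground_truth_spec")
}

new_label_vector <- function(labels, spec = NULL) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  structure(labels, spec = spec, class = c("label_vector", "integer"))
}

#' Label a cohort from a single critical voxel
#'
#' `label[i] = 1` iff subject `i`'s lesion covers `voxel`. Deterministic;
#' `sum(labels)` always equals the voxel's hit count.
#'
#' @param dataset A [lesion_dataset()].
#' @param voxel Length-3 voxel index inside the grid.
#' @return A `label_vector` (integer 0/1 vector aligned to the masks).
#' @export
label_single_voxel <- function(dataset, voxel) {
  voxel <- as.integer(voxel)
  stopifnot(length(voxel) == 3L)
  if (any(voxel < 1L) || any(voxel > dataset$grid$dims)) {
    stop("voxel index out of bounds")
  }
  lin <- linear_index(matrix(voxel, 1L), dataset$grid$dims)
  labs <- vapply(dataset$masks, function(m) m$voxels[lin], integer(1L))
  new_label_vector(labs,
                   ground_truth_spec("single-voxel", voxel))
}

# smallest damaged-voxel count satisfying count / n_area >= fraction;
# integer comparison avoids floating-point trouble at the inclusive boundary
min_damage_count <- function(n_area, fraction) {
  k <- as.integer(ceiling(fraction * n_area - 1e-9))
  max(k, 1L)
}

#' Label a cohort from an area-set ground-truth model
#'
#' The damage criterion is met when at least `spec$damage_fraction` of the
#' voxels of any target area are damaged (inclusive threshold, compared on
#' integer counts; union across areas). Subjects meeting the criterion are
#' labelled affected with probability `spec$deficit_probability`, using one
#' coin per subject drawn from `spec$seed`; subjects failing the criterion
#' are always unaffected (stochasticity is one-sided). `noiseless = TRUE`
#' regenerates the deterministic labels (probability forced to 1), used when
#' evaluating a trained model against the criterion itself.
#'
#' @param dataset A [lesion_dataset()].
#' @param parc A [parcellation()] on the same grid.
#' @param spec A [ground_truth_spec()] of kind `"area-set"`.
#' @param noiseless Force `deficit_probability = 1`.
#' @return A `label_vector`. A single-class result (all 0 or all 1) is
#'   flagged with a warning; downstream inference rejects it.
#' @export
label_area_model <- function(dataset, parc, spec, noiseless = FALSE) {
  stopifnot(inherits(spec, "ground_truth_spec"), spec$kind == "area-set")
  stop_if_grid_mismatch(dataset$grid, parc$grid, "parcellation")
  if (!all(spec$target %in% parc$area_ids)) {
    stop("target area(s) missing from the parcellation: ",
         paste(setdiff(spec$target, parc$area_ids), collapse = ", "))
  }
  meets <- rep(FALSE, n_subjects(dataset))
  for (a in spec$target) {
    vox <- area_voxels(parc, a)
    need <- min_damage_count(nrow(vox), spec$damage_fraction)
    overlap <- colSums(lesion_matrix(dataset, vox))
    meets <- meets | (overlap >= need)
  }
  if (noiseless || spec$deficit_probability >= 1) {
    labs <- as.integer(meets)
  } else {
    coin <- withr::with_seed(spec$seed,
                             stats::runif(n_subjects(dataset)) < spec$deficit_probability)
    labs <- as.integer(meets & coin)
  }
  if (all(labs == 0L) || all(labs == 1L)) {
    warning("single-class label vector (all ", labs[1L],
            "): downstream inference will reject it")
  }
  new_label_vector(labs, spec)
}

#' Voxels tested in the mass-univariate analysis
#'
#' Only adequately sampled voxels are modelled: those damaged in at least
#' `min_hits` masks (default 4). Returned in canonical (column-major) order;
#' the count is non-increasing in `min_hits`.
#'
#' @param dataset A [lesion_dataset()].
#' @param min_hits Minimum per-voxel hit count (>= 1).
#' @return `n x 3` integer matrix of voxel indices.
#' @export
tested_voxels <- function(dataset, min_hits = 4L) {
  stopifnot(is_count(min_hits), min_hits >= 1L)
  which_voxels(dataset$hit_count >= min_hits)
}
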