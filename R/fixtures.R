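#' Two-region toy cohort (canonical mislocalization fixture)
#'
#' The textbook picture of stereotypy-driven mislocalization, built exactly:
#' a spatially extended critical area A (a 20-voxel line), a compact
#' non-critical collateral area B (a 3x3x3 block, well separated from A),
#' and a remote region C (an inferior slab). "Affected-type" lesions damage
#' a short random contiguous sub-segment of A *plus all of B* — B has zero
#' spatial variability across affected lesions while damage to A is
#' scattered. "Unaffected-type" lesions are compact blocks wholly inside C.
#' Under the ground-truth rule "any damage to A causes the deficit", every B
#' voxel is damaged if and only if the deficit is present, so B shows
#' perfect voxel-wise association while each A voxel shows only partial
#' association: mass-univariate inference drags the inferred locus from A
#' onto B.
#'
#' @param n_affected Number of affected-type lesions (>= 2).
#' @param n_unaffected Number of unaffected-type lesions (>= 2).
#' @param seed Integer seed.
#' @param seg_len Length (voxels) of the random sub-segment of A.
#' @return A list with elements `dataset` ([lesion_dataset()]),
#'   `parcellation` (areas `A = 1`, `B = 2`, `C = 3`), `A_voxels`,
#'   `B_voxels`, `labels_rule` (the area id + damage fraction reproducing
#'   the affected-type indicator via [label_area_model()]).
#' @export
make_two_region_toy <- function(n_affected, n_unaffected, seed = 1L,
                                seg_len = 3L) {
  stopifnot(n_affected >= 2L, n_unaffected >= 2L, seg_len >= 1L)
  grid <- voxel_grid(c(32L, 12L, 12L), spacing = c(2, 2, 2))
  labels <- array(0L, grid$dims)
  labels[2:21, 6L, 6L] <- 1L                       # A: extended line
  labels[26:28, 5:7, 5:7] <- 2L                    # B: compact block
  labels[, , 1:3] <- 3L                            # C: inferior slab
  parc <- parcellation(labels, grid)
  A <- area_voxels(parc, 1L)
  B <- area_voxels(parc, 2L)
  stopifnot(seg_len < nrow(A))
  B_lin <- linear_index(B, grid$dims)
  A_lin <- linear_index(A, grid$dims)

  masks <- vector("list", n_affected + n_unaffected)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n_affected)) {
      arr <- array(0L, grid$dims)
      start <- sample.int(nrow(A) - seg_len + 1L, 1L)
      arr[A_lin[start:(start + seg_len - 1L)]] <- 1L
      arr[B_lin] <- 1L
      masks[[i]] <- lesion_mask(arr, grid, sprintf("affected-%03d", i))
    }
    for (i in seq_len(n_unaffected)) {
      arr <- array(0L, grid$dims)
      cx <- sample(2:31, 1L); cy <- sample(2:11, 1L)
      arr[(cx - 1L):(cx + 1L), (cy - 1L):(cy + 1L), 1:3] <- 1L
      masks[[n_affected + i]] <- lesion_mask(arr, grid,
                                             sprintf("unaffected-%03d", i))
    }
  })
  list(dataset = lesion_dataset(masks), parcellation = parc,
       A_voxels = A, B_voxels = B,
       labels_rule = list(areas = 1L, damage_fraction = 1 / nrow(A)))
}

#' Stereotyped two-critical-area fixture
#'
#' The fixture behind the univariate-versus-multivariate localization
#' contrast. Two disjoint critical areas A1 and A2 (10-voxel lines) play the
#' role of two distant functional loci; a compact collateral region M plays
#' the role of tissue damaged by strokes reaching *either* area (the shared
#' proximal territory). Affected lesions damage a random contiguous
#' sub-segment of one critical area, include M with probability
#' `p_collateral_affected`, and carry an incidental remote block in the
#' inferior slab C; unaffected lesions carry the C block and include M with
#' probability `p_collateral_unaffected`. M is therefore the strongest
#' *single-voxel* correlate of the deficit even though it is not critical —
#' voxel-wise inference concentrates there — while the full damage pattern
#' over A1 and A2 determines the label exactly, which a multivariate
#' classifier can exploit.
#'
#' Ground truth: damage to >= `damage fraction` of either A1 or A2 (areas 1
#' and 2 of the returned parcellation) causes the deficit; the fixed
#' sub-segment length (`seg_len` of 10 voxels) keeps the cohort linearly
#' separable under the deterministic rule.
#'
#' @inheritParams make_two_region_toy
#' @param seg_len Sub-segment length (voxels) of the damaged critical area.
#' @param p_collateral_affected Probability that an affected lesion includes
#'   the collateral block M.
#' @param p_collateral_unaffected Probability that an unaffected lesion
#'   includes M.
#' @return A list with `dataset`, `parcellation` (areas `A1 = 1`, `A2 = 2`,
#'   `M = 3`, `C = 4`), `true_area_ids` (`c(1, 2)`), `truth_voxels` (index
#'   matrix of A1 union A2).
#' @export
make_two_area_fixture <- function(n_affected, n_unaffected, seed = 1L,
                                  seg_len = 4L,
                                  p_collateral_affected = 0.9,
                                  p_collateral_unaffected = 0.3) {
  stopifnot(n_affected >= 2L, n_unaffected >= 2L,
            seg_len >= 1L, seg_len <= 10L)
  grid <- voxel_grid(c(32L, 16L, 12L), spacing = c(2, 2, 2))
  labels <- array(0L, grid$dims)
  labels[4:13, 4L, 8L] <- 1L                       # A1: critical line
  labels[4:13, 12L, 8L] <- 2L                      # A2: critical line
  labels[24:26, 7:9, 7:9] <- 3L                    # M: shared collateral
  labels[, , 1:3] <- 4L                            # C: inferior slab
  parc <- parcellation(labels, grid)
  A1_lin <- linear_index(area_voxels(parc, 1L), grid$dims)
  A2_lin <- linear_index(area_voxels(parc, 2L), grid$dims)
  M_lin <- linear_index(area_voxels(parc, 3L), grid$dims)
  n_area <- length(A1_lin)

  add_c_block <- function(arr) {
    cx <- sample(2:31, 1L); cy <- sample(2:15, 1L)
    arr[(cx - 1L):(cx + 1L), (cy - 1L):(cy + 1L), 1:3] <- 1L
    arr
  }
  masks <- vector("list", n_affected + n_unaffected)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n_affected)) {
      arr <- array(0L, grid$dims)
      lin <- if (stats::runif(1) < 0.5) A1_lin else A2_lin
      start <- sample.int(n_area - seg_len + 1L, 1L)
      arr[lin[start:(start + seg_len - 1L)]] <- 1L
      if (stats::runif(1) < p_collateral_affected) arr[M_lin] <- 1L
      arr <- add_c_block(arr)
      masks[[i]] <- lesion_mask(arr, grid, sprintf("affected-%03d", i))
    }
    for (i in seq_len(n_unaffected)) {
      arr <- array(0L, grid$dims)
      if (stats::runif(1) < p_collateral_unaffected) arr[M_lin] <- 1L
      arr <- add_c_block(arr)
      masks[[n_affected + i]] <- lesion_mask(arr, grid,
                                             sprintf("unaffected-%03d", i))
    }
  })
  truth <- rbind(area_voxels(parc, 1L), area_voxels(parc, 2L))
  list(dataset = lesion_dataset(masks), parcellation = parc,
       true_area_ids = c(1L, 2L), truth_voxels = truth)
}
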