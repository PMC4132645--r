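#' Territory tree: a branching damage architecture
#'
#' Real stroke lesions are stereotyped: damage co-occurs along the branches
#' of the arterial tree, inducing strong voxel-voxel correlations. The
#' territory tree is this package's minimal generative architecture with
#' that property: the canonical hemisphere is partitioned into `n_branches`
#' contiguous territories by a seeded Voronoi construction (the first seed,
#' placed at the medial face centre, is the trunk), and territories are
#' organised into a rooted tree by breadth-first traversal of their
#' adjacency graph from the trunk. It is a model of stereotypy, not a claim
#' about vascular anatomy.
#'
#' @param grid A [voxel_grid()].
#' @param n_branches Total number of territories, including the trunk.
#' @param seed Integer seed; identical inputs give identical trees.
#' @param midline_index Canonical-hemisphere extent along the first axis.
#' @return An object of class `territory_tree` with fields `grid`,
#'   `midline_index`, `n_territories`, `parent` (NA for the root), `depth`,
#'   `territory_voxels` (list of index matrices), `labels` (3-D array,
#'   0 outside the hemisphere), `root_id` (always 1).
#' @export
#' @examples
#' tree <- make_territory_tree(voxel_grid(c(16, 16, 16), c(2, 2, 2)), 6, seed = 1)
#' tree$depth
make_territory_tree <- function(grid, n_branches, seed,
                                midline_index = default_midline(grid)) {
  stopifnot(is_count(n_branches), n_branches >= 1L)
  hemi <- hemisphere_voxels(grid, midline_index)
  if (nrow(hemi) < n_branches) {
    stop("grid too small to host the requested number of territories")
  }
  world <- voxel_to_world(grid, hemi)
  withr::with_seed(as.integer(seed), {
    # trunk seed: hemisphere voxel nearest the centre of the medial face
    medial <- voxel_to_world(grid, c(midline_index,
                                     ceiling(grid$dims[2L] / 2),
                                     ceiling(grid$dims[3L] / 2)))
    d_med <- rowSums(sweep(world, 2L, as.numeric(medial), "-")^2)
    seeds <- which.min(d_med)
    if (n_branches > 1L) {
      pool <- setdiff(seq_len(nrow(hemi)), seeds)
      seeds <- c(seeds, sample(pool, n_branches - 1L))
    }
  })
  # Voronoi assignment by world distance to the nearest seed; the hemisphere
  # slab is convex, so every cell is connected
  seed_world <- world[seeds, , drop = FALSE]
  d2 <- outer(rowSums(world^2), rep(1, n_branches)) -
    2 * world %*% t(seed_world) +
    outer(rep(1, nrow(world)), rowSums(seed_world^2))
  assign <- max.col(-d2, ties.method = "first")

  labels <- array(0L, grid$dims)
  labels[linear_index(hemi, grid$dims)] <- assign
  territory_voxels <- lapply(seq_len(n_branches),
                             function(t) hemi[assign == t, , drop = FALSE])

  # adjacency between territories via 6-connected voxel neighbours
  adj <- matrix(FALSE, n_branches, n_branches)
  for (ax in 1:3) {
    shift <- c(0L, 0L, 0L); shift[ax] <- 1L
    nb <- sweep(hemi, 2L, shift, "+")
    ok <- nb[, ax] <= grid$dims[ax]
    if (ax == 1L) ok <- ok & nb[, 1L] <= midline_index
    a <- assign[ok]
    b <- labels[linear_index(nb[ok, , drop = FALSE], grid$dims)]
    diff <- a != b & b > 0L
    if (any(diff)) {
      adj[cbind(a[diff], b[diff])] <- TRUE
      adj[cbind(b[diff], a[diff])] <- TRUE
    }
  }
  # breadth-first tree from the trunk (territory 1)
  parent <- rep(NA_integer_, n_branches)
  depth <- rep(NA_integer_, n_branches)
  depth[1L] <- 0L
  queue <- 1L
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    nbrs <- which(adj[cur, ] & is.na(depth))
    for (nb in nbrs) {
      parent[nb] <- cur
      depth[nb] <- depth[cur] + 1L
      queue <- c(queue, nb)
    }
  }
  if (anyNA(depth)) {
    # disconnected cells cannot occur on a convex slab, but guard anyway:
    # attach any orphan to the trunk
    orphan <- which(is.na(depth))
    parent[orphan] <- 1L
    depth[orphan] <- 1L
  }
  structure(list(grid = grid, midline_index = as.integer(midline_index),
                 n_territories = as.integer(n_branches), parent = parent,
                 depth = depth, territory_voxels = territory_voxels,
                 labels = labels, root_id = 1L),
            class = "territory_tree")
}

#' @export
print.territory_tree <- function(x, ...) {
  cat(sprintf("<territory_tree> %d territories (max depth %d) on %d x %d x %d grid\n",
              x$n_territories, max(x$depth), x$grid$dims[1], x$grid$dims[2],
              x$grid$dims[3]))
  invisible(x)
}

# path of territory ids from the root down to node u (inclusive)
tree_path_to <- function(tree, u) {
  path <- u
  while (!is.na(tree$parent[path[1L]])) path <- c(tree$parent[path[1L]], path)
  path
}

#' Sample one stereotyped lesion from a territory tree
#'
#' Emulates an occlusion along the branching architecture: a territory `u`
#' is drawn uniformly and the lesion is the union of the territories on the
#' root-to-`u` path, each intermediate territory at depth `d` retained with
#' probability `incl_decay^d` (the trunk and `u` itself always). Proximal
#' territories are therefore damaged more consistently than distal ones —
#' damage anywhere distal co-occurs with a low-variance proximal core, which
#' is exactly the stereotypy that biases mass-univariate mapping. Voxel-level
#' Bernoulli erosion at `noise_rate` then roughens the boundary. Lesions
#' below the volume floor are redrawn (bounded retries).
#'
#' @param tree A [make_territory_tree()] result.
#' @param noise_rate Per-voxel erosion probability in `[0, 1)`.
#' @param incl_decay Depth-decay of territory inclusion probability, in
#'   `(0, 1]`.
#' @param min_volume_voxels Volume floor in voxels (27 voxels = 216 mm^3 at
#'   2 mm isotropic).
#' @param seed Integer seed.
#' @param max_retries Redraw budget for the volume floor.
#' @param subject_id Subject identifier.
#' @return A [lesion_mask()].
#' @export
sample_stereotyped_lesion <- function(tree, noise_rate = 0.1,
                                      incl_decay = 0.85,
                                      min_volume_voxels = 27L,
                                      seed = 1L, max_retries = 25L,
                                      subject_id = "subject") {
  stopifnot(inherits(tree, "territory_tree"),
            noise_rate >= 0, noise_rate < 1,
            incl_decay > 0, incl_decay <= 1)
  grid <- tree$grid
  withr::with_seed(as.integer(seed), {
    for (try in seq_len(max_retries)) {
      u <- sample.int(tree$n_territories, 1L)
      path <- tree_path_to(tree, u)
      keep <- stats::runif(length(path)) < incl_decay^tree$depth[path]
      keep[path == tree$root_id] <- TRUE
      keep[path == u] <- TRUE
      vox <- do.call(rbind, tree$territory_voxels[path[keep]])
      if (noise_rate > 0) {
        vox <- vox[stats::runif(nrow(vox)) >= noise_rate, , drop = FALSE]
      }
      if (nrow(vox) >= min_volume_voxels) {
        arr <- array(0L, grid$dims)
        arr[linear_index(vox, grid$dims)] <- 1L
        return(lesion_mask(arr, grid, subject_id))
      }
    }
  })
  stop(sprintf("could not satisfy the volume floor (%d voxels) in %d draws",
               min_volume_voxels, max_retries))
}

#' Sample one independent-damage (null) lesion
#'
#' The counterfactual generator: i.i.d. Bernoulli damage at every voxel of
#' the canonical hemisphere, with no spatial structure whatsoever. On such a
#' cohort mass-univariate mislocalization has no preferred direction and
#' averages out near zero.
#'
#' @param grid A [voxel_grid()].
#' @param per_voxel_p Damage probability per voxel, in `(0, 1)`.
#' @param seed Integer seed.
#' @param midline_index Canonical-hemisphere extent.
#' @inheritParams sample_stereotyped_lesion
#' @return A [lesion_mask()].
#' @export
sample_independent_lesion <- function(grid, per_voxel_p, seed = 1L,
                                      midline_index = default_midline(grid),
                                      min_volume_voxels = 27L,
                                      max_retries = 25L,
                                      subject_id = "subject") {
  stopifnot(per_voxel_p > 0, per_voxel_p < 1)
  hemi <- hemisphere_voxels(grid, midline_index)
  expected <- nrow(hemi) * per_voxel_p
  if (expected < min_volume_voxels / 3) {
    stop("per_voxel_p incompatible with the volume floor: expected volume ",
         sprintf("%.1f voxels << minimum %d", expected, min_volume_voxels))
  }
  lin <- linear_index(hemi, grid$dims)
  withr::with_seed(as.integer(seed), {
    for (try in seq_len(max_retries)) {
      dam <- stats::runif(nrow(hemi)) < per_voxel_p
      if (sum(dam) >= min_volume_voxels) {
        arr <- array(0L, grid$dims)
        arr[lin[dam]] <- 1L
        return(lesion_mask(arr, grid, subject_id))
      }
    }
  })
  stop(sprintf("could not satisfy the volume floor (%d voxels) in %d draws",
               min_volume_voxels, max_retries))
}

#' Sample one blob lesion
#'
#' A compact axis-aligned box of random centre and half-widths inside the
#' canonical hemisphere: spatially localized but without branching
#' structure. Mainly useful as a third, intermediate cohort type.
#'
#' @inheritParams sample_independent_lesion
#' @param radius_range Integer range of the box half-width (voxels).
#' @return A [lesion_mask()].
#' @export
sample_blob_lesion <- function(grid, radius_range = c(2L, 4L), seed = 1L,
                               midline_index = default_midline(grid),
                               min_volume_voxels = 27L, max_retries = 25L,
                               subject_id = "subject") {
  withr::with_seed(as.integer(seed), {
    for (try in seq_len(max_retries)) {
      radii <- seq.int(radius_range[1L], radius_range[2L])
      r <- radii[sample.int(length(radii), 1L)]
      ctr <- c(sample.int(midline_index, 1L),
               sample.int(grid$dims[2L], 1L),
               sample.int(grid$dims[3L], 1L))
      lo <- pmax(ctr - r, 1L)
      hi <- pmin(ctr + r, c(midline_index, grid$dims[2L], grid$dims[3L]))
      n_box <- prod(hi - lo + 1L)
      if (n_box >= min_volume_voxels) {
        arr <- array(0L, grid$dims)
        arr[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- 1L
        return(lesion_mask(arr, grid, subject_id))
      }
    }
  })
  stop(sprintf("could not satisfy the volume floor (%d voxels) in %d draws",
               min_volume_voxels, max_retries))
}

#' Simulate a lesion cohort
#'
#' Convenience wrapper drawing `n_subjects` lesions from one generator, with
#' per-subject seeds derived from `seed` (see [derive_seed()]); the result
#' is a pure function of its arguments.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param generator `"stereotyped"`, `"independent"` or `"blob"`.
#' @param grid A [voxel_grid()]; defaults to the desk-scale 32^3 grid at
#'   2 mm isotropic.
#' @param seed Integer cohort seed.
#' @param n_branches Territory count for the stereotyped generator.
#' @param per_voxel_p Damage probability for the independent generator.
#' @param midline_index Canonical-hemisphere extent.
#' @param min_volume_voxels Volume floor in voxels.
#' @param ... Further arguments passed to the per-subject sampler.
#' @return A [lesion_dataset()]; the generating `territory_tree` (if any) is
#'   attached as attribute `"tree"`.
#' @export
simulate_cohort <- function(n_subjects, generator = c("stereotyped",
                                                      "independent", "blob"),
                            grid = voxel_grid(c(32L, 32L, 32L), c(2, 2, 2)),
                            seed = 1L, n_branches = 12L, per_voxel_p = 0.05,
                            midline_index = default_midline(grid),
                            min_volume_voxels = 27L, ...) {
  generator <- match.arg(generator)
  stopifnot(is_count(n_subjects), n_subjects >= 2L)
  tree <- NULL
  if (generator == "stereotyped") {
    tree <- make_territory_tree(grid, n_branches,
                                seed = derive_seed(seed, "territory-tree"),
                                midline_index = midline_index)
  }
  masks <- lapply(seq_len(n_subjects), function(i) {
    sid <- sprintf("sub-%04d", i)
    s_i <- derive_seed(seed, paste0("subject-", i))
    switch(generator,
           stereotyped = sample_stereotyped_lesion(
             tree, seed = s_i, min_volume_voxels = min_volume_voxels,
             subject_id = sid, ...),
           independent = sample_independent_lesion(
             grid, per_voxel_p, seed = s_i, midline_index = midline_index,
             min_volume_voxels = min_volume_voxels, subject_id = sid, ...),
           blob = sample_blob_lesion(
             grid, seed = s_i, midline_index = midline_index,
             min_volume_voxels = min_volume_voxels, subject_id = sid, ...))
  })
  ds <- lesion_dataset(masks)
  attr(ds, "tree") <- tree
  ds
}

#' Seeded Voronoi-style synthetic parcellation
#'
#' Partitions the canonical hemisphere into `n_areas` contiguous labelled
#' areas (a stand-in for an anatomical atlas such as a Brodmann template):
#' `n_areas` seed voxels are drawn and every hemisphere voxel is assigned to
#' its nearest seed in world coordinates. Deterministic given the seed.
#'
#' @param grid A [voxel_grid()].
#' @param n_areas Number of areas (>= 1).
#' @param seed Integer seed.
#' @param midline_index Canonical-hemisphere extent.
#' @return A [parcellation()].
#' @export
make_synthetic_parcellation <- function(grid, n_areas, seed,
                                        midline_index = default_midline(grid)) {
  stopifnot(is_count(n_areas), n_areas >= 1L)
  hemi <- hemisphere_voxels(grid, midline_index)
  if (nrow(hemi) < n_areas) stop("grid too small for the requested area count")
  world <- voxel_to_world(grid, hemi)
  withr::with_seed(as.integer(seed), {
    seeds <- sample.int(nrow(hemi), n_areas)
  })
  seed_world <- world[seeds, , drop = FALSE]
  d2 <- outer(rowSums(world^2), rep(1, n_areas)) -
    2 * world %*% t(seed_world) +
    outer(rep(1, nrow(world)), rowSums(seed_world^2))
  assign <- max.col(-d2, ties.method = "first")
  labels <- array(0L, grid$dims)
  labels[linear_index(hemi, grid$dims)] <- assign
  parcellation(labels, grid)
}
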