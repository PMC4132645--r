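test_that("territory tree partitions the hemisphere and is deterministic", {
  g <- voxel_grid(c(32L, 32L, 32L), spacing = c(2, 2, 2))
  tree <- make_territory_tree(g, 8L, seed = 11)
  hemi <- hemisphere_voxels(g)
  # disjoint-union audit by exhaustive voxel count
  all_vox <- do.call(rbind, tree$territory_voxels)
  expect_equal(nrow(all_vox), nrow(hemi))
  expect_identical(sort(linear_index(all_vox, g$dims)),
                   sort(linear_index(hemi, g$dims)))
  expect_true(all(vapply(tree$territory_voxels, nrow, integer(1)) >= 1L))
  # rooted tree: root has no parent, everyone else exactly one, depths consistent
  expect_true(is.na(tree$parent[tree$root_id]))
  expect_true(all(!is.na(tree$parent[-tree$root_id])))
  expect_true(all(tree$depth[-tree$root_id] ==
                    tree$depth[tree$parent[-tree$root_id]] + 1L))
  # determinism
  tree2 <- make_territory_tree(g, 8L, seed = 11)
  expect_identical(tree2$labels, tree$labels)
  expect_identical(tree2$parent, tree$parent)
  # degenerate tree: one territory covering the hemisphere
  t1 <- make_territory_tree(g, 1L, seed = 3)
  expect_equal(nrow(t1$territory_voxels[[1]]), nrow(hemi))
  expect_error(make_territory_tree(voxel_grid(c(2L, 1L, 1L)), 5L, seed = 1),
               "too small")
})

test_that("stereotyped lesions keep the trunk core and correlate along branches", {
  g <- voxel_grid(c(16L, 16L, 16L), spacing = c(2, 2, 2))
  tree <- make_territory_tree(g, 8L, seed = 6)
  # no-randomness path: single-territory tree, zero noise => lesion == trunk
  t1 <- make_territory_tree(g, 1L, seed = 6)
  m0 <- sample_stereotyped_lesion(t1, noise_rate = 0, seed = 5)
  expect_identical(which_voxels(m0$voxels), t1$territory_voxels[[1]])
  # determinism of the sampler
  expect_identical(sample_stereotyped_lesion(tree, seed = 99)$voxels,
                   sample_stereotyped_lesion(tree, seed = 99)$voxels)

  draws <- lapply(1:500, function(i)
    sample_stereotyped_lesion(tree, seed = 1000 + i))
  # trunk voxels are damaged more often than distal-leaf voxels
  trunk_vox <- tree$territory_voxels[[tree$root_id]][1, , drop = FALSE]
  leaf <- which.max(tree$depth)
  leaf_vox <- tree$territory_voxels[[leaf]][1, , drop = FALSE]
  hit_at <- function(vox) {
    lin <- linear_index(vox, g$dims)
    vapply(draws, function(m) m$voxels[lin], integer(1))
  }
  expect_gt(mean(hit_at(trunk_vox)), mean(hit_at(leaf_vox)))
  # same-branch territory damage correlates more than cross-branch; the
  # fixture tree (seed 6) has grandchildren under two distinct branches
  children <- which(tree$parent == tree$root_id)
  sub_a <- which(tree$parent == children[1])
  sub_b <- which(tree$parent == children[2])
  expect_gte(length(sub_a), 1L)
  expect_gte(length(sub_b), 1L)
  dam_frac <- function(t_id) {
    lin <- linear_index(tree$territory_voxels[[t_id]], g$dims)
    vapply(draws, function(m) mean(m$voxels[lin]), numeric(1))
  }
  same_branch <- cor(dam_frac(children[1]), dam_frac(sub_a[1]))
  cross_branch <- cor(dam_frac(children[1]), dam_frac(sub_b[1]))
  expect_gt(same_branch, cross_branch)
})

test_that("independent lesions are uncorrelated Bernoulli damage", {
  g <- voxel_grid(c(12L, 12L, 12L), spacing = c(2, 2, 2))
  # near-1 damage probability fills the hemisphere
  full <- sample_independent_lesion(g, 0.999, seed = 1, min_volume_voxels = 10)
  expect_gt(sum(full$voxels) / nrow(hemisphere_voxels(g)), 0.99)
  expect_error(sample_independent_lesion(g, 0.001, seed = 1),
               "incompatible")

  p <- 0.15
  draws <- lapply(1:600, function(i)
    sample_independent_lesion(g, p, seed = 2000 + i, min_volume_voxels = 10))
  hemi <- hemisphere_voxels(g)
  lin <- linear_index(hemi, g$dims)
  X <- vapply(draws, function(m) m$voxels[lin], integer(length(lin)))
  # mean lesion fraction within 3 standard errors of p
  frac <- colMeans(X)
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - p), 3 * se + 1e-12)
  # pairwise voxel damage correlation ~ 0
  set.seed(4)
  pairs <- cbind(sample(nrow(hemi), 40), sample(nrow(hemi), 40))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  rs <- apply(pairs, 1, function(pr) cor(X[pr[1], ], X[pr[2], ]))
  expect_lt(max(abs(rs)), 0.2)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("cohort generators are pure functions of (spec, seed)", {
  g <- voxel_grid(c(12L, 12L, 12L), spacing = c(2, 2, 2))
  a <- simulate_cohort(10, "stereotyped", grid = g, seed = 77,
                       n_branches = 5, min_volume_voxels = 10)
  b <- simulate_cohort(10, "stereotyped", grid = g, seed = 77,
                       n_branches = 5, min_volume_voxels = 10)
  expect_identical(a$hit_count, b$hit_count)
  expect_identical(lapply(a$masks, `[[`, "voxels"),
                   lapply(b$masks, `[[`, "voxels"))
  d <- simulate_cohort(10, "blob", grid = g, seed = 77, min_volume_voxels = 10)
  expect_identical(d$hit_count,
                   simulate_cohort(10, "blob", grid = g, seed = 77,
                                   min_volume_voxels = 10)$hit_count)
  # every emitted mask is binary and above the volume floor
  for (ds in list(a, d, small_independent())) {
    for (m in ds$masks) {
      expect_true(all(m$voxels %in% c(0L, 1L)))
      expect_gte(sum(m$voxels), 10)
    }
  }
})

test_that("synthetic parcellation partitions the hemisphere deterministically", {
  g <- voxel_grid(c(16L, 16L, 16L), spacing = c(2, 2, 2))
  parc <- make_synthetic_parcellation(g, 7L, seed = 5)
  hemi <- hemisphere_mask(g)
  expect_identical(parc$labels > 0L, hemi)     # every hemisphere voxel labelled
  expect_identical(parc$area_ids, 1:7)
  expect_identical(make_synthetic_parcellation(g, 7L, seed = 5)$labels,
                   parc$labels)
  one <- make_synthetic_parcellation(g, 1L, seed = 5)
  expect_equal(sum(one$labels == 1L), sum(hemi))
})
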