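test_that("single-voxel sweep equals model-by-model computation", {
  ds <- small_stereotyped()
  res <- single_voxel_sweep(ds, min_hits = 4L, alpha = 0.01)
  tested <- tested_voxels(ds, 4L)
  thr <- bonferroni_threshold(0.01, nrow(tested))
  # independently recompute a handful of models through the one-model API
  set.seed(30)
  pick <- sample(nrow(tested), 8)
  lin_all <- linear_index(res$field$voxels, ds$grid$dims)
  for (ix in pick) {
    v <- tested[ix, ]
    labs <- label_single_voxel(ds, v)
    sig <- significance(compute_pmap(ds, labs, tested = tested), thr)
    pos <- match(linear_index(matrix(v, 1), ds$grid$dims), lin_all)
    if (sig$empty) {
      expect_true(is.na(pos))
    } else {
      d <- displacement(drop(voxel_to_world(ds$grid, v)), sig$com_mm)
      expect_equal(res$field$vectors[pos, ], d$vector)
    }
  }
  # bookkeeping: every tested voxel is either a vector or a failure
  expect_equal(nrow(res$field$voxels) + nrow(res$field$failures), nrow(tested))
  expect_equal(res$summary$n_models, nrow(tested))
})

test_that("sweep results are invariant to subject order and grid translation", {
  ds <- small_stereotyped()
  base <- single_voxel_sweep(ds, min_hits = 4L)
  # joint permutation of masks leaves the field unchanged
  set.seed(31)
  perm <- sample(n_subjects(ds))
  ds_p <- lesion_dataset(ds$masks[perm])
  perm_res <- single_voxel_sweep(ds_p, min_hits = 4L)
  expect_equal(perm_res$field$vectors, base$field$vectors)
  expect_identical(perm_res$field$voxels, base$field$voxels)
  # translating the grid origin translates loci but not displacements
  g2 <- voxel_grid(ds$grid$dims, ds$grid$spacing, ds$grid$origin + c(10, -4, 2))
  ds_t <- lesion_dataset(lapply(ds$masks, function(m) {
    m$grid <- g2
    m
  }))
  trans <- single_voxel_sweep(ds_t, min_hits = 4L)
  expect_equal(trans$field$vectors, base$field$vectors)
  expect_equal(trans$summary$mean_mm, base$summary$mean_mm)
})

test_that("stereotyped cohorts mislocalize more than matched independent ones", {
  ster <- small_stereotyped()
  ind <- small_independent()
  s_ster <- single_voxel_sweep(ster, min_hits = 4L)
  s_ind <- single_voxel_sweep(ind, min_hits = 4L)
  expect_gt(s_ster$summary$mean_mm, s_ind$summary$mean_mm)
  # the null cohort's mean displacement vector has no preferred direction
  mean_vec <- colMeans(s_ind$field$vectors)
  expect_lt(sqrt(sum(mean_vec^2)), 2)  # within one voxel spacing
})

test_that("area sweep is deterministic for probability-1 models and tracks areas", {
  ds <- small_stereotyped()
  parc <- make_synthetic_parcellation(ds$grid, 5L, seed = 9)
  a <- area_model_sweep(ds, parc, damage_fraction = 0.2,
                        deficit_probability = 1, seed = 1)
  b <- area_model_sweep(ds, parc, damage_fraction = 0.2,
                        deficit_probability = 1, seed = 999)
  expect_equal(a$per_model, b$per_model)     # seed-independent when p = 1
  expect_equal(a$n_models, 5L)
  # com and peak loci come from the same p-maps but need not coincide
  pk <- area_model_sweep(ds, parc, damage_fraction = 0.2,
                         deficit_probability = 1, locus_mode = "peak")
  expect_equal(pk$n_models, a$n_models)
  expect_equal(pk$per_model$area, a$per_model$area)
})

test_that("threshold sweep produces one complete summary per fraction", {
  ds <- small_stereotyped()
  parc <- make_synthetic_parcellation(ds$grid, 4L, seed = 9)
  sw <- threshold_sweep(ds, parc, fractions = c(0.1, 0.3, 0.6),
                        deficit_probability = 1)
  expect_length(sw$summaries, 3L)
  expect_true(all(sw$table$n_models == 4L))
  means <- vapply(sw$summaries, `[[`, numeric(1), "mean_mm")
  expect_equal(sw$mean_of_means_mm, mean(means[is.finite(means)]))
  expect_error(threshold_sweep(ds, parc, fractions = c(0.1, 1.5)))
  # default fraction grid spans 5%..60% in 12 bins
  expect_equal(eval(formals(threshold_sweep)$fractions),
               seq(0.05, 0.60, by = 0.05))
})

test_that("multi-area model supports top-k retention and Dice reporting", {
  fx <- make_two_area_fixture(40, 40, seed = 13)
  res <- multi_area_model(fx$dataset, fx$parcellation, fx$true_area_ids,
                          deficit_probability = 1, retain = "topk")
  k <- nrow(fx$truth_voxels)
  expect_equal(nrow(res$retained), k)          # top-k contract
  expect_true(res$dice_union >= 0 && res$dice_union <= 1)
  expect_equal(nrow(res$displacement_from_each), 2L)
  res5 <- multi_area_model(fx$dataset, fx$parcellation, fx$true_area_ids,
                           deficit_probability = 1, retain = "topk", k = 5L)
  expect_equal(nrow(res5$retained), 5L)
  # retained top-k sets are nested
  lin <- function(m) linear_index(m, fx$dataset$grid$dims)
  expect_true(all(lin(res5$retained) %in% lin(res$retained)))
})
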