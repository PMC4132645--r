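# a tiny linearly separable design: one informative voxel column plus noise
separable_design <- function(n = 40L, v = 6L, seed = 50L) {
  g <- voxel_grid(c(v, 2L, 2L), spacing = c(2, 2, 2))
  withr::with_seed(seed, {
    y <- rep(c(1L, 0L), n / 2)
    x <- matrix(rbinom(n * v, 1, 0.3), n, v)
    x[, 3L] <- y                       # column 3 encodes the label perfectly
    masks <- lapply(seq_len(n), function(i) {
      arr <- array(0L, g$dims)
      arr[seq_len(v), 1L, 1L] <- x[i, ]
      arr[, 2L, 2L] <- 1L              # padding so no mask is empty
      lesion_mask(arr, g, sprintf("s%02d", i))
    })
    list(dataset = lesion_dataset(masks), y = y,
         tested = cbind(seq_len(v), 1L, 1L))
  })
}

test_that("design matrix mirrors masks restricted to tested voxels", {
  sep <- separable_design()
  tested <- matrix(as.integer(sep$tested), ncol = 3L)
  design <- build_design(sep$dataset, sep$y, tested = tested)
  expect_equal(dim(design$x), c(40L, 6L))
  # row sums = per-mask lesioned tested-voxel counts
  expect_equal(rowSums(design$x),
               vapply(sep$dataset$masks,
                      function(m) sum(m$voxels[linear_index(tested, design$grid$dims)]),
                      integer(1)))
  # column sums = hit counts restricted to tested voxels
  expect_equal(colSums(design$x),
               sep$dataset$hit_count[tested])
  expect_error(build_design(sep$dataset, rep(1L, 40)), "single-class")
})

test_that("c_search spans 41 integer-exponent costs and separates the toy", {
  sep <- separable_design()
  design <- build_design(sep$dataset, sep$y, tested = sep$tested)
  expect_length(2^(-20:20), 41L)  # printed range under the integer-step rule
  cs <- c_search(design, c_exponents = seq(-12, 12, by = 4), n_splits = 6L,
                 test_size = 6L, seed = 3)
  expect_equal(max(cs$mean_accuracy), 1)       # separable => some C is perfect
  expect_true(cs$chosen_C %in% 2^seq(-12, 12, by = 4))
  # determinism: same seed, same search result
  cs2 <- c_search(design, c_exponents = seq(-12, 12, by = 4), n_splits = 6L,
                  test_size = 6L, seed = 3)
  expect_identical(cs$chosen_C, cs2$chosen_C)
  expect_identical(cs$accuracy, cs2$accuracy)
  expect_identical(cs$splits, cs2$splits)
})

test_that("weight maps rank the informative voxel first and respect symmetry", {
  sep <- separable_design()
  design <- build_design(sep$dataset, sep$y, tested = sep$tested)
  wmap <- fit_weight_map(design, C = 1)
  expect_equal(unname(which.max(abs(wmap$w))), 3L)
  expect_gt(wmap$w[3L], 0)                     # positive pushes toward affected
  # flipping all labels negates the weight vector
  flipped <- build_design(sep$dataset, 1L - sep$y, tested = sep$tested)
  wflip <- fit_weight_map(flipped, C = 1)
  expect_equal(wflip$w, -wmap$w, tolerance = 1e-6)
  # duplicating a subject leaves the decision function essentially unchanged
  dup <- lesion_dataset(c(sep$dataset$masks, sep$dataset$masks[1]))
  ddup <- build_design(dup, c(sep$y, sep$y[1]), tested = sep$tested)
  wdup <- fit_weight_map(ddup, C = 100)
  expect_equal(wdup$w, fit_weight_map(design, C = 100)$w, tolerance = 1e-3)
})

test_that("top-k weight thresholding is exact, ordered and nested", {
  sep <- separable_design()
  design <- build_design(sep$dataset, sep$y, tested = sep$tested)
  wmap <- fit_weight_map(design, C = 1)
  expect_equal(nrow(threshold_weights_topk(wmap, 6L)), 6L)  # k = |domain|
  top1 <- threshold_weights_topk(wmap, 1L)
  expect_equal(top1[1, 1], 3L)                 # argmax voxel
  lin <- function(m) linear_index(m, design$grid$dims)
  for (k in 1:5) {
    expect_true(all(lin(threshold_weights_topk(wmap, k)) %in%
                      lin(threshold_weights_topk(wmap, k + 1L))))
  }
  expect_error(threshold_weights_topk(wmap, 7L))
})

test_that("noiseless evaluation reports per-split sensitivity and specificity", {
  fx <- make_two_area_fixture(40, 40, seed = 21)
  spec <- ground_truth_spec("area-set", fx$true_area_ids,
                            damage_fraction = 0.2, deficit_probability = 1)
  labs <- label_area_model(fx$dataset, fx$parcellation, spec)
  design <- build_design(fx$dataset, labs)
  cs <- c_search(design, c_exponents = seq(-4, 4, by = 2), n_splits = 5L,
                 test_size = 10L, seed = 7)
  wmap <- fit_weight_map(design, search = cs)
  perf <- evaluate_noiseless(wmap, fx$dataset, fx$parcellation, spec)
  expect_equal(nrow(perf$per_split), 5L)
  expect_true(all(perf$per_split >= 0 & perf$per_split <= 1, na.rm = TRUE))
  # the fixture is separable: the tuned model is perfect on held-out data
  expect_equal(perf$sensitivity_mean, 1)
  expect_equal(perf$specificity_mean, 1)
  expect_equal(perf$sensitivity_sd, 0)
  # invariance to subject order
  set.seed(60)
  perm <- sample(n_subjects(fx$dataset))
  ds_p <- lesion_dataset(fx$dataset$masks[perm])
  labs_p <- label_area_model(ds_p, fx$parcellation, spec)
  design_p <- build_design(ds_p, labs_p)
  cs_p <- c_search(design_p, c_exponents = seq(-4, 4, by = 2), n_splits = 5L,
                   test_size = 10L, seed = 7)
  perf_p <- evaluate_noiseless(fit_weight_map(design_p, search = cs_p),
                               ds_p, fx$parcellation, spec)
  expect_equal(perf_p$sensitivity_mean, perf$sensitivity_mean)
  expect_equal(perf_p$specificity_mean, perf$specificity_mean)
})

test_that("compare_localization computes Dice and com offsets per method", {
  g <- voxel_grid(c(8L, 8L, 8L), spacing = c(2, 2, 2))
  truth <- cbind(1:4, 1L, 1L)
  storage.mode(truth) <- "integer"
  other <- cbind(5:8, 1L, 1L)
  storage.mode(other) <- "integer"
  cmp <- compare_localization(g, truth, truth, truth)
  expect_equal(cmp$dice_univariate, 1)
  expect_equal(cmp$com_offset_multivariate_mm, 0)
  cmp2 <- compare_localization(g, other, truth, truth)
  expect_equal(cmp2$dice_univariate, 0)
  expect_equal(cmp2$dice_multivariate, 1)
  expect_equal(cmp2$com_offset_univariate_mm, 8)  # 4 voxels at 2 mm
})
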