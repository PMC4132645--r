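# Brute-force two-sided Fisher oracle: enumerate every 2x2 table with the
# observed margins, compute each table's point probability from factorials,
# and sum the probabilities not exceeding the observed table's. Independent
# of the package's dhyper-based implementation.
fisher_oracle_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  k <- a + c
  table_prob <- function(aa) {
    bb <- r1 - aa
    cc <- k - aa
    dd <- n - aa - bb - cc
    exp(lfactorial(r1) + lfactorial(n - r1) + lfactorial(k) +
          lfactorial(n - k) - lfactorial(n) - lfactorial(aa) -
          lfactorial(bb) - lfactorial(cc) - lfactorial(dd))
  }
  support <- max(0, k + r1 - n):min(k, r1)
  probs <- vapply(support, table_prob, numeric(1))
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# lazily built shared fixtures (one build per test run)
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

small_grid <- function() voxel_grid(c(12L, 12L, 12L), spacing = c(2, 2, 2))

# hand-built 6-subject dataset on a tiny grid: mask i damages the voxel
# column x = 1..i at (y, z) = (2, 2), so hit counts are a staircase
staircase_dataset <- function() {
  fixture("staircase", {
    g <- voxel_grid(c(6L, 4L, 4L), spacing = c(2, 2, 2))
    masks <- lapply(1:6, function(i) {
      arr <- array(0L, g$dims)
      arr[seq_len(i), 2L, 2L] <- 1L
      lesion_mask(arr, g, sprintf("s%d", i))
    })
    lesion_dataset(masks)
  })
}

small_stereotyped <- function() {
  fixture("small_stereotyped",
          simulate_cohort(40, "stereotyped", grid = small_grid(), seed = 42,
                          n_branches = 6, min_volume_voxels = 10))
}

small_independent <- function() {
  fixture("small_independent",
          simulate_cohort(40, "independent", grid = small_grid(), seed = 42,
                          per_voxel_p = 0.08, min_volume_voxels = 10))
}
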