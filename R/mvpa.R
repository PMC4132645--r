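#' Build the subjects-by-voxels design matrix
#'
#' Each case is specified by one binary predictor per tested voxel (damage
#' present/absent) and one binary target (the ground-truth label). Columns
#' follow the canonical tested-voxel order, recorded for weight-map
#' reshaping; row `i` is mask `i` restricted to the tested voxels.
#'
#' @param dataset A [lesion_dataset()].
#' @param labels 0/1 label vector aligned to the masks (both classes
#'   required).
#' @param tested `n x 3` matrix of tested voxels; defaults to
#'   [tested_voxels()] at `min_hits = 4`.
#' @return An object of class `design_matrix`: `x` (N x V binary matrix),
#'   `y` (integer labels), `voxels`, `grid`.
#' @export
build_design <- function(dataset, labels, tested = NULL) {
  labels <- as.integer(labels)
  if (length(labels) != n_subjects(dataset)) {
    stop("label vector length does not match the dataset")
  }
  if (length(unique(labels)) < 2L) {
    stop("single-class target: a classifier cannot be trained")
  }
  if (is.null(tested)) tested <- tested_voxels(dataset, 4L)
  stopifnot(nrow(tested) >= 1L)
  x <- t(lesion_matrix(dataset, tested))
  structure(list(x = x, y = labels, voxels = tested, grid = dataset$grid),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d cases x %d voxel predictors (%d affected)\n",
              nrow(x$x), ncol(x$x), sum(x$y)))
  invisible(x)
}

# linear SVM fit with weights oriented so positive scores push toward
# 'affected' (libsvm's decision sign depends on class encounter order)
svm_linear <- function(x, y, C, tolerance = 1e-3) {
  fit <- e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "linear",
                    cost = C, scale = FALSE, tolerance = tolerance)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  f <- drop(x %*% w) + b
  if (mean(f[y == 1L]) < mean(f[y == 0L])) {
    w <- -w
    b <- -b
    f <- -f
  }
  list(w = w, bias = b, scores = f)
}

svm_predict_scores <- function(w, bias, x) drop(x %*% w) + bias

# draw n_splits train/test partitions; resample any split whose training
# half is single-class (bounded retries)
draw_splits <- function(y, n_splits, test_size, seed, max_retries = 100L) {
  n <- length(y)
  stopifnot(test_size >= 1L, test_size < n)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_splits), function(s) {
      for (r in seq_len(max_retries)) {
        test <- sort(sample.int(n, test_size))
        train <- setdiff(seq_len(n), test)
        if (length(unique(y[train])) == 2L) {
          return(list(train = train, test = test))
        }
      }
      stop("degenerate class balance: could not draw a two-class training split")
    })
  })
}

#' Search the SVM cost parameter over repeated random splits
#'
#' Candidate costs are the powers of two over `c_exponents` (default integer
#' exponents -20..20, 41 values). One fixed set of `n_splits` random
#' train/test partitions (default 17; test fraction 25/581 of N, at least 1)
#' is drawn and reused for every candidate, giving a paired comparison
#' across costs. The chosen cost maximizes mean held-out accuracy, ties
#' resolved toward the smaller cost (stronger regularization). Inputs are
#' binary, so no feature scaling is applied.
#'
#' @param design A [build_design()] result.
#' @param c_exponents Integer exponents of the candidate costs `2^e`.
#' @param n_splits Number of random train/test splits (>= 2).
#' @param test_size Held-out cases per split; default `round(N * 25/581)`,
#'   at least 1.
#' @param seed Integer seed for the split draw.
#' @param tolerance libsvm termination tolerance.
#' @return An object of class `c_search_result`: `chosen_C`,
#'   `chosen_exponent`, `accuracy` (splits x costs matrix), `mean_accuracy`
#'   (per cost), `splits`, `split_perf` (per-split sensitivity/specificity/
#'   accuracy at the chosen cost).
#' @export
c_search <- function(design, c_exponents = -20:20, n_splits = 17L,
                     test_size = NULL, seed = 1L, tolerance = 1e-3) {
  stopifnot(inherits(design, "design_matrix"), n_splits >= 2L)
  n <- nrow(design$x)
  if (is.null(test_size)) test_size <- max(1L, as.integer(round(n * 25 / 581)))
  splits <- draw_splits(design$y, n_splits, test_size,
                        derive_seed(seed, "svm-splits"))
  Cs <- 2^c_exponents
  acc <- matrix(NA_real_, n_splits, length(Cs),
                dimnames = list(NULL, sprintf("2^%d", c_exponents)))
  perf <- vector("list", length(Cs))
  for (ci in seq_along(Cs)) {
    rows <- matrix(NA_real_, n_splits, 3L,
                   dimnames = list(NULL, c("sensitivity", "specificity",
                                           "accuracy")))
    for (s in seq_len(n_splits)) {
      sp <- splits[[s]]
      fit <- svm_linear(design$x[sp$train, , drop = FALSE],
                        design$y[sp$train], Cs[ci], tolerance)
      sc <- svm_predict_scores(fit$w, fit$bias,
                               design$x[sp$test, , drop = FALSE])
      pred <- as.integer(sc > 0)
      truth <- design$y[sp$test]
      rows[s, ] <- c(
        if (any(truth == 1L)) mean(pred[truth == 1L] == 1L) else NA_real_,
        if (any(truth == 0L)) mean(pred[truth == 0L] == 0L) else NA_real_,
        mean(pred == truth))
      acc[s, ci] <- rows[s, "accuracy"]
    }
    perf[[ci]] <- rows
  }
  mean_acc <- colMeans(acc)
  best <- which(mean_acc >= max(mean_acc) - 1e-12)[1L]  # tie -> smallest C
  structure(list(chosen_C = Cs[best], chosen_exponent = c_exponents[best],
                 accuracy = acc, mean_accuracy = mean_acc, splits = splits,
                 split_perf = perf[[best]], test_size = test_size,
                 tolerance = tolerance),
            class = "c_search_result")
}

#' @export
print.c_search_result <- function(x, ...) {
  cat(sprintf("<c_search_result> chosen C = 2^%d; mean held-out accuracy %.3f over %d splits (test size %d)\n",
              x$chosen_exponent, max(x$mean_accuracy), nrow(x$accuracy),
              x$test_size))
  invisible(x)
}

#' Fit the voxel weight map at a chosen cost
#'
#' Trains the linear SVM on the full design and extracts the primal weight
#' vector (one weight per tested voxel; the linear combination of support
#' vectors) and bias, with the sign convention that a positive weight pushes
#' the decision toward 'affected'. The weights index each voxel's
#' contribution to the discrimination.
#'
#' @param design A [build_design()] result.
#' @param C Cost parameter; omit when `search` is given.
#' @param search Optional [c_search()] result supplying `chosen_C`, the
#'   split definitions, and split performance.
#' @param tolerance libsvm termination tolerance.
#' @return An object of class `weight_map`: `grid`, `voxels`, `w`, `bias`,
#'   `chosen_C`, `split_perf`, `splits`.
#' @export
fit_weight_map <- function(design, C = NULL, search = NULL,
                           tolerance = 1e-3) {
  stopifnot(inherits(design, "design_matrix"))
  if (is.null(C)) {
    stopifnot(inherits(search, "c_search_result"))
    C <- search$chosen_C
  }
  fit <- svm_linear(design$x, design$y, C, tolerance)
  structure(list(grid = design$grid, voxels = design$voxels, w = fit$w,
                 bias = fit$bias, chosen_C = C,
                 split_perf = if (!is.null(search)) search$split_perf,
                 splits = if (!is.null(search)) search$splits,
                 tolerance = tolerance),
            class = "weight_map")
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf("<weight_map> %d voxel weights at C = %g; |w| in [%.3g, %.3g]\n",
              length(x$w), x$chosen_C, min(abs(x$w)), max(abs(x$w))))
  invisible(x)
}

#' Write a weight map as NIfTI-1
#'
#' `NaN` outside the tested-voxel domain.
#'
#' @param wmap A [fit_weight_map()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_weight_map <- function(wmap, path) {
  arr <- array(NaN, wmap$grid$dims)
  arr[linear_index(wmap$voxels, wmap$grid$dims)] <- wmap$w
  write_nifti_volume(arr, wmap$grid, path, datatype = "double")
}

#' Top-k voxels of a weight map
#'
#' The `k` voxels with the largest signed weight (damage-to-deficit is the
#' direction of interest), ties broken by canonical voxel order; set
#' `use_abs = TRUE` to rank by absolute weight instead. Used to match the
#' retained-set size of a mass-univariate result. Nested:
#' `topk(k1)` is a subset of `topk(k2)` whenever `k1 <= k2`.
#'
#' @param wmap A [fit_weight_map()] result.
#' @param k Number of voxels, `1 <= k <= length(wmap$w)`.
#' @param use_abs Rank by `|w|` instead of signed `w`.
#' @return `k x 3` voxel index matrix.
#' @export
threshold_weights_topk <- function(wmap, k, use_abs = FALSE) {
  stopifnot(is_count(k), k >= 1L, k <= length(wmap$w))
  key <- if (use_abs) -abs(wmap$w) else -wmap$w
  ord <- order(key, seq_along(wmap$w))
  wmap$voxels[ord[seq_len(k)], , drop = FALSE]
}

#' Noiseless held-out performance of the trained model
#'
#' Final model performance is evaluated against the deterministic damage
#' criterion itself — labels regenerated with deficit probability forced to
#' 1 — so that label noise does not contaminate the estimate of how well
#' the model was trained. For each stored split, the SVM is retrained at
#' the chosen cost on the training half and sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and accuracy are computed on the held-out half.
#'
#' @param wmap A [fit_weight_map()] result carrying splits (fit via
#'   `search = `[c_search()]).
#' @param dataset A [lesion_dataset()].
#' @param parc A [parcellation()].
#' @param spec The [ground_truth_spec()] defining the damage criterion.
#' @param splits Optional split list overriding the one stored in `wmap`.
#' @return An object of class `performance_stats`: `sensitivity_mean`,
#'   `sensitivity_sd`, `specificity_mean`, `specificity_sd`,
#'   `accuracy_mean`, `per_split`.
#' @export
evaluate_noiseless <- function(wmap, dataset, parc, spec, splits = NULL) {
  stopifnot(inherits(wmap, "weight_map"))
  splits <- splits %||% wmap$splits
  if (is.null(splits)) stop("no splits available: fit the weight map via c_search")
  labels <- label_area_model(dataset, parc, spec, noiseless = TRUE)
  design <- build_design(dataset, labels, tested = wmap$voxels)
  per <- matrix(NA_real_, length(splits), 3L,
                dimnames = list(NULL, c("sensitivity", "specificity",
                                        "accuracy")))
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    fit <- svm_linear(design$x[sp$train, , drop = FALSE],
                      design$y[sp$train], wmap$chosen_C, wmap$tolerance)
    sc <- svm_predict_scores(fit$w, fit$bias,
                             design$x[sp$test, , drop = FALSE])
    pred <- as.integer(sc > 0)
    truth <- design$y[sp$test]
    per[s, ] <- c(
      if (any(truth == 1L)) mean(pred[truth == 1L] == 1L) else NA_real_,
      if (any(truth == 0L)) mean(pred[truth == 0L] == 0L) else NA_real_,
      mean(pred == truth))
  }
  structure(list(
    sensitivity_mean = mean(per[, 1L], na.rm = TRUE),
    sensitivity_sd = stats::sd(per[, 1L], na.rm = TRUE),
    specificity_mean = mean(per[, 2L], na.rm = TRUE),
    specificity_sd = stats::sd(per[, 2L], na.rm = TRUE),
    accuracy_mean = mean(per[, 3L]),
    per_split = as.data.frame(per)),
    class = "performance_stats")
}

#' @export
print.performance_stats <- function(x, ...) {
  cat(sprintf("<performance_stats> sensitivity %.3f (SD = %.3f), specificity %.3f (SD = %.3f)\n",
              x$sensitivity_mean, x$sensitivity_sd,
              x$specificity_mean, x$specificity_sd))
  invisible(x)
}

#' Compare univariate and multivariate localization against ground truth
#'
#' Dice overlap of each method's retained voxel set with the true critical
#' set, plus each set's centre-of-mass offset from the truth's centre of
#' mass. Retained-set sizes should be matched by the caller (top-k on both
#' sides) for a fair comparison.
#'
#' @param grid The common [voxel_grid()].
#' @param univariate `n x 3` voxel set retained by the mass-univariate
#'   analysis.
#' @param multivariate `n x 3` voxel set retained from the weight map.
#' @param truth `n x 3` voxel set of the true critical region (non-empty).
#' @return A list: `dice_univariate`, `dice_multivariate`,
#'   `com_offset_univariate_mm`, `com_offset_multivariate_mm` (magnitudes).
#' @export
compare_localization <- function(grid, univariate, multivariate, truth) {
  stopifnot(is.matrix(truth), nrow(truth) >= 1L)
  truth_com <- centre_of_mass(grid, truth)
  off <- function(set) {
    if (nrow(set) == 0L) return(NA_real_)
    displacement(truth_com, centre_of_mass(grid, set))$magnitude
  }
  list(dice_univariate = dice_coefficient(grid, univariate, truth),
       dice_multivariate = dice_coefficient(grid, multivariate, truth),
       com_offset_univariate_mm = off(univariate),
       com_offset_multivariate_mm = off(multivariate))
}
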