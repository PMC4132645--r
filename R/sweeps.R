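new_sweep_summary <- function(per_model, n_failures,
                              sd_type = "population") {
  mags <- per_model$magnitude_mm
  structure(list(mean_mm = if (length(mags)) mean(mags) else NA_real_,
                 sd_mm = sd_by_type(mags, sd_type),
                 n_models = nrow(per_model) + n_failures,
                 n_failures = n_failures,
                 per_model = per_model,
                 sd_type = sd_type),
            class = "sweep_summary")
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat(sprintf("<sweep_summary> %d models (%d failed): mean displacement %.2f mm (%s sd %.2f mm)\n",
              x$n_models, x$n_failures, x$mean_mm, x$sd_type, x$sd_mm))
  cat("  (mean/sd over successful models only; failures are recorded, not dropped silently)\n")
  invisible(x)
}

locus_of <- function(sig, locus_mode) {
  if (locus_mode == "com") sig$com_mm else sig$peak_mm
}

#' Single-voxel model sweep: the error vector field
#'
#' For every tested voxel in turn: take that voxel as the critical locus,
#' label the cohort by damage at it, run the voxel-wise test over all tested
#' voxels, Bonferroni-threshold the p-map, and record the displacement from
#' the true voxel's world coordinate to the centre of mass (or peak) of the
#' significant set. The result is the error vector field — the magnitude and
#' direction of mass-univariate mislocalization at every adequately sampled
#' location — plus mean/SD summaries of the magnitudes.
#'
#' The sweep shares one damage matrix across models: for model voxel `v` and
#' tested voxel `w`, the contingency cell `a` is the number of subjects
#' damaging both, i.e. one cross-product of the damage matrix serves every
#' model, and exact p-values are lookup-table reads (margins depend only on
#' hit counts). Results are identical to running each model independently.
#'
#' @param dataset A [lesion_dataset()].
#' @param min_hits Tested-voxel threshold (default 4).
#' @param alpha Familywise alpha before Bonferroni correction (default 0.01).
#' @param locus_mode `"com"` (centre of mass) or `"peak"`.
#' @param mode Test mode, see [fisher_exact_p()].
#' @param sd_type `"population"` (denominator n, the default) or `"sample"`.
#' @return A list with `field` ([error_vector_field()]) and `summary`
#'   (`sweep_summary`).
#' @export
single_voxel_sweep <- function(dataset, min_hits = 4L, alpha = 0.01,
                               locus_mode = c("com", "peak"),
                               mode = c("exact", "asymptotic"),
                               sd_type = "population") {
  locus_mode <- match.arg(locus_mode)
  mode <- match.arg(mode)
  tested <- tested_voxels(dataset, min_hits)
  V <- nrow(tested)
  if (V < 1L) stop("dataset has no tested voxel at this min_hits")
  n <- n_subjects(dataset)
  M <- lesion_matrix(dataset, tested)
  h <- as.integer(rowSums(M))
  world <- voxel_to_world(dataset$grid, tested)
  thr <- bonferroni_threshold(alpha, V)
  A <- tcrossprod(M)                    # A[w, v] = subjects damaging both
  cache <- new.env(parent = emptyenv())

  vectors <- matrix(NA_real_, V, 3L)
  n_sig <- integer(V)
  ok <- logical(V)
  for (v in seq_len(V)) {
    m <- h[v]                           # label margin = hit count at v
    key <- as.character(m)
    P <- cache[[key]]
    if (is.null(P)) {
      P <- fisher_p_lookup(m, n)
      cache[[key]] <- P
    }
    p <- P[cbind(h + 1L, A[, v] + 1L)]
    sig <- p < thr
    n_sig[v] <- sum(sig)
    if (!any(sig)) next
    if (locus_mode == "com") {
      loc <- colMeans(world[sig, , drop = FALSE])
    } else {
      p_sig <- p[sig]
      loc <- colMeans(world[sig, , drop = FALSE][p_sig <= min(p_sig), ,
                                                 drop = FALSE])
    }
    vectors[v, ] <- loc - world[v, ]
    ok[v] <- TRUE
  }
  field <- error_vector_field(dataset$grid,
                              tested[ok, , drop = FALSE],
                              vectors[ok, , drop = FALSE],
                              failures = tested[!ok, , drop = FALSE])
  per_model <- data.frame(i = tested[ok, 1L], j = tested[ok, 2L],
                          k = tested[ok, 3L],
                          dx_mm = vectors[ok, 1L], dy_mm = vectors[ok, 2L],
                          dz_mm = vectors[ok, 3L],
                          magnitude_mm = sqrt(rowSums(vectors[ok, ,
                                                              drop = FALSE]^2)),
                          n_significant = n_sig[ok])
  list(field = field,
       summary = new_sweep_summary(per_model, sum(!ok), sd_type))
}

#' Area-model sweep
#'
#' One ground-truth model per parcellation area: the deficit occurs (with
#' `deficit_probability`) when at least `damage_fraction` of the area is
#' damaged. Each model's displacement runs from the area's centre of mass to
#' the centre of mass (or peak) of its significant cluster. Areas yielding a
#' single-class label vector, or an empty significant set, are recorded as
#' failures and excluded from the mean/SD.
#'
#' @inheritParams single_voxel_sweep
#' @param parc A [parcellation()] on the dataset grid.
#' @param areas Area ids to model; default all areas.
#' @param damage_fraction Damage criterion, see [ground_truth_spec()].
#' @param deficit_probability Deficit probability given the criterion.
#' @param seed Sweep seed; each area's deficit coin uses a seed derived from
#'   it, so a deterministic model (`deficit_probability = 1`) is independent
#'   of `seed`.
#' @return A `sweep_summary`; `per_model` has one row per successful area.
#' @export
area_model_sweep <- function(dataset, parc, areas = parc$area_ids,
                             damage_fraction = 0.20,
                             deficit_probability = 0.90, seed = 1L,
                             min_hits = 4L, alpha = 0.01,
                             locus_mode = c("com", "peak"),
                             mode = c("exact", "asymptotic"),
                             sd_type = "population") {
  locus_mode <- match.arg(locus_mode)
  mode <- match.arg(mode)
  tested <- tested_voxels(dataset, min_hits)
  if (nrow(tested) == 0L) stop("dataset has no tested voxel at this min_hits")
  M <- lesion_matrix(dataset, tested)
  h <- as.integer(rowSums(M))
  thr <- bonferroni_threshold(alpha, nrow(tested))
  cache <- new.env(parent = emptyenv())

  rows <- list()
  n_fail <- 0L
  for (a in areas) {
    spec <- ground_truth_spec("area-set", a,
                              damage_fraction = damage_fraction,
                              deficit_probability = deficit_probability,
                              seed = derive_seed(seed, paste0("area-", a)))
    labels <- withCallingHandlers(
      label_area_model(dataset, parc, spec),
      warning = function(w) invokeRestart("muffleWarning"))
    if (length(unique(as.integer(labels))) < 2L) {
      n_fail <- n_fail + 1L
      next
    }
    p <- pmap_values(M, h, labels, mode = mode, cache = cache)
    pm <- structure(list(grid = dataset$grid, voxels = tested, p = p,
                         n_tested = nrow(tested), mode = mode),
                    class = "pmap")
    sig <- significance(pm, thr)
    if (sig$empty) {
      n_fail <- n_fail + 1L
      next
    }
    true_mm <- centre_of_mass(parc$grid, area_voxels(parc, a))
    dis <- displacement(true_mm, locus_of(sig, locus_mode))
    rows[[length(rows) + 1L]] <- data.frame(
      area = a, dx_mm = dis$vector[1L], dy_mm = dis$vector[2L],
      dz_mm = dis$vector[3L], magnitude_mm = dis$magnitude,
      n_significant = sig$n_significant)
  }
  per_model <- if (length(rows)) do.call(rbind, rows) else
    data.frame(area = integer(0), dx_mm = numeric(0), dy_mm = numeric(0),
               dz_mm = numeric(0), magnitude_mm = numeric(0),
               n_significant = integer(0))
  new_sweep_summary(per_model, n_fail, sd_type)
}

#' Damage-threshold sweep over area models
#'
#' Repeats [area_model_sweep()] for a list of damage fractions (default 5%
#' to 60% in 5% bins, 12 values), to show that area-model mislocalization is
#' not an artefact of one criterion choice. Also reports the mean of the
#' per-fraction mean displacements and its SD across fractions.
#'
#' @inheritParams area_model_sweep
#' @param fractions Damage fractions, each in `(0, 1]`.
#' @return A list of class `threshold_sweep`: `fractions`, `summaries`
#'   (one `sweep_summary` per fraction), `mean_of_means_mm`,
#'   `sd_across_fractions_mm`, `table` (fraction, mean, sd, n_models,
#'   n_failures).
#' @export
threshold_sweep <- function(dataset, parc, areas = parc$area_ids,
                            fractions = seq(0.05, 0.60, by = 0.05),
                            deficit_probability = 0.90, seed = 1L,
                            min_hits = 4L, alpha = 0.01,
                            locus_mode = c("com", "peak"),
                            mode = c("exact", "asymptotic"),
                            sd_type = "population") {
  stopifnot(length(fractions) >= 1L, all(fractions > 0), all(fractions <= 1))
  summaries <- lapply(fractions, function(f) {
    area_model_sweep(dataset, parc, areas = areas, damage_fraction = f,
                     deficit_probability = deficit_probability, seed = seed,
                     min_hits = min_hits, alpha = alpha,
                     locus_mode = locus_mode, mode = mode, sd_type = sd_type)
  })
  means <- vapply(summaries, `[[`, numeric(1L), "mean_mm")
  tab <- data.frame(
    fraction = fractions,
    mean_mm = means,
    sd_mm = vapply(summaries, `[[`, numeric(1L), "sd_mm"),
    n_models = vapply(summaries, `[[`, integer(1L), "n_models"),
    n_failures = vapply(summaries, `[[`, integer(1L), "n_failures"))
  structure(list(fractions = fractions, summaries = summaries,
                 mean_of_means_mm = mean(means[is.finite(means)]),
                 sd_across_fractions_mm = sd_by_type(means, sd_type),
                 table = tab),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> %d fractions (%.0f%%..%.0f%%): mean of means %.2f mm (sd %.2f mm)\n",
              length(x$fractions), 100 * min(x$fractions),
              100 * max(x$fractions), x$mean_of_means_mm,
              x$sd_across_fractions_mm))
  invisible(x)
}

#' Retain the k most significant voxels of a p-map
#'
#' The display-matched thresholding used to compare retained sets of equal
#' size across methods: exactly `k` voxels of smallest p, ties broken by
#' canonical voxel order.
#'
#' @param pmap A [compute_pmap()] result.
#' @param k Number of voxels to retain, `1 <= k <= n_tested`.
#' @return `k x 3` voxel index matrix.
#' @export
retain_topk <- function(pmap, k) {
  stopifnot(is_count(k), k >= 1L, k <= pmap$n_tested)
  ord <- order(pmap$p, seq_along(pmap$p))
  pmap$voxels[ord[seq_len(k)], , drop = FALSE]
}

#' Two-area (distributed ground truth) model
#'
#' Damage to at least `damage_fraction` of *either* of two areas causes the
#' deficit (union rule): the simplest distributed functional architecture.
#' Runs the mass-univariate analysis on those labels and summarizes where
#' the retained voxels fall relative to both true areas. Retention is either
#' the Bonferroni suprathreshold set or — for display-matched comparison
#' with a multivariate weight map — the top-`k` most significant voxels,
#' with `k` defaulting to the size of the union of the true areas.
#'
#' @inheritParams area_model_sweep
#' @param area_pair Length-2 vector of area ids.
#' @param retain `"bonferroni"` or `"topk"`.
#' @param k Retained-set size for `retain = "topk"`.
#' @return A list of class `multi_area_result`: `labels`, `pmap`,
#'   `significance` (Bonferroni result), `retained` (index matrix per
#'   `retain`), `com_mm` of the retained set, `displacement_from_each`
#'   (table), `displacement_from_union`, `dice_union`.
#' @export
multi_area_model <- function(dataset, parc, area_pair, damage_fraction = 0.20,
                             deficit_probability = 0.90, seed = 1L,
                             min_hits = 4L, alpha = 0.01,
                             retain = c("bonferroni", "topk"), k = NULL,
                             mode = c("exact", "asymptotic")) {
  retain <- match.arg(retain)
  mode <- match.arg(mode)
  stopifnot(length(area_pair) == 2L)
  spec <- ground_truth_spec("area-set", area_pair,
                            damage_fraction = damage_fraction,
                            deficit_probability = deficit_probability,
                            seed = derive_seed(seed, "multi-area"))
  labels <- label_area_model(dataset, parc, spec)
  if (length(unique(as.integer(labels))) < 2L) {
    stop("single-class label vector: choose better-sampled areas")
  }
  pm <- compute_pmap(dataset, labels, min_hits = min_hits, mode = mode)
  sig <- significance(pm, bonferroni_threshold(alpha, pm$n_tested))
  union_vox <- do.call(rbind, lapply(area_pair,
                                     function(a) area_voxels(parc, a)))
  if (retain == "topk") {
    if (is.null(k)) k <- nrow(union_vox)
    retained <- retain_topk(pm, min(k, pm$n_tested))
  } else {
    retained <- sig$voxels
  }
  if (nrow(retained) == 0L) {
    return(structure(list(labels = labels, pmap = pm, significance = sig,
                          retained = retained, com_mm = NULL,
                          displacement_from_each = NULL,
                          displacement_from_union = NULL,
                          dice_union = 0, empty = TRUE),
                     class = "multi_area_result"))
  }
  com <- centre_of_mass(parc$grid, retained)
  per_area <- do.call(rbind, lapply(area_pair, function(a) {
    dis <- displacement(centre_of_mass(parc$grid, area_voxels(parc, a)), com)
    data.frame(area = a, dx_mm = dis$vector[1L], dy_mm = dis$vector[2L],
               dz_mm = dis$vector[3L], magnitude_mm = dis$magnitude)
  }))
  dis_union <- displacement(centre_of_mass(parc$grid, union_vox), com)
  structure(list(labels = labels, pmap = pm, significance = sig,
                 retained = retained, com_mm = com,
                 displacement_from_each = per_area,
                 displacement_from_union = dis_union,
                 dice_union = dice_coefficient(parc$grid, retained, union_vox),
                 empty = FALSE),
            class = "multi_area_result")
}

#' @export
print.multi_area_result <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<multi_area_result> empty retained set\n")
    return(invisible(x))
  }
  cat(sprintf("<multi_area_result> %d retained voxels; Dice with true union %.3f; displacement from union com %.2f mm\n",
              nrow(x$retained), x$dice_union,
              x$displacement_from_union$magnitude))
  invisible(x)
}
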