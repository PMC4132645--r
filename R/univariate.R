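#' Per-voxel 2x2 contingency table
#'
#' Cross-tabulates damage at one voxel against the group label:
#' `a` = damaged & affected, `b` = damaged & unaffected, `c` = undamaged &
#' affected, `d` = undamaged & unaffected. Margins satisfy
#' `a + b = hit_count[voxel]` and `a + c = sum(labels)`.
#'
#' @param dataset A [lesion_dataset()].
#' @param labels 0/1 label vector aligned to the masks.
#' @param voxel Length-3 voxel index.
#' @return A list of class `contingency_table` with fields `a`, `b`, `c`,
#'   `d`, `n`.
#' @export
contingency <- function(dataset, labels, voxel) {
  labels <- as.integer(labels)
  if (length(labels) != n_subjects(dataset)) {
    stop("label vector length does not match the dataset")
  }
  lin <- linear_index(matrix(as.integer(voxel), 1L), dataset$grid$dims)
  dam <- vapply(dataset$masks, function(m) m$voxels[lin], integer(1L))
  a <- sum(dam == 1L & labels == 1L)
  b <- sum(dam == 1L & labels == 0L)
  c_ <- sum(dam == 0L & labels == 1L)
  d <- sum(dam == 0L & labels == 0L)
  structure(list(a = a, b = b, c = c_, d = d, n = length(labels)),
            class = "contingency_table")
}

# p-values over tested voxels from a prebuilt damage matrix.
# M: V x N damage matrix; h: rowSums(M); labels: 0/1 vector.
# cache: optional environment memoising exact lookup tables by label margin.
pmap_values <- function(M, h, labels, mode = c("exact", "asymptotic"),
                        cache = NULL) {
  mode <- match.arg(mode)
  labels <- as.integer(labels)
  n <- length(labels)
  m <- sum(labels)
  a <- as.vector(M %*% labels)
  if (mode == "exact") {
    key <- as.character(m)
    P <- if (!is.null(cache) && !is.null(cache[[key]])) {
      cache[[key]]
    } else {
      tab <- fisher_p_lookup(m, n)
      if (!is.null(cache)) cache[[key]] <- tab
      tab
    }
    return(P[cbind(h + 1L, a + 1L)])
  }
  b <- h - a
  c_ <- m - a
  d <- n - h - c_
  stat <- n * (a * d - b * c_)^2 /
    (pmax(h, 1) * pmax(n - h, 1) * pmax(m, 1) * pmax(n - m, 1))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[h == 0 | h == n | m == 0 | m == n] <- 1
  p
}

#' Voxel-wise p-value map
#'
#' Runs the association test independently at every tested voxel (those hit
#' at least `min_hits` times), producing the p-value map that conventional
#' lesion-symptom mapping thresholds.
#'
#' @param dataset A [lesion_dataset()].
#' @param labels 0/1 label vector aligned to the masks (both classes must be
#'   present).
#' @param tested Optional `n x 3` matrix of voxels to test; defaults to
#'   [tested_voxels()] at `min_hits`.
#' @param min_hits Minimum per-voxel hit count defining the tested set.
#' @param mode Test mode, see [fisher_exact_p()].
#' @return An object of class `pmap`: `grid`, `voxels`, `p`, `n_tested`,
#'   `mode`.
#' @export
compute_pmap <- function(dataset, labels, tested = NULL, min_hits = 4L,
                         mode = c("exact", "asymptotic")) {
  mode <- match.arg(mode)
  labels <- as.integer(labels)
  if (length(labels) != n_subjects(dataset)) {
    stop("label vector length does not match the dataset")
  }
  if (length(unique(labels)) < 2L) {
    stop("single-class label vector: association is undefined")
  }
  if (is.null(tested)) tested <- tested_voxels(dataset, min_hits)
  if (nrow(tested) == 0L) stop("no tested voxels at this min_hits")
  M <- lesion_matrix(dataset, tested)
  h <- as.integer(rowSums(M))
  p <- pmap_values(M, h, labels, mode = mode)
  structure(list(grid = dataset$grid, voxels = tested, p = p,
                 n_tested = nrow(tested), mode = mode),
            class = "pmap")
}

#' @export
print.pmap <- function(x, ...) {
  cat(sprintf("<pmap> %d tested voxels (%s mode); min p = %.3g\n",
              x$n_tested, x$mode, min(x$p)))
  invisible(x)
}

#' Threshold a p-map and summarize the significant cluster
#'
#' The significant set is `{v : p[v] < threshold}` (strict). Its localization
#' summaries are the centre of mass (unweighted mean of the world
#' coordinates of significant voxels) and the peak (the voxel of minimal p;
#' ties resolved as the centre of mass of all voxels attaining the minimum,
#' a deterministic, orientation-unbiased rule). An empty set is a valid,
#' flagged outcome with undefined loci. The whole suprathreshold set is
#' treated as one cluster; no connected-component step is applied.
#'
#' @param pmap A [compute_pmap()] result.
#' @param threshold Per-test significance threshold (e.g. from
#'   [bonferroni_threshold()]).
#' @return An object of class `significance_result`: `threshold`, `voxels`
#'   (significant set, index matrix), `n_significant`, `com_mm`, `peak_mm`,
#'   `peak_p`, `empty`.
#' @export
significance <- function(pmap, threshold) {
  stopifnot(inherits(pmap, "pmap"), is.numeric(threshold),
            length(threshold) == 1L)
  sig <- pmap$p < threshold
  voxels <- pmap$voxels[sig, , drop = FALSE]
  if (!any(sig)) {
    return(structure(list(threshold = threshold, voxels = voxels,
                          n_significant = 0L, com_mm = NULL, peak_mm = NULL,
                          peak_p = NA_real_, empty = TRUE),
                     class = "significance_result"))
  }
  p_sig <- pmap$p[sig]
  com <- centre_of_mass(pmap$grid, voxels)
  pk_min <- min(p_sig)
  peak_set <- voxels[p_sig <= pk_min, , drop = FALSE]
  peak <- centre_of_mass(pmap$grid, peak_set)
  structure(list(threshold = threshold, voxels = voxels,
                 n_significant = sum(sig), com_mm = com, peak_mm = peak,
                 peak_p = pk_min, empty = FALSE),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<significance_result> empty (threshold %.3g)\n", x$threshold))
  } else {
    cat(sprintf("<significance_result> %d voxels < %.3g; com (%.1f, %.1f, %.1f) mm; peak p %.3g\n",
                x$n_significant, x$threshold, x$com_mm[1], x$com_mm[2],
                x$com_mm[3], x$peak_p))
  }
  invisible(x)
}

#' Displacement from a true to an inferred locus
#'
#' @param true_mm Length-3 mm coordinate of the true locus.
#' @param inferred_mm Length-3 mm coordinate of the inferred locus, or
#'   `NULL` (empty significance result), which is an error here — callers
#'   record such models as failures instead.
#' @return A list with `vector` (inferred - true, mm) and `magnitude`
#'   (Euclidean norm, mm).
#' @export
displacement <- function(true_mm, inferred_mm) {
  if (is.null(inferred_mm)) {
    stop(errorCondition("inferred locus undefined (empty significance result)",
                        class = c("lesionmapr_empty_result", "lesionmapr_error")))
  }
  stopifnot(length(true_mm) == 3L, length(inferred_mm) == 3L)
  v <- as.numeric(inferred_mm) - as.numeric(true_mm)
  list(vector = v, magnitude = sqrt(sum(v^2)))
}

#' Dice overlap between two voxel sets
#'
#' `2 |X & Y| / (|X| + |Y|)`; `1` for identical non-empty sets, `0` for
#' disjoint sets.
#'
#' @param grid The common [voxel_grid()].
#' @param x,y `n x 3` voxel index matrices.
#' @return Numeric in `[0, 1]`.
#' @export
dice_coefficient <- function(grid, x, y) {
  stopifnot(is.matrix(x), is.matrix(y))
  if (nrow(x) + nrow(y) == 0L) return(NA_real_)
  lx <- linear_index(x, grid$dims)
  ly <- linear_index(y, grid$dims)
  2 * length(intersect(lx, ly)) / (length(lx) + length(ly))
}
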