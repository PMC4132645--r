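#' Read a run configuration file
#'
#' A flat YAML document with per-stage sections (`cohort`, `ground_truth`,
#' `inference`, `multivariate`), a global `seed` and an `output_dir`. Every
#' stochastic stage derives its own seed from the global seed and the stage
#' name, so one config re-runs bit-identically. The config is validated and
#' echoed verbatim into each run manifest.
#'
#' @param path Path to a YAML config.
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

check_prob <- function(cfg, section, field, default = NULL) {
  val <- cfg[[section]][[field]] %||% default
  if (!is.null(val) && (!is.numeric(val) || val < 0 || val > 1)) {
    stop(sprintf("config field %s.%s must be a probability in [0, 1], got %s",
                 section, field, format(val)), call. = FALSE)
  }
  invisible(val)
}

#' Validate a run configuration
#'
#' @param cfg A config list, e.g. from [read_run_config()].
#' @return `cfg` with defaults filled in; errors name the offending field.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "lesionmapr-run"
  check_prob(cfg, "cohort", "noise_rate")
  check_prob(cfg, "cohort", "per_voxel_p")
  check_prob(cfg, "ground_truth", "damage_fraction")
  check_prob(cfg, "ground_truth", "deficit_probability")
  for (f in cfg$inference$fractions %||% numeric(0)) {
    if (!is.numeric(f) || f <= 0 || f > 1) {
      stop(sprintf("config field inference.fractions must lie in (0, 1], got %s",
                   format(f)), call. = FALSE)
    }
  }
  cfg
}

config_grid <- function(cfg) {
  dims <- as.integer(cfg$cohort$dims %||% c(32L, 32L, 32L))
  spacing <- as.numeric(cfg$cohort$spacing %||% c(2, 2, 2))
  voxel_grid(dims, spacing)
}

config_ground_truth <- function(cfg) {
  gt <- cfg$ground_truth %||% stop("config is missing the ground_truth section")
  kind <- gt$kind %||% "area-set"
  if (kind == "single-voxel") {
    ground_truth_spec("single-voxel", as.integer(gt$voxel))
  } else {
    ground_truth_spec("area-set", as.integer(gt$areas),
                      damage_fraction = gt$damage_fraction %||% 0.20,
                      deficit_probability = gt$deficit_probability %||% 0.90,
                      seed = derive_seed(cfg$seed, "ground-truth"))
  }
}

config_labels <- function(cfg, dataset, parc) {
  spec <- config_ground_truth(cfg)
  if (spec$kind == "single-voxel") {
    label_single_voxel(dataset, spec$target)
  } else {
    label_area_model(dataset, parc, spec)
  }
}

load_inputs <- function(cfg) {
  dataset <- read_cohort(cfg$input_cohort %||%
                           file.path(cfg$output_dir, "cohort"),
                         min_volume_mm3 = cfg$cohort$min_volume_mm3 %||% 216)
  parc <- if (!is.null(cfg$parcellation)) {
    read_parcellation(cfg$parcellation, reference_grid = dataset$grid)
  }
  list(dataset = dataset, parc = parc)
}

write_manifest <- function(cfg, dir, artifacts) {
  manifest <- list(
    config = cfg,
    package = "lesionmapr",
    version = as.character(utils::packageVersion("lesionmapr")),
    seed = cfg$seed,
    artifacts = as.list(tools::md5sum(artifacts)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run one pipeline subcommand
#'
#' The package's command-line surface: `simulate` emits a cohort (NIfTI
#' stack + manifest), `map-univariate` runs the voxel-wise analysis for one
#' ground-truth model, `map-multivariate` runs the SVM analysis,
#' `sweep` builds the single-voxel error vector field or the
#' damage-threshold sweep, and `compare` contrasts univariate and
#' multivariate localization at matched retained-set sizes. All outputs land
#' under `cfg$output_dir`, accompanied by a `manifest.json` echoing the
#' config, seeds and artifact checksums; inputs are never mutated.
#'
#' @param name One of `"simulate"`, `"map-univariate"`,
#'   `"map-multivariate"`, `"sweep"`, `"compare"`.
#' @param cfg A config list (see [read_run_config()]).
#' @return A list of produced artifact paths, invisibly.
#' @export
run_subcommand <- function(name = c("simulate", "map-univariate",
                                    "map-multivariate", "sweep", "compare"),
                           cfg) {
  name <- match.arg(name)
  cfg <- validate_run_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  inf <- cfg$inference %||% list()
  alpha <- inf$alpha %||% 0.01
  min_hits <- as.integer(inf$min_hits %||% 4L)
  mode <- inf$mode %||% "exact"
  locus_mode <- inf$locus_mode %||% "com"
  artifacts <- character(0)

  if (name == "simulate") {
    grid <- config_grid(cfg)
    ds <- simulate_cohort(
      n_subjects = as.integer(cfg$cohort$n_subjects %||% 100L),
      generator = cfg$cohort$generator %||% "stereotyped",
      grid = grid, seed = derive_seed(cfg$seed, "cohort"),
      n_branches = as.integer(cfg$cohort$n_branches %||% 12L),
      per_voxel_p = cfg$cohort$per_voxel_p %||% 0.05,
      min_volume_voxels = as.integer(cfg$cohort$min_volume_voxels %||% 27L))
    cohort_dir <- file.path(cfg$output_dir, "cohort")
    artifacts <- c(artifacts, write_cohort(ds, cohort_dir))
    if (!is.null(attr(ds, "tree"))) {
      tpath <- file.path(cfg$output_dir, "territories.nii.gz")
      write_nifti_volume(attr(ds, "tree")$labels, grid, tpath,
                         datatype = "int16")
      artifacts <- c(artifacts, tpath)
    }
  } else if (name == "map-univariate") {
    io <- load_inputs(cfg)
    labels <- config_labels(cfg, io$dataset, io$parc)
    pm <- compute_pmap(io$dataset, labels, min_hits = min_hits, mode = mode)
    sig <- significance(pm, bonferroni_threshold(alpha, pm$n_tested))
    parr <- array(NaN, pm$grid$dims)
    parr[linear_index(pm$voxels, pm$grid$dims)] <- pm$p
    ppath <- file.path(cfg$output_dir, "pmap.nii.gz")
    write_nifti_volume(parr, pm$grid, ppath, datatype = "double")
    sarr <- array(0L, pm$grid$dims)
    if (!sig$empty) sarr[linear_index(sig$voxels, pm$grid$dims)] <- 1L
    spath <- file.path(cfg$output_dir, "significant.nii.gz")
    write_nifti_volume(sarr, pm$grid, spath, datatype = "uint8")
    summ <- data.frame(
      n_tested = pm$n_tested, threshold = sig$threshold,
      n_significant = sig$n_significant,
      com_x_mm = sig$com_mm[1L] %||% NA_real_,
      com_y_mm = sig$com_mm[2L] %||% NA_real_,
      com_z_mm = sig$com_mm[3L] %||% NA_real_,
      peak_p = sig$peak_p)
    tpath <- file.path(cfg$output_dir, "univariate_summary.tsv")
    utils::write.table(summ, tpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts <- c(artifacts, ppath, spath, tpath)
  } else if (name == "map-multivariate") {
    io <- load_inputs(cfg)
    labels <- config_labels(cfg, io$dataset, io$parc)
    design <- build_design(io$dataset, labels,
                           tested = tested_voxels(io$dataset, min_hits))
    mv <- cfg$multivariate %||% list()
    search <- c_search(design,
                       c_exponents = seq.int(mv$c_min_exp %||% -20L,
                                             mv$c_max_exp %||% 20L),
                       n_splits = as.integer(mv$splits %||% 17L),
                       test_size = mv$test_size,
                       seed = derive_seed(cfg$seed, "svm"))
    wmap <- fit_weight_map(design, search = search)
    wpath <- file.path(cfg$output_dir, "weight_map.nii.gz")
    write_weight_map(wmap, wpath)
    perf <- cbind(split = seq_len(nrow(search$split_perf)),
                  as.data.frame(search$split_perf),
                  chosen_C = search$chosen_C)
    fpath <- file.path(cfg$output_dir, "svm_performance.tsv")
    utils::write.table(perf, fpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts <- c(artifacts, wpath, fpath)
  } else if (name == "sweep") {
    io <- load_inputs(cfg)
    kind <- inf$sweep %||% "single-voxel"
    if (kind == "single-voxel") {
      res <- single_voxel_sweep(io$dataset, min_hits = min_hits,
                                alpha = alpha, locus_mode = locus_mode,
                                mode = mode)
      vpath <- file.path(cfg$output_dir, "error_vector_field.tsv")
      export_vector_field(res$field, vpath, "tsv")
      npath <- file.path(cfg$output_dir, "error_vector_field")
      nii <- export_vector_field(res$field, npath, "nifti-triplet")
      spath <- file.path(cfg$output_dir, "sweep_summary.tsv")
      utils::write.table(
        data.frame(mean_mm = res$summary$mean_mm, sd_mm = res$summary$sd_mm,
                   n_models = res$summary$n_models,
                   n_failures = res$summary$n_failures),
        spath, sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts <- c(artifacts, vpath, nii, spath)
    } else {
      fractions <- as.numeric(inf$fractions %||% seq(0.05, 0.60, by = 0.05))
      sw <- threshold_sweep(io$dataset, io$parc, fractions = fractions,
                            deficit_probability =
                              cfg$ground_truth$deficit_probability %||% 0.90,
                            seed = derive_seed(cfg$seed, "threshold-sweep"),
                            min_hits = min_hits, alpha = alpha,
                            locus_mode = locus_mode, mode = mode)
      tpath <- file.path(cfg$output_dir, "threshold_sweep.tsv")
      utils::write.table(sw$table, tpath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      artifacts <- c(artifacts, tpath)
    }
  } else if (name == "compare") {
    io <- load_inputs(cfg)
    spec <- config_ground_truth(cfg)
    stopifnot(spec$kind == "area-set")
    truth <- do.call(rbind, lapply(spec$target,
                                   function(a) area_voxels(io$parc, a)))
    k <- as.integer(cfg$multivariate$topk %||% nrow(truth))
    labels <- label_area_model(io$dataset, io$parc, spec)
    pm <- compute_pmap(io$dataset, labels, min_hits = min_hits, mode = mode)
    uni <- retain_topk(pm, min(k, pm$n_tested))
    design <- build_design(io$dataset, labels, tested = pm$voxels)
    mv <- cfg$multivariate %||% list()
    search <- c_search(design,
                       c_exponents = seq.int(mv$c_min_exp %||% -20L,
                                             mv$c_max_exp %||% 20L),
                       n_splits = as.integer(mv$splits %||% 17L),
                       test_size = mv$test_size,
                       seed = derive_seed(cfg$seed, "svm"))
    wmap <- fit_weight_map(design, search = search)
    multi <- threshold_weights_topk(wmap, min(k, length(wmap$w)))
    cmp <- compare_localization(io$dataset$grid, uni, multi, truth)
    cpath <- file.path(cfg$output_dir, "localization_comparison.tsv")
    utils::write.table(as.data.frame(cmp), cpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts <- c(artifacts, cpath)
  }
  write_manifest(cfg, cfg$output_dir, artifacts)
  invisible(artifacts)
}
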