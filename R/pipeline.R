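#' Pipeline configuration with study-default parameters
#'
#' Collects every stage parameter with defaults equal to the study design:
#' 12 mm smoothing FWHM, FDR q = 0.05, cluster extent 100 voxels, 10,000
#' permutations, component display threshold z > 1.5, VOI radius 8 mm (all
#' in the x10-scaled frame).
#'
#' @param synthetic a `synthetic_config` describing the cohort to simulate
#'   (default [synthetic_config()]), or NULL when `manifest` is given.
#' @param manifest optional path to a TSV manifest (subject_id, group, path)
#'   of pre-aligned NIfTI volumes plus `mask_path`; used instead of
#'   simulation.
#' @param mask_path NIfTI brain mask path (required with `manifest`).
#' @param fwhm_mm preprocessing smoothing FWHM (default 12).
#' @param fdr_q FDR level for voxelwise and edge tests (default 0.05).
#' @param extent cluster extent threshold in voxels (default 100).
#' @param connectivity cluster neighbourhood code (default 18).
#' @param n_perm permutation count (default 10000).
#' @param z_threshold component display threshold (default 1.5).
#' @param voi_radius_mm VOI sphere radius (default 8).
#' @param voi_table VOI centre table; defaults to the synthetic config's
#'   table when simulating, else [default_voi_table()].
#' @param n_components "auto" (MDL estimate) or a positive integer.
#' @param family_alpha familywise level of the efficiency test (default 0.05).
#' @param stages character subset of c("voxelwise", "ica", "connectivity",
#'   "efficiency") to run (default all).
#' @param seed integer seed governing simulation, ICA and permutations.
#' @param out_dir optional output directory for per-stage files.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            manifest = NULL, mask_path = NULL,
                            fwhm_mm = 12, fdr_q = 0.05, extent = 100,
                            connectivity = 18, n_perm = 10000,
                            z_threshold = 1.5, voi_radius_mm = 8,
                            voi_table = NULL,
                            n_components = "auto", family_alpha = 0.05,
                            stages = c("voxelwise", "ica", "connectivity",
                                       "efficiency"),
                            seed = 1L, out_dir = NULL) {
  if (is.null(synthetic) && is.null(manifest))
    stop("either a synthetic config or a manifest is required")
  if (!is.null(manifest) && is.null(mask_path))
    stop("`mask_path` is required with a manifest")
  bad <- setdiff(stages, c("voxelwise", "ica", "connectivity", "efficiency"))
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(voi_table))
    voi_table <- if (!is.null(synthetic)) synthetic$voi_table
                 else default_voi_table()
  structure(list(synthetic = synthetic, manifest = manifest,
                 mask_path = mask_path, fwhm_mm = fwhm_mm, fdr_q = fdr_q,
                 extent = extent, connectivity = connectivity,
                 n_perm = n_perm, z_threshold = z_threshold,
                 voi_radius_mm = voi_radius_mm, voi_table = voi_table,
                 n_components = n_components, family_alpha = family_alpha,
                 stages = stages, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `synthetic`
#' mapping is passed to [synthetic_config()]. Keys not present keep their
#' study defaults.
#'
#' @param path YAML filename.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synthetic)) {
    sy <- y$synthetic
    if (!is.null(sy$group_sizes)) sy$group_sizes <- unlist(sy$group_sizes)
    args$synthetic <- do.call(synthetic_config, sy)
  }
  for (k in c("manifest", "mask_path", "fwhm_mm", "fdr_q", "extent",
              "connectivity", "n_perm", "z_threshold", "voi_radius_mm",
              "n_components", "family_alpha", "stages", "seed", "out_dir"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

.load_manifest_cohort <- function(config) {
  man <- utils::read.delim(config$manifest, stringsAsFactors = FALSE)
  mask_vol <- read_mask(config$mask_path)
  scans <- lapply(split(man, man$group), function(rows)
    scan_set(lapply(rows$path, read_volume), rows$subject_id,
             rows$group[1]))
  list(scans = scans, mask = mask_vol, ground_truth = NULL)
}

#' Run the full metabolic-connectivity maturation pipeline
#'
#' Generates (or loads) the cohort, preprocesses every volume (Gaussian
#' smoothing then global-uptake normalization), and runs the enabled
#' analysis stages: voxelwise paired contrasts with FDR and cluster extent
#' between consecutive (and first-vs-last) age groups, pooled-group spatial
#' ICA, VOI connectivity with permutation edge tests, and per-VOI energy
#' efficiency with Bonferroni-corrected permutation tests. Deterministic
#' given the config (all randomness flows from `config$seed`).
#'
#' @param config a `pipeline_config`.
#' @return A report list (class `pipeline_report`) with per-stage results
#'   and the seeds used; written as `report.json` (plus per-stage TSV/NIfTI
#'   files) when `config$out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (!is.null(config$manifest)) .load_manifest_cohort(config)
            else generate_cohort(config$synthetic)
  mask <- cohort$mask
  groups <- names(cohort$scans)
  pre <- lapply(cohort$scans, preprocess_scans, mask = mask,
                fwhm_mm = config$fwhm_mm)
  report <- list(
    schema = "metconn-report-1",
    seed = config$seed,
    groups = lapply(cohort$scans, function(s)
      list(label = s$group, n_subjects = length(s))),
    n_volumes = sum(vapply(cohort$scans, length, integer(1))),
    parameters = list(fwhm_mm = config$fwhm_mm, fdr_q = config$fdr_q,
                      extent = config$extent, n_perm = config$n_perm,
                      z_threshold = config$z_threshold,
                      voi_radius_mm = config$voi_radius_mm,
                      family_alpha = config$family_alpha)
  )
  contrasts <- list()
  if (length(groups) >= 2) {
    for (i in seq_len(length(groups) - 1))
      contrasts[[length(contrasts) + 1L]] <- c(groups[i], groups[i + 1])
    if (length(groups) > 2)
      contrasts[[length(contrasts) + 1L]] <- c(groups[1],
                                               groups[length(groups)])
  }
  if ("voxelwise" %in% config$stages) {
    report$voxelwise <- lapply(contrasts, function(ct) {
      sm <- paired_t_map(pre[[ct[1]]], pre[[ct[2]]], mask)
      cl <- significant_clusters(sm, q = config$fdr_q,
                                 extent = config$extent,
                                 connectivity = config$connectivity)
      list(contrast = sprintf("%s_vs_%s", ct[2], ct[1]),
           n_pairs = sm$n_pairs, df = sm$df,
           n_significant_voxels = sum(cl$significant),
           clusters = cl$table)
    })
  }
  if ("ica" %in% config$stages) {
    x <- pool_data_matrix(pre, mask)
    k <- if (identical(config$n_components, "auto")) {
      est <- estimate_ncomp(x)
      as.integer(est)
    } else as.integer(config$n_components)
    comps <- infomax_ica(x, k, seed = config$seed)
    report$ica <- list(
      n_components = k,
      estimated = identical(config$n_components, "auto"),
      eigenvalues = as.numeric(.subject_pca(x)$values),
      var_retained = comps$var_retained,
      converged = comps$converged,
      n_suprathreshold = as.integer(rowSums(
        threshold_component(comps$maps, config$z_threshold))))
    if (!is.null(config$out_dir))
      write_components(comps, mask,
                       file.path(config$out_dir, "components.nii.gz"),
                       file.path(config$out_dir, "mixing.tsv"))
  }
  needs_voi <- any(c("connectivity", "efficiency") %in% config$stages)
  if (needs_voi) {
    tmpl <- pre[[1]]$volumes[[1]]
    masks <- voi_masks(config$voi_table, tmpl, config$voi_radius_mm)
    vms <- lapply(pre, extract_voi_means, masks = masks)
  }
  if ("connectivity" %in% config$stages) {
    mats <- lapply(vms, correlation_matrix)
    edge_tests <- lapply(contrasts, function(ct) {
      et <- permutation_edge_test(vms[[ct[1]]], vms[[ct[2]]],
                                  n_perm = config$n_perm,
                                  seed = config$seed, q = config$fdr_q)
      list(comparison = sprintf("%s_vs_%s", ct[2], ct[1]),
           n_edges = nrow(et), edges = as.data.frame(et))
    })
    report$connectivity <- list(
      n_vois = length(masks),
      matrices = lapply(mats, function(cm) list(group = cm$group,
                                                n_subjects = cm$n_subjects,
                                                r = cm$r)),
      comparisons = edge_tests)
  }
  if ("efficiency" %in% config$stages) {
    report$efficiency <- list(
      per_group = lapply(vms, function(m) as.data.frame(efficiency_result(m))),
      comparisons = lapply(contrasts, function(ct) {
        et <- permutation_efficiency_test(vms[[ct[1]]], vms[[ct[2]]],
                                          n_perm = config$n_perm,
                                          seed = config$seed,
                                          family_alpha = config$family_alpha)
        list(comparison = sprintf("%s_vs_%s", ct[2], ct[1]),
             vois = as.data.frame(et))
      }))
  }
  if (!is.null(cohort$ground_truth))
    report$ground_truth <- list(
      correlations = cohort$ground_truth$correlations,
      means = cohort$ground_truth$means)
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' Validate the structural schema of a pipeline report
#'
#' Checks the report against the checked-in JSON schema
#' (`inst/extdata/report-schema.json`): required top-level fields, stage
#' field types, and per-stage required keys.
#'
#' @param report a `pipeline_report` (or a list parsed from report.json).
#' @return TRUE invisibly; stops with a message on the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "metconn"))
  for (f in unlist(schema$required))
    if (is.null(report[[f]])) stop("report is missing required field: ", f)
  if (!identical(as.character(report$schema), schema$properties$schema$const))
    stop("unknown report schema id: ", report$schema)
  if (!is.numeric(report$n_volumes) && !is.integer(report$n_volumes))
    stop("n_volumes must be numeric")
  if (!is.null(report$connectivity)) {
    for (cmp in report$connectivity$comparisons)
      for (f in unlist(schema$properties$connectivity$comparison_required))
        if (is.null(cmp[[f]]))
          stop("connectivity comparison missing field: ", f)
  }
  invisible(TRUE)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d volumes in %d groups; stages: %s\n",
              x$n_volumes, length(x$groups),
              paste(intersect(c("voxelwise", "ica", "connectivity",
                                "efficiency"), names(x)), collapse = ", ")))
  invisible(x)
}
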