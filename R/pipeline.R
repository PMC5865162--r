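#' Run the full subtyping pipeline on a synthetic cohort
#'
#' Orchestrates the workflow end to end: simulate (or accept) a cohort,
#' extract the radiomic feature table, discover subtypes, characterize them
#' by survival, spatial distribution and molecular composition, and run the
#' within- versus pooled EGFRvIII classification. All tabular artifacts are
#' written under `outdir`, stamped with a hash of the configuration and the
#' master seed, so a run is reproducible bit for bit given (config, seed).
#'
#' @param outdir Output directory.
#' @param n_subjects Cohort size (when simulating).
#' @param volume_shape Voxel grid of the simulated volumes.
#' @param cohort Optional pre-built `synthetic_cohort` (skips simulation).
#' @param k_range Candidate K values.
#' @param n_runs K-means restarts per K.
#' @param folds Folds for the reproducibility check.
#' @param cv_runs Restarts per training fold in the reproducibility check.
#' @param seed Master integer seed.
#' @param write_volumes Also write every NIfTI volume (large; default FALSE
#'   writes tables, reports and the atlas only).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the in-memory results: `cohort`, `table`,
#'   `model`, `survival`, `model_comparison`, `spatial`, `radiogenomics`,
#'   `association`.
#' @export
run_pipeline <- function(outdir,
                         n_subjects = 90L,
                         volume_shape = c(40L, 40L, 40L),
                         cohort = NULL,
                         k_range = 2:6,
                         n_runs = 200L,
                         folds = 10L,
                         cv_runs = 50L,
                         seed = 1L,
                         write_volumes = FALSE,
                         verbose = interactive()) {
  say <- function(...) if (verbose) message(...)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config <- list(n_subjects = n_subjects, volume_shape = volume_shape,
                 k_range = k_range, n_runs = n_runs, folds = folds,
                 cv_runs = cv_runs, seed = seed)

  if (is.null(cohort)) {
    say("simulating cohort ...")
    spec <- cohort_spec(n_subjects, volume_shape = volume_shape,
                        random_seed = seed)
    cohort <- generate_cohort(spec)
  }
  utils::write.csv(cohort$clinical, file.path(outdir, "clinical.csv"),
                   row.names = FALSE)
  RNifti::writeNifti(cohort$atlas, file.path(outdir, "atlas.nii.gz"))
  if (write_volumes) write_cohort(cohort, file.path(outdir, "volumes"))

  say("extracting radiomic features ...")
  catalog <- feature_catalog()
  tab <- extract_feature_table(cohort, catalog)
  write_feature_table(tab, file.path(outdir, "features.csv"))
  write_catalog(catalog, file.path(outdir, "catalog.json"))

  say("discovering subtypes ...")
  model <- discover_subtypes(tab, k_range = k_range, n_runs = n_runs,
                             seed = seed)
  write_subtype_model(model, file.path(outdir, "subtype_model.json"))
  labels <- model$labels
  attr(labels, "cluster_names") <- model$cluster_names
  write_labels(labels, file.path(outdir, "subtype_labels.csv"))
  repro <- tryCatch(
    cv_reproducibility(apply_scaling(model$scaling, tab), model$K,
                       folds = folds, seed = seed, n_runs = cv_runs,
                       reference_labels = model$labels),
    error = function(e) {
      message("reproducibility check skipped: ", conditionMessage(e))
      NA_real_
    })
  assoc <- feature_association(tab, model$labels)
  utils::write.csv(assoc, file.path(outdir, "feature_association.csv"),
                   row.names = FALSE)

  say("survival characterization ...")
  records <- cohort$clinical
  records$time <- records$survival_months
  records$subtype <- model$cluster_names[model$labels[records$subject_id]]
  loc <- t(vapply(cohort$studies, function(s)
    compute_location_features(s$segmentation, cohort$atlas), numeric(9)))
  records <- cbind(records, loc[records$subject_id, , drop = FALSE])
  surv <- tryCatch(subtype_survival(records), error = function(e) {
    message("survival characterization skipped: ", conditionMessage(e))
    NULL
  })
  comp <- tryCatch(suppressWarnings(model_comparison(records)),
                   error = function(e) {
                     message("model comparison skipped: ", conditionMessage(e))
                     NULL
                   })
  .write_report(list(
    k_report = model$k_report,
    chosen_k = model$K,
    cv_reproducibility_pct = as.numeric(repro),
    medians = if (!is.null(surv)) as.list(surv$medians) else NULL,
    logrank = if (!is.null(surv)) surv$logrank[c("chisq", "df", "p")] else NULL,
    pairwise_hr = if (!is.null(surv)) surv$pairwise_hr else NULL,
    c_index = comp),
    file.path(outdir, "survival_report.json"), config, seed)
  if (!is.null(surv)) {
    for (s in names(surv$km))
      write_km_curve(surv$km[[s]], file.path(outdir, sprintf("km_%s.csv", s)))
  }

  say("spatial distribution ...")
  cores <- lapply(cohort$studies, function(s) subregion_masks(s$segmentation)$core)
  maps <- subtype_probability_map(cores, records$subtype)
  for (m in maps)
    RNifti::writeNifti(m$map, file.path(outdir,
                                        sprintf("frequency_map_%s.nii.gz",
                                                m$subtype)))
  regional <- subtype_regional_summary(cores, records$subtype, cohort$atlas)
  utils::write.csv(data.frame(subtype = rownames(regional), regional,
                              check.names = FALSE),
                   file.path(outdir, "regional_proportions.csv"),
                   row.names = FALSE)

  say("radiogenomic analysis ...")
  chisq <- tryCatch(
    composition_chisq(records$subtype, records$molecular_subtype),
    error = function(e) list(chisq = NA_real_, df = NA, p = NA_real_))
  rg <- tryCatch(
    suppressWarnings(svm_within_vs_pooled(tab, records$egfrviii,
                                          records$subtype, seed = seed)),
    error = function(e) {
      message("radiogenomic classification skipped: ", conditionMessage(e))
      NULL
    })
  es <- tryCatch(
    suppressWarnings(
      within_vs_pooled_effect_sizes(tab, records$egfrviii, records$subtype)),
    error = function(e) NULL)
  .write_report(list(
    composition_chisq = chisq[c("chisq", "df", "p")],
    per_stratum = rg$per_stratum,
    weighted_accuracy = rg$weighted_accuracy,
    pooled_accuracy = rg$pooled_accuracy),
    file.path(outdir, "radiogenomics_report.json"), config, seed)
  if (!is.null(es)) {
    utils::write.csv(
      data.frame(feature = rownames(es$abs_d), es$abs_d, check.names = FALSE),
      file.path(outdir, "effect_sizes.csv"), row.names = FALSE)
  }

  invisible(list(cohort = cohort, table = tab, model = model,
                 reproducibility = repro, survival = surv,
                 model_comparison = comp, spatial = list(
                   maps = maps, regional = regional),
                 radiogenomics = rg, effect_sizes = es,
                 association = assoc, composition = chisq))
}
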