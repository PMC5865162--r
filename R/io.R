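#' Write one imaging study to NIfTI
#'
#' One `.nii.gz` per channel plus the segmentation, named
#' `<subject>_<channel>.nii.gz` and `<subject>_seg.nii.gz`.
#'
#' @param study An `imaging_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ch in names(study$channels)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", study$subject_id, ch))
    RNifti::writeNifti(study$channels[[ch]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, sprintf("%s_seg.nii.gz", study$subject_id))
  RNifti::writeNifti(study$segmentation, p)
  invisible(c(paths, p))
}

#' Read one imaging study from NIfTI files
#'
#' @param dir Directory holding `<subject>_<channel>.nii.gz` files and
#'   `<subject>_seg.nii.gz`.
#' @param subject_id Subject identifier.
#' @param channels Channel labels to read (default all 11).
#' @param clinical Optional one-row clinical data.frame to attach.
#' @return An `imaging_study`. Errors name the offending files on a volume
#'   shape mismatch, and list the allowed labels on an unknown segmentation
#'   label.
#' @export
read_study <- function(dir, subject_id, channels = mpmri_channels(),
                       clinical = NULL) {
  vols <- list()
  ref_shape <- NULL; ref_file <- NULL
  for (ch in channels) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", subject_id, ch))
    if (!file.exists(p)) stop("missing channel file: ", p)
    v <- as.array(RNifti::readNifti(p))
    if (is.null(ref_shape)) { ref_shape <- dim(v); ref_file <- p }
    else if (!identical(dim(v), ref_shape))
      stop(sprintf("volume shape mismatch between %s and %s", ref_file, p))
    vols[[ch]] <- v
  }
  ps <- file.path(dir, sprintf("%s_seg.nii.gz", subject_id))
  if (!file.exists(ps)) stop("missing segmentation file: ", ps)
  seg <- as.array(RNifti::readNifti(ps))
  storage.mode(seg) <- "integer"
  if (!is.null(ref_shape) && !identical(dim(seg), ref_shape))
    stop(sprintf("volume shape mismatch between %s and %s", ref_file, ps))
  allowed <- c(0L, unname(subregion_labels()))
  bad <- setdiff(unique(as.vector(seg)), allowed)
  if (length(bad) > 0)
    stop(sprintf("unknown segmentation label(s) %s; allowed labels: %s",
                 paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  structure(list(subject_id = subject_id, channels = vols,
                 segmentation = seg, clinical = clinical,
                 truth_archetype = clinical$truth_archetype),
            class = "imaging_study")
}

#' Write a whole synthetic cohort to disk
#'
#' Per-subject NIfTI volumes under `dir/<subject_id>/`, the atlas as
#' `atlas.nii.gz` and the clinical table as `clinical.csv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$studies) write_study(s, file.path(dir, s$subject_id))
  RNifti::writeNifti(cohort$atlas, file.path(dir, "atlas.nii.gz"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param channels Channel labels to read per subject.
#' @return List with `studies`, `clinical`, `atlas`.
#' @export
read_cohort <- function(dir, channels = mpmri_channels()) {
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  atlas <- as.array(RNifti::readNifti(file.path(dir, "atlas.nii.gz")))
  storage.mode(atlas) <- "integer"
  attr(atlas, "regions") <- atlas_region_names()
  studies <- lapply(seq_len(nrow(clinical)), function(i) {
    id <- clinical$subject_id[i]
    read_study(file.path(dir, id), id, channels = channels,
               clinical = clinical[i, , drop = FALSE])
  })
  names(studies) <- clinical$subject_id
  structure(list(studies = studies, clinical = clinical, atlas = atlas,
                 spec = NULL),
            class = "synthetic_cohort")
}

#' Write / read a feature table as CSV
#'
#' Floating-point values are written with 10 significant digits; the
#' round-trip is lossless to well below 1e-9 relative error.
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @return `write_feature_table`: invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  X <- table$X
  df <- data.frame(subject_id = rownames(X),
                   signif(X, digits = 10),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param catalog Optional `feature_catalog` to attach and order by.
#' @return `read_feature_table`: a `feature_table`.
#' @export
read_feature_table <- function(path, catalog = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$subject_id
  if (!is.null(catalog)) {
    missing <- setdiff(catalog$name, colnames(X))
    if (length(missing) > 0)
      stop("feature table is missing catalog feature(s): ",
           paste(missing, collapse = ", "))
    X <- X[, catalog$name, drop = FALSE]
  }
  structure(list(subjects = rownames(X), catalog = catalog, X = X,
                 imputed = NULL),
            class = "feature_table")
}

#' Write a feature catalog as JSON
#'
#' @param catalog A `feature_catalog`.
#' @param path JSON path.
#' @export
write_catalog <- function(catalog, path) {
  jsonlite::write_json(as.data.frame(catalog), path, auto_unbox = FALSE,
                       na = "null", digits = NA)
  invisible(path)
}

#' Serialize / restore a subtype model as JSON
#'
#' Full-precision serialization of the scaling, centroids and cluster names:
#' a restored model yields identical assignments on any table.
#'
#' @param model A `subtype_model`.
#' @param path JSON path.
#' @export
write_subtype_model <- function(model, path) {
  payload <- list(
    K = model$K,
    centroids = lapply(seq_len(nrow(model$centroids)),
                       function(i) unname(model$centroids[i, ])),
    scaling = list(min = unname(model$scaling$min),
                   max = unname(model$scaling$max),
                   constant = unname(model$scaling$constant)),
    features = model$features,
    cluster_names = model$cluster_names,
    labels = if (!is.null(model$labels))
      list(subject = names(model$labels), cluster = unname(model$labels))
    else NULL,
    silhouette = model$silhouette,
    frequency = model$frequency,
    seed = model$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_subtype_model
#' @return `read_subtype_model`: a `subtype_model`.
#' @export
read_subtype_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- do.call(rbind, if (is.list(j$centroids)) j$centroids
                       else list(j$centroids))
  if (is.matrix(j$centroids)) centroids <- j$centroids
  colnames(centroids) <- j$features
  rownames(centroids) <- j$cluster_names
  scaling <- structure(list(min = stats::setNames(j$scaling$min, j$features),
                            max = stats::setNames(j$scaling$max, j$features),
                            constant = stats::setNames(j$scaling$constant,
                                                       j$features),
                            features = j$features),
                       class = "scaling_model")
  labels <- if (!is.null(j$labels))
    stats::setNames(as.integer(j$labels$cluster), j$labels$subject) else NULL
  structure(list(K = as.integer(j$K), centroids = centroids,
                 scaling = scaling, labels = labels,
                 cluster_names = j$cluster_names, k_report = NULL,
                 silhouette = j$silhouette, frequency = j$frequency,
                 features = j$features, seed = j$seed),
            class = "subtype_model")
}

#' Write subtype labels as CSV
#'
#' @param labels Named integer assignment (e.g. from [assign_new()]).
#' @param path CSV path.
#' @param cluster_names Display names in index order.
#' @export
write_labels <- function(labels, path,
                         cluster_names = attr(labels, "cluster_names")) {
  df <- data.frame(subject_id = names(labels),
                   cluster = unname(labels),
                   subtype = if (!is.null(cluster_names))
                     cluster_names[unname(labels)] else unname(labels))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a Kaplan-Meier curve as CSV (time, survival, at-risk)
#'
#' @param curve A `km_curve`.
#' @param path CSV path.
#' @export
write_km_curve <- function(curve, path) {
  utils::write.csv(data.frame(time = curve$time, surv = curve$surv,
                              n_risk = curve$n_risk),
                   path, row.names = FALSE)
  invisible(path)
}

# Short stable fingerprint of a configuration list, used to stamp artifacts.
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

# Write a report as JSON stamped with the run configuration hash and seed.
.write_report <- function(report, path, config, seed) {
  jsonlite::write_json(c(list(config_hash = .config_hash(config),
                              seed = seed), report),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(path)
}
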