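#' Subregion masks of a segmentation
#'
#' @param segmentation Integer 3D label volume (labels per
#'   [subregion_labels()]).
#' @return List of logical arrays: `TU`, `NC`, `ED`, `core` (TU | NC),
#'   `WT` (TU | NC | ED).
#' @export
subregion_masks <- function(segmentation) {
  labs <- subregion_labels()
  tu <- segmentation == labs[["TU"]]
  nc <- segmentation == labs[["NC"]]
  ed <- segmentation == labs[["ED"]]
  list(TU = tu, NC = nc, ED = ed, core = tu | nc, WT = tu | nc | ed)
}

#' Volumetric features of the tumor subregions
#'
#' Volumes are voxel counts. Returns the three subregion volumes normalized
#' by total brain size, the edema fraction of the whole tumor and the
#' enhancing-to-core ratio.
#'
#' @param segmentation Integer 3D label volume.
#' @param brain_mask Logical 3D array (nonempty).
#' @return Named numeric of length 5: `ED_VOLUME`, `NC_VOLUME`, `TU_VOLUME`
#'   (each / brain volume), `ED_TO_WT_RATIO` = ED / (ED + NC + TU),
#'   `TU_TO_NC_RATIO` = TU / NC (NA when NC is empty).
#' @export
compute_volumetric_features <- function(segmentation, brain_mask) {
  nb <- sum(brain_mask)
  if (nb == 0) stop("brain mask is empty")
  m <- subregion_masks(segmentation)
  ed <- sum(m$ED); nc <- sum(m$NC); tu <- sum(m$TU)
  wt <- ed + nc + tu
  c(ED_VOLUME = ed / nb, NC_VOLUME = nc / nb, TU_VOLUME = tu / nb,
    ED_TO_WT_RATIO = if (wt > 0) ed / wt else 0,
    TU_TO_NC_RATIO = if (nc > 0) tu / nc else NA_real_)
}

# Count exposed faces of a binary mask along one axis (both directions):
# voxels in the mask whose axis-neighbor is outside the mask or the volume.
.exposed_along <- function(mask, axis) {
  d <- dim(mask)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(mask, perm)
  dm <- dim(a)
  a <- matrix(a, nrow = dm[1])
  inner_hi <- sum(a[-dm[1], , drop = FALSE] & !a[-1, , drop = FALSE])
  inner_lo <- sum(a[-1, , drop = FALSE] & !a[-dm[1], , drop = FALSE])
  border <- sum(a[1, ]) + sum(a[dm[1], ])
  inner_hi + inner_lo + border
}

#' Circularity of a 2D mask
#'
#' 4 * pi * Area / Perimeter^2, with Area the voxel count and Perimeter the
#' exposed-edge count (4-connectivity). Under these discrete definitions the
#' maximal value pi/4 is attained by axis-aligned squares; a rasterized disk
#' tends to pi^2/16 (the exposed-edge perimeter of a disk is the taxicab
#' perimeter 8r). Values are therefore comparative, not calibrated to 1 for
#' circles.
#'
#' @param mask_2d Logical 2D matrix, nonempty.
#' @return Circularity in (0, pi/4].
#' @export
compute_circularity <- function(mask_2d) {
  stopifnot(length(dim(mask_2d)) == 2)
  area <- sum(mask_2d)
  if (area == 0) stop("empty 2D mask")
  per <- .exposed_along(mask_2d, 1L) + .exposed_along(mask_2d, 2L)
  4 * pi * area / per^2
}

#' Sphericity of a 3D mask
#'
#' pi^(1/3) * (6 V)^(2/3) / A, with V the voxel count and A the exposed-face
#' count. The maximal value (pi/6)^(1/3) ~= 0.806 is attained by cubes; a
#' rasterized ball tends to 2/3 (face counting overestimates a sphere's
#' surface by a factor 3/2). Values are comparative, not calibrated to 1
#' for balls.
#'
#' @param mask_3d Logical 3D array, nonempty.
#' @return Sphericity in (0, (pi/6)^(1/3)].
#' @export
compute_sphericity <- function(mask_3d) {
  stopifnot(length(dim(mask_3d)) == 3)
  vol <- sum(mask_3d)
  if (vol == 0) stop("empty 3D mask")
  area <- .exposed_along(mask_3d, 1L) + .exposed_along(mask_3d, 2L) +
    .exposed_along(mask_3d, 3L)
  pi^(1 / 3) * (6 * vol)^(2 / 3) / area
}

# Axial slice (third axis) with the largest in-mask area; the 2D shape
# measure is taken on that slice.
.max_area_slice <- function(mask_3d) {
  areas <- apply(mask_3d, 3, sum)
  mask_3d[, , which.max(areas)]
}

#' First-order intensity statistics in a region
#'
#' @param channel_volume Numeric 3D array.
#' @param region_mask Logical 3D array.
#' @return Named numeric `c(mean, sd)`; the SD is the population standard
#'   deviation (divisor n). Both NA for an empty region.
#' @export
compute_intensity_stats <- function(channel_volume, region_mask) {
  v <- channel_volume[region_mask]
  n <- length(v)
  if (n == 0) return(c(mean = NA_real_, sd = NA_real_))
  m <- mean(v)
  c(mean = m, sd = sqrt(sum((v - m)^2) / n))
}

#' Normalize a channel to [0, 1] within the brain
#'
#' Intensities are clipped at the 1st and 99th percentile of in-brain voxels
#' and min-max scaled, making the five-bin histogram features comparable
#' across subjects.
#'
#' @param channel_volume Numeric 3D array.
#' @param brain_mask Logical 3D array.
#' @param probs Clipping percentiles (default 0.01 and 0.99).
#' @return Numeric 3D array with in-brain values in [0, 1] (out-of-brain
#'   voxels set to 0).
#' @export
normalize_channel <- function(channel_volume, brain_mask, probs = c(0.01, 0.99)) {
  q <- stats::quantile(channel_volume[brain_mask], probs, names = FALSE)
  out <- array(0, dim = dim(channel_volume))
  v <- pmin(pmax(channel_volume[brain_mask], q[1]), q[2])
  out[brain_mask] <- if (q[2] > q[1]) (v - q[1]) / (q[2] - q[1]) else 0
  out
}

#' Five-bin histogram features of a region
#'
#' Percentage of in-region voxels in each of `n_bins` equal-width bins on
#' [0, 1] (last bin closed on the right). The channel must already be
#' normalized to [0, 1] (see [normalize_channel()]).
#'
#' @param channel_volume Normalized numeric 3D array.
#' @param region_mask Logical 3D array.
#' @param n_bins Number of bins (default 5).
#' @return Numeric vector of `n_bins` percentages summing to 100 (all NA for
#'   an empty region).
#' @export
compute_histogram_features <- function(channel_volume, region_mask, n_bins = 5L) {
  v <- channel_volume[region_mask]
  if (length(v) == 0) return(rep(NA_real_, n_bins))
  b <- pmin(pmax(floor(v * n_bins) + 1L, 1L), n_bins)
  100 * tabulate(b, nbins = n_bins) / length(v)
}

#' Tumor location features: core percentage per atlas region
#'
#' For the tumor core (TU + NC), the percentage of core voxels falling in
#' each of the nine atlas regions. Sums to 100 whenever the core lies inside
#' the atlas-covered brain.
#'
#' @param segmentation Integer 3D label volume.
#' @param atlas_label_map Integer 3D array with labels 1..9 (0 = outside).
#' @return Named numeric of length 9 (names `LOC_<region>`).
#' @export
compute_location_features <- function(segmentation, atlas_label_map) {
  core <- subregion_masks(segmentation)$core
  n <- sum(core)
  if (n == 0) stop("tumor core (TU + NC) is empty")
  counts <- tabulate(atlas_label_map[core], nbins = 9L)
  stats::setNames(100 * counts / n, paste0("LOC_", atlas_region_names()))
}

#' The default radiomic feature catalog
#'
#' Enumerates the five-family catalog: 11 volumetric & shape features, 66
#' intensity features (mean and SD x 11 channels x 3 subregions), 165
#' histogram features (5 bins x 11 channels x 3 subregions), 24 GLCM texture
#' features (6 measures x 4 structural channels on the whole tumor), 9
#' location features and 3 biophysical growth pass-through features — 278 in
#' total. Feature names follow the `Subregion_FAMILY_Channel[_Bin]` scheme
#' (e.g. `ED_BINS_FLAIR_3`, `TU_MEAN_rCBV`). An exclusion list allows
#' reproducing smaller historical catalog variants whose exact membership is not
#' recoverable.
#'
#' @param exclude Character vector of feature names to drop.
#' @return A data.frame of class `feature_catalog` with columns `name`,
#'   `family`, `region`, `channel`, `bin`.
#' @export
feature_catalog <- function(exclude = character()) {
  chans <- mpmri_channels()
  regions <- c("ED", "NC", "TU")
  rows <- list()
  add <- function(name, family, region = NA, channel = NA, bin = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, family = family, region = region, channel = channel,
      bin = bin, stringsAsFactors = FALSE)
  }
  for (nm in c("ED_VOLUME", "NC_VOLUME", "TU_VOLUME",
               "ED_TO_WT_RATIO", "TU_TO_NC_RATIO"))
    add(nm, "volumetric_shape", sub("_.*", "", nm))
  for (reg in c("NC", "NCTU", "WT")) {
    add(paste0(reg, "_CIRCULARITY"), "volumetric_shape", reg)
    add(paste0(reg, "_SPHERICITY"), "volumetric_shape", reg)
  }
  for (reg in regions) for (ch in chans) for (st in c("MEAN", "STD"))
    add(paste(reg, st, ch, sep = "_"), "intensity", reg, ch)
  for (reg in regions) for (ch in chans) for (b in 1:5)
    add(paste(reg, "BINS", ch, b, sep = "_"), "histogram", reg, ch, b)
  for (ch in c("T1", "T1CE", "T2", "FLAIR"))
    for (ms in c("ENERGY", "CONTRAST", "ENTROPY", "CORRELATION",
                 "DISSIMILARITY", "HOMOGENEITY"))
      add(paste("WT", ms, ch, sep = "_"), "texture", "WT", ch)
  for (reg in atlas_region_names())
    add(paste0("LOC_", reg), "location", reg)
  for (nm in c("GROWTH_DT", "GROWTH_DW", "GROWTH_FOCI"))
    add(nm, "growth")
  cat <- do.call(rbind, rows)
  if (anyDuplicated(cat$name)) stop("duplicate feature names in catalog")
  cat <- cat[!cat$name %in% exclude, , drop = FALSE]
  rownames(cat) <- NULL
  class(cat) <- c("feature_catalog", "data.frame")
  cat
}

# All features of one subject, as a named vector over the full default
# catalog; selection/ordering against a user catalog happens in
# extract_feature_table().
.subject_features <- function(study, atlas, texture_cfg = texture_config()) {
  seg <- study$segmentation
  brain <- atlas > 0L
  m <- subregion_masks(seg)
  out <- compute_volumetric_features(seg, brain)
  shape_regions <- list(NC = m$NC, NCTU = m$NC | m$TU, WT = m$WT)
  for (reg in names(shape_regions)) {
    msk <- shape_regions[[reg]]
    out[paste0(reg, "_CIRCULARITY")] <-
      if (sum(msk) > 0) compute_circularity(.max_area_slice(msk)) else NA_real_
    out[paste0(reg, "_SPHERICITY")] <-
      if (sum(msk) > 0) compute_sphericity(msk) else NA_real_
  }
  if (is.null(study$channels))
    stop(sprintf("subject %s has no channel volumes", study$subject_id))
  for (ch in mpmri_channels()) {
    if (is.null(study$channels[[ch]]))
      stop(sprintf("subject %s is missing channel %s", study$subject_id, ch))
  }
  for (reg in c("ED", "NC", "TU")) {
    msk <- m[[reg]]
    for (ch in mpmri_channels()) {
      st <- compute_intensity_stats(study$channels[[ch]], msk)
      out[paste(reg, "MEAN", ch, sep = "_")] <- st[["mean"]]
      out[paste(reg, "STD", ch, sep = "_")] <- st[["sd"]]
    }
  }
  for (ch in mpmri_channels()) {
    normed <- normalize_channel(study$channels[[ch]], brain)
    for (reg in c("ED", "NC", "TU")) {
      h <- compute_histogram_features(normed, m[[reg]])
      out[paste(reg, "BINS", ch, 1:5, sep = "_")] <- h
    }
  }
  for (ch in c("T1", "T1CE", "T2", "FLAIR")) {
    g <- compute_glcm_measures(study$channels[[ch]], m$WT, texture_cfg)
    out[paste("WT", toupper(names(g)), ch, sep = "_")] <- g
  }
  out[paste0("LOC_", atlas_region_names())] <-
    compute_location_features(seg, atlas)
  out["GROWTH_DT"] <- study$clinical$growth_dt
  out["GROWTH_DW"] <- study$clinical$growth_dw
  out["GROWTH_FOCI"] <- study$clinical$growth_foci
  out
}

#' Extract the cohort feature table
#'
#' One row per subject, columns in catalog order. Missing values (e.g.
#' TU/NC ratio when NC is empty) are imputed by the per-feature cohort
#' median; the imputed cells are recorded in the `"imputed"` attribute.
#'
#' @param cohort A `synthetic_cohort`, or a plain list of `imaging_study`.
#' @param catalog A `feature_catalog` (default the full 278-feature catalog).
#' @param atlas Atlas label map; taken from the cohort when available.
#' @param texture_cfg A [texture_config()].
#' @return Object of class `feature_table`: list with `subjects`, `catalog`
#'   and numeric matrix `X` (subjects x features).
#' @export
extract_feature_table <- function(cohort, catalog = feature_catalog(),
                                  atlas = NULL,
                                  texture_cfg = texture_config()) {
  studies <- if (inherits(cohort, "synthetic_cohort")) cohort$studies else cohort
  if (is.null(atlas) && inherits(cohort, "synthetic_cohort")) atlas <- cohort$atlas
  if (is.null(atlas)) stop("an atlas label map is required for location features")
  rows <- lapply(studies, .subject_features, atlas = atlas,
                 texture_cfg = texture_cfg)
  X <- do.call(rbind, lapply(rows, function(r) r[catalog$name]))
  colnames(X) <- catalog$name
  rownames(X) <- unname(vapply(studies, function(s) s$subject_id, character(1)))
  imputed <- which(is.na(X), arr.ind = TRUE)
  if (nrow(imputed) > 0) {
    med <- apply(X, 2, stats::median, na.rm = TRUE)
    X[imputed] <- med[imputed[, 2]]
  }
  structure(list(subjects = rownames(X), catalog = catalog, X = X,
                 imputed = if (nrow(imputed) > 0)
                   data.frame(subject = rownames(X)[imputed[, 1]],
                              feature = colnames(X)[imputed[, 2]])
                 else NULL),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Radiomic feature table: %d subjects x %d features\n",
              nrow(x$X), ncol(x$X)))
  print(table(x$catalog$family))
  if (!is.null(x$imputed))
    cat(sprintf("%d missing cells imputed by cohort median\n", nrow(x$imputed)))
  invisible(x)
}

#' @export
as.matrix.feature_table <- function(x, ...) x$X
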