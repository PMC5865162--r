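#' Synthetic nine-region brain parcellation
#'
#' Builds a deterministic, fabricated parcellation of an ellipsoidal brain
#' volume into the nine anatomical regions used for tumor location features
#' (frontal, temporal, parietal, basal ganglia, insula, cc fornix, occipital,
#' cerebellum, brain stem). The parcellation is synthetic: region boundaries
#' are simple geometric rules in atlas space, not a registered template.
#' Voxels outside the brain are 0.
#'
#' Axis convention: axis 1 = left-right, axis 2 = posterior-anterior (large
#' index anterior), axis 3 = inferior-superior (large index superior).
#'
#' @param shape Integer vector of 3 volume dimensions (each >= 16; regions
#'   are all guaranteed nonempty for shapes >= 24).
#' @return Integer 3D array with labels 1..9 inside the brain, 0 outside;
#'   label k corresponds to `atlas_region_names()[k]`. The region names are
#'   attached as attribute `"regions"`.
#' @export
synthetic_atlas <- function(shape = c(48L, 48L, 48L)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 16))
  ctr <- (shape + 1) / 2
  semi <- 0.42 * shape
  ix <- (seq_len(shape[1]) - ctr[1]) / semi[1]
  iy <- (seq_len(shape[2]) - ctr[2]) / semi[2]
  iz <- (seq_len(shape[3]) - ctr[3]) / semi[3]
  fx <- array(ix, dim = shape)
  fy <- array(rep(iy, each = shape[1]), dim = shape)
  fz <- array(rep(iz, each = shape[1] * shape[2]), dim = shape)
  brain <- fx^2 + fy^2 + fz^2 <= 1
  zf <- (fz + 1) / 2      # 0 = inferior pole, 1 = superior pole
  yf <- (fy + 1) / 2      # 0 = posterior pole, 1 = anterior pole
  rc <- sqrt(fx^2 + fy^2) # normalized distance to the vertical midline axis

  lab <- array(0L, dim = shape)
  regions <- atlas_region_names()
  code <- function(nm) match(nm, regions)
  bottom <- brain & zf < 0.22
  lab[bottom & rc < 0.35] <- code("brain_stem")
  lab[bottom & rc >= 0.35] <- code("cerebellum")
  central <- brain & !bottom & rc < 0.25
  lab[central & zf > 0.62] <- code("cc_fornix")
  lab[central & zf <= 0.62 & zf > 0.45] <- code("basal_ganglia")
  lab[central & zf <= 0.45] <- code("insula")
  outer <- brain & !bottom & rc >= 0.25
  lab[outer & yf > 0.62] <- code("frontal")
  lab[outer & yf < 0.30] <- code("occipital")
  mid <- outer & yf >= 0.30 & yf <= 0.62
  lab[mid & zf < 0.55] <- code("temporal")
  lab[mid & zf >= 0.55] <- code("parietal")
  attr(lab, "regions") <- regions
  lab
}

#' Brain mask of a synthetic volume
#'
#' @param shape Integer vector of 3 volume dimensions.
#' @return Logical 3D array: TRUE inside the ellipsoidal synthetic brain.
#' @export
synthetic_brain_mask <- function(shape = c(48L, 48L, 48L)) {
  synthetic_atlas(shape) > 0L
}
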