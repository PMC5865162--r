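#' @keywords internal
"_PACKAGE"

#' Imaging channels of the multi-parametric MRI protocol
#'
#' The eleven co-registered channels the pipeline operates on: structural
#' (T1, T1CE, T2, FLAIR), diffusion-tensor derived (AX, FA, RAD, TR) and
#' dynamic susceptibility contrast perfusion derived (rCBV, PH, PSR).
#'
#' @return Character vector of the 11 channel labels.
#' @export
mpmri_channels <- function() {
  c("T1", "T1CE", "T2", "FLAIR", "AX", "FA", "RAD", "TR", "rCBV", "PH", "PSR")
}

#' Tumor subregion labels
#'
#' Segmentation subregions: enhancing tumor (TU), non-enhancing core (NC) and
#' peritumoral edema (ED). Integer codes follow the BraTS-style convention
#' 1 = NC, 2 = ED, 4 = TU (0 = background / normal brain).
#'
#' @return Named integer vector `c(NC = 1, ED = 2, TU = 4)`.
#' @export
subregion_labels <- function() {
  c(NC = 1L, ED = 2L, TU = 4L)
}

#' Names of the nine atlas regions
#'
#' @return Character vector of the 9 anatomical region labels.
#' @export
atlas_region_names <- function() {
  c("frontal", "temporal", "parietal", "basal_ganglia", "insula",
    "cc_fornix", "occipital", "cerebellum", "brain_stem")
}

# Per-(region, channel) Gaussian intensity means. Units are arbitrary: only
# the between-archetype orderings are meaningful (the source data carry no
# absolute calibration). Rows: background brain, TU, NC, ED.
.base_intensity_means <- function() {
  m <- rbind(
    brain = c(T1 = 0.50, T1CE = 0.45, T2 = 0.45, FLAIR = 0.40, AX = 0.50,
              FA = 0.50, RAD = 0.40, TR = 0.45, rCBV = 0.35, PH = 0.35, PSR = 0.60),
    TU    = c(T1 = 0.45, T1CE = 0.90, T2 = 0.55, FLAIR = 0.55, AX = 0.50,
              FA = 0.30, RAD = 0.50, TR = 0.50, rCBV = 0.60, PH = 0.55, PSR = 0.50),
    NC    = c(T1 = 0.35, T1CE = 0.40, T2 = 0.60, FLAIR = 0.50, AX = 0.45,
              FA = 0.30, RAD = 0.50, TR = 0.50, rCBV = 0.45, PH = 0.45, PSR = 0.50),
    ED    = c(T1 = 0.40, T1CE = 0.45, T2 = 0.70, FLAIR = 0.75, AX = 0.60,
              FA = 0.35, RAD = 0.60, TR = 0.65, rCBV = 0.40, PH = 0.40, PSR = 0.55)
  )
  m
}

# Archetype-specific additive offsets encoding the qualitative imaging
# contrasts along three physiological axes, expressed across all modality
# families (as in real subtypes, where the distinctive features span every
# modality): cellularity (diffusivities TR/AX/RAD high and FA low when
# cellularity is low: rim-enhancing > irregular > solid in TR), vascularity
# (rCBV/PH high and PSR low when neovascularization is high: solid >
# irregular > rim-enhancing in rCBV), and water/infiltration (FLAIR/T2 in
# edema highest for the fluid-rich irregular edema). T1CE adds the bright
# enhancing rim of the rim-enhancing archetype.
.archetype_offsets <- function(name) {
  z <- matrix(0, 4, 11, dimnames = list(c("brain", "TU", "NC", "ED"), mpmri_channels()))
  core <- c("TU", "NC")
  if (name == "rim_enhancing") {
    z[core, "TR"] <- 0.20; z[core, "AX"] <- 0.15; z[core, "RAD"] <- 0.15
    z[core, "FA"] <- -0.10
    z[core, "rCBV"] <- -0.12; z["ED", "rCBV"] <- -0.06
    z[core, "PH"] <- -0.10; z[core, "PSR"] <- 0.10
    z["TU", "T1CE"] <- 0.15
    z["NC", "T1"] <- 0.06
  } else if (name == "irregular") {
    z[core, "TR"] <- 0.08; z[core, "AX"] <- 0.06; z[core, "RAD"] <- 0.06
    z["ED", "TR"] <- 0.12; z["ED", "AX"] <- 0.10
    z["ED", "FLAIR"] <- 0.20; z["ED", "T2"] <- 0.15
    z[core, "rCBV"] <- 0.04; z["ED", "rCBV"] <- 0.02
    z["TU", "T1CE"] <- -0.05
  } else if (name == "solid") {
    z[core, "TR"] <- -0.12; z["ED", "TR"] <- -0.10
    z[core, "AX"] <- -0.10; z[core, "RAD"] <- -0.10
    z[core, "FA"] <- 0.10; z["ED", "FA"] <- 0.05
    z[core, "rCBV"] <- 0.18; z["ED", "rCBV"] <- 0.10
    z[core, "PH"] <- 0.12; z["ED", "PH"] <- 0.06
    z[core, "PSR"] <- -0.10
    z["ED", "FLAIR"] <- -0.08; z["ED", "T2"] <- -0.06
  }
  z
}

#' Construct a subtype archetype for the synthetic cohort generator
#'
#' An archetype bundles everything the generator needs to plant one imaging
#' subtype: per-(region, channel) Gaussian intensity parameters, edema size
#' relative to the tumor core, boundary irregularity, survival distribution,
#' mutation prevalences, molecular-subtype mixture and preferred anatomical
#' location.
#'
#' @param name Archetype label.
#' @param intensity_means 4 x 11 matrix of mean intensities (rows brain, TU,
#'   NC, ED; columns [mpmri_channels()]), arbitrary units.
#' @param intensity_sd Voxelwise within-region standard deviation.
#' @param subject_sd Between-subject standard deviation of region means.
#' @param edema_scale Ratio of edema volume to core (TU + NC) volume, > 0.
#' @param irregularity Boundary-perturbation amplitude in voxels, >= 0.
#' @param core_radius Mean core radius in voxels.
#' @param survival_median Median overall survival in months, > 0.
#' @param censoring_fraction Expected fraction of censored subjects in [0, 1].
#' @param age_log_hr Log hazard ratio per decade of age (centered at 58 y).
#' @param egfrviii_prevalence Prevalence of EGFRvIII mutation in [0, 1].
#' @param idh1_mutant_prob Probability of IDH1 mutation in [0, 1].
#' @param mgmt_methylated_prob Probability of MGMT promoter methylation.
#' @param molecular_mixture Probability vector over the four transcriptomic
#'   subtypes (classical, mesenchymal, proneural, neural); must sum to 1.
#' @param spatial_center Atlas region label where tumors are preferentially
#'   seeded (one of [atlas_region_names()]).
#' @param growth_params Named list with mean/sd pairs for the three
#'   biophysical growth pass-through features (dt, dw, foci).
#'
#' @return An object of class `subtype_archetype`.
#' @seealso [default_archetypes()]
#' @export
subtype_archetype <- function(name,
                              intensity_means,
                              intensity_sd = 0.08,
                              subject_sd = 0.02,
                              edema_scale,
                              irregularity,
                              core_radius = 6,
                              survival_median,
                              censoring_fraction = 0.2,
                              age_log_hr = 0.15,
                              egfrviii_prevalence,
                              idh1_mutant_prob = 0.02,
                              mgmt_methylated_prob = 0.45,
                              molecular_mixture,
                              spatial_center,
                              growth_params = list(dt = c(150, 20),
                                                   dw = c(0.7, 0.1),
                                                   foci = c(1.3, 0.5))) {
  stopifnot(is.matrix(intensity_means),
            nrow(intensity_means) == 4, ncol(intensity_means) == 11)
  if (!(edema_scale > 0)) stop("edema_scale must be > 0")
  if (irregularity < 0) stop("irregularity must be >= 0")
  if (!(survival_median > 0)) stop("survival_median must be > 0")
  probs <- c(censoring_fraction, egfrviii_prevalence, idh1_mutant_prob,
             mgmt_methylated_prob, molecular_mixture)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (abs(sum(molecular_mixture) - 1) > 1e-9)
    stop("molecular_mixture must sum to 1")
  if (length(molecular_mixture) != 4 || is.null(names(molecular_mixture)))
    stop("molecular_mixture must be a named length-4 probability vector")
  if (!spatial_center %in% atlas_region_names())
    stop("spatial_center must be one of the nine atlas region labels")
  structure(list(
    name = name,
    intensity_means = intensity_means,
    intensity_sd = intensity_sd,
    subject_sd = subject_sd,
    edema_scale = edema_scale,
    irregularity = irregularity,
    core_radius = core_radius,
    survival_median = survival_median,
    censoring_fraction = censoring_fraction,
    age_log_hr = age_log_hr,
    egfrviii_prevalence = egfrviii_prevalence,
    idh1_mutant_prob = idh1_mutant_prob,
    mgmt_methylated_prob = mgmt_methylated_prob,
    molecular_mixture = molecular_mixture,
    spatial_center = spatial_center,
    growth_params = growth_params
  ), class = "subtype_archetype")
}

#' Default archetypes: rim-enhancing, irregular and solid
#'
#' The three planted imaging subtypes with their characteristic contrasts:
#' the rim-enhancing archetype has the longest survival (median 19 months),
#' the highest core trace (low cellularity), the lowest rCBV, medium edema
#' and the most regular boundary; the irregular archetype (median 12 months)
#' has the largest, most irregular, fluid-rich edema; the solid archetype
#' (median 6 months) has the highest cellularity (lowest trace), the highest
#' rCBV, and a small, well-circumscribed edema. EGFRvIII prevalences are
#' 12.50%, 39.02% and 30.61% respectively; the molecular mixtures favour
#' proneural, neural/mesenchymal and classical tumors respectively.
#'
#' @return Named list of three `subtype_archetype` objects
#'   (`rim_enhancing`, `irregular`, `solid`).
#' @export
default_archetypes <- function() {
  base <- .base_intensity_means()
  mk <- function(name, ...) {
    subtype_archetype(name = name,
                      intensity_means = base + .archetype_offsets(name), ...)
  }
  list(
    rim_enhancing = mk(
      "rim_enhancing",
      intensity_sd = 0.06,  # homogeneous texture
      edema_scale = 1.4, irregularity = 0.5, core_radius = 6,
      survival_median = 19, egfrviii_prevalence = 0.125,
      idh1_mutant_prob = 0.06,
      molecular_mixture = c(classical = 0.15, mesenchymal = 0.15,
                            proneural = 0.55, neural = 0.15),
      spatial_center = "frontal",
      growth_params = list(dt = c(120, 15), dw = c(0.5, 0.10), foci = c(1.1, 0.4))
    ),
    irregular = mk(
      "irregular",
      intensity_sd = 0.12,  # heterogeneous signal
      edema_scale = 2.2, irregularity = 2.5, core_radius = 6,
      survival_median = 12, egfrviii_prevalence = 0.3902,
      idh1_mutant_prob = 0.02,
      molecular_mixture = c(classical = 0.10, mesenchymal = 0.40,
                            proneural = 0.10, neural = 0.40),
      spatial_center = "temporal",
      growth_params = list(dt = c(160, 20), dw = c(0.7, 0.12), foci = c(1.8, 0.6))
    ),
    solid = mk(
      "solid",
      intensity_sd = 0.08,
      edema_scale = 0.7, irregularity = 1.2, core_radius = 6,
      survival_median = 6, egfrviii_prevalence = 0.3061,
      idh1_mutant_prob = 0.005,
      molecular_mixture = c(classical = 0.55, mesenchymal = 0.15,
                            proneural = 0.15, neural = 0.15),
      spatial_center = "temporal",
      growth_params = list(dt = c(200, 25), dw = c(0.9, 0.15), foci = c(1.3, 0.5))
    )
  )
}

#' @export
print.subtype_archetype <- function(x, ...) {
  cat("Subtype archetype:", x$name, "\n")
  cat(sprintf("  median survival %.1f months, censoring fraction %.2f\n",
              x$survival_median, x$censoring_fraction))
  cat(sprintf("  edema scale %.2f, irregularity %.2f voxels, core radius %.1f\n",
              x$edema_scale, x$irregularity, x$core_radius))
  cat(sprintf("  EGFRvIII %.1f%%, IDH1-mutant %.1f%%, MGMT-methylated %.1f%%\n",
              100 * x$egfrviii_prevalence, 100 * x$idh1_mutant_prob,
              100 * x$mgmt_methylated_prob))
  cat("  molecular mixture:",
      paste(sprintf("%s %.0f%%", names(x$molecular_mixture),
                    100 * x$molecular_mixture), collapse = ", "), "\n")
  cat("  preferred location:", x$spatial_center, "\n")
  invisible(x)
}
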