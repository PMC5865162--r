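#' Cohort specification for the synthetic generator
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param archetype_proportions Probability vector over the three archetypes
#'   (must sum to 1); names, if given, must match the archetype list used at
#'   generation time.
#' @param volume_shape Integer vector of 3 voxel dimensions (each >= 16).
#' @param voxel_noise_sd Additional independent voxel noise (intensity
#'   units, >= 0) applied to every channel on top of the archetype's
#'   within-region spread.
#' @param random_seed Master integer seed; the whole cohort is a
#'   deterministic function of (spec, archetypes).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        archetype_proportions = c(rim_enhancing = 1, irregular = 1, solid = 1) / 3,
                        volume_shape = c(48L, 48L, 48L),
                        voxel_noise_sd = 0.02,
                        random_seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  volume_shape <- as.integer(volume_shape)
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (length(volume_shape) != 3 || any(volume_shape < 16))
    stop("volume_shape must have 3 components, each >= 16")
  if (abs(sum(archetype_proportions) - 1) > 1e-9)
    stop("archetype_proportions must sum to 1")
  if (any(archetype_proportions < 0)) stop("archetype_proportions must be >= 0")
  if (voxel_noise_sd < 0) stop("voxel_noise_sd must be >= 0")
  structure(list(n_subjects = n_subjects,
                 archetype_proportions = archetype_proportions,
                 volume_shape = volume_shape,
                 voxel_noise_sd = voxel_noise_sd,
                 random_seed = as.integer(random_seed)),
            class = "cohort_spec")
}

# Evaluate RNG-consuming code under a local seed, restoring the caller's
# RNG state afterwards.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Smooth random field: standard-normal draws on a coarse grid, trilinearly
# upsampled to the full volume. Gives low-frequency boundary perturbations.
.smooth_noise <- function(shape, n_coarse = 5L) {
  g <- array(stats::rnorm(n_coarse^3), dim = rep(n_coarse, 3))
  interp_axis <- function(arr, d_out, axis) {
    m <- dim(arr)[axis]
    pos <- seq(1, m, length.out = d_out)
    i0 <- pmin(floor(pos), m - 1L); fr <- pos - i0
    W <- matrix(0, d_out, m)
    W[cbind(seq_len(d_out), i0)] <- 1 - fr
    W[cbind(seq_len(d_out), i0 + 1L)] <- fr
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    dm <- dim(a)
    out <- W %*% matrix(a, nrow = dm[1])
    out <- array(out, dim = c(d_out, dm[2], dm[3]))
    aperm(out, order(perm))
  }
  f <- interp_axis(g, shape[1], 1L)
  f <- interp_axis(f, shape[2], 2L)
  interp_axis(f, shape[3], 3L)
}

# Expected censored fraction for exponential event times (rate lambda) under
# administrative censoring C ~ U(0, u) is (1 - exp(-lambda u)) / (lambda u);
# invert it so the window width hits a target fraction.
.censor_window <- function(median_months, censoring_fraction) {
  if (censoring_fraction <= 0) return(Inf)
  if (censoring_fraction >= 1) return(0)
  lambda <- log(2) / median_months
  f <- function(x) (1 - exp(-x)) / x - censoring_fraction
  x <- stats::uniroot(f, c(1e-8, 500), tol = 1e-10)$root
  x / lambda
}

#' Draw censored exponential survival times
#'
#' Event times are exponential with the given median (rate log(2)/median);
#' censoring is independent administrative censoring, uniform on a window
#' calibrated so the expected censored fraction equals
#' `censoring_fraction`. An optional age covariate acts multiplicatively on
#' the hazard (`age_log_hr` per decade, centered at 58 years).
#'
#' @param n Number of subjects.
#' @param median_months Median event time in months.
#' @param censoring_fraction Expected fraction censored, in [0, 1).
#' @param age Optional vector of ages (years), length n.
#' @param age_log_hr Log hazard ratio per decade of age.
#' @return data.frame with columns `time` (months) and `event`
#'   (1 = death observed, 0 = censored).
#' @export
draw_survival <- function(n, median_months, censoring_fraction = 0,
                          age = NULL, age_log_hr = 0) {
  lambda <- rep(log(2) / median_months, n)
  if (!is.null(age)) lambda <- lambda * exp(age_log_hr * (age - 58) / 10)
  t_event <- stats::rexp(n, rate = lambda)
  u <- .censor_window(median_months, censoring_fraction)
  if (is.finite(u)) {
    c_time <- stats::runif(n, 0, u)
    data.frame(time = pmin(t_event, c_time),
               event = as.integer(t_event <= c_time))
  } else {
    data.frame(time = t_event, event = rep(1L, n))
  }
}

# Eligible tumor-center voxels: deep enough inside the brain and far enough
# from the volume faces that the whole edema envelope fits. Errors (naming
# the first offending dimension) when the volume cannot host the tumor.
.eligible_centers <- function(atlas, margin, region_code = NULL) {
  shape <- dim(atlas)
  for (d in 1:3) {
    if (shape[d] < 2 * margin + 2)
      stop(sprintf(paste0("tumor (radius + irregularity margin = %d voxels) ",
                          "exceeds volume bounds along dimension %d ",
                          "(extent %d)"), margin, d, shape[d]))
  }
  ctr <- (shape + 1) / 2
  semi <- 0.42 * shape
  idx <- which(atlas > 0L)
  co <- arrayInd(idx, shape)
  rho2 <- ((co[, 1] - ctr[1]) / semi[1])^2 + ((co[, 2] - ctr[2]) / semi[2])^2 +
    ((co[, 3] - ctr[3]) / semi[3])^2
  ok <- rho2 <= 0.55^2 &
    co[, 1] > margin & co[, 1] <= shape[1] - margin &
    co[, 2] > margin & co[, 2] <= shape[2] - margin &
    co[, 3] > margin & co[, 3] <= shape[3] - margin
  if (!is.null(region_code)) ok <- ok & atlas[idx] == region_code
  idx[ok]
}

#' Generate one synthetic imaging study
#'
#' Builds a single subject from an archetype: an ellipsoidal tumor core split
#' into an enhancing shell (TU) and non-enhancing interior (NC), surrounded
#' by an edema envelope (ED) whose volume is `edema_scale` times the core;
#' the boundary is perturbed by a smooth random field with amplitude
#' `irregularity` voxels. Channel volumes are Gaussian draws from the
#' archetype's per-(region, channel) parameters plus a per-subject random
#' effect on region means and independent voxel noise. The clinical record
#' (age, censored survival, mutation and molecular labels, growth features)
#' is drawn from the archetype's distributions.
#'
#' The study is a deterministic function of (archetype, spec, subject_seed).
#'
#' @param archetype A `subtype_archetype`.
#' @param spec A `cohort_spec`.
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Subject identifier string.
#' @param atlas Optional precomputed atlas (from [synthetic_atlas()] at
#'   `spec$volume_shape`); recomputed when NULL.
#' @param channels If FALSE, skip the 11 channel volumes (segmentation and
#'   clinical record only) — useful for large survival-only cohorts.
#' @return An object of class `imaging_study`: list with `subject_id`,
#'   `channels` (named list of 3D arrays or NULL), `segmentation` (integer
#'   3D array, labels per [subregion_labels()]), `clinical` (one-row
#'   data.frame) and `truth_archetype`.
#' @export
generate_subject <- function(archetype, spec, subject_seed,
                             subject_id = sprintf("S%06d", subject_seed %% 1000000L),
                             atlas = NULL, channels = TRUE) {
  stopifnot(inherits(archetype, "subtype_archetype"), inherits(spec, "cohort_spec"))
  if (is.null(atlas)) atlas <- synthetic_atlas(spec$volume_shape)
  # rare degenerate geometries (a subregion emptied by the boundary
  # perturbation) are retried deterministically with derived seeds
  for (attempt in 0:7) {
    out <- tryCatch(
      .generate_subject_once(archetype, spec,
                             subject_seed + attempt * 1000003L,
                             subject_id, atlas, channels),
      gliotype_degenerate = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("degenerate tumor geometry persisted across retries; ",
       "increase volume_shape or core_radius")
}

.generate_subject_once <- function(archetype, spec, subject_seed,
                                   subject_id, atlas, channels) {
  .with_seed(subject_seed, {
    shape <- spec$volume_shape
    r <- min(max(3, stats::rnorm(1, archetype$core_radius, 0.35)),
             archetype$core_radius + 1.5)
    ax <- r * stats::runif(3, 0.9, 1.15)
    ax_out <- ax * (1 + archetype$edema_scale)^(1 / 3)
    margin <- as.integer(ceiling(max(ax_out) + archetype$irregularity + 1))

    # Preferred atlas region with supratentorial spillover: glioblastoma is
    # a supratentorial tumor, so the fallback placement excludes the
    # cerebellum and brain stem.
    supratentorial <- c("frontal", "temporal", "parietal", "basal_ganglia",
                        "insula", "occipital")
    elig <- .eligible_centers(atlas, margin,
                              region_code = match(archetype$spatial_center,
                                                  atlas_region_names()))
    use_pref <- stats::runif(1) < 0.85 && length(elig) > 0
    if (!use_pref) {
      alt <- sample(supratentorial, 1)
      elig <- .eligible_centers(atlas, margin,
                                region_code = match(alt, atlas_region_names()))
      if (length(elig) == 0) elig <- .eligible_centers(atlas, margin)
    }
    if (length(elig) == 0)
      stop(sprintf(paste0("no eligible tumor center: margin %d voxels does ",
                          "not fit inside the brain along dimension %d"),
                   margin, which.min(shape)))
    ctr <- as.numeric(arrayInd(elig[sample.int(length(elig), 1)], shape))

    dx <- (seq_len(shape[1]) - ctr[1])
    dy <- (seq_len(shape[2]) - ctr[2])
    dz <- (seq_len(shape[3]) - ctr[3])
    X <- array(dx, dim = shape)
    Y <- array(rep(dy, each = shape[1]), dim = shape)
    Z <- array(rep(dz, each = shape[1] * shape[2]), dim = shape)
    rho_core <- sqrt((X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2)
    rho_out <- sqrt((X / ax_out[1])^2 + (Y / ax_out[2])^2 + (Z / ax_out[3])^2)

    if (archetype$irregularity > 0) {
      pert <- archetype$irregularity * .smooth_noise(shape)
    } else {
      pert <- 0
    }
    brain <- atlas > 0L
    core <- (rho_core <= 1 + pert / mean(ax)) & brain
    envelope <- (rho_out <= 1 + pert / mean(ax_out)) & brain
    shell_t <- 1.8
    tu <- core & (rho_core >= 1 - shell_t / mean(ax) + pert / mean(ax))
    nc <- core & !tu
    ed <- envelope & !core

    labs <- subregion_labels()
    seg <- array(0L, dim = shape)
    seg[nc] <- labs[["NC"]]; seg[ed] <- labs[["ED"]]; seg[tu] <- labs[["TU"]]
    if (!all(c(sum(tu), sum(nc), sum(ed)) > 0))
      stop(structure(class = c("gliotype_degenerate", "error", "condition"),
                     list(message = "degenerate tumor geometry: a subregion is empty",
                          call = NULL)))

    age <- round(min(85, max(25, stats::rnorm(1, 58, 10))))
    surv <- draw_survival(1, archetype$survival_median,
                          archetype$censoring_fraction,
                          age = age, age_log_hr = archetype$age_log_hr)
    gp <- archetype$growth_params
    clinical <- data.frame(
      subject_id = subject_id,
      age = age,
      survival_months = surv$time,
      event = surv$event,
      egfrviii = ifelse(stats::runif(1) < archetype$egfrviii_prevalence,
                        "present", "absent"),
      idh1 = ifelse(stats::runif(1) < archetype$idh1_mutant_prob,
                    "mutant", "wildtype"),
      mgmt = ifelse(stats::runif(1) < archetype$mgmt_methylated_prob,
                    "methylated", "unmethylated"),
      molecular_subtype = sample(names(archetype$molecular_mixture), 1,
                                 prob = archetype$molecular_mixture),
      truth_archetype = archetype$name,
      growth_dt = stats::rnorm(1, gp$dt[1], gp$dt[2]),
      growth_dw = stats::rnorm(1, gp$dw[1], gp$dw[2]),
      growth_foci = max(1, round(stats::rnorm(1, gp$foci[1], gp$foci[2]))),
      stringsAsFactors = FALSE
    )
    vols <- NULL
    if (channels) {
      mu <- archetype$intensity_means +
        matrix(stats::rnorm(44, 0, archetype$subject_sd), 4, 11)
      dimnames(mu) <- dimnames(archetype$intensity_means)
      nb <- sum(brain); ntu <- sum(tu); nnc <- sum(nc); ned <- sum(ed)
      vols <- lapply(mpmri_channels(), function(ch) {
        v <- array(0, dim = shape)
        v[brain] <- stats::rnorm(nb, mu["brain", ch], archetype$intensity_sd)
        v[tu] <- stats::rnorm(ntu, mu["TU", ch], archetype$intensity_sd)
        v[nc] <- stats::rnorm(nnc, mu["NC", ch], archetype$intensity_sd)
        v[ed] <- stats::rnorm(ned, mu["ED", ch], archetype$intensity_sd)
        if (spec$voxel_noise_sd > 0)
          v[brain] <- v[brain] + stats::rnorm(nb, 0, spec$voxel_noise_sd)
        v
      })
      names(vols) <- mpmri_channels()
    }

    structure(list(subject_id = subject_id, channels = vols,
                   segmentation = seg, clinical = clinical,
                   truth_archetype = archetype$name),
              class = "imaging_study")
  })
}

#' Generate a synthetic cohort
#'
#' Assigns each subject to an archetype (multinomial with
#' `spec$archetype_proportions`), derives one seed per subject from the
#' master seed, and generates all studies plus a cohort clinical table.
#' Optionally a fraction of the molecular labels is masked to "unknown",
#' emulating incomplete mutation panels.
#'
#' @param spec A `cohort_spec`.
#' @param archetypes Named list of `subtype_archetype` (default
#'   [default_archetypes()]); `spec$archetype_proportions` must align with
#'   its order (or names).
#' @param channels Generate the 11 channel volumes (FALSE for a lightweight
#'   segmentation + clinical cohort).
#' @param missing_rates Named numeric: probability each of egfrviii / idh1 /
#'   mgmt is masked to "unknown".
#' @return Object of class `synthetic_cohort`: list with `studies` (list of
#'   `imaging_study`), `clinical` (data.frame, CSV-ready), `atlas`, `spec`.
#' @export
generate_cohort <- function(spec, archetypes = default_archetypes(),
                            channels = TRUE,
                            missing_rates = c(egfrviii = 0.1, idh1 = 0.1, mgmt = 0.1)) {
  stopifnot(inherits(spec, "cohort_spec"))
  props <- spec$archetype_proportions
  if (!is.null(names(props)) && !is.null(names(archetypes))) {
    if (!all(names(props) %in% names(archetypes)))
      stop("archetype_proportions names do not match the archetype list")
    archetypes <- archetypes[names(props)]
  }
  n <- spec$n_subjects
  atlas <- synthetic_atlas(spec$volume_shape)
  plan <- .with_seed(spec$random_seed, {
    list(assign = sample(names(archetypes), n, replace = TRUE, prob = props),
         seeds = sample.int(.Machine$integer.max - 1L, n),
         mask = matrix(stats::runif(3 * n), n, 3,
                       dimnames = list(NULL, c("egfrviii", "idh1", "mgmt"))))
  })
  ids <- sprintf("S%03d", seq_len(n))
  studies <- vector("list", n)
  for (i in seq_len(n)) {
    studies[[i]] <- generate_subject(archetypes[[plan$assign[i]]], spec,
                                     subject_seed = plan$seeds[i],
                                     subject_id = ids[i], atlas = atlas,
                                     channels = channels)
  }
  names(studies) <- ids
  clinical <- do.call(rbind, lapply(studies, function(s) s$clinical))
  rownames(clinical) <- NULL
  for (lab in c("egfrviii", "idh1", "mgmt")) {
    rate <- missing_rates[[lab]]
    if (!is.null(rate) && rate > 0)
      clinical[[lab]][plan$mask[, lab] < rate] <- "unknown"
  }
  structure(list(studies = studies, clinical = clinical, atlas = atlas,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic mpMRI cohort: %d subjects, volume %s, seed %d\n",
              x$spec$n_subjects, paste(x$spec$volume_shape, collapse = "x"),
              x$spec$random_seed))
  print(table(x$clinical$truth_archetype))
  invisible(x)
}

#' @export
print.imaging_study <- function(x, ...) {
  cat("Imaging study", x$subject_id, "\n")
  cat("  channels:", if (is.null(x$channels)) "none (clinical-only)"
      else paste(names(x$channels), collapse = " "), "\n")
  labs <- subregion_labels()
  cnt <- vapply(labs, function(l) sum(x$segmentation == l), integer(1))
  cat("  subregion voxels:",
      paste(sprintf("%s=%d", names(labs), cnt), collapse = " "), "\n")
  if (!is.null(x$truth_archetype)) cat("  truth archetype:", x$truth_archetype, "\n")
  invisible(x)
}
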