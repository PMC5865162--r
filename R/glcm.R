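#' Texture (GLCM) configuration
#'
#' Gray-level co-occurrence texture settings: intensities are quantized to
#' `gray_levels` equal-width levels over the region's own intensity range;
#' co-occurrences are collected for the 26 principal 3D directions (the
#' nonzero sign vectors in \{-1, 0, 1\}^3) at each distance in `distances`
#' (distances 1 and 2 voxels realize a 2-voxel co-occurrence radius), over
#' voxel pairs lying both inside the region. Matrices are symmetric; the six
#' measures are averaged over all (direction, distance) matrices.
#'
#' @param gray_levels Number of quantization levels (>= 2, default 32).
#' @param distances Integer offsets multiplying each direction (default 1:2).
#' @return Object of class `texture_config`.
#' @export
texture_config <- function(gray_levels = 32L, distances = 1:2) {
  stopifnot(gray_levels >= 2, all(distances >= 1))
  dirs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
  structure(list(gray_levels = as.integer(gray_levels),
                 distances = as.integer(distances),
                 directions = dirs,
                 measures = c("energy", "contrast", "entropy", "correlation",
                              "dissimilarity", "homogeneity")),
            class = "texture_config")
}

# Quantize in-mask intensities to levels 0..G-1 over the region's [min, max];
# constant regions map to level 0. Out-of-mask voxels are NA.
.quantize_region <- function(volume, mask, gray_levels) {
  q <- array(NA_real_, dim = dim(volume))
  v <- volume[mask]
  rng <- range(v)
  if (rng[2] > rng[1]) {
    q[mask] <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * gray_levels),
                    gray_levels - 1)
  } else {
    q[mask] <- 0
  }
  q
}

# Symmetric co-occurrence counts (length G^2, row-major by first level) for
# one offset, over pairs with both ends in the mask. NULL when no pair.
.glcm_counts <- function(q, offset, gray_levels) {
  d <- dim(q)
  lo <- pmax(1 - offset, 1); hi <- pmin(d - offset, d)
  if (any(lo > hi)) return(NULL)
  i1 <- lo[1]:hi[1]; j1 <- lo[2]:hi[2]; k1 <- lo[3]:hi[3]
  a <- q[i1, j1, k1, drop = FALSE]
  b <- q[i1 + offset[1], j1 + offset[2], k1 + offset[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  a <- a[ok]; b <- b[ok]
  cnt <- tabulate(a * gray_levels + b + 1, nbins = gray_levels^2) +
    tabulate(b * gray_levels + a + 1, nbins = gray_levels^2)
  cnt
}

# The six texture measures of one normalized symmetric GLCM (vector p of
# length G^2). Correlation is NA for zero marginal variance.
.glcm_measures <- function(p, gray_levels) {
  G <- gray_levels
  I <- rep(0:(G - 1), times = G)  # first index varies fastest in .glcm_counts
  J <- rep(0:(G - 1), each = G)
  nz <- p > 0
  pn <- p[nz]; In <- I[nz]; Jn <- J[nz]
  mu_i <- sum(pn * In); mu_j <- sum(pn * Jn)
  var_i <- sum(pn * (In - mu_i)^2); var_j <- sum(pn * (Jn - mu_j)^2)
  c(energy = sum(pn^2),
    contrast = sum(pn * (In - Jn)^2),
    entropy = -sum(pn * log(pn)),
    correlation = if (var_i > 0 && var_j > 0)
      sum(pn * (In - mu_i) * (Jn - mu_j)) / sqrt(var_i * var_j)
    else NA_real_,
    dissimilarity = sum(pn * abs(In - Jn)),
    homogeneity = sum(pn / (1 + (In - Jn)^2)))
}

#' GLCM texture measures of a region
#'
#' Quantizes the in-region intensities, builds one symmetric co-occurrence
#' matrix per (direction, distance), computes energy, contrast, entropy,
#' correlation, dissimilarity and homogeneity on each normalized matrix, and
#' returns their average over all matrices with at least one co-occurring
#' pair. Since opposite directions yield identical symmetric matrices, each
#' direction pair is evaluated once.
#'
#' A constant region collapses to a single-cell GLCM: energy = homogeneity
#' = 1, contrast = entropy = dissimilarity = 0 and correlation NA (zero
#' variance).
#'
#' @param channel_volume Numeric 3D array.
#' @param region_mask Logical 3D array with >= 2 voxels.
#' @param config A [texture_config()].
#' @return Named numeric of the 6 measures.
#' @export
compute_glcm_measures <- function(channel_volume, region_mask,
                                  config = texture_config()) {
  if (sum(region_mask) < 2) stop("region must have >= 2 voxels")
  G <- config$gray_levels
  q <- .quantize_region(channel_volume, region_mask, G)
  # one representative per +/- direction pair: matrices are identical
  dirs <- config$directions
  keep <- apply(dirs, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  dirs <- dirs[keep, , drop = FALSE]
  rows <- list()
  for (dist in config$distances) {
    for (r in seq_len(nrow(dirs))) {
      cnt <- .glcm_counts(q, dirs[r, ] * dist, G)
      if (is.null(cnt)) next
      rows[[length(rows) + 1L]] <- .glcm_measures(cnt / sum(cnt), G)
    }
  }
  if (length(rows) == 0L) stop("no co-occurring voxel pairs in region")
  M <- do.call(rbind, rows)
  out <- colMeans(M, na.rm = TRUE)
  if (all(is.na(M[, "correlation"]))) out["correlation"] <- NA_real_
  out
}
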