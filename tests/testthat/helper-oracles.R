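# Independent brute-force oracles used to validate the package's
# implementations on small inputs.

# Adjusted Rand index by exhaustive item-pair counting.
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}

# All set partitions of n items as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in 1:(mx + 1)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# GLCM measures by explicit per-pair enumeration over all 26 directions and
# all distances, averaging the per-matrix measures.
oracle_glcm <- function(volume, mask, gray_levels = 32L, distances = 1:2) {
  d <- dim(volume)
  v <- volume[mask]
  rng <- range(v)
  q <- array(NA_real_, dim = d)
  q[mask] <- if (rng[2] > rng[1])
    pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * gray_levels), gray_levels - 1)
  else 0
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
  per_matrix <- list()
  for (dist in distances) for (r in seq_len(nrow(dirs))) {
    off <- dirs[r, ] * dist
    M <- matrix(0, gray_levels, gray_levels)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (is.na(q[i, j, k])) next
      i2 <- i + off[1]; j2 <- j + off[2]; k2 <- k + off[3]
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3])
        next
      if (is.na(q[i2, j2, k2])) next
      M[q[i, j, k] + 1, q[i2, j2, k2] + 1] <-
        M[q[i, j, k] + 1, q[i2, j2, k2] + 1] + 1
    }
    M <- M + t(M)
    if (sum(M) == 0) next
    p <- M / sum(M)
    I <- row(p) - 1; J <- col(p) - 1
    nz <- p > 0
    mu_i <- sum(p * I); mu_j <- sum(p * J)
    var_i <- sum(p * (I - mu_i)^2); var_j <- sum(p * (J - mu_j)^2)
    per_matrix[[length(per_matrix) + 1L]] <- c(
      energy = sum(p[nz]^2),
      contrast = sum(p * (I - J)^2),
      entropy = -sum(p[nz] * log(p[nz])),
      correlation = if (var_i > 0 && var_j > 0)
        sum(p * (I - mu_i) * (J - mu_j)) / sqrt(var_i * var_j) else NA_real_,
      dissimilarity = sum(p * abs(I - J)),
      homogeneity = sum(p / (1 + (I - J)^2)))
  }
  M <- do.call(rbind, per_matrix)
  out <- colMeans(M, na.rm = TRUE)
  if (all(is.na(M[, "correlation"]))) out["correlation"] <- NA_real_
  out
}

# Per-region voxel tally of a core mask against an atlas, as percentages.
oracle_region_tally <- function(core, atlas, n_regions = 9L) {
  counts <- numeric(n_regions)
  idx <- which(core)
  for (v in idx) {
    lab <- atlas[v]
    if (lab >= 1 && lab <= n_regions) counts[lab] <- counts[lab] + 1
  }
  100 * counts / length(idx)
}
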