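test_that("feature scaling maps the discovery range to [0, 1] unclipped", {
  X <- cbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 1, 3))
  sc <- fit_scaling(X)
  S <- apply_scaling(sc, X)
  expect_equal(unname(S[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(S[, "b"]), c(0, 0, 0))
  expect_true(sc$constant[["b"]])
  # replication values beyond the discovery range are not clipped
  S2 <- apply_scaling(sc, cbind(a = 8, b = 5, c = 1))
  expect_equal(unname(S2[1, "a"]), 1.5)
  expect_error(apply_scaling(sc, cbind(a = 1, b = 2)), "missing: c")
  # idempotence property on random tables
  set.seed(10)
  for (i in 1:5) {
    R <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, letters[1:6]))
    SS <- apply_scaling(fit_scaling(R), R)
    expect_true(all(SS >= 0 & SS <= 1))
  }
})

test_that("adjusted Rand index matches its defining examples", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  set.seed(11)
  lab <- sample(1:3, 20, replace = TRUE)
  expect_equal(adjusted_rand_index(lab, lab), 1)
  expect_equal(adjusted_rand_index(lab, c("x", "y", "z")[lab]), 1)
  expect_error(adjusted_rand_index(1:4, 1:5), "length")
})

test_that("ARI equals the pair-counting oracle on exhaustive partitions", {
  parts <- all_partitions(5)  # all 52 set partitions of 5 items
  for (i in seq_along(parts)) for (j in i:length(parts)) {
    expect_equal(adjusted_rand_index(parts[[i]], parts[[j]]),
                 oracle_ari(parts[[i]], parts[[j]]),
                 tolerance = 1e-12)
  }
  # sampled label vectors of length 6 and 7
  set.seed(12)
  for (n in 6:7) for (r in 1:150) {
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b),
                 tolerance = 1e-12)
  }
})

test_that("ARI agrees with an independent library implementation", {
  skip_if_not_installed("mclust")
  set.seed(23)
  for (r in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("the K-means ensemble is deterministic and recovers planted triplets", {
  pg <- planted_gaussians(n_per = 10, p = 4, sep = 30, seed = 13)
  rs <- run_kmeans_ensemble(pg$X, K = 3, n_runs = 30, seed = 7)
  expect_equal(ncol(rs$labels), 30)
  # restarts whose initial centers cover all three clusters converge to the
  # planted partition; the representative assignment always recovers it
  ari_truth <- apply(rs$labels, 2, adjusted_rand_index, pg$labels)
  expect_gte(mean(ari_truth == 1), 0.4)
  rep_lab <- suppressWarnings(representative_assignment(rs))
  expect_equal(adjusted_rand_index(rep_lab, pg$labels), 1)
  # every run keeps exactly K nonempty clusters
  expect_true(all(apply(rs$labels, 2, function(l) length(unique(l))) == 3))
  rs2 <- run_kmeans_ensemble(pg$X, K = 3, n_runs = 30, seed = 7)
  expect_identical(rs$labels, rs2$labels)
  expect_identical(rs$silhouette, rs2$silhouette)
  rs1 <- run_kmeans_ensemble(pg$X, K = 3, n_runs = 1, seed = 7)
  expect_equal(ncol(rs1$labels), 1)
  expect_error(run_kmeans_ensemble(pg$X[1:5, ], K = 10, n_runs = 1, seed = 1),
               "exceeds")
})

test_that("K selection is stability-driven", {
  pg <- planted_gaussians(n_per = 20, p = 6, sep = 10, seed = 14)
  ks <- select_k(pg$X, k_range = 2:6, n_runs = 40, seed = 5)
  expect_equal(ks$report$K, 2:6)
  expect_true(all(ks$report$average_ari >= -1 & ks$report$average_ari <= 1))
  # the chosen K attains the maximum (smallest K on ties)
  expect_equal(ks$chosen_k,
               ks$report$K[which.max(ks$report$average_ari)])
  # a single Gaussian blob has no stable split: its K = 2 stability sits far
  # below the planted three-cluster stability
  set.seed(15)
  blob <- matrix(rnorm(60 * 6), 60, 6)
  ks2 <- select_k(blob, k_range = 2:2, n_runs = 40, seed = 5)
  expect_lt(ks2$report$average_ari[1],
            ks$report$average_ari[ks$report$K == 3] - 0.2)
})

test_that("the representative assignment prefers separability within frequent classes", {
  # all runs identical up to relabeling -> that partition
  labs <- cbind(c(1, 1, 2, 2), c(2, 2, 1, 1), c(1, 1, 2, 2))
  rs <- structure(list(K = 2L, labels = labs, silhouette = c(0.8, 0.8, 0.8),
                       seed = 1L, n_retries = 0L),
                  class = "cluster_run_set")
  rep1 <- representative_assignment(rs)
  expect_equal(adjusted_rand_index(rep1, c(1, 1, 2, 2)), 1)
  expect_equal(attr(rep1, "frequency"), 1)

  # two classes at 60% / 40%: the less frequent but better-separated wins
  p1 <- c(1, 1, 1, 2, 2, 2)
  p2 <- c(1, 1, 2, 2, 2, 2)
  labs2 <- cbind(p1, p1, p1, p2, p2)
  rs2 <- structure(list(K = 2L, labels = labs2,
                        silhouette = c(0.4, 0.4, 0.4, 0.9, 0.9),
                        seed = 1L, n_retries = 0L),
                   class = "cluster_run_set")
  rep2 <- representative_assignment(rs2)
  expect_equal(adjusted_rand_index(rep2, p2), 1)
  expect_equal(attr(rep2, "silhouette"), 0.9)

  # every class below the threshold -> most frequent, with a warning
  mk <- function(i) { x <- rep(1, 8); x[i] <- 2; x }
  labs3 <- cbind(mk(1), mk(2), mk(3), mk(4), mk(5), mk(6))  # all ~17%
  rs3 <- structure(list(K = 2L, labels = labs3, silhouette = rep(0.1, 6),
                        seed = 1L, n_retries = 0L),
                   class = "cluster_run_set")
  expect_warning(rep3 <- representative_assignment(rs3, 0.2), "falling back")
  expect_equal(adjusted_rand_index(rep3, mk(1)), 1)
})

test_that("mean silhouette behaves at its extremes", {
  X <- rbind(c(0, 0), c(0, 0.1), c(10, 10), c(10, 10.1))
  expect_gt(silhouette_mean(X, c(1, 1, 2, 2)), 0.9)
  # consistent relabeling leaves it unchanged
  expect_equal(silhouette_mean(X, c(1, 1, 2, 2)),
               silhouette_mean(X, c(2, 2, 1, 1)))
  # two halves of one distribution are barely separable
  set.seed(16)
  Y <- matrix(rnorm(400), 200, 2)
  expect_lt(abs(silhouette_mean(Y, rep(1:2, 100))), 0.1)
  expect_error(silhouette_mean(X, c(1, 1, 1, 1)), "2 clusters")
})

test_that("cross-validated reproducibility separates signal from noise", {
  pg <- planted_gaussians(n_per = 30, p = 6, sep = 10, seed = 17)
  S <- apply_scaling(fit_scaling(pg$X), pg$X)
  rep <- cv_reproducibility(S, K = 3, folds = 10, seed = 3, n_runs = 30)
  expect_equal(as.numeric(rep), 100)
  expect_error(cv_reproducibility(S, K = 3, folds = 1, seed = 3), "folds")
  # pure noise: held-out agreement falls toward chance (100/K = 33%)
  set.seed(18)
  noise <- matrix(rnorm(60 * 6), 60, 6)
  Sn <- apply_scaling(fit_scaling(noise), noise)
  repn <- suppressWarnings(cv_reproducibility(Sn, K = 3, folds = 5, seed = 3,
                                              n_runs = 30))
  expect_lt(as.numeric(repn), 75)
})

test_that("nearest-centroid assignment respects scaling and the tie rule", {
  pg <- planted_gaussians(n_per = 20, p = 6, sep = 10, seed = 19)
  colnames(pg$X) <- paste0("f", 1:6)
  model <- suppressWarnings(discover_subtypes(pg$X, fixed_k = 3, n_runs = 30,
                                              seed = 4))
  # a discovery centroid maps to its own cluster
  cen_raw <- model$centroids * (model$scaling$max - model$scaling$min)[
    col(model$centroids)] + model$scaling$min[col(model$centroids)]
  colnames(cen_raw) <- colnames(pg$X)
  own <- assign_new(model, cen_raw)
  expect_equal(as.integer(own), 1:3)
  # held-out subjects from the same archetypes
  pg2 <- planted_gaussians(n_per = 10, p = 6, sep = 10, seed = 20)
  colnames(pg2$X) <- paste0("f", 1:6)
  newlab <- assign_new(model, pg2$X)
  expect_gte(adjusted_rand_index(newlab, pg2$labels), 0.9)
  # equidistant point -> lowest cluster index
  tie_model <- structure(list(
    K = 2L,
    centroids = rbind(c(0, 1), c(1, 0)),
    scaling = structure(list(min = c(a = 0, b = 0), max = c(a = 1, b = 1),
                             constant = c(a = FALSE, b = FALSE),
                             features = c("a", "b")),
                        class = "scaling_model"),
    cluster_names = c("c1", "c2"), features = c("a", "b")),
    class = "subtype_model")
  expect_equal(as.integer(assign_new(tie_model, cbind(a = 0.5, b = 0.5))), 1L)
  expect_error(assign_new(tie_model, cbind(a = 1)), "missing")
})

test_that("feature association applies Kruskal-Wallis with Bonferroni", {
  # identical values in every group: H exactly 0
  x <- rep(c(3, 1, 4, 1, 5, 9, 2, 6), 3)
  g <- rep(1:3, each = 8)
  fa <- feature_association(cbind(f = x), g)
  expect_equal(fa$H, 0)
  expect_equal(fa$p_adjusted, 1)
  # planted separation survives correction over 278 features
  set.seed(21)
  n <- 50
  X <- matrix(rnorm(3 * n * 278), 3 * n, 278,
              dimnames = list(NULL, paste0("F", 1:278)))
  X[, 1] <- X[, 1] + rep(c(0, 5, 10), each = n)
  g3 <- rep(1:3, each = n)
  fa3 <- feature_association(X, g3)
  expect_true(fa3$significant[1])
  expect_true(all(fa3$p_adjusted <= 1))
  expect_equal(fa3$p_adjusted, pmin(1, fa3$p * 278))
  expect_error(feature_association(X, rep(1, 3 * n)), "2 groups")
})

test_that("subtype discovery is reproducible end to end", {
  pg <- planted_gaussians(n_per = 15, p = 5, sep = 10, seed = 22)
  m1 <- discover_subtypes(pg$X, k_range = 2:4, n_runs = 30, seed = 9)
  m2 <- discover_subtypes(pg$X, k_range = 2:4, n_runs = 30, seed = 9)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$centroids, m2$centroids)
  expect_equal(m1$K, 3)
})
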