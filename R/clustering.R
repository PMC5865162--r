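# Accept a feature_table, matrix or data.frame as the clustering input.
.as_feature_matrix <- function(x) {
  if (inherits(x, "feature_table")) return(x$X)
  if (is.data.frame(x)) return(as.matrix(x))
  if (is.matrix(x)) return(x)
  stop("expected a feature_table, matrix or data.frame")
}

#' Fit the [0, 1] feature scaling of a discovery table
#'
#' Records the per-feature minimum and maximum of the discovery cohort.
#' Constant features are flagged and scale to 0.
#'
#' @param table Feature table (a `feature_table`, matrix or data.frame).
#' @return Object of class `scaling_model` with `min`, `max`, `constant`.
#' @export
fit_scaling <- function(table) {
  X <- .as_feature_matrix(table)
  mn <- apply(X, 2, min); mx <- apply(X, 2, max)
  structure(list(min = mn, max = mx, constant = mx <= mn,
                 features = colnames(X)),
            class = "scaling_model")
}

#' Apply a fitted scaling to a table
#'
#' Discovery values map into [0, 1]; values of a new (replication) table may
#' fall outside [0, 1] and are deliberately not clipped, preserving the
#' geometry of the discovery feature space.
#'
#' @param model A `scaling_model` from [fit_scaling()].
#' @param table Feature table with the model's features (any order).
#' @return Numeric matrix of scaled values.
#' @export
apply_scaling <- function(model, table) {
  X <- .as_feature_matrix(table)
  if (!is.null(model$features)) {
    missing <- setdiff(model$features, colnames(X))
    if (length(missing) > 0)
      stop("unknown feature name(s) in new table; missing: ",
           paste(missing, collapse = ", "))
    X <- X[, model$features, drop = FALSE]
  }
  rng <- model$max - model$min
  rng[model$constant] <- 1
  out <- sweep(sweep(X, 2, model$min, "-"), 2, rng, "/")
  out[, model$constant] <- 0
  out
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement between two label vectors:
#' permutation-invariant, 1 iff the partitions are identical up to
#' relabeling, 0 in expectation for independent partitions.
#'
#' @param labels_a,labels_b Label vectors of equal length >= 2.
#' @return Numeric in [-1, 1].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 items")
  a <- match(labels_a, unique(labels_a))
  b <- match(labels_b, unique(labels_b))
  ka <- max(a); kb <- max(b)
  tab <- tabulate((a - 1L) * kb + b, nbins = ka * kb)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  ai <- tabulate(a, nbins = ka); bj <- tabulate(b, nbins = kb)
  sum_a <- sum(comb2(ai)); sum_b <- sum(comb2(bj))
  tot <- comb2(n)
  expected <- sum_a * sum_b / tot
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)  # both partitions trivial (all-one-cluster)
  (sum_ij - expected) / (mx - expected)
}

# Canonical key of a partition: labels renumbered by first appearance, so
# two runs get the same key iff their partitions are identical up to
# relabeling (equivalently, ARI = 1 for non-degenerate partitions).
.partition_key <- function(labels) {
  paste(match(labels, unique(labels)), collapse = ".")
}

#' Run a K-means ensemble
#'
#' Runs Lloyd K-means `n_runs` times, each initialized with K distinct
#' subjects chosen uniformly at random, recording the label vector and mean
#' silhouette of each run. Runs that converge to an empty cluster are
#' re-seeded (bounded retries). Deterministic given the master seed.
#'
#' @param scaled_table Numeric matrix (subjects x features), already scaled.
#' @param K Number of clusters (<= number of subjects).
#' @param n_runs Number of K-means restarts (default 1000).
#' @param seed Master integer seed.
#' @param iter_max Lloyd iteration cap per run.
#' @param dist_matrix Optional precomputed `dist` object for the silhouette.
#' @return Object of class `cluster_run_set`: `K`, `labels` (n x n_runs
#'   integer matrix), `silhouette` (per-run mean silhouette), `n_retries`.
#' @export
run_kmeans_ensemble <- function(scaled_table, K, n_runs = 1000L, seed = 1L,
                                iter_max = 300L, dist_matrix = NULL) {
  X <- .as_feature_matrix(scaled_table)
  n <- nrow(X)
  if (K > n) stop("K exceeds the number of subjects")
  if (is.null(dist_matrix)) dist_matrix <- stats::dist(X)
  labs <- matrix(NA_integer_, n, n_runs)
  sil <- numeric(n_runs)
  n_retries <- 0L
  .with_seed(seed, {
    for (r in seq_len(n_runs)) {
      for (attempt in 1:25) {
        centers <- X[sample.int(n, K), , drop = FALSE]
        km <- tryCatch(
          suppressWarnings(stats::kmeans(X, centers = centers,
                                         iter.max = iter_max,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(km) && length(unique(km$cluster)) == K) break
        km <- NULL
        n_retries <- n_retries + 1L
      }
      if (is.null(km))
        stop("K-means repeatedly produced empty clusters; K too large?")
      labs[, r] <- km$cluster
      sil[r] <- silhouette_mean(X, km$cluster, dist_matrix = dist_matrix)
    }
  })
  structure(list(K = as.integer(K), labels = labs, silhouette = sil,
                 seed = as.integer(seed), n_retries = n_retries),
            class = "cluster_run_set")
}

# Average ARI over all unordered run pairs. Identical partitions are grouped
# first, so only distinct-partition pairs need an ARI evaluation; an optional
# pair subsample bounds the cost for very diverse ensembles.
.average_pairwise_ari <- function(run_set, max_pairs = Inf) {
  labs <- run_set$labels
  nr <- ncol(labs)
  if (nr < 2) return(NA_real_)
  keys <- apply(labs, 2, .partition_key)
  grp <- match(keys, unique(keys))
  cnt <- tabulate(grp)
  reps <- labs[, match(seq_along(cnt), grp), drop = FALSE]
  g <- length(cnt)
  total_pairs <- nr * (nr - 1) / 2
  if (g * (g - 1) / 2 > max_pairs) {
    pick <- .with_seed(run_set$seed + 7L, {
      cbind(sample.int(nr, max_pairs, replace = TRUE),
            sample.int(nr, max_pairs, replace = TRUE))
    })
    pick <- pick[pick[, 1] != pick[, 2], , drop = FALSE]
    vals <- vapply(seq_len(nrow(pick)), function(i)
      adjusted_rand_index(labs[, pick[i, 1]], labs[, pick[i, 2]]), numeric(1))
    return(mean(vals))
  }
  s <- sum(cnt * (cnt - 1) / 2)  # identical-partition pairs: ARI = 1
  if (g > 1) {
    for (i in 1:(g - 1)) for (j in (i + 1):g) {
      s <- s + cnt[i] * cnt[j] * adjusted_rand_index(reps[, i], reps[, j])
    }
  }
  s / total_pairs
}

#' Select K by ensemble stability (average adjusted Rand index)
#'
#' For each K in the range, runs a K-means ensemble and computes the average
#' ARI over all unordered pairs of runs; the chosen K maximizes this
#' stability (ties broken toward the smaller K).
#'
#' @param scaled_table Scaled numeric matrix.
#' @param k_range Candidate K values (default 2:6).
#' @param n_runs Restarts per K (default 1000).
#' @param seed Master seed; each K uses a seed derived from it.
#' @param max_pairs Cap on distinct-partition pair evaluations per K.
#' @return Object of class `k_selection_report`: data.frame `report`
#'   (K, average ARI), `chosen_k`, and the per-K `run_sets`.
#' @export
select_k <- function(scaled_table, k_range = 2:6, n_runs = 1000L, seed = 1L,
                     max_pairs = Inf) {
  X <- .as_feature_matrix(scaled_table)
  dist_matrix <- stats::dist(X)
  run_sets <- list()
  avg <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    rs <- run_kmeans_ensemble(X, k_range[i], n_runs = n_runs,
                              seed = seed + i, dist_matrix = dist_matrix)
    run_sets[[i]] <- rs
    avg[i] <- .average_pairwise_ari(rs, max_pairs = max_pairs)
  }
  chosen <- k_range[which.max(avg)]  # which.max takes the first (smallest K)
  structure(list(report = data.frame(K = k_range, average_ari = avg),
                 chosen_k = chosen, run_sets = run_sets),
            class = "k_selection_report")
}

#' @export
print.k_selection_report <- function(x, ...) {
  cat("K selection by ensemble stability (average pairwise ARI):\n")
  print(x$report, row.names = FALSE)
  cat("chosen K =", x$chosen_k, "\n")
  invisible(x)
}

#' Mean silhouette of a clustering
#'
#' Standard silhouette with Euclidean distance, averaged over subjects;
#' singleton clusters contribute 0.
#'
#' @param scaled_table Numeric matrix.
#' @param labels Cluster labels (>= 2 distinct values).
#' @param dist_matrix Optional precomputed `dist` object.
#' @return Numeric in [-1, 1].
#' @export
silhouette_mean <- function(scaled_table, labels, dist_matrix = NULL) {
  if (length(unique(labels)) < 2)
    stop("silhouette requires at least 2 clusters")
  if (is.null(dist_matrix)) {
    X <- .as_feature_matrix(scaled_table)
    dist_matrix <- stats::dist(X)
  }
  sil <- cluster::silhouette(as.integer(factor(labels)), dist_matrix)
  mean(sil[, "sil_width"])
}

#' Representative assignment of a run ensemble
#'
#' Groups the runs into equivalence classes (identical partitions up to
#' relabeling, i.e. pairwise ARI = 1); among classes covering at least
#' `frequency_threshold` of the runs, returns the assignment with the
#' highest mean silhouette. If no class reaches the threshold, the most
#' frequent class is returned with a warning.
#'
#' @param run_set A `cluster_run_set`.
#' @param frequency_threshold Minimum class frequency (default 0.20).
#' @return Integer label vector; attributes `frequency` (class share of
#'   runs) and `silhouette` (its mean silhouette).
#' @export
representative_assignment <- function(run_set, frequency_threshold = 0.20) {
  labs <- run_set$labels
  nr <- ncol(labs)
  if (nr < 1) stop("empty run set")
  keys <- apply(labs, 2, .partition_key)
  grp <- match(keys, unique(keys))
  cnt <- tabulate(grp)
  # runs in one class share the partition, hence the silhouette
  class_sil <- vapply(seq_along(cnt),
                      function(g) run_set$silhouette[match(g, grp)], numeric(1))
  qual <- which(cnt >= frequency_threshold * nr)
  if (length(qual) > 0) {
    win <- qual[which.max(class_sil[qual])]
  } else {
    win <- which.max(cnt)
    warning(sprintf(paste0("no assignment class reached the %.0f%% frequency ",
                           "threshold; falling back to the most frequent ",
                           "class (%.1f%% of runs)"),
                    100 * frequency_threshold, 100 * cnt[win] / nr))
  }
  out <- labs[, match(win, grp)]
  attr(out, "frequency") <- cnt[win] / nr
  attr(out, "silhouette") <- class_sil[win]
  out
}

# Best K_train -> K_ref label mapping by maximum agreement (exhaustive over
# permutations; K <= 7 in practice).
.align_clusters <- function(train_labels, ref_labels, K) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  conf <- matrix(0L, K, K)
  for (i in seq_along(train_labels))
    conf[train_labels[i], ref_labels[i]] <- conf[train_labels[i], ref_labels[i]] + 1L
  best <- NULL; best_score <- -1L
  for (p in perms(seq_len(K))) {
    score <- sum(conf[cbind(seq_len(K), p)])
    if (score > best_score) { best_score <- score; best <- p }
  }
  best
}

#' Cross-validated reproducibility of the subtype assignment
#'
#' Ten-fold (by default) reproducibility: the reference labels come from the
#' full-data representative assignment; in each fold the remaining folds are
#' re-clustered, held-out subjects are assigned to the nearest training
#' centroid, training clusters are aligned to the reference clusters by
#' maximum-agreement matching, and held-out agreement is counted. Returns
#' the pooled percentage agreement.
#'
#' @param scaled_table Scaled numeric matrix.
#' @param K Number of clusters.
#' @param folds Number of folds (default 10; must be >= 2 and <= n).
#' @param seed Master seed (fold split and ensembles).
#' @param n_runs Restarts per training ensemble (default 100).
#' @param reference_labels Optional reference assignment; computed from a
#'   full-data ensemble (`n_runs` restarts) when NULL.
#' @return Percentage agreement in [0, 100], with attribute `per_fold`.
#' @export
cv_reproducibility <- function(scaled_table, K, folds = 10L, seed = 1L,
                               n_runs = 100L, reference_labels = NULL) {
  X <- .as_feature_matrix(scaled_table)
  n <- nrow(X)
  if (folds < 2) stop("folds must be >= 2")
  if (n < folds) stop("more folds than subjects")
  if (is.null(reference_labels)) {
    rs <- run_kmeans_ensemble(X, K, n_runs = n_runs, seed = seed)
    reference_labels <- suppressWarnings(representative_assignment(rs))
  }
  fold_id <- .with_seed(seed + 1L, sample(rep_len(seq_len(folds), n)))
  if (min(tabulate(fold_id, folds)) < K)
    stop("a fold has fewer than K subjects")
  agree <- 0L; per_fold <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    if (length(tr) < K) stop("a training split has fewer than K subjects")
    rs <- run_kmeans_ensemble(X[tr, , drop = FALSE], K, n_runs = n_runs,
                              seed = seed + 100L + f)
    tr_labels <- suppressWarnings(representative_assignment(rs))
    centroids <- rowsum(X[tr, , drop = FALSE], tr_labels) /
      as.vector(table(tr_labels))
    d2 <- outer(rowSums(X[te, , drop = FALSE]^2), rowSums(centroids^2), "+") -
      2 * X[te, , drop = FALSE] %*% t(centroids)
    te_train_lab <- max.col(-d2, ties.method = "first")
    map <- .align_clusters(tr_labels, reference_labels[tr], K)
    hit <- map[te_train_lab] == reference_labels[te]
    agree <- agree + sum(hit)
    per_fold[f] <- 100 * mean(hit)
  }
  structure(100 * agree / n, per_fold = per_fold)
}

#' Kruskal-Wallis association of each feature with the subtype labels
#'
#' Per feature: Kruskal-Wallis H (with tie correction), raw p, Bonferroni
#' adjusted p (min(1, p * n_features)), and a significance flag at adjusted
#' p < 0.05.
#'
#' @param table Feature table (matrix-like).
#' @param labels Group labels (>= 2 nonempty groups).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return data.frame with columns feature, H, p, p_adjusted, significant.
#' @export
feature_association <- function(table, labels, alpha = 0.05) {
  X <- .as_feature_matrix(table)
  g <- factor(labels)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) == 0)) stop("a group is empty")
  res <- t(apply(X, 2, function(col) {
    if (length(unique(col)) == 1) return(c(H = 0, p = 1))
    kt <- stats::kruskal.test(col, g)
    c(H = unname(kt$statistic), p = kt$p.value)
  }))
  p_adj <- stats::p.adjust(res[, "p"], method = "bonferroni")
  data.frame(feature = colnames(X), H = res[, "H"], p = res[, "p"],
             p_adjusted = p_adj, significant = p_adj < alpha,
             row.names = NULL)
}
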