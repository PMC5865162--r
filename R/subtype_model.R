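#' Discover imaging subtypes by stability-selected K-means
#'
#' The central fitting function: scales the discovery feature table to
#' [0, 1], selects K by the stability (average pairwise adjusted Rand index)
#' of repeated K-means ensembles, picks the representative assignment (the
#' most separable partition among those recurring in at least 20% of runs),
#' computes cluster centroids in scaled space and — when the catalog allows —
#' names the clusters by their centroid signature (edema size and rCBV
#' contrasts: largest edema = irregular; of the rest, higher rCBV = solid,
#' lower = rim-enhancing).
#'
#' @param table Discovery feature table (`feature_table`, matrix or
#'   data.frame); must be complete (no missing values).
#' @param k_range Candidate numbers of clusters (default 2:6).
#' @param n_runs K-means restarts per K (default 1000).
#' @param seed Master integer seed; the whole fit is deterministic given it.
#' @param frequency_threshold Minimum frequency of the representative
#'   assignment class (default 0.20).
#' @param fixed_k Optional: skip K selection and use this K.
#' @param max_pairs Cap on pairwise-ARI evaluations per K (see [select_k()]).
#' @return Object of class `subtype_model`: `K`, `centroids` (K x p, scaled
#'   space), `scaling` (the [fit_scaling()] model), `labels` (discovery
#'   assignment, named by cluster display name), `cluster_names`,
#'   `k_report`, `silhouette`, `frequency`, `seed`.
#' @seealso [predict.subtype_model()], [select_k()],
#'   [representative_assignment()]
#' @export
discover_subtypes <- function(table, k_range = 2:6, n_runs = 1000L, seed = 1L,
                              frequency_threshold = 0.20, fixed_k = NULL,
                              max_pairs = Inf) {
  X <- .as_feature_matrix(table)
  if (anyNA(X)) stop("discovery table contains missing values; impute first")
  scaling <- fit_scaling(X)
  S <- apply_scaling(scaling, X)
  if (is.null(fixed_k)) {
    ksel <- select_k(S, k_range = k_range, n_runs = n_runs, seed = seed,
                     max_pairs = max_pairs)
    K <- ksel$chosen_k
    run_set <- ksel$run_sets[[match(K, k_range)]]
  } else {
    K <- as.integer(fixed_k)
    ksel <- NULL
    run_set <- run_kmeans_ensemble(S, K, n_runs = n_runs, seed = seed + 1L)
  }
  rep_lab <- representative_assignment(run_set,
                                       frequency_threshold = frequency_threshold)
  centroids <- rowsum(S, as.integer(rep_lab)) / as.vector(table(rep_lab))
  nm <- .name_clusters(centroids, colnames(X), K)
  rownames(centroids) <- nm
  labels <- stats::setNames(as.integer(rep_lab), rownames(X))
  structure(list(K = K, centroids = centroids, scaling = scaling,
                 labels = labels, cluster_names = nm,
                 k_report = if (is.null(ksel)) NULL else ksel$report,
                 silhouette = attr(rep_lab, "silhouette"),
                 frequency = attr(rep_lab, "frequency"),
                 features = colnames(X), seed = as.integer(seed)),
            class = "subtype_model")
}

# Display names from centroid signatures (cosmetic): requires K = 3 and the
# edema-ratio and tumor rCBV features; otherwise generic names.
.name_clusters <- function(centroids, features, K) {
  if (K == 3 && all(c("ED_TO_WT_RATIO", "TU_MEAN_rCBV") %in% features)) {
    ed <- centroids[, "ED_TO_WT_RATIO"]
    cb <- centroids[, "TU_MEAN_rCBV"]
    nm <- character(3)
    irr <- which.max(ed)
    nm[irr] <- "irregular"
    rest <- setdiff(1:3, irr)
    nm[rest[which.max(cb[rest])]] <- "solid"
    nm[nm == ""] <- "rim_enhancing"
    nm
  } else {
    paste0("subtype_", seq_len(K))
  }
}

#' Assign new subjects to fitted subtypes by nearest centroid
#'
#' Scales the new table with the discovery scaling (values may fall outside
#' [0, 1]; they are not clipped) and assigns each subject to the cluster
#' whose centroid is closest in Euclidean distance. Exact ties go to the
#' lowest cluster index.
#'
#' @param model A `subtype_model`.
#' @param new_table Feature table carrying the model's features.
#' @return Integer cluster indices named by subject, with attribute
#'   `cluster_names` (display names in index order).
#' @export
assign_new <- function(model, new_table) {
  S <- apply_scaling(model$scaling, new_table)
  d2 <- outer(rowSums(S^2), rowSums(model$centroids^2), "+") -
    2 * S %*% t(model$centroids)
  idx <- max.col(-d2, ties.method = "first")
  out <- stats::setNames(idx, rownames(S))
  attr(out, "cluster_names") <- model$cluster_names
  out
}

#' @rdname assign_new
#' @param object A `subtype_model`.
#' @param newdata New feature table; when omitted, the discovery labels are
#'   returned.
#' @param ... Unused.
#' @export
predict.subtype_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$labels)
  assign_new(object, newdata)
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("Imaging subtype model: K = %d (%d subjects, %d features)\n",
              x$K, length(x$labels), length(x$features)))
  if (!is.null(x$k_report)) {
    cat("stability (average pairwise ARI) by K:\n")
    print(x$k_report, row.names = FALSE)
  }
  cat(sprintf("representative assignment: silhouette %.3f, frequency %.1f%%\n",
              x$silhouette, 100 * x$frequency))
  cat("cluster sizes:\n")
  print(stats::setNames(as.integer(table(x$labels)), x$cluster_names))
  invisible(x)
}

#' @export
summary.subtype_model <- function(object, ...) {
  sizes <- as.integer(table(object$labels))
  out <- list(K = object$K,
              sizes = stats::setNames(sizes, object$cluster_names),
              proportions = stats::setNames(sizes / sum(sizes),
                                            object$cluster_names),
              k_report = object$k_report,
              silhouette = object$silhouette,
              frequency = object$frequency)
  class(out) <- "summary.subtype_model"
  out
}

#' @export
print.summary.subtype_model <- function(x, ...) {
  cat(sprintf("Subtype model with K = %d clusters\n", x$K))
  cat("cluster proportions (%):\n")
  print(round(100 * x$proportions, 2))
  if (!is.null(x$k_report)) {
    cat("stability by K:\n"); print(x$k_report, row.names = FALSE)
  }
  cat(sprintf("silhouette %.3f, representative frequency %.1f%%\n",
              x$silhouette, 100 * x$frequency))
  invisible(x)
}

#' Plot a subtype model's stability curve and cluster sizes
#'
#' @param x A `subtype_model`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.subtype_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  if (!is.null(x$k_report)) {
    plot(x$k_report$K, x$k_report$average_ari, type = "b", pch = 19,
         xlab = "K", ylab = "average pairwise ARI",
         main = "Ensemble stability", ...)
    graphics::abline(v = x$K, lty = 2)
  }
  graphics::barplot(table(x$labels), names.arg = x$cluster_names,
                    ylab = "subjects", main = "Cluster sizes", las = 2)
  invisible(x)
}
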