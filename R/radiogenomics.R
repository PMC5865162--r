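#' Cohen's d effect size with pooled standard deviation
#'
#' (mean1 - mean0) / pooled SD, pooled SD = sqrt(((n0-1) s0^2 +
#' (n1-1) s1^2) / (n0 + n1 - 2)).
#'
#' @param group0_values,group1_values Numeric vectors, each of length >= 2.
#' @return Effect size; NA (with attribute `degenerate = TRUE`) when the
#'   pooled SD is zero.
#' @export
cohens_d <- function(group0_values, group1_values) {
  n0 <- length(group0_values); n1 <- length(group1_values)
  if (n0 < 2 || n1 < 2) stop("both groups need >= 2 values")
  s0 <- stats::var(group0_values); s1 <- stats::var(group1_values)
  sp <- sqrt(((n0 - 1) * s0 + (n1 - 1) * s1) / (n0 + n1 - 2))
  if (sp == 0) return(structure(NA_real_, degenerate = TRUE))
  (mean(group1_values) - mean(group0_values)) / sp
}

#' Within- versus pooled mutation effect sizes per feature
#'
#' For each feature, |Cohen's d| between mutation-present and -absent
#' subjects, computed within each subtype stratum and pooled across all
#' subjects. Subjects with unknown mutation status are excluded; strata
#' where either mutation group has fewer than `min_group` members are
#' omitted with a warning.
#'
#' @param table Feature table (matrix-like).
#' @param mutation_labels "present" / "absent" / "unknown" per subject.
#' @param subtype_labels Subtype label per subject.
#' @param min_group Minimum per-group size within a stratum (default 2).
#' @return Object of class `effect_size_report`: matrix `abs_d` (features x
#'   strata, strata = subtypes plus "pooled") and per-stratum ranked feature
#'   lists in `ranking`.
#' @export
within_vs_pooled_effect_sizes <- function(table, mutation_labels,
                                          subtype_labels, min_group = 2L) {
  X <- .as_feature_matrix(table)
  known <- mutation_labels %in% c("present", "absent")
  X <- X[known, , drop = FALSE]
  mut <- mutation_labels[known] == "present"
  sub <- as.character(subtype_labels)[known]
  strata <- c(sort(unique(sub)), "pooled")
  d_one <- function(rows) {
    if (sum(mut[rows]) < min_group || sum(!mut[rows]) < min_group)
      return(rep(NA_real_, ncol(X)))
    apply(X[rows, , drop = FALSE], 2, function(col)
      abs(cohens_d(col[!mut[rows]], col[mut[rows]])))
  }
  abs_d <- vapply(strata, function(s) {
    rows <- if (s == "pooled") seq_along(mut) else which(sub == s)
    d_one(rows)
  }, numeric(ncol(X)))
  rownames(abs_d) <- colnames(X)
  dropped <- strata[colSums(!is.na(abs_d)) == 0]
  if (length(dropped) > 0)
    warning("strata too small for effect sizes, omitted: ",
            paste(dropped, collapse = ", "))
  ranking <- lapply(strata, function(s) {
    v <- abs_d[, s]
    names(sort(v, decreasing = TRUE, na.last = NA))
  })
  names(ranking) <- strata
  structure(list(abs_d = abs_d, ranking = ranking),
            class = "effect_size_report")
}

#' Stratified cross-validation folds
#'
#' Assigns fold ids 1..k balancing the class proportions; depends only on
#' the labels and the seed (never on the feature values).
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per subject.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.factor(y)
  fold <- integer(length(y))
  .with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# Inner-CV accuracy of an RBF-SVM on a feature subset.
.svm_cv_accuracy <- function(X, y, cols, fold, cost = 1, gamma = NULL) {
  correct <- 0L
  for (f in unique(fold)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    args <- list(x = X[tr, cols, drop = FALSE], y = y[tr],
                 kernel = "radial", cost = cost)
    if (!is.null(gamma)) args$gamma <- gamma
    m <- do.call(e1071::svm, args)
    pred <- stats::predict(m, X[!tr, cols, drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

# Sequential forward feature selection scored by inner-CV SVM accuracy;
# stops when no candidate improves the best accuracy (patience 1) or at
# max_features.
.sequential_selection <- function(X, y, inner_fold, max_features = 15L) {
  p <- ncol(X)
  selected <- integer(0)
  best <- -Inf
  while (length(selected) < min(max_features, p)) {
    cand <- setdiff(seq_len(p), selected)
    acc <- vapply(cand, function(j)
      .svm_cv_accuracy(X, y, c(selected, j), inner_fold), numeric(1))
    if (max(acc) > best) {
      best <- max(acc)
      selected <- c(selected, cand[which.max(acc)])
    } else break
  }
  if (length(selected) == 0) selected <- 1L
  selected
}

#' Nested cross-validated RBF-SVM with sequential feature selection
#'
#' One stratum's classifier: stratified outer folds; inside each training
#' fold, sequential forward feature selection scored by inner-CV SVM
#' accuracy, then a small C/gamma grid search on the selected subset, a
#' final RBF-SVM fit, and prediction of the held-out fold. Feature selection
#' and hyperparameter search never see the held-out fold.
#'
#' @param X Numeric feature matrix.
#' @param y Binary factor of class labels.
#' @param folds Number of outer folds (default 5; reduced to the minority
#'   class size when needed).
#' @param inner_folds Inner folds for selection/grid (default 3).
#' @param max_features Cap on selected features (default 15).
#' @param cost_grid,gamma_factors Hyperparameter grids; gamma is
#'   `factor / n_selected_features`.
#' @param seed Integer seed (fold assignment).
#' @param fold_id Optional externally supplied outer fold assignment.
#' @return List with `accuracy` (percent), `correct`, `n`, `predictions`,
#'   `selected` (per-fold selected feature names), `fold_id`.
#' @export
svm_nested_cv <- function(X, y, folds = 5L, inner_folds = 3L,
                          max_features = 15L, cost_grid = c(1, 10),
                          gamma_factors = c(0.5, 1, 2), seed = 1L,
                          fold_id = NULL) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need both classes present")
  folds <- min(folds, min(table(y)))
  if (folds < 2) stop("minority class too small for cross-validation")
  if (is.null(fold_id)) fold_id <- stratified_folds(y, folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  selected <- list()
  for (f in sort(unique(fold_id))) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    if (nlevels(ytr) < 2) stop("a training fold lost a class; reduce folds")
    inner_k <- min(inner_folds, min(table(ytr)))
    inner <- stratified_folds(ytr, max(2L, inner_k), seed + 1000L + f)
    sel <- .sequential_selection(Xtr, ytr, inner, max_features = max_features)
    grid <- expand.grid(cost = cost_grid,
                        gamma = gamma_factors / length(sel))
    acc <- vapply(seq_len(nrow(grid)), function(i)
      .svm_cv_accuracy(Xtr, ytr, sel, inner,
                       cost = grid$cost[i], gamma = grid$gamma[i]),
      numeric(1))
    bi <- which.max(acc)
    m <- e1071::svm(Xtr[, sel, drop = FALSE], ytr, kernel = "radial",
                    cost = grid$cost[bi], gamma = grid$gamma[bi])
    pred[te] <- stats::predict(m, X[te, sel, drop = FALSE])
    selected[[as.character(f)]] <-
      if (!is.null(colnames(X))) colnames(X)[sel] else sel
  }
  correct <- sum(pred == y)
  list(accuracy = 100 * correct / length(y), correct = correct,
       n = length(y), predictions = pred, selected = selected,
       fold_id = fold_id)
}

#' Null model for the rim-enhancing subtype
#'
#' Every rim-enhancing subject is predicted mutation-absent (no classifier
#' is trained for this low-prevalence stratum); the accuracy is the fraction
#' of truly mutation-absent subjects.
#'
#' @param mutation_labels "present"/"absent" labels of the rim-enhancing
#'   subjects (status known).
#' @return List with `predictions` (all "absent"), `correct`, `n`,
#'   `accuracy` (percent; NA for an empty stratum).
#' @export
rim_null_model <- function(mutation_labels) {
  n <- length(mutation_labels)
  correct <- sum(mutation_labels == "absent")
  list(predictions = rep("absent", n), correct = correct, n = n,
       accuracy = if (n > 0) 100 * correct / n else NA_real_)
}

#' Weighted-accuracy aggregation across strata
#'
#' The average accuracy over strata weighted by stratum size: total correct
#' divided by total classified — never the unweighted mean of the stratum
#' accuracies.
#'
#' @param correct Integer vector of correctly classified counts per stratum.
#' @param n Integer vector of stratum sizes.
#' @return Percentage in [0, 100].
#' @export
weighted_accuracy <- function(correct, n) {
  stopifnot(length(correct) == length(n), all(correct <= n))
  100 * sum(correct) / sum(n)
}

#' Within-subtype versus pooled EGFRvIII classification
#'
#' Tests the radiogenomic hypothesis that mutation signatures are clearer
#' inside phenotypically uniform subtypes: builds one nested-CV RBF-SVM per
#' subtype (except the rim-enhancing stratum, which uses the mutation-absent
#' null model) and one pooled classifier across all subjects, then compares
#' the size-weighted within-subtype accuracy with the pooled accuracy.
#' Subjects with unknown mutation status are excluded throughout.
#'
#' @param table Feature table (matrix-like).
#' @param mutation_labels "present"/"absent"/"unknown" per subject.
#' @param subtype_labels Subtype label per subject.
#' @param seed Integer seed.
#' @param rim_label Stratum handled by the null model (default
#'   "rim_enhancing"; set NULL to train classifiers for all strata).
#' @param min_stratum Minimum stratum size; smaller strata are omitted with
#'   a warning (default 10).
#' @param ... Passed to [svm_nested_cv()] (folds, max_features, grids, ...).
#' @return Object of class `classifier_report`: `per_stratum` data.frame
#'   (stratum, n, correct, accuracy, method), `weighted_accuracy`,
#'   `pooled_accuracy`, `selected` feature names per stratum, `seed`.
#' @export
svm_within_vs_pooled <- function(table, mutation_labels, subtype_labels,
                                 seed = 1L, rim_label = "rim_enhancing",
                                 min_stratum = 10L, ...) {
  X <- .as_feature_matrix(table)
  known <- mutation_labels %in% c("present", "absent")
  X <- X[known, , drop = FALSE]
  mut <- factor(mutation_labels[known], levels = c("absent", "present"))
  sub <- as.character(subtype_labels)[known]
  strata <- sort(unique(sub))
  rows <- list(); selected <- list()
  for (s in strata) {
    idx <- which(sub == s)
    if (!is.null(rim_label) && s == rim_label) {
      nm <- rim_null_model(as.character(mut[idx]))
      rows[[s]] <- data.frame(stratum = s, n = nm$n, correct = nm$correct,
                              accuracy = nm$accuracy, method = "null_model")
      next
    }
    if (length(idx) < min_stratum || nlevels(droplevels(mut[idx])) < 2) {
      warning(sprintf("stratum '%s' too small or single-class; omitted", s))
      next
    }
    cv <- svm_nested_cv(X[idx, , drop = FALSE], mut[idx],
                        seed = seed + match(s, strata), ...)
    rows[[s]] <- data.frame(stratum = s, n = cv$n, correct = cv$correct,
                            accuracy = cv$accuracy, method = "svm_nested_cv")
    selected[[s]] <- unique(unlist(cv$selected))
  }
  pooled <- svm_nested_cv(X, mut, seed = seed, ...)
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  structure(list(
    per_stratum = per,
    weighted_accuracy = weighted_accuracy(per$correct, per$n),
    pooled_accuracy = pooled$accuracy,
    pooled_n = pooled$n,
    selected = selected,
    seed = as.integer(seed)),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Within- vs across-subtype EGFRvIII classification\n")
  print(x$per_stratum, row.names = FALSE, digits = 4)
  cat(sprintf("weighted within-subtype accuracy: %.2f%% (total correct / total n)\n",
              x$weighted_accuracy))
  cat(sprintf("pooled classifier accuracy:       %.2f%% (n = %d)\n",
              x$pooled_accuracy, x$pooled_n))
  invisible(x)
}

#' Pearson chi-square test of subtype x category composition
#'
#' @param subtype_labels Subtype label per subject.
#' @param categorical_labels Second categorical label per subject (e.g.
#'   transcriptomic subtype).
#' @return List with `chisq`, `df` = (r-1)(c-1), `p`, `table`.
#' @export
composition_chisq <- function(subtype_labels, categorical_labels) {
  tab <- table(subtype_labels, categorical_labels)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an empty row or column")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Simulate a feature table with planted subtype-specific mutation signatures
#'
#' Standalone feature-level generator for radiogenomic experiments: subjects
#' are assigned to the three subtypes, mutation status follows the
#' archetype prevalences, and mutation shifts a disjoint block of features
#' per non-rim subtype by `effect_size` pooled standard deviations — the
#' rim-enhancing stratum carries no signature (its prediction rule is the
#' null model). Features are otherwise standard normal.
#'
#' @param n Number of subjects.
#' @param n_features Total number of features.
#' @param signature_size Features per subtype signature block.
#' @param effect_size Mean shift (in SD units) of signature features in
#'   mutated subjects of the corresponding subtype.
#' @param prevalences Named mutation prevalence per subtype.
#' @param proportions Subtype mixing proportions.
#' @param seed Integer seed.
#' @return List with `features` (matrix), `mutation`
#'   ("present"/"absent"), `subtype`, and `signature` (feature indices per
#'   subtype).
#' @export
simulate_radiogenomic_features <- function(n = 300L, n_features = 30L,
                                           signature_size = 5L,
                                           effect_size = 1.5,
                                           prevalences = c(rim_enhancing = 0.125,
                                                           irregular = 0.3902,
                                                           solid = 0.3061),
                                           proportions = c(rim_enhancing = 0.1442,
                                                           irregular = 0.3990,
                                                           solid = 0.4567),
                                           seed = 1L) {
  stopifnot(2 * signature_size <= n_features)
  .with_seed(seed, {
    subtype <- sample(names(proportions), n, replace = TRUE, prob = proportions)
    mutation <- ifelse(stats::runif(n) < prevalences[subtype], "present", "absent")
    X <- matrix(stats::rnorm(n * n_features), n, n_features,
                dimnames = list(sprintf("S%03d", 1:n),
                                sprintf("F%03d", 1:n_features)))
    signature <- list(irregular = 1:signature_size,
                      solid = signature_size + 1:signature_size)
    for (s in names(signature)) {
      hit <- subtype == s & mutation == "present"
      X[hit, signature[[s]]] <- X[hit, signature[[s]]] + effect_size
    }
    list(features = X, mutation = mutation, subtype = subtype,
         signature = signature)
  })
}
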