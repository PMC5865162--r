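#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function; the median is the
#' smallest time with S(t) <= 0.5 (left endpoint if S sits exactly at 0.5
#' over an interval), NA if S never reaches 0.5.
#'
#' @param records data.frame with columns `time` (> 0, months) and `event`
#'   (1 = death observed, 0 = censored).
#' @return Object of class `km_curve`: `time`, `surv`, `n_risk`, `median`,
#'   `n`, `events`.
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1)
  if (any(records$time <= 0)) stop("survival times must be > 0")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 or 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  s <- fit$surv
  med <- if (any(s <= 0.5)) fit$time[which(s <= 0.5)[1]] else NA_real_
  structure(list(time = fit$time, surv = s, n_risk = fit$n.risk,
                 median = med, n = nrow(records),
                 events = sum(records$event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, median %s months\n",
              x$n, x$events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  t <- c(0, rep(x$time, each = 2))
  s <- c(1, 1, rep(x$surv, each = 2)[-(2 * length(x$surv))])
  plot(t, s, type = "l", ylim = c(0, 1), xlab = "months",
       ylab = "survival probability", ...)
  invisible(x)
}

#' Log-rank (Mantel-Cox) test across groups
#'
#' @param records data.frame with `time`, `event` and a `group` column (or
#'   pass `group` separately).
#' @param group Optional group labels aligned to `records`.
#' @return List with `chisq`, `df` (groups - 1) and `p`.
#' @export
logrank_test <- function(records, group = records$group) {
  g <- factor(group)
  if (nlevels(g) < 2) stop("log-rank test needs >= 2 groups")
  if (any(table(g) == 0)) stop("a group is empty")
  d <- data.frame(time = records$time, event = records$event, g = g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  df <- nlevels(g) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood fit with Breslow tie handling. Reports coefficients,
#' hazard ratios with 95% confidence intervals, Wald p-values, and the
#' Harrell concordance of the linear predictor with its p-value against 0.5.
#'
#' @param records data.frame with `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names; factors are
#'   expanded to indicator contrasts.
#' @return Object of class `cox_report`: `coefficients` data.frame (term,
#'   coef, hr, ci_lower, ci_upper, p), `c_index`, `c_index_p`, `n`, `fit`.
#' @export
cox_fit <- function(records, covariates) {
  stopifnot(all(covariates %in% names(records)))
  for (cv in covariates) {
    v <- records[[cv]]
    if (length(unique(v[!is.na(v)])) < 2)
      stop(sprintf("covariate '%s' is constant", cv))
  }
  if (sum(records$event) < 2 ||
      length(unique(records$time[records$event == 1])) < 2)
    stop("need >= 2 distinct event times")
  fm <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fm, data = records, ties = "breslow")
  if (!is.null(fit$info) && isTRUE(fit$info$converged == FALSE))
    stop("Cox partial-likelihood maximization did not converge")
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  coefficients <- data.frame(
    term = rownames(co),
    coef = co[, "coef"],
    hr = ci[, "exp(coef)"],
    ci_lower = ci[, "lower .95"],
    ci_upper = ci[, "upper .95"],
    p = co[, "Pr(>|z|)"],
    row.names = NULL)
  lp <- unname(stats::predict(fit, type = "lp"))
  cc <- harrell_c(lp, records)
  structure(list(coefficients = coefficients, c_index = cc$c_index,
                 c_index_p = cc$p, n = nrow(records), fit = fit),
            class = "cox_report")
}

#' @export
print.cox_report <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (n = %d, Breslow ties)\n", x$n))
  df <- x$coefficients
  df$hr <- sprintf("%.3f (%.3f-%.3f)", df$hr, df$ci_lower, df$ci_upper)
  print(df[, c("term", "coef", "hr", "p")], row.names = FALSE, digits = 3)
  cat(sprintf("Harrell c-index %.3f (p = %.3g vs 0.5)\n", x$c_index, x$c_index_p))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Over comparable pairs (the earlier time carries an event), a pair is
#' concordant when the shorter survival has the higher risk score; score
#' ties count 0.5. Pairs with tied times, or where the earlier time is
#' censored, are not comparable. The p-value against c = 0.5 uses a normal
#' approximation with the linearized U-statistic variance over per-subject
#' concordance contributions (pairs sharing a subject are correlated, so
#' the variance scales with the number of subjects, not of pairs).
#'
#' @param risk_scores Numeric risk scores (higher = shorter expected
#'   survival), aligned to `records`.
#' @param records data.frame with `time` and `event`.
#' @return List with `c_index`, `p`, `n_pairs`.
#' @export
harrell_c <- function(risk_scores, records) {
  stopifnot(length(risk_scores) == nrow(records))
  t <- records$time; e <- records$event
  n <- length(t)
  s <- numeric(n)  # concordance score of pairs involving each subject
  w <- numeric(n)  # comparable pairs involving each subject
  npairs <- 0
  for (i in which(e == 1)) {
    later <- which(t > t[i])
    m <- length(later)
    if (m == 0) next
    npairs <- npairs + m
    contrib <- (risk_scores[i] > risk_scores[later]) +
      0.5 * (risk_scores[i] == risk_scores[later])
    s[i] <- s[i] + sum(contrib); w[i] <- w[i] + m
    s[later] <- s[later] + contrib; w[later] <- w[later] + 1
  }
  if (npairs == 0) stop("no comparable pairs")
  c_index <- sum(s) / sum(w)
  var_c <- 4 * sum((s - c_index * w)^2) / sum(w)^2
  if (var_c <= 0) {
    p <- if (abs(c_index - 0.5) < 1e-12) 1 else 0
  } else {
    z <- (c_index - 0.5) / sqrt(var_c)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(c_index = c_index, p = p, n_pairs = npairs)
}

#' Compare the six Cox covariate configurations
#'
#' Fits Cox models on (i) age, (ii) the nine location percentages, (iii)
#' imaging subtype, (iv) subtype + age, (v) subtype + location, (vi) age +
#' location + subtype, and reports the apparent (fitting-cohort) Harrell
#' c-index of each. Subtype enters as K - 1 indicators with rim-enhancing
#' (when present) as the reference level.
#'
#' @param records data.frame with `time`, `event`, `age`, `subtype` and the
#'   nine `LOC_*` location columns.
#' @param reference_subtype Reference level for the subtype factor.
#' @return data.frame with columns `model`, `covariates`, `c_index`, `p`.
#' @export
model_comparison <- function(records, reference_subtype = "rim_enhancing") {
  loc_cols <- grep("^LOC_", names(records), value = TRUE)
  if (length(loc_cols) == 0) stop("no LOC_* location columns found")
  # drop (near-)constant location columns to keep fits well-posed
  loc_cols <- loc_cols[vapply(loc_cols, function(cv)
    length(unique(records[[cv]])) > 1, logical(1))]
  records$subtype <- factor(records$subtype)
  if (reference_subtype %in% levels(records$subtype))
    records$subtype <- stats::relevel(records$subtype, reference_subtype)
  configs <- list(
    age = "age",
    location = loc_cols,
    subtype = "subtype",
    subtype_age = c("subtype", "age"),
    subtype_location = c("subtype", loc_cols),
    age_location_subtype = c("age", loc_cols, "subtype"))
  out <- lapply(names(configs), function(nm) {
    rep <- cox_fit(records, configs[[nm]])
    data.frame(model = nm,
               covariates = paste(configs[[nm]], collapse = "+"),
               c_index = rep$c_index, p = rep$c_index_p)
  })
  do.call(rbind, out)
}

#' Subtype survival characterization
#'
#' Convenience wrapper: per-subtype Kaplan-Meier curves and medians, the
#' global log-rank test, and pairwise Cox hazard ratios between subtypes
#' (reference listed first in each pair).
#'
#' @param records data.frame with `time`, `event` and `subtype`.
#' @return List with `km` (per-subtype `km_curve`), `medians`, `logrank`,
#'   `pairwise_hr` data.frame.
#' @export
subtype_survival <- function(records) {
  sub <- factor(records$subtype)
  km <- lapply(levels(sub), function(s) km_estimate(records[sub == s, ]))
  names(km) <- levels(sub)
  medians <- vapply(km, function(k) k$median, numeric(1))
  lr <- logrank_test(records, group = sub)
  pairs <- utils::combn(levels(sub), 2)
  hr <- apply(pairs, 2, function(pr) {
    d <- records[sub %in% pr, ]
    d$grp <- factor(d$subtype, levels = pr)  # first level = reference
    rep <- cox_fit(d, "grp")
    data.frame(reference = pr[1], comparison = pr[2],
               hr = rep$coefficients$hr[1],
               ci_lower = rep$coefficients$ci_lower[1],
               ci_upper = rep$coefficients$ci_upper[1],
               p = rep$coefficients$p[1])
  })
  list(km = km, medians = medians, logrank = lr,
       pairwise_hr = do.call(rbind, hr))
}
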