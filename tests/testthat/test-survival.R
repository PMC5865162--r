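test_that("Kaplan-Meier estimate matches hand product-limit computation", {
  rec <- data.frame(time = 1:10, event = 1)
  km <- km_estimate(rec)
  expect_equal(km$surv, seq(0.9, 0, by = -0.1))
  expect_equal(km$median, 5)

  one <- km_estimate(data.frame(time = 7, event = 0))
  expect_true(all(one$surv == 1))
  expect_true(is.na(one$median))

  same <- km_estimate(data.frame(time = rep(4, 6), event = 1))
  expect_equal(same$surv, 0)
  expect_equal(same$median, 4)

  expect_error(km_estimate(data.frame(time = c(1, -2), event = 1)), "> 0")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(30)
  t <- sort(rexp(40, 0.1))
  km <- km_estimate(data.frame(time = t, event = 1))
  emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$surv, emp)
})

test_that("the log-rank test separates different hazards", {
  rec <- data.frame(time = rep(1:10, 2), event = 1,
                    group = rep(c("a", "b"), each = 10))
  same <- logrank_test(rec)
  expect_lt(same$chisq, 1e-10)
  expect_equal(same$p, 1, tolerance = 1e-6)

  set.seed(31)
  rec2 <- data.frame(
    time = c(rexp(200, log(2) / 19), rexp(200, log(2) / 6)),
    event = 1, group = rep(c("slow", "fast"), each = 200))
  expect_lt(logrank_test(rec2)$p, 0.001)

  rec3 <- data.frame(time = rexp(30, 1) + 0.01, event = 1,
                     group = rep(c("a", "b", "c"), 10))
  expect_equal(logrank_test(rec3)$df, 2)
  expect_error(logrank_test(data.frame(time = 1:3, event = 1, group = "a")),
               "2 groups")
})

test_that("the Cox fit recovers a planted hazard ratio", {
  set.seed(32)
  x <- rep(c(0, 1), each = 2500)
  t <- rexp(5000, 0.05 * exp(log(2) * x))
  rec <- data.frame(time = t, event = 1, x = x)
  fit <- cox_fit(rec, "x")
  expect_gt(fit$coefficients$hr[1], 1.8)
  expect_lt(fit$coefficients$hr[1], 2.2)
  expect_true(fit$coefficients$ci_lower[1] <= fit$coefficients$hr[1])
  expect_true(fit$coefficients$ci_upper[1] >= fit$coefficients$hr[1])

  # independent covariate: CI covers 1
  set.seed(33)
  rec2 <- data.frame(time = rexp(800, 0.1), event = 1, z = rnorm(800))
  fit2 <- cox_fit(rec2, "z")
  expect_true(fit2$coefficients$ci_lower[1] < 1 &&
                fit2$coefficients$ci_upper[1] > 1)

  # rescaling a covariate rescales its coefficient, not the model
  rec3 <- rec2; rec3$z <- 2 * rec3$z
  fit3 <- cox_fit(rec3, "z")
  expect_equal(fit3$coefficients$coef[1], fit2$coefficients$coef[1] / 2,
               tolerance = 1e-6)

  rec4 <- rec2; rec4$z <- 1
  expect_error(cox_fit(rec4, "z"), "constant")
  expect_error(cox_fit(data.frame(time = c(1, 2), event = c(1, 0),
                                  z = c(0, 1)), "z"),
               "event times")
})

test_that("Harrell's c-index follows its pair-counting definition", {
  rec <- data.frame(time = c(2, 5, 9, 13), event = 1)
  expect_equal(harrell_c(-rec$time, rec)$c_index, 1)
  expect_equal(harrell_c(rep(0, 4), rec)$c_index, 0.5)
  # strictly increasing transforms leave c unchanged
  set.seed(34)
  rec2 <- data.frame(time = rexp(300, 0.1), event = rbinom(300, 1, 0.8))
  sc <- rnorm(300)
  expect_equal(harrell_c(sc, rec2)$c_index,
               harrell_c(exp(3 * sc), rec2)$c_index)
  # random scores concentrate near 0.5
  set.seed(35)
  rec3 <- data.frame(time = rexp(2000, 0.1), event = 1)
  c3 <- harrell_c(rnorm(2000), rec3)
  expect_gt(c3$c_index, 0.47); expect_lt(c3$c_index, 0.53)
  expect_gt(c3$p, 0.001)
  expect_error(harrell_c(1, data.frame(time = 3, event = 0)), "comparable")
})

test_that("c-index agrees with the survival package on censored data", {
  set.seed(36)
  rec <- data.frame(time = round(rexp(300, 0.1), 4),
                    event = rbinom(300, 1, 0.7))
  sc <- rnorm(300)
  mine <- harrell_c(sc, rec)$c_index
  ref <- survival::concordance(survival::Surv(time, event) ~ sc, data = rec,
                               reverse = TRUE)$concordance
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("model comparison ranks covariate configurations sensibly", {
  set.seed(37)
  n <- 450
  subtype <- sample(c("rim_enhancing", "irregular", "solid"), n, replace = TRUE)
  meds <- c(rim_enhancing = 19, irregular = 12, solid = 6)
  rec <- data.frame(
    time = rexp(n, log(2) / meds[subtype]),
    event = 1, age = round(rnorm(n, 58, 10)), subtype = subtype)
  loc <- matrix(abs(rnorm(n * 9)), n, 9)
  loc <- 100 * loc / rowSums(loc)
  colnames(loc) <- paste0("LOC_", atlas_region_names())
  rec <- cbind(rec, loc)
  comp <- model_comparison(rec)
  expect_equal(nrow(comp), 6)
  ci <- setNames(comp$c_index, comp$model)
  # only subtype carries signal here
  expect_gt(ci[["subtype"]], ci[["age"]])
  expect_gt(ci[["subtype"]], ci[["location"]])
  # the joint model is at least as concordant as each single-covariate model
  expect_gte(ci[["age_location_subtype"]] + 1e-9,
             max(ci[["age"]], ci[["location"]], ci[["subtype"]]))

  # all-noise covariates hover near 0.5
  rec_noise <- rec
  rec_noise$subtype <- sample(rec$subtype)
  rec_noise$time <- rexp(n, 0.1)
  comp2 <- model_comparison(rec_noise)
  expect_true(all(comp2$c_index > 0.45 & comp2$c_index < 0.58))
})

test_that("subtype survival characterization orders the planted archetypes", {
  set.seed(38)
  co <- generate_cohort(cohort_spec(240, volume_shape = c(40, 40, 40),
                                    random_seed = 8), channels = FALSE)
  rec <- co$clinical
  rec$time <- rec$survival_months
  rec$subtype <- rec$truth_archetype
  sv <- subtype_survival(rec)
  expect_true(sv$medians[["rim_enhancing"]] > sv$medians[["irregular"]])
  expect_true(sv$medians[["irregular"]] > sv$medians[["solid"]])
  expect_lt(sv$logrank$p, 0.001)
  hr <- sv$pairwise_hr
  rim_solid <- hr$hr[hr$reference == "rim_enhancing" & hr$comparison == "solid"]
  expect_gt(rim_solid, 1)
})
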