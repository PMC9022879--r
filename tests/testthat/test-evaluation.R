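test_that("coefficient_of_variation is sd/mean with n-1 denominator", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  set.seed(2)
  v <- rlnorm(50)
  expect_equal(coefficient_of_variation(7.3 * v),
               coefficient_of_variation(v), tolerance = 1e-12)
  expect_error(coefficient_of_variation(3), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("cov_about_fit removes a linear trend and falls back on constant x", {
  x <- 1:20
  expect_equal(as.numeric(cov_about_fit(2 * x + 1, x)), 0,
               tolerance = 1e-12)
  cst <- cov_about_fit(c(1, 2, 3, 4), rep(5, 4))
  expect_true(attr(cst, "fallback"))
  expect_equal(as.numeric(cst), coefficient_of_variation(c(1, 2, 3, 4)))
  expect_error(cov_about_fit(1:2, 1:2), "n >= 3")

  # y independent of x: CoVf approaches CoV at large n
  set.seed(9)
  y <- rlnorm(1000, 0, 0.2)
  x <- runif(1000)
  covf <- as.numeric(cov_about_fit(y, x))
  cov <- coefficient_of_variation(y)
  expect_lt(abs(covf - cov) / cov, 0.05)
})

test_that("pearson_test reproduces the R-to-t conversion", {
  # construct n = 27 data with sample correlation exactly 0.5
  n <- 27
  x <- as.numeric(scale(1:n))
  set.seed(3)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x))
  z <- as.numeric(scale(z))
  y <- 0.5 * x + sqrt(1 - 0.25) * z
  pt <- pearson_test(x, y)
  expect_equal(pt$R, 0.5, tolerance = 1e-12)
  expect_equal(pt$t, 2.886751, tolerance = 1e-6)
  expect_equal(pt$p, 0.0079127, tolerance = 1e-5)

  # independent route: stats::cor.test uses the same t reference
  ct <- cor.test(x, y)
  expect_equal(pt$p, ct$p.value, tolerance = 1e-12)

  # symmetric exact-zero correlation
  x0 <- c(-1, 0, 1, -1, 0, 1)
  y0 <- c(1, 0, 1, 1, 0, 1)
  pt0 <- pearson_test(x0, y0)
  expect_equal(pt0$R, 0)
  expect_equal(pt0$t, 0)
  expect_equal(pt0$p, 1)

  expect_error(pearson_test(rep(1, 5), 1:5), "constant")
  deg <- pearson_test(1:5, 2 * (1:5))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})

test_that("pearson_test p matches a permutation oracle at n = 10", {
  set.seed(14)
  x <- rnorm(10)
  y <- 0.4 * x + rnorm(10)
  pt <- pearson_test(x, y)
  n_perm <- 40000
  r_obs <- abs(cor(x, y))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (abs(cor(x, sample(y))) >= r_obs - 1e-12) hits <- hits + 1L
  }
  p_perm <- hits / n_perm
  mc_se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(pt$p - p_perm), 2 * mc_se + 0.01)
})

test_that("bonferroni_alpha divides the family alpha", {
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "m")
  expect_error(bonferroni_alpha(1.2, 5), "family_alpha")
})

test_that("kfold folds partition the cohort and are seed-reproducible", {
  tab <- quiet_training(17)
  cv <- kfold_cross_validate(tab, seed = 99)
  sizes <- table(cv$assignments)
  expect_equal(unname(as.integer(sizes)), rep(66L, 5))
  expect_setequal(names(cv$assignments), tab$patients$patient_id)

  cv2 <- kfold_cross_validate(tab, seed = 99)
  expect_identical(cv$assignments, cv2$assignments)
  expect_equal(cv$summary, cv2$summary, tolerance = 1e-15)

  cv3 <- kfold_cross_validate(tab, seed = 100)
  expect_false(identical(cv$assignments, cv3$assignments))

  # remainder spreading: 23 patients in 3 folds -> 8/8/7
  small <- generate_cohort(sim_config(n_training = 23, n_test = 0,
                                      n_brain = 0, seed = 1))$training
  cv_small <- kfold_cross_validate(small, k = 3, seed = 1)
  expect_equal(sort(as.integer(table(cv_small$assignments)),
                    decreasing = TRUE), c(8L, 8L, 7L))
  expect_error(kfold_cross_validate(small, k = 5), "too small")
})

test_that("fold-out coefficients are fitted without the fold's patients", {
  tab <- quiet_training(23)
  cv <- kfold_cross_validate(tab, seed = 5)
  f1 <- names(cv$assignments)[cv$assignments == 1]
  refit <- fit_model(subset_cohort(tab, setdiff(tab$patients$patient_id,
                                                f1)))
  expect_equal(unname(cv$coefficients["fold1", ]),
               unname(refit$coefficients), tolerance = 1e-10)
})

test_that("cross-validated SUVfdg is calibrated and decorrelated", {
  tab <- quiet_training(31)
  cv <- kfold_cross_validate(tab, seed = 31)
  s <- cv$summary
  fdg <- s[s$metric == "suv_fdg", ]
  expect_lt(abs(fdg$cov_mean - 0.162), 0.03)
  expect_lt(abs(fdg$r_weight_mean), 0.15)
  covs <- setNames(s$cov_mean, s$metric)
  expect_true(covs["suv_fdg"] == min(covs))
  expect_true(covs["suv_bw"] == max(covs))
})

test_that("welch_t_test matches its anchors and df bounds", {
  g <- c(1.2, 1.4, 1.1, 1.6)
  same <- welch_t_test(g, g)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t_test(1, g), "n >= 2")
  expect_error(welch_t_test(rep(1, 4), g), "zero-variance")

  set.seed(6)
  for (i in 1:25) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), sd = 3)
    wt <- welch_t_test(a, b)
    expect_gte(wt$df, min(length(a), length(b)) - 1)
    expect_lte(wt$df, length(a) + length(b) - 2)
  }
})

test_that("pediatric vs adult brain groups separate decisively", {
  detections <- 0L
  set.seed(77)
  for (i in 1:100) {
    ped <- rnorm(22, 4.7, 0.9)
    adu <- rnorm(43, 3.1, 0.6)
    if (welch_t_test(ped, adu)$p < 0.01) detections <- detections + 1L
  }
  expect_equal(detections, 100L)  # power is essentially 1 at this effect
})

test_that("test_cohort_report has the expected layout and behavior", {
  syn <- generate_cohort(sim_config(seed = 12))
  rep <- test_cohort_report(syn$training, syn$test,
                            tissues = c("liver", "blood", "spleen"))
  expect_equal(nrow(rep), 12)  # 3 tissues x 4 metrics
  expect_setequal(unique(rep$metric),
                  c("suv_bw", "suv_lbm", "suv_bsa", "suv_fdg"))
  expect_true(all(c("cov", "r_weight", "p_weight", "r_height",
                    "p_height", "r_age", "p_age") %in% names(rep)))
  # brain is absent from the whole-body test cohort
  expect_warning(
    rep2 <- test_cohort_report(syn$training, syn$test,
                               tissues = c("liver", "brain")),
    "absent")
  expect_equal(nrow(rep2), 4)

  liver <- rep[rep$tissue == "liver", ]
  expect_lt(liver$cov[liver$metric == "suv_fdg"],
            liver$cov[liver$metric == "suv_bw"])
})

test_that("blood SUVfdg shows no age correlation on generated cohorts", {
  nonsig <- 0L
  for (i in 1:20) {
    syn <- generate_cohort(sim_config(seed = 3000 + i))
    rep <- test_cohort_report(syn$training, syn$test, tissues = "blood")
    p_age <- rep$p_age[rep$metric == "suv_fdg"]
    if (p_age > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 16)  # ~95% expected; allow Monte-Carlo slack
})

test_that("CoV and Pearson R ignore metric rescaling", {
  set.seed(8)
  v <- rlnorm(80, 0, 0.3)
  w <- rnorm(80, 70, 15)
  k <- 1e-4  # e.g. a different SUVbsa scale convention
  expect_equal(coefficient_of_variation(k * v),
               coefficient_of_variation(v), tolerance = 1e-12)
  expect_equal(pearson_test(k * v, w)$R, pearson_test(v, w)$R,
               tolerance = 1e-12)
})

test_that("cv report serializes with its seed", {
  tab <- quiet_training(2)
  cv <- kfold_cross_validate(tab, seed = 41)
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_report(cv, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$seed, 41)
  expect_equal(obj$k, 5)
  expect_equal(nrow(obj$folds), 20)
})
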