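test_that("build_design lays out powers, response and exclusions", {
  tab <- tiny_cohort()
  d <- build_design(tab, model_specs()$A)
  i <- which(d$data$patient_id == "p1")  # h = 1.62, w = 70
  expect_equal(unname(d$X[i, ]), c(1.62^3, 1.62^2, 1.62, 70, 1))
  expect_equal(colnames(d$X), c("h3", "h2", "h1", "w1", "(Intercept)"))
  # response is the natural log of the inverse %ID/ml
  expect_equal(d$y[i], log(1 / d$data$pct_id_ml[i]))

  m <- tiny_measurements()
  m$pct_id_ml <- c(0.01, 0.02, 0.03)
  m$conc_bq_ml <- NULL
  tab2 <- cohort_table(tiny_patients(), m)
  d2 <- build_design(tab2, model_specs()$H2)
  expect_equal(d2$y[d2$data$patient_id == "p1"], log(100),
               tolerance = 1e-12)

  # a patient without a liver measurement is excluded with a warning
  tab3 <- cohort_table(tiny_patients(), tiny_measurements()[-2, ])
  expect_warning(d3 <- build_design(tab3, model_specs()$A),
                 "without a liver")
  expect_equal(nrow(d3$data), 2)
})

test_that("noiseless model-A data is interpolated exactly", {
  cf <- published_coefficients()
  tab <- exact_cohort(n = 40, coeffs = cf)
  fit <- fit_model(tab, model_specs()$A)
  expect_equal(unname(fit$coefficients),
               c(cf$a, cf$b, cf$c, cf$d, cf$e), tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)
  expect_equal(fit$adj_r2, 1)
})

test_that("residuals sum to zero and fits ignore patient order", {
  tab <- quiet_training(7)
  fit <- fit_model(tab)
  expect_lt(abs(sum(fit$residuals)), 1e-8)

  # permute patients and measurements; coefficients unchanged
  set.seed(1)
  perm <- sample.int(nrow(tab$patients))
  tab2 <- cohort_table(tab$patients[perm, ],
                       tab$measurements[sample.int(nrow(tab$measurements)), ])
  fit2 <- fit_model(tab2)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-9)
  expect_equal(fit2$rss, fit$rss, tolerance = 1e-9)
})

test_that("constant height yields a singularity error naming the columns", {
  pat <- tiny_patients()
  pat$height_m <- 1.70
  pat <- rbind(pat, within(pat, patient_id <- paste0(patient_id, "b")))
  m <- rbind(tiny_measurements(),
             within(tiny_measurements(),
                    patient_id <- paste0(patient_id, "b")))
  tab <- cohort_table(pat, m)
  expect_error(fit_model(tab, model_specs()$H3), "collinear",
               class = "suvfdg_singular_error")
})

test_that("OLS matches an independent numerical RSS minimizer", {
  # generic optimizer on the raw sum of squared errors, started off-truth
  for (seed in c(2, 9)) {
    syn <- generate_cohort(sim_config(n_training = 45, n_test = 0,
                                      n_brain = 0, seed = seed))
    tab <- syn$training
    d <- build_design(tab, model_specs()$A)
    # minimize the RSS with a generic optimizer in a standardized basis
    # (the raw cubic basis is too ill-conditioned for finite-step
    # descent), then map the optimum back to raw coefficients
    k <- ncol(d$X) - 1L
    mu <- colMeans(d$X[, 1:k, drop = FALSE])
    sg <- apply(d$X[, 1:k, drop = FALSE], 2, sd)
    Z <- cbind(sweep(sweep(d$X[, 1:k, drop = FALSE], 2, mu), 2, sg, "/"),
               1)
    rss_fun <- function(g) sum((d$y - drop(Z %*% g))^2)
    rss_grad <- function(g) -2 * drop(crossprod(Z, d$y - drop(Z %*% g)))
    opt <- optim(rep(0, k + 1), rss_fun, rss_grad, method = "BFGS",
                 control = list(maxit = 10000, reltol = 1e-16))
    # Newton polish with a finite-difference Hessian of the gradient
    # (exact for a quadratic objective, up to roundoff)
    par <- opt$par
    H <- matrix(0, k + 1, k + 1)
    step <- 1e-4
    for (j in seq_len(k + 1)) {
      ej <- replace(rep(0, k + 1), j, step)
      H[, j] <- (rss_grad(par + ej) - rss_grad(par - ej)) / (2 * step)
    }
    par <- par - solve(H, rss_grad(par))
    opt <- list(par = par, value = rss_fun(par))
    beta_opt <- unname(c(opt$par[1:k] / sg,
                         opt$par[k + 1] - sum(opt$par[1:k] * mu / sg)))
    fit <- fit_model(tab, model_specs()$A)
    expect_equal(unname(fit$coefficients), beta_opt, tolerance = 1e-6)
    expect_lte(fit$rss, opt$value + 1e-10)  # OLS is the true minimum
  }
})

test_that("coefficient estimates land within 3 standard errors of truth", {
  cf <- published_coefficients()
  truth <- c(cf$a, cf$b, cf$c, cf$d, cf$e)
  hits <- matrix(0, nrow = 20, ncol = 5)
  for (i in 1:20) {
    fit <- fit_model(quiet_training(400 + i))
    hits[i, ] <- abs(fit$coefficients - truth) <= 3 * fit$se
  }
  # ~99.7% expected per coefficient; allow two misses in 20
  expect_true(all(colSums(hits) >= 18))
})

test_that("information criteria follow the stated convention", {
  ic <- information_criteria(rss = 100, tss = 500, n = 100, p = 5)
  expect_equal(ic$aic, 12)                 # n*log(rss/n) = 0, 2K = 12
  expect_equal(ic$bic, 6 * log(100), tolerance = 1e-12)
  expect_equal(ic$adj_r2, 1 - (100 / 95) / (500 / 99), tolerance = 1e-12)
  exact <- information_criteria(rss = 0, tss = 500, n = 100, p = 5)
  expect_equal(exact$adj_r2, 1)
  expect_true(exact$degenerate)
  expect_error(information_criteria(rss = 1, tss = 1, n = 5, p = 5), "n > p")
})

test_that("nested models never increase RSS and compare_models ranks them", {
  tab <- quiet_training(21)
  cmp <- compare_models(tab, model_specs())
  rss <- setNames(cmp$rss, cmp$model)
  expect_lte(rss[["H4"]], rss[["H3"]])
  expect_lte(rss[["H3"]], rss[["H2"]])
  expect_lte(rss[["A"]], rss[["H3"]])   # A nests H3
  expect_lte(rss[["B"]], rss[["H2"]])   # B nests H2
  expect_equal(sum(cmp$best_aic), 1)
  expect_error(compare_models(tab, model_specs("A")), "at least two")
})

test_that("model A is preferred by AIC on data generated from it", {
  wins <- 0L
  n_seeds <- 50
  for (i in seq_len(n_seeds)) {
    cmp <- compare_models(quiet_training(1000 + i), model_specs())
    if (cmp$model[cmp$best_aic] == "A") wins <- wins + 1L
  }
  expect_gte(wins, 0.8 * n_seeds)
})

test_that("residual correlations expose a missing weight term", {
  # H3 omits the true weight effect (d > 0): residuals correlate with
  # weight; refitting with model A removes the correlation
  tab <- quiet_training(33)
  fit_h3 <- fit_model(tab, model_specs()$H3)
  rc <- residual_correlation(fit_h3, "weight")
  expect_gt(rc$R, 0)
  expect_lt(rc$p, 0.01)

  nonsig <- 0L
  for (i in 1:30) {
    fit_a <- fit_model(quiet_training(2000 + i), model_specs()$A)
    rc_a <- residual_correlation(fit_a, "weight")
    if (rc_a$p > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 24)  # ~95% expected under the generating model
})

test_that("age exclusion removes exactly the under-threshold patients", {
  tab <- quiet_training(8)
  fit <- fit_model(tab)
  rc <- residual_correlation(fit, "height", exclude_under_age = 12)
  expect_equal(rc$n_used, sum(tab$patients$age_y >= 12))
  expect_error(residual_correlation(fit_model(exact_cohort()), "weight"),
               class = "suvfdg_degenerate_error")
})

test_that("a model-A fit exports BHN coefficients with CIs", {
  fit <- fit_model(quiet_training(5))
  cf <- as_bhn_coefficients(fit)
  expect_s3_class(cf, "bhn_coefficients")
  expect_equal(cf$a, unname(fit$coefficients["h3"]))
  expect_equal(cf$ci95$d, unname(fit$ci95["w1", ]))
  expect_error(as_bhn_coefficients(fit_model(quiet_training(5),
                                             model_specs()$H3)),
               "model-A")
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(length(rep$coefficients), 5)
  expect_equal(rep$n, 330)
})
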