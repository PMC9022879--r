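# Comparison statistics: CoV, CoV about a fitted line, Pearson tests,
# Bonferroni thresholds, k-fold cross-validation of the four SUV metrics,
# Welch t-test and test-cohort reports.
#
# Rationale for CoV as the primary criterion: confounding by body habitus
# can only add variance on top of the tissue's true normal range, so the
# SUV metric with the smallest CoV is the least biased normalizer.

SUV_METRICS <- c("suv_bw", "suv_lbm", "suv_bsa", "suv_fdg")

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return The CoV as a fraction.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop_suvfdg("need at least 2 values for a CoV")
  m <- mean(values)
  if (m == 0) stop_suvfdg("CoV undefined for zero mean")
  stats::sd(values) / m
}

#' Coefficient of variation about a fitted line
#'
#' Regresses `y` on `x` by simple least squares and returns the residual
#' dispersion `sqrt(RSS / (n - 2))` divided by `mean(y)`. Compared with
#' the plain CoV this separates a habitus-driven trend from residual
#' scatter: for a metric with no trend, CoVf approaches the CoV. When `x`
#' is constant the regression is degenerate and the plain CoV is returned
#' with attribute `fallback = TRUE`.
#'
#' @param y Metric values, length >= 3.
#' @param x Covariate (e.g. weight), same length.
#' @return CoVf as a fraction (attribute `fallback` flags the degenerate
#'   constant-`x` case).
#' @export
cov_about_fit <- function(y, x) {
  if (length(y) < 3L || length(x) != length(y)) {
    stop_suvfdg("need n >= 3 and equal-length x, y")
  }
  if (stats::sd(x) == 0) {
    out <- coefficient_of_variation(y)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  out <- sqrt(rss / (length(y) - 2)) / mean(y)
  attr(out, "fallback") <- FALSE
  out
}

#' Pearson correlation test via the t-distribution
#'
#' Computes the sample Pearson correlation R and its two-tailed p-value
#' by converting R to a t-statistic, \eqn{t = R \sqrt{n-2} / \sqrt{1 -
#' R^2}}, referred to a t-distribution with `n - 2` degrees of freedom —
#' the probability of seeing a sample |R| that large when the true
#' population correlation is zero.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `R`, `t`, `p`, `n`, and `degenerate = TRUE` when
#'   |R| = 1 (p reported as 0).
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) {
    stop_suvfdg("need equal-length x, y with n >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_suvfdg("pearson_test undefined for constant input")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    return(list(R = r, t = sign(r) * Inf, p = 0, n = n, degenerate = TRUE))
  }
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(R = r, t = t, p = p, n = n, degenerate = FALSE)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param family_alpha Family-wise alpha level in (0, 1).
#' @param m Number of comparisons, >= 1.
#' @return The per-comparison threshold `family_alpha / m`.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m = 5) {
  if (length(m) != 1L || m < 1) stop_suvfdg("`m` must be >= 1")
  if (family_alpha <= 0 || family_alpha >= 1) {
    stop_suvfdg("`family_alpha` must be in (0, 1)")
  }
  family_alpha / m
}

# Per-fold statistics of the liver SUV panel: CoV plus correlation to
# weight and height for each metric.
#' @keywords internal
#' @noRd
fold_metric_stats <- function(panel, patients, fold_id, alpha) {
  idx <- match(panel$patient_id, patients$patient_id)
  w <- patients$weight_kg[idx]
  h <- patients$height_m[idx]
  do.call(rbind, lapply(SUV_METRICS, function(metric) {
    v <- panel[[metric]]
    ok <- !is.na(v)
    pw <- pearson_test(v[ok], w[ok])
    ph <- pearson_test(v[ok], h[ok])
    data.frame(
      fold = fold_id, metric = metric,
      cov = coefficient_of_variation(v[ok]),
      r_weight = pw$R, p_weight = pw$p,
      r_height = ph$R, p_height = ph$p,
      sig_weight = pw$p < alpha, sig_height = ph$p < alpha,
      n = sum(ok),
      stringsAsFactors = FALSE
    )
  }))
}

#' K-fold cross-validation of the SUV metrics
#'
#' Randomly partitions the cohort's liver patients into `k` near-equal
#' folds (seeded shuffle; remainders spread one per fold). For each fold
#' the model is fitted on the complement, SUVfdg on the held-out patients
#' is computed with those fold-out coefficients, and all four SUV metrics
#' are summarized by their CoV and Pearson correlation to height and
#' weight. Correlations are computed per fold and then summarized across
#' folds; significance is assessed at the Bonferroni-adjusted level
#' `alpha` (default 0.05/5 = 0.01, matching a five-test family regardless
#' of `k`).
#'
#' @param table A [cohort_table()] with liver measurements.
#' @param spec A [model_spec()]; defaults to model `A`.
#' @param k Number of folds, default 5.
#' @param seed Integer seed driving the single random partition.
#' @param alpha Per-comparison significance threshold; default
#'   `bonferroni_alpha(0.05, 5)`.
#' @param lbm_formula Passed to [compute_panel()].
#' @return An object of class `cv_report`: list with `folds` (per-fold,
#'   per-metric data frame), `summary` (per-metric mean and sd of CoV and
#'   correlations, significant-correlation counts), `coefficients`
#'   (k x p matrix of fold-out fits), `assignments` (patient_id -> fold),
#'   `k`, `seed`, `alpha`, `spec`.
#' @export
kfold_cross_validate <- function(table, spec = model_specs()$A, k = 5,
                                 seed = 1,
                                 alpha = bonferroni_alpha(0.05, 5),
                                 lbm_formula = "janmahasatian") {
  stopifnot(inherits(table, "cohort_table"))
  df <- liver_frame(table)
  n <- nrow(df)
  p_coef <- length(spec$height_powers) + length(spec$weight_powers) + 1L
  if (n < k * (p_coef + 2L)) {
    stop_suvfdg("cohort too small for ", k, "-fold CV of a ", p_coef,
                "-parameter model (need >= ", k * (p_coef + 2L),
                " liver patients, got ", n, ")")
  }
  # seeded shuffle, then near-equal contiguous folds
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold_of <- rep(seq_len(k), times = sizes)[order(perm)]
  names(fold_of) <- df$patient_id  # df order

  folds <- NULL
  coef_list <- vector("list", k)
  for (f in seq_len(k)) {
    held <- df$patient_id[fold_of == f]
    train_tab <- subset_cohort(table, setdiff(df$patient_id, held))
    fit <- fit_model(train_tab, spec)
    coef_list[[f]] <- fit$coefficients

    held_tab <- subset_cohort(table, held, tissues = "liver")
    # bw/lbm/bsa do not depend on the fit; overwrite bhn/suv_fdg with the
    # fold-out polynomial so any spec (not just model A) cross-validates
    panel <- suppressWarnings(
      compute_panel(held_tab, published_coefficients(),
                    lbm_formula = lbm_formula))
    dh <- build_design(held_tab, spec)
    bhn_out <- 100 * exp(drop(dh$X %*% fit$coefficients))
    panel$bhn <- bhn_out[match(panel$patient_id, dh$data$patient_id)]
    panel$suv_fdg <- suv_fdg(panel$pct_id_ml, panel$bhn)
    folds <- rbind(folds,
                   fold_metric_stats(panel, held_tab$patients, f, alpha))
  }
  coefficients <- do.call(rbind, coef_list)
  rownames(coefficients) <- paste0("fold", seq_len(k))

  summary <- do.call(rbind, lapply(SUV_METRICS, function(metric) {
    fr <- folds[folds$metric == metric, ]
    data.frame(
      metric = metric,
      cov_mean = mean(fr$cov), cov_sd = stats::sd(fr$cov),
      r_weight_mean = mean(fr$r_weight),
      r_weight_sd = stats::sd(fr$r_weight),
      p_weight_mean = mean(fr$p_weight),
      n_sig_weight = sum(fr$sig_weight),
      r_height_mean = mean(fr$r_height),
      r_height_sd = stats::sd(fr$r_height),
      p_height_mean = mean(fr$p_height),
      n_sig_height = sum(fr$sig_height),
      stringsAsFactors = FALSE
    )
  }))

  structure(
    list(folds = folds, summary = summary, coefficients = coefficients,
         assignments = fold_of, k = k, seed = seed, alpha = alpha,
         spec = spec),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(x$k, "-fold cross-validation (seed ", x$seed, ", model ",
      x$spec$name, ", alpha ", x$alpha, ")\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-8s CoV %.3f±%.3f | R(w) %+.3f±%.3f [%d sig] | R(h) %+.3f±%.3f [%d sig]\n",
      s$metric[i], s$cov_mean[i], s$cov_sd[i],
      s$r_weight_mean[i], s$r_weight_sd[i], s$n_sig_weight[i],
      s$r_height_mean[i], s$r_height_sd[i], s$n_sig_height[i]))
  }
  invisible(x)
}

#' Subset a cohort by patient and tissue
#'
#' @param table A [cohort_table()].
#' @param patient_ids Patient identifiers to keep.
#' @param tissues Optional tissue subset to keep.
#' @return A [cohort_table()] restricted to the requested patients (and
#'   tissues).
#' @export
subset_cohort <- function(table, patient_ids, tissues = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  p <- table$patients[table$patients$patient_id %in% patient_ids, ,
                      drop = FALSE]
  m <- table$measurements[
    table$measurements$patient_id %in% patient_ids, , drop = FALSE]
  if (!is.null(tissues)) m <- m[m$tissue %in% tissues, , drop = FALSE]
  rownames(p) <- rownames(m) <- NULL
  cohort_table(p, m)
}

#' Welch two-sample t-test
#'
#' Unpaired two-tailed two-sample t-test assuming unequal variances
#' (Welch statistic with Welch--Satterthwaite degrees of freedom).
#'
#' @param group1,group2 Numeric vectors, each n >= 2 with positive
#'   variance.
#' @return List with `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`, `t`,
#'   `df`, `p`.
#' @export
welch_t_test <- function(group1, group2) {
  if (length(group1) < 2L || length(group2) < 2L) {
    stop_suvfdg("each group needs n >= 2")
  }
  if (stats::sd(group1) == 0 || stats::sd(group2) == 0) {
    stop_suvfdg("welch_t_test undefined for zero-variance group")
  }
  ht <- stats::t.test(group1, group2, var.equal = FALSE,
                      alternative = "two.sided")
  list(
    mean1 = mean(group1), sd1 = stats::sd(group1), n1 = length(group1),
    mean2 = mean(group2), sd2 = stats::sd(group2), n2 = length(group2),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value
  )
}

#' Test-cohort evaluation report
#'
#' Fits the model once on the training cohort, then evaluates every
#' requested tissue in the test cohort: for each tissue and each of the
#' four SUV metrics, the CoV and the Pearson correlation (R, p) to
#' weight, height and age. Tissues absent from the test cohort are
#' omitted with a warning.
#'
#' @param train A [cohort_table()] with liver measurements.
#' @param test A [cohort_table()] with the tissues to evaluate.
#' @param spec A [model_spec()]; defaults to model `A`.
#' @param tissues Character vector of tissues to report.
#' @param lbm_formula Passed to [compute_panel()].
#' @return A data frame with one row per (tissue, metric): `tissue`,
#'   `metric`, `n`, `cov`, `r_weight`, `p_weight`, `r_height`,
#'   `p_height`, `r_age`, `p_age`. The training fit is attached as
#'   attribute `fit`.
#' @export
test_cohort_report <- function(train, test, spec = model_specs()$A,
                               tissues = c("liver", "blood", "spleen",
                                           "brain"),
                               lbm_formula = "janmahasatian") {
  fit <- fit_model(train, spec)
  coeffs <- as_bhn_coefficients(fit)
  panel <- suppressWarnings(
    compute_panel(test, coeffs, lbm_formula = lbm_formula))
  pts <- test$patients
  out <- NULL
  for (tis in tissues) {
    sub <- panel[panel$tissue == tis, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("tissue '", tis, "' absent from the test cohort; omitted",
              call. = FALSE)
      next
    }
    idx <- match(sub$patient_id, pts$patient_id)
    covs <- list(weight = pts$weight_kg[idx], height = pts$height_m[idx],
                 age = pts$age_y[idx])
    for (metric in SUV_METRICS) {
      v <- sub[[metric]]
      ok <- !is.na(v)
      row <- data.frame(tissue = tis, metric = metric, n = sum(ok),
                        cov = coefficient_of_variation(v[ok]),
                        stringsAsFactors = FALSE)
      for (cn in names(covs)) {
        pt <- pearson_test(v[ok], covs[[cn]][ok])
        row[[paste0("r_", cn)]] <- pt$R
        row[[paste0("p_", cn)]] <- pt$p
      }
      out <- rbind(out, row)
    }
  }
  if (is.null(out)) stop_suvfdg("none of the requested tissues present")
  attr(out, "fit") <- fit
  out
}

#' Write a cross-validation report
#'
#' Serializes a [kfold_cross_validate()] report as JSON (full structure,
#' seed included) and optionally the per-fold table as TSV.
#'
#' @param report A `cv_report`.
#' @param path JSON output path.
#' @param tsv Optional TSV path for the per-fold table.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path, tsv = NULL) {
  stopifnot(inherits(report, "cv_report"))
  obj <- list(
    k = report$k, seed = report$seed, alpha = report$alpha,
    model = report$spec$name,
    coefficients = apply(report$coefficients, 1, as.list),
    folds = report$folds, summary = report$summary
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  if (!is.null(tsv)) {
    utils::write.table(report$folds, tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
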