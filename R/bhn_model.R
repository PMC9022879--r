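# Polynomial model family on log inverse liver concentration,
# ordinary-least-squares fitting, and information-criteria model selection.
#
# The response is log(ml/%ID) = -log(liver %ID/ml), natural log. Modeling
# the log of the inverse concentration targets percent accuracy and
# guarantees a positive normalizer 100*exp(fit).

#' Define a polynomial model of height and weight
#'
#' A model specification is a set of height powers and weight powers plus
#' an intercept (always present). The built-in family ([model_specs()]):
#' \itemize{
#'   \item `H2`, `H3`, `H4` — 2nd/3rd/4th-order polynomials in height only;
#'   \item `A` — 3rd-order height plus linear weight (the model behind the
#'     published BHN);
#'   \item `B` — 2nd-order height plus linear weight;
#'   \item `C` — 3rd-order weight plus linear height (the habitus model
#'     that fails for small patients).
#' }
#'
#' @param height_powers Integer vector of positive height powers (may be
#'   empty).
#' @param weight_powers Integer vector of positive weight powers (may be
#'   empty).
#' @param name Label used in reports.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(height_powers, weight_powers = integer(),
                       name = NULL) {
  height_powers <- sort(unique(as.integer(height_powers)),
                        decreasing = TRUE)
  weight_powers <- sort(unique(as.integer(weight_powers)),
                        decreasing = TRUE)
  if (length(height_powers) == 0L && length(weight_powers) == 0L) {
    stop_suvfdg("a model needs at least one height or weight term")
  }
  if (any(c(height_powers, weight_powers) < 1L)) {
    stop_suvfdg("polynomial powers must be positive integers")
  }
  if (is.null(name)) {
    name <- paste0("h", paste(height_powers, collapse = ""),
                   if (length(weight_powers))
                     paste0("w", paste(weight_powers, collapse = "")))
  }
  structure(list(height_powers = height_powers,
                 weight_powers = weight_powers,
                 intercept = TRUE, name = name),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  terms <- c(sprintf("h^%d", x$height_powers),
             sprintf("w^%d", x$weight_powers), "1")
  cat("Model", x$name, ":", paste(terms, collapse = " + "), "\n")
  invisible(x)
}

#' @rdname model_spec
#' @param which Optional character vector selecting a subset by name.
#' @return `model_specs()` returns a named list of the built-in
#'   `model_spec` objects `H2`, `H3`, `H4`, `A`, `B`, `C`.
#' @export
model_specs <- function(which = NULL) {
  all <- list(
    H2 = model_spec(1:2, name = "H2"),
    H3 = model_spec(1:3, name = "H3"),
    H4 = model_spec(1:4, name = "H4"),
    A = model_spec(1:3, 1L, name = "A"),
    B = model_spec(1:2, 1L, name = "B"),
    C = model_spec(1L, 1:3, name = "C")
  )
  if (is.null(which)) return(all)
  unknown <- setdiff(which, names(all))
  if (length(unknown)) {
    stop_suvfdg("unknown model spec(s): ", paste(unknown, collapse = ", "))
  }
  all[which]
}

# Per-patient modeling frame: mean liver %ID/ml and demographics.
#' @keywords internal
#' @noRd
liver_frame <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  m <- table$measurements
  liver <- m[m$tissue == "liver", , drop = FALSE]
  p <- table$patients
  missing_liver <- setdiff(p$patient_id, liver$patient_id)
  if (length(missing_liver)) {
    warning(length(missing_liver),
            " patient(s) without a liver measurement excluded from the fit",
            call. = FALSE)
  }
  if (nrow(liver) == 0L) {
    stop_suvfdg("no liver measurements in the cohort")
  }
  bad <- liver$pct_id_ml <= 0 | !is.finite(liver$pct_id_ml)
  if (any(bad)) {
    stop_suvfdg("non-positive liver %ID/ml for patient(s) ",
                paste(unique(liver$patient_id[bad]), collapse = ", "))
  }
  pct <- tapply(liver$pct_id_ml, liver$patient_id, mean)
  ids <- names(pct)
  idx <- match(ids, p$patient_id)
  data.frame(
    patient_id = ids,
    height_m = p$height_m[idx],
    weight_kg = p$weight_kg[idx],
    age_y = p$age_y[idx],
    sex = p$sex[idx],
    pct_id_ml = as.numeric(pct),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Build the design matrix and response for a model fit
#'
#' The response is the natural log of the inverse per-patient mean liver
#' \%ID/ml, i.e. `log(ml/%ID)`. The basis has one column per height power
#' (descending), then one per weight power (descending), then the
#' intercept — so for model `A` the columns line up with the coefficients
#' `a, b, c, d, e`. Patients with several liver measurements contribute
#' their mean \%ID/ml; patients without a liver measurement are excluded
#' with a warning.
#'
#' @param table A [cohort_table()].
#' @param spec A [model_spec()].
#' @return A list with elements `X` (design matrix), `y` (response
#'   vector) and `data` (per-patient frame with demographics).
#' @export
build_design <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  df <- liver_frame(table)
  y <- log(1 / df$pct_id_ml)
  cols <- c(
    lapply(spec$height_powers, function(k) df$height_m^k),
    lapply(spec$weight_powers, function(k) df$weight_kg^k),
    list(rep(1, nrow(df)))
  )
  X <- do.call(cbind, cols)
  colnames(X) <- c(sprintf("h%d", spec$height_powers),
                   sprintf("w%d", spec$weight_powers), "(Intercept)")
  list(X = X, y = y, data = df)
}

#' Fit a BHN model by ordinary least squares
#'
#' Least-squares fit of `log(ml/%ID)` on the polynomial basis of `spec`,
#' with coefficient standard errors and 95\% confidence intervals from
#' the usual linear-model covariance \eqn{\hat\sigma^2 (X'X)^{-1}} and
#' t-quantiles on `n - p` degrees of freedom.
#'
#' @param table A [cohort_table()] with liver measurements.
#' @param spec A [model_spec()]; defaults to model `A`.
#' @return An object of class `bhn_fit`: a list with `spec`,
#'   `coefficients` (named vector), `se`, `ci95` (p x 2 matrix),
#'   `residuals`, `fitted`, `rss`, `tss`, `n`, `p`, `aic`, `bic`,
#'   `adj_r2` and `data` (the per-patient modeling frame).
#' @export
fit_model <- function(table, spec = model_specs()$A) {
  d <- build_design(table, spec)
  X <- d$X
  y <- d$y
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2L) {
    stop_suvfdg("need at least p + 2 = ", p + 2, " patients, got ", n)
  }
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):p]]
    stop_suvfdg("design is rank-deficient; collinear column(s): ",
                paste(dropped, collapse = ", "),
                class = "suvfdg_singular_error")
  }
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(diag(xtx_inv) * sigma2)
  names(se) <- colnames(X)
  tcrit <- stats::qt(0.975, df = n - p)
  ci95 <- cbind(lower = coefs - tcrit * se, upper = coefs + tcrit * se)
  ic <- information_criteria(rss = rss, tss = tss, n = n, p = p)
  structure(
    list(spec = spec, coefficients = coefs, se = se, ci95 = ci95,
         residuals = res, fitted = fit$fitted.values,
         rss = rss, tss = tss, n = n, p = p,
         aic = ic$aic, bic = ic$bic, adj_r2 = ic$adj_r2,
         data = d$data),
    class = "bhn_fit"
  )
}

#' @export
print.bhn_fit <- function(x, ...) {
  cat("BHN model fit —", x$spec$name, "(n =", x$n, ")\n")
  tab <- cbind(estimate = x$coefficients, se = x$se, x$ci95)
  print(round(tab, 5))
  cat(sprintf("RSS %.4f | AIC %.1f | BIC %.1f | adjR2 %.4f\n",
              x$rss, x$aic, x$bic, x$adj_r2))
  invisible(x)
}

#' Convert a model-A fit to BHN coefficients
#'
#' Maps the fitted `(h3, h2, h1, w1, intercept)` coefficients of a model-A
#' fit onto the `(a, b, c, d, e)` parameters of [bhn_coefficients()],
#' carrying the fit's 95\% confidence intervals along.
#'
#' @param fit A `bhn_fit` of a model with height powers \{1,2,3\} and
#'   weight power \{1\}.
#' @return A [bhn_coefficients()] object.
#' @export
as_bhn_coefficients <- function(fit) {
  stopifnot(inherits(fit, "bhn_fit"))
  s <- fit$spec
  if (!identical(s$height_powers, c(3L, 2L, 1L)) ||
      !identical(s$weight_powers, 1L)) {
    stop_suvfdg("only a model-A fit (h^3+h^2+h+w+1) maps onto BHN ",
                "coefficients a..e")
  }
  cf <- fit$coefficients
  ci <- fit$ci95
  bhn_coefficients(
    a = cf[["h3"]], b = cf[["h2"]], c = cf[["h1"]], d = cf[["w1"]],
    e = cf[["(Intercept)"]],
    ci95 = list(a = unname(ci["h3", ]), b = unname(ci["h2", ]),
                c = unname(ci["h1", ]), d = unname(ci["w1", ]),
                e = unname(ci["(Intercept)", ])),
    provenance = sprintf("fit:model-%s:n=%d", s$name, fit$n)
  )
}

#' Information criteria for a least-squares fit
#'
#' Gaussian profile-likelihood convention with the residual variance
#' counted as a parameter (`K = p + 1`):
#' \deqn{AIC = n \log(RSS/n) + 2K, \quad BIC = n \log(RSS/n) + K \log n}
#' and \eqn{adjR^2 = 1 - (RSS/(n-p)) / (TSS/(n-1))}. Additive constants
#' of the log-likelihood are dropped, so only differences between models
#' on the same data are meaningful. An exact fit (`rss == 0`) yields
#' `adj_r2 = 1` with `aic`/`bic` degenerate at `-Inf` and `degenerate =
#' TRUE`.
#'
#' @param fit A `bhn_fit`; alternatively supply `rss`, `tss`, `n`, `p`
#'   directly.
#' @param rss,tss,n,p Residual sum of squares, total sum of squares,
#'   number of observations, number of fitted coefficients.
#' @return List with `aic`, `bic`, `adj_r2`, `degenerate`.
#' @export
information_criteria <- function(fit = NULL, rss = fit$rss,
                                 tss = fit$tss, n = fit$n, p = fit$p) {
  if (rss < 0 || n <= p) stop_suvfdg("need rss >= 0 and n > p")
  k <- p + 1
  if (rss == 0) {
    return(list(aic = -Inf, bic = -Inf, adj_r2 = 1, degenerate = TRUE))
  }
  list(
    aic = n * log(rss / n) + 2 * k,
    bic = n * log(rss / n) + k * log(n),
    adj_r2 = 1 - (rss / (n - p)) / (tss / (n - 1)),
    degenerate = FALSE
  )
}

#' Compare candidate models on one cohort
#'
#' Fits every spec and tabulates AIC, BIC and adjusted R^2 (lower is
#' better for the criteria, higher for adjusted R^2); the best model per
#' criterion is flagged.
#'
#' @param table A [cohort_table()].
#' @param specs A list of [model_spec()] objects (>= 2); defaults to the
#'   full built-in family.
#' @return A data frame with one row per model: `model`, `n`, `p`, `rss`,
#'   `aic`, `bic`, `adj_r2`, and logical columns `best_aic`, `best_bic`,
#'   `best_adj_r2`. The fitted objects are attached as attribute `fits`.
#' @export
compare_models <- function(table, specs = model_specs()) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  if (length(specs) < 2L) {
    stop_suvfdg("need at least two model specs to compare")
  }
  fits <- lapply(specs, function(s) fit_model(table, s))
  out <- data.frame(
    model = vapply(fits, function(f) f$spec$name, character(1)),
    n = vapply(fits, function(f) f$n, numeric(1)),
    p = vapply(fits, function(f) f$p, numeric(1)),
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    adj_r2 = vapply(fits, function(f) f$adj_r2, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$best_aic <- out$aic == min(out$aic)
  out$best_bic <- out$bic == min(out$bic)
  out$best_adj_r2 <- out$adj_r2 == max(out$adj_r2)
  attr(out, "fits") <- fits
  out
}

#' Correlation of fit residuals with a habitus covariate
#'
#' Pearson test ([pearson_test()]) of the fit residuals against patient
#' height or weight. A well-specified habitus model leaves no residual
#' correlation with either covariate. Pediatric patients can be excluded
#' (e.g. under 12 years) so that the few small patients do not dominate
#' the correlation.
#'
#' @param fit A `bhn_fit`.
#' @param covariate `"height"` or `"weight"`.
#' @param exclude_under_age Optional age threshold in years; patients with
#'   `age < exclude_under_age` are dropped before the test.
#' @return List with `R`, `t`, `p`, `n_used`.
#' @export
residual_correlation <- function(fit, covariate = c("height", "weight"),
                                 exclude_under_age = NULL) {
  stopifnot(inherits(fit, "bhn_fit"))
  covariate <- match.arg(covariate)
  keep <- rep(TRUE, fit$n)
  if (!is.null(exclude_under_age)) {
    keep <- fit$data$age_y >= exclude_under_age
  }
  res <- fit$residuals[keep]
  x <- switch(covariate, height = fit$data$height_m,
              weight = fit$data$weight_kg)[keep]
  if (sum(keep) < 3L) stop_suvfdg("fewer than 3 residuals after exclusion")
  if (stats::sd(res) <= 1e-10) {  # exact interpolation up to roundoff
    stop_suvfdg("zero-variance residuals (exact fit); correlation ",
                "undefined", class = "suvfdg_degenerate_error")
  }
  pt <- pearson_test(x, res)
  list(R = pt$R, t = pt$t, p = pt$p, n_used = sum(keep))
}

#' Write a fit report as JSON
#'
#' @param fit A `bhn_fit`.
#' @param path Output path.
#' @param residuals_csv Optional path for a per-patient residuals CSV.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, residuals_csv = NULL) {
  stopifnot(inherits(fit, "bhn_fit"))
  obj <- list(
    model = fit$spec$name,
    coefficients = as.list(fit$coefficients),
    se = as.list(fit$se),
    ci95 = apply(fit$ci95, 1, as.numeric, simplify = FALSE),
    n = fit$n, p = fit$p, rss = fit$rss,
    aic = fit$aic, bic = fit$bic, adj_r2 = fit$adj_r2
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(residuals_csv)) {
    utils::write.csv(
      data.frame(patient_id = fit$data$patient_id,
                 residual = fit$residuals),
      residuals_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
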