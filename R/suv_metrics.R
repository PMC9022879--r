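# Body-habitus surrogates (BSA, LBM, BHN) and the four SUV metrics.

#' Du Bois body surface area
#'
#' The Du Bois & Du Bois power-law estimate
#' `0.007184 * height_cm^0.725 * weight_kg^0.425` in square meters, the
#' surrogate behind SUVbsa.
#'
#' @param height Height in meters, > 0. Vectorized.
#' @param weight Weight in kilograms, > 0.
#' @return Body surface area in m^2.
#' @export
bsa_dubois <- function(height, weight) {
  assert_positive(height, "height")
  assert_positive(weight, "weight")
  0.007184 * (height * 100)^0.725 * weight^0.425
}

#' Lean body mass estimate
#'
#' Sex-specific lean-body-mass estimates from height and weight. The
#' default Janmahasatian formula (the one behind the PERCIST SUL
#' convention) is
#' \deqn{male: 9270 W / (6680 + 216\,BMI)\quad
#'       female: 9270 W / (8780 + 244\,BMI)}
#' with \eqn{BMI = W / h^2}. The older James formula
#' (`1.10 W - 128 (W/h_{cm})^2` male, `1.07 W - 148 (W/h_{cm})^2` female)
#' is selectable; it can go non-positive for extreme obesity, in which
#' case an error is raised.
#'
#' @param weight Weight in kilograms, > 0. Vectorized.
#' @param height Height in meters, > 0.
#' @param sex `"female"` or `"male"` (vectorized, no missing values —
#'   callers should treat LBM-based metrics as unavailable when sex is
#'   unknown).
#' @param formula `"janmahasatian"` (default) or `"james"`.
#' @return Lean body mass in kilograms.
#' @export
lbm_estimate <- function(weight, height, sex,
                         formula = c("janmahasatian", "james")) {
  formula <- match.arg(formula)
  assert_positive(weight, "weight")
  assert_positive(height, "height")
  if (any(is.na(sex)) || !all(sex %in% SEXES)) {
    stop_suvfdg("`sex` must be 'female' or 'male' with no missing values")
  }
  male <- sex == "male"
  lbm <- if (formula == "janmahasatian") {
    bmi <- weight / height^2
    ifelse(male,
           9270 * weight / (6680 + 216 * bmi),
           9270 * weight / (8780 + 244 * bmi))
  } else {
    h_cm <- height * 100
    ifelse(male,
           1.10 * weight - 128 * (weight / h_cm)^2,
           1.07 * weight - 148 * (weight / h_cm)^2)
  }
  if (any(lbm <= 0)) {
    stop_suvfdg("LBM estimate non-positive; inputs outside the formula's ",
                "valid range")
  }
  lbm
}

#' Evaluate the body-habitus normalizer
#'
#' Computes `BHN(h, w) = 100 * exp(a h^3 + b h^2 + c h + d w + e)` in
#' milliliters. With the published coefficient set the function is
#' strictly increasing in both height and weight, but monotonicity is not
#' guaranteed for refitted coefficients; evaluation outside the
#' plausibility envelope therefore warns rather than refuses.
#'
#' @param height Height in meters. Vectorized.
#' @param weight Weight in kilograms.
#' @param coeffs A [bhn_coefficients()] object; defaults to the published
#'   set.
#' @param envelope Numeric vector `(h_min, h_max, w_min, w_max)` of the
#'   plausibility envelope; inputs outside it trigger a warning.
#' @return BHN in milliliters, strictly positive.
#' @export
bhn_evaluate <- function(height, weight,
                         coeffs = published_coefficients(),
                         envelope = c(0.6, 2.1, 5, 200)) {
  stopifnot(inherits(coeffs, "bhn_coefficients"))
  if (!all(is.finite(c(height, weight)))) {
    stop_suvfdg("height and weight must be finite")
  }
  outside <- height < envelope[1] | height > envelope[2] |
    weight < envelope[3] | weight > envelope[4]
  if (any(outside)) {
    warning(sum(outside), " input(s) outside the plausibility envelope ",
            "(height ", envelope[1], "-", envelope[2], " m, weight ",
            envelope[3], "-", envelope[4], " kg); BHN extrapolated",
            call. = FALSE)
  }
  100 * exp(coeffs$a * height^3 + coeffs$b * height^2 +
              coeffs$c * height + coeffs$d * weight + coeffs$e)
}

#' SUV metrics from \%ID/ml
#'
#' The four standardized-uptake-value metrics, each \%ID/ml multiplied by
#' a body-habitus normalizer:
#' \itemize{
#'   \item `suv_bw`: body weight in grams (1 g/ml assumed), so
#'     `pct_id_ml * 1000 * weight / 100` — unitless.
#'   \item `suv_lbm` (SUL): lean body mass in grams, same kernel.
#'   \item `suv_bsa`: body surface area, `(pct_id_ml / 100) * bsa`. The
#'     scale convention (no extra constant) only shifts the metric by a
#'     cohort-wide factor; every reported statistic (CoV, Pearson R) is
#'     scale-invariant.
#'   \item `suv_fdg`: the fitted BHN volume, `pct_id_ml * bhn / 100` —
#'     unitless and calibrated so normal liver averages 1.0.
#' }
#'
#' @param pct_id_ml Percent injected dose per ml (see [pct_id_per_ml()]).
#' @param weight Body weight in kilograms, > 0.
#' @return Numeric vector of SUV values.
#' @export
suv_bw <- function(pct_id_ml, weight) {
  assert_positive(weight, "weight")
  pct_id_ml * (1000 * weight) / 100
}

#' @rdname suv_bw
#' @param lbm Lean body mass in kilograms, > 0 (see [lbm_estimate()]).
#' @export
suv_lbm <- function(pct_id_ml, lbm) {
  assert_positive(lbm, "lbm")
  pct_id_ml * (1000 * lbm) / 100
}

#' @rdname suv_bw
#' @param bsa Body surface area in m^2, > 0 (see [bsa_dubois()]).
#' @export
suv_bsa <- function(pct_id_ml, bsa) {
  assert_positive(bsa, "bsa")
  (pct_id_ml / 100) * bsa
}

#' @rdname suv_bw
#' @param bhn Body-habitus normalizer volume in ml, > 0 (see
#'   [bhn_evaluate()]).
#' @export
suv_fdg <- function(pct_id_ml, bhn) {
  assert_positive(bhn, "bhn")
  pct_id_ml * bhn / 100
}

#' Compute the full SUV panel for a cohort
#'
#' One row per measurement with the \%ID/ml, the three habitus surrogates
#' (BSA, LBM, BHN) and all four SUV metrics. Patients with missing sex get
#' `NA` for `lbm` and `suv_lbm` only; all other metrics are computed.
#'
#' @param table A [cohort_table()].
#' @param coeffs [bhn_coefficients()] used for the BHN; defaults to the
#'   published set.
#' @param lbm_formula Passed to [lbm_estimate()].
#' @param envelope Passed to [bhn_evaluate()].
#' @return A data frame with columns `patient_id`, `tissue`,
#'   `uptake_min`, `pct_id_ml`, `bsa`, `lbm`, `bhn`, `suv_bw`, `suv_lbm`,
#'   `suv_bsa`, `suv_fdg`. The coefficient provenance and LBM formula are
#'   recorded as attributes `coeffs_provenance` and `lbm_formula`.
#' @export
compute_panel <- function(table, coeffs = published_coefficients(),
                          lbm_formula = c("janmahasatian", "james"),
                          envelope = c(0.6, 2.1, 5, 200)) {
  stopifnot(inherits(table, "cohort_table"))
  lbm_formula <- match.arg(lbm_formula)
  m <- table$measurements
  p <- table$patients
  idx <- match(m$patient_id, p$patient_id)
  h <- p$height_m[idx]
  w <- p$weight_kg[idx]
  sex <- p$sex[idx]

  bsa <- bsa_dubois(h, w)
  bhn <- bhn_evaluate(h, w, coeffs, envelope)
  lbm <- rep(NA_real_, length(h))
  known <- !is.na(sex)
  if (any(known)) {
    lbm[known] <- lbm_estimate(w[known], h[known], sex[known], lbm_formula)
  }

  out <- data.frame(
    patient_id = m$patient_id,
    tissue = m$tissue,
    uptake_min = m$uptake_min,
    pct_id_ml = m$pct_id_ml,
    bsa = bsa, lbm = lbm, bhn = bhn,
    suv_bw = suv_bw(m$pct_id_ml, w),
    suv_lbm = ifelse(is.na(lbm), NA_real_,
                     m$pct_id_ml * (1000 * ifelse(is.na(lbm), 1, lbm)) /
                       100),
    suv_bsa = suv_bsa(m$pct_id_ml, bsa),
    suv_fdg = suv_fdg(m$pct_id_ml, bhn),
    stringsAsFactors = FALSE
  )
  attr(out, "coeffs_provenance") <- coeffs$provenance
  attr(out, "lbm_formula") <- lbm_formula
  out
}
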