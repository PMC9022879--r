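# Small in-code fixtures shared across test files.

# Three adults with round numbers; liver %ID/ml chosen so SUVs are easy
# to verify by hand.
tiny_patients <- function() {
  data.frame(
    patient_id = c("p1", "p2", "p3"),
    sex = c("female", "male", "female"),
    age_y = c(45, 60, 30),
    height_m = c(1.62, 1.80, 1.55),
    weight_kg = c(70, 85, 58),
    injected_bq = c(2.59e8, 3.15e8, 2.15e8),
    cohort_role = "training",
    stringsAsFactors = FALSE
  )
}

tiny_measurements <- function() {
  data.frame(
    patient_id = c("p1", "p2", "p3"),
    tissue = "liver",
    uptake_min = c(60, 65, 58),
    conc_bq_ml = c(8000, 9000, 7000),
    stringsAsFactors = FALSE
  )
}

tiny_cohort <- function() {
  cohort_table(tiny_patients(), tiny_measurements())
}

# Noiseless cohort generated exactly from known model-A coefficients:
# log(ml/%ID) = a h^3 + b h^2 + c h + d w + e with no dispersion.
exact_cohort <- function(n = 40, coeffs = published_coefficients(),
                         seed = 11) {
  set.seed(seed)
  h <- runif(n, 0.9, 2.0)
  w <- runif(n, 15, 120)
  expo <- coeffs$a * h^3 + coeffs$b * h^2 + coeffs$c * h +
    coeffs$d * w + coeffs$e
  pct <- exp(-expo)
  patients <- data.frame(
    patient_id = sprintf("x%03d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    age_y = runif(n, 5, 80),
    height_m = h, weight_kg = w,
    injected_bq = 3.7e6 * w,
    stringsAsFactors = FALSE
  )
  meas <- data.frame(
    patient_id = patients$patient_id,
    tissue = "liver",
    uptake_min = 60,
    pct_id_ml = pct,
    stringsAsFactors = FALSE
  )
  cohort_table(patients, meas)
}

# Default synthetic training cohort, suppressing the uptake-window and
# envelope chatter that is irrelevant to most tests.
quiet_training <- function(seed) {
  generate_cohort(sim_config(seed = seed))$training
}
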