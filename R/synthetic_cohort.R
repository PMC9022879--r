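# Seeded synthetic-cohort generator.
#
# The generator emulates the statistical structure the analysis assumes —
# published demographic group moments, a liver uptake law equal to the
# published model-A polynomial plus lognormal dispersion, and blood /
# spleen / brain values calibrated to the printed normal ranges. It is
# not a kinetic model of FDG physiology.

#' Synthetic cohort configuration
#'
#' Defaults encode the reference cohort: a 330-patient training group
#' (153 adult women, 116 adult men, 61 pediatric), an 86-patient test
#' group (45/31/10) and a 65-patient brain-only group (14/29/22).
#' Demographics per group: adult women height N(1.62, 0.07^2) m and
#' weight 70 +/- 19 kg, adult men N(1.74, 0.09^2) and 83 +/- 20 kg,
#' pediatric (under 12 y) height N(1.17, 0.20^2) and weight 23 +/- 11 kg
#' coupled to height. Tissue uptake: liver log(ml/\%ID) follows the
#' model-A polynomial with the published coefficients plus N(0, 0.16^2)
#' noise (so true-coefficient liver SUVfdg is lognormal with CoV ~ 0.161);
#' blood SUVfdg 0.8 +/- 0.11, spleen mean 0.9 (an assumption — the
#' reference prints only the spleen CoV, 0.16), brain 3.1 +/- 0.6 for
#' adults and 4.7 +/- 0.9 for pediatric patients (18 y and under).
#'
#' @param n_training,n_test,n_brain Cohort sizes.
#' @param liver_log_sd Log-scale liver dispersion.
#' @param blood_mean,blood_sd,spleen_mean,spleen_cov Blood/spleen SUVfdg
#'   population parameters (lognormal).
#' @param brain_adult_mean,brain_adult_sd,brain_ped_mean,brain_ped_sd
#'   Brain SUVfdg normal parameters by age group.
#' @param brain_ped_age Age cut (years) separating pediatric from adult
#'   brain uptake (inclusive on the pediatric side).
#' @param pediatric_age_cut Demographic pediatric/adult cut in years.
#' @param dose_mbq_per_kg,dose_jitter Injected-dose rule: `weight *
#'   dose_mbq_per_kg` MBq with multiplicative uniform jitter of
#'   `+/- dose_jitter`; cancels out of every SUV and exists only to
#'   exercise the \%ID/ml path.
#' @param uptake_window Acquisition window (minutes) for simulated uptake
#'   times.
#' @param coeffs True liver-law coefficients ([bhn_coefficients()]).
#' @param seed Integer seed; every sampled quantity is reproducible from
#'   it.
#' @return An object of class `sim_config` (a named list, including the
#'   per-group demographic parameter blocks under `$groups` and the
#'   cohort compositions under `$composition`).
#' @export
sim_config <- function(n_training = 330, n_test = 86, n_brain = 65,
                       liver_log_sd = 0.16,
                       blood_mean = 0.8, blood_sd = 0.11,
                       spleen_mean = 0.9, spleen_cov = 0.16,
                       brain_adult_mean = 3.1, brain_adult_sd = 0.6,
                       brain_ped_mean = 4.7, brain_ped_sd = 0.9,
                       brain_ped_age = 18,
                       pediatric_age_cut = 12,
                       dose_mbq_per_kg = 3.7, dose_jitter = 0.1,
                       uptake_window = c(55, 75),
                       coeffs = published_coefficients(),
                       seed = 1) {
  if (any(c(liver_log_sd, blood_sd, spleen_cov, brain_adult_sd,
            brain_ped_sd) < 0)) {
    stop_suvfdg("dispersion parameters must be >= 0")
  }
  if (uptake_window[1] >= uptake_window[2]) {
    stop_suvfdg("uptake_window must be (low, high) with low < high")
  }
  groups <- list(
    female = list(sex = "female", height_mean = 1.62, height_sd = 0.07,
                  height_bounds = c(1.35, 1.95),
                  weight_mean = 70, weight_sd = 19,
                  age_range = c(13, 91)),
    male = list(sex = "male", height_mean = 1.74, height_sd = 0.09,
                height_bounds = c(1.40, 2.10),
                weight_mean = 83, weight_sd = 20,
                age_range = c(13, 91)),
    pediatric = list(sex = NA, height_mean = 1.17, height_sd = 0.20,
                     height_bounds = c(0.55, 1.80),
                     weight_mean = 23, weight_sd = 11,
                     weight_height_power = 2.5,
                     age_range = c(0.75, 12))
  )
  composition <- list(
    training = c(female = 153, male = 116, pediatric = 61) / 330,
    test = c(female = 45, male = 31, pediatric = 10) / 86,
    brain_only = c(female = 14, male = 29, pediatric = 22) / 65
  )
  structure(
    list(n_training = n_training, n_test = n_test, n_brain = n_brain,
         composition = composition, groups = groups,
         liver_log_sd = liver_log_sd,
         blood_mean = blood_mean, blood_sd = blood_sd,
         spleen_mean = spleen_mean, spleen_cov = spleen_cov,
         brain_adult_mean = brain_adult_mean,
         brain_adult_sd = brain_adult_sd,
         brain_ped_mean = brain_ped_mean, brain_ped_sd = brain_ped_sd,
         brain_ped_age = brain_ped_age,
         pediatric_age_cut = pediatric_age_cut,
         dose_mbq_per_kg = dose_mbq_per_kg, dose_jitter = dose_jitter,
         uptake_window = uptake_window, coeffs = coeffs, seed = seed),
    class = "sim_config"
  )
}

# ---- distribution helpers ---------------------------------------------

# moments E[h^k] of a truncated normal, by numerical quadrature
#' @keywords internal
#' @noRd
tnorm_moment <- function(k, mean, sd, lower, upper) {
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  stats::integrate(function(h) h^k * stats::dnorm(h, mean, sd) / z,
                   lower, upper, rel.tol = 1e-10)$value
}

# inverse-CDF sampler for a truncated normal (deterministic given RNG)
#' @keywords internal
#' @noRd
rtnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# lognormal (meanlog, sdlog) matched to an arithmetic mean and CoV
#' @keywords internal
#' @noRd
lognormal_params <- function(mean, cv) {
  sdlog2 <- log(1 + cv^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Adult weight model: weight = BMI * height^2 with BMI lognormal,
# independent of height within the group. The BMI parameters are solved
# in closed form from the truncated-normal height moments so the group
# weight mean and sd match the configured values.
#' @keywords internal
#' @noRd
adult_bmi_params <- function(g) {
  m2 <- tnorm_moment(2, g$height_mean, g$height_sd, g$height_bounds[1],
                     g$height_bounds[2])
  m4 <- tnorm_moment(4, g$height_mean, g$height_sd, g$height_bounds[1],
                     g$height_bounds[2])
  eb <- g$weight_mean / m2
  eb2 <- (g$weight_sd^2 + g$weight_mean^2) / m4
  if (eb2 <= eb^2) {
    stop_suvfdg("configured weight sd too small for the height spread")
  }
  sdlog2 <- log(eb2 / eb^2)
  list(meanlog = log(eb) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Pediatric weight model: weight = k * height^q * lognormal noise, with
# q fixed (allometric growth) and (k, noise CoV) solved so the group
# weight mean and sd match the configured values.
#' @keywords internal
#' @noRd
pediatric_weight_params <- function(g) {
  q <- g$weight_height_power
  mq <- tnorm_moment(q, g$height_mean, g$height_sd, g$height_bounds[1],
                     g$height_bounds[2])
  m2q <- tnorm_moment(2 * q, g$height_mean, g$height_sd,
                      g$height_bounds[1], g$height_bounds[2])
  k <- g$weight_mean / mq
  ex2 <- (g$weight_sd^2 + g$weight_mean^2) / (k^2 * m2q)
  if (ex2 <= 1) {
    stop_suvfdg("configured pediatric weight sd too small for the ",
                "height spread at power ", q)
  }
  list(k = k, q = q, cv = sqrt(ex2 - 1))
}

# largest-remainder allocation of n into groups by proportion; the
# reference compositions are exact counts, not random draws
#' @keywords internal
#' @noRd
allocate_groups <- function(n, proportions) {
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0)) {
    stop_suvfdg("group proportions must be non-negative and sum to 1")
  }
  raw <- n * proportions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

# ---- sampling ---------------------------------------------------------

#' Sample patient demographics
#'
#' Draws `n` patients with the configured group composition (exact
#' largest-remainder counts), truncated-normal heights, weights coupled
#' to height (adults: lognormal BMI times height squared; pediatric:
#' allometric power law times lognormal noise — both moment-matched to
#' the configured group mean/sd), uniform ages within the group range,
#' and injected activity from the dose rule. Pediatric sex is assigned
#' 50/50.
#'
#' @param n Number of patients (>= 0).
#' @param composition Named proportions over `female`, `male`,
#'   `pediatric`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param id_prefix Prefix for generated patient identifiers.
#' @return A patients data frame as used by [cohort_table()].
#' @export
sample_demographics <- function(n, composition, config = sim_config(),
                                seed = config$seed, id_prefix = "P") {
  stopifnot(inherits(config, "sim_config"))
  if (n == 0) {
    return(data.frame(patient_id = character(), sex = character(),
                      age_y = numeric(), height_m = numeric(),
                      weight_kg = numeric(), injected_bq = numeric(),
                      cohort_role = character(),
                      stringsAsFactors = FALSE))
  }
  counts <- allocate_groups(n, composition)
  with_seed(seed, {
    rows <- lapply(names(counts), function(gname) {
      ng <- counts[[gname]]
      if (ng == 0) return(NULL)
      g <- config$groups[[gname]]
      h <- rtnorm(ng, g$height_mean, g$height_sd, g$height_bounds[1],
                  g$height_bounds[2])
      if (gname == "pediatric") {
        pw <- pediatric_weight_params(g)
        ln <- lognormal_params(1, pw$cv)
        w <- pw$k * h^pw$q * stats::rlnorm(ng, ln$meanlog, ln$sdlog)
        sex <- sample(c("female", "male"), ng, replace = TRUE)
      } else {
        bp <- adult_bmi_params(g)
        w <- stats::rlnorm(ng, bp$meanlog, bp$sdlog) * h^2
        sex <- rep(g$sex, ng)
      }
      w <- pmin(pmax(w, 2.5), 295)  # plausibility clip, ~never active
      age <- stats::runif(ng, g$age_range[1], g$age_range[2])
      data.frame(sex = sex, age_y = age, height_m = h, weight_kg = w,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    jitter <- stats::runif(nrow(out), 1 - config$dose_jitter,
                           1 + config$dose_jitter)
    out$injected_bq <- config$dose_mbq_per_kg * 1e6 * out$weight_kg *
      jitter
    out$patient_id <- sprintf("%s%04d", id_prefix, seq_len(nrow(out)))
    out$cohort_role <- NA_character_
    rownames(out) <- NULL
    out[, c("patient_id", "sex", "age_y", "height_m", "weight_kg",
            "injected_bq", "cohort_role")]
  })
}

#' Sample tissue uptake for a set of patients
#'
#' Liver: `log(ml/%ID) = polyA(h, w; coeffs) + N(0, liver_log_sd^2)`, so
#' the true-coefficient liver SUVfdg equals `exp(-eps)` — lognormal with
#' CoV `sqrt(exp(sd^2) - 1)` (~0.161 at the default 0.16). Blood and
#' spleen true SUVfdg are lognormal with the configured mean/sd; brain is
#' normal with age-group-specific parameters. \%ID/ml is back-computed
#' as `true_suv_fdg * 100 / BHN_true(h, w)` and the stored concentration
#' as `%ID/ml * injected / 100`; uptake times are uniform in the window.
#'
#' @param patients A patients data frame (see [sample_demographics()]).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param tissues Tissues to simulate for every patient.
#' @return A list with `measurements` (as used by [cohort_table()]) and
#'   `truth` (data frame `patient_id`, `tissue`, `true_suv_fdg`).
#' @export
sample_uptake <- function(patients, config = sim_config(),
                          seed = config$seed, tissues = "liver") {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(patients)
  cf <- config$coeffs
  bhn_true <- suppressWarnings(
    bhn_evaluate(patients$height_m, patients$weight_kg, cf))
  win <- config$uptake_window

  with_seed(seed, {
    meas <- NULL
    truth <- NULL
    for (tis in tissues) {
      suv_true <- switch(
        tis,
        liver = exp(-stats::rnorm(n, 0, config$liver_log_sd)),
        blood = {
          lp <- lognormal_params(config$blood_mean,
                                 config$blood_sd / config$blood_mean)
          stats::rlnorm(n, lp$meanlog, lp$sdlog)
        },
        spleen = {
          lp <- lognormal_params(config$spleen_mean, config$spleen_cov)
          stats::rlnorm(n, lp$meanlog, lp$sdlog)
        },
        brain = {
          ped <- patients$age_y <= config$brain_ped_age
          mu <- ifelse(ped, config$brain_ped_mean, config$brain_adult_mean)
          sg <- ifelse(ped, config$brain_ped_sd, config$brain_adult_sd)
          v <- stats::rnorm(n, mu, sg)
          while (any(v <= 0)) {  # resample the (practically absent) tail
            bad <- v <= 0
            v[bad] <- stats::rnorm(sum(bad), mu[bad], sg[bad])
          }
          v
        },
        stop_suvfdg("unknown tissue: ", tis)
      )
      pct <- suv_true * 100 / bhn_true
      conc <- pct * patients$injected_bq / 100
      meas <- rbind(meas, data.frame(
        patient_id = patients$patient_id,
        tissue = tis,
        uptake_min = stats::runif(n, win[1], win[2]),
        conc_bq_ml = conc,
        pct_id_ml = pct,
        stringsAsFactors = FALSE
      ))
      truth <- rbind(truth, data.frame(
        patient_id = patients$patient_id, tissue = tis,
        true_suv_fdg = suv_true, stringsAsFactors = FALSE
      ))
    }
    list(measurements = meas, truth = truth)
  })
}

#' Generate a full synthetic cohort set
#'
#' Builds the training (liver only), test (liver, blood, spleen) and
#' brain-only cohorts with their configured sizes and compositions, plus
#' a truth sidecar holding the generating coefficients and every
#' measurement's true SUVfdg, for parameter-recovery and calibration
#' tests. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_cohort`: list with `training`,
#'   `test`, `brain_only` (each a [cohort_table()]), `truth` (list:
#'   `coefficients`, `seed`, `per_measurement` data frame) and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  build <- function(n, comp_name, role, prefix, tissues, offset) {
    pats <- sample_demographics(n, config$composition[[comp_name]],
                                config, seed = derive_seed(seed, offset),
                                id_prefix = prefix)
    if (nrow(pats) == 0) {
      return(list(table = cohort_table(pats), truth = NULL))
    }
    pats$cohort_role <- role
    up <- sample_uptake(pats, config, seed = derive_seed(seed, offset + 1),
                        tissues = tissues)
    list(table = cohort_table(pats, up$measurements), truth = up$truth)
  }
  tr <- build(config$n_training, "training", "training", "T", "liver", 1)
  te <- build(config$n_test, "test", "test", "S",
              c("liver", "blood", "spleen"), 3)
  br <- build(config$n_brain, "brain_only", "brain_only", "B", "brain", 5)
  structure(
    list(
      training = tr$table, test = te$table, brain_only = br$table,
      truth = list(
        coefficients = config$coeffs,
        seed = seed,
        per_measurement = rbind(tr$truth, te$truth, br$truth)
      ),
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort (seed ", x$truth$seed, ")\n", sep = "")
  cat("  training:  ", nrow(x$training$patients), "patients\n")
  cat("  test:      ", nrow(x$test$patients), "patients\n")
  cat("  brain-only:", nrow(x$brain_only$patients), "patients\n")
  invisible(x)
}

#' Write the truth sidecar of a synthetic cohort
#'
#' JSON sidecar with the generating coefficients, the seed, the key
#' dispersion settings and each measurement's true SUVfdg; used by
#' recovery tests and kept separate from the cohort CSVs.
#'
#' @param x A `synthetic_cohort`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(x, path) {
  stopifnot(inherits(x, "synthetic_cohort"))
  cf <- x$truth$coefficients
  obj <- list(
    seed = x$truth$seed,
    coefficients = list(a = cf$a, b = cf$b, c = cf$c, d = cf$d, e = cf$e,
                        provenance = cf$provenance),
    liver_log_sd = x$config$liver_log_sd,
    blood_mean = x$config$blood_mean, blood_sd = x$config$blood_sd,
    spleen_mean = x$config$spleen_mean,
    spleen_cov = x$config$spleen_cov,
    per_measurement = x$truth$per_measurement
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
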