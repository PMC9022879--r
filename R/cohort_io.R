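# Cohort container and delimited-text I/O.
#
# Canonical units throughout: height in meters, weight in kilograms,
# injected activity in becquerels, uptake time in minutes post injection,
# concentrations in Bq/ml decay-corrected to injection time.

TISSUES <- c("liver", "blood", "spleen", "brain")
SEXES <- c("female", "male")
COHORT_ROLES <- c("training", "test", "brain_only")

# Plausibility invariants on patient records (canonical units).
PATIENT_BOUNDS <- list(
  height_m = c(0.3, 2.5),
  weight_kg = c(2, 300),
  age_y = c(0, 120)
)

#' Construct a cohort table
#'
#' A cohort table couples one row per patient (demographics and injected
#' activity) with one row per tissue measurement (ROI mean concentration,
#' decay-corrected to injection time, and its uptake time). All values are
#' stored in canonical units: meters, kilograms, becquerels, minutes.
#'
#' @param patients A data frame with columns `patient_id`, `sex`
#'   (`"female"`/`"male"`, may be `NA`), `age_y`, `height_m`, `weight_kg`,
#'   `injected_bq` and optionally `cohort_role` (`"training"`, `"test"`,
#'   `"brain_only"` or `NA`).
#' @param measurements A data frame with columns `patient_id`, `tissue`
#'   (one of liver, blood, spleen, brain), `uptake_min`, and `pct_id_ml`
#'   and/or `conc_bq_ml`. If `pct_id_ml` is absent it is derived as
#'   `100 * conc_bq_ml / injected_bq` of the owning patient.
#' @return An object of class `cohort_table`: a list with elements
#'   `patients` and `measurements`.
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
cohort_table <- function(patients, measurements = NULL) {
  patients <- as.data.frame(patients)
  if (is.null(measurements)) {
    measurements <- data.frame(
      patient_id = character(), tissue = character(),
      uptake_min = numeric(), conc_bq_ml = numeric(),
      pct_id_ml = numeric(), stringsAsFactors = FALSE
    )
  }
  measurements <- as.data.frame(measurements)

  req_p <- c("patient_id", "sex", "age_y", "height_m", "weight_kg",
             "injected_bq")
  missing_p <- setdiff(req_p, names(patients))
  if (length(missing_p)) {
    stop_suvfdg("patients is missing column(s): ",
                paste(missing_p, collapse = ", "),
                class = "suvfdg_schema_error")
  }
  if (!"cohort_role" %in% names(patients)) {
    patients$cohort_role <- NA_character_
  }
  patients$patient_id <- as.character(patients$patient_id)

  if (anyDuplicated(patients$patient_id)) {
    stop_suvfdg("duplicate patient_id: ",
                paste(unique(patients$patient_id[
                  duplicated(patients$patient_id)]), collapse = ", "))
  }
  validate_patients(patients)

  if (nrow(measurements)) {
    req_m <- c("patient_id", "tissue", "uptake_min")
    missing_m <- setdiff(req_m, names(measurements))
    if (length(missing_m)) {
      stop_suvfdg("measurements is missing column(s): ",
                  paste(missing_m, collapse = ", "),
                  class = "suvfdg_schema_error")
    }
    measurements$patient_id <- as.character(measurements$patient_id)
    if (!"conc_bq_ml" %in% names(measurements)) {
      measurements$conc_bq_ml <- NA_real_
    }
    if (!"pct_id_ml" %in% names(measurements)) {
      idx <- match(measurements$patient_id, patients$patient_id)
      measurements$pct_id_ml <-
        100 * measurements$conc_bq_ml / patients$injected_bq[idx]
    }
    orphans <- setdiff(measurements$patient_id, patients$patient_id)
    if (length(orphans)) {
      stop_suvfdg("measurements reference unknown patient_id: ",
                  paste(orphans, collapse = ", "))
    }
    validate_measurements(measurements)
  } else {
    for (col in c("conc_bq_ml", "pct_id_ml")) {
      if (!col %in% names(measurements)) measurements[[col]] <- numeric()
    }
  }

  structure(list(patients = patients, measurements = measurements),
            class = "cohort_table")
}

#' @keywords internal
#' @noRd
validate_patients <- function(patients) {
  problems <- character()
  check <- function(ok, msg) {
    bad <- which(!ok)
    if (length(bad)) {
      problems <<- c(problems, paste0(
        "patient row ", paste(bad, collapse = ","), ": ", msg))
    }
  }
  sx <- patients$sex
  check(is.na(sx) | sx %in% SEXES, "sex must be 'female' or 'male'")
  b <- PATIENT_BOUNDS
  check(is.finite(patients$height_m) &
          patients$height_m > b$height_m[1] &
          patients$height_m < b$height_m[2],
        sprintf("height_m must be in (%g, %g) m", b$height_m[1],
                b$height_m[2]))
  check(is.finite(patients$weight_kg) &
          patients$weight_kg > b$weight_kg[1] &
          patients$weight_kg < b$weight_kg[2],
        sprintf("weight_kg must be in (%g, %g) kg", b$weight_kg[1],
                b$weight_kg[2]))
  check(is.finite(patients$injected_bq) & patients$injected_bq > 0,
        "injected_bq must be > 0")
  check(is.finite(patients$age_y) & patients$age_y >= 0 &
          patients$age_y < b$age_y[2],
        "age_y must be in [0, 120) years")
  rl <- patients$cohort_role
  check(is.na(rl) | rl %in% COHORT_ROLES,
        "cohort_role must be training, test or brain_only")
  if (length(problems)) {
    stop_suvfdg(paste(problems, collapse = "\n"),
                class = "suvfdg_row_error")
  }
  invisible(patients)
}

#' @keywords internal
#' @noRd
validate_measurements <- function(measurements) {
  problems <- character()
  check <- function(ok, msg) {
    bad <- which(!ok)
    if (length(bad)) {
      problems <<- c(problems, paste0(
        "measurement row ", paste(bad, collapse = ","), ": ", msg))
    }
  }
  check(measurements$tissue %in% TISSUES,
        paste0("tissue must be one of ", paste(TISSUES, collapse = ", ")))
  check(is.finite(measurements$uptake_min) & measurements$uptake_min > 0,
        "uptake_min must be > 0")
  check(is.finite(measurements$pct_id_ml) & measurements$pct_id_ml > 0,
        "pct_id_ml must be > 0")
  check(is.na(measurements$conc_bq_ml) |
          (is.finite(measurements$conc_bq_ml) &
             measurements$conc_bq_ml > 0),
        "conc_bq_ml must be > 0 when present")
  if (length(problems)) {
    stop_suvfdg(paste(problems, collapse = "\n"),
                class = "suvfdg_row_error")
  }
  invisible(measurements)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x$patients), "patients,",
      nrow(x$measurements), "measurements\n")
  if (nrow(x$measurements)) {
    tab <- table(x$measurements$tissue)
    cat("  tissues:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  roles <- table(x$patients$cohort_role, useNA = "no")
  if (length(roles)) {
    cat("  roles:  ", paste(names(roles), roles, sep = "=",
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a cohort file
#'
#' Reads a delimited text file with one row per (patient, tissue)
#' measurement, patient demographics repeated on every row. Recognised
#' columns: `patient_id`, `sex`, `age_y`, `height_m` or `height_cm`,
#' `weight_kg`, `injected_bq` or `injected_mbq`, `tissue`, `uptake_min`,
#' `conc_bq_ml` and/or `pct_id_ml`, optional `cohort_role`. Rows with an
#' empty `tissue` carry a patient without measurements.
#'
#' Heights given in centimeters and activities in megabecquerels are
#' converted to the canonical meters/becquerels on read. Demographics
#' repeated across rows of one patient must agree exactly; when both a
#' raw concentration and a precomputed `pct_id_ml` are present they must
#' agree within 0.1\% relative.
#'
#' @param path Path to a delimited text file with a header.
#' @param units Optional list overriding unit autodetection, with elements
#'   `height` (`"m"` or `"cm"`) and `activity` (`"Bq"` or `"MBq"`)
#'   applying to generically named `height` / `injected` columns.
#' @param sep Field separator, default comma.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, units = NULL, sep = ",") {
  if (!file.exists(path)) {
    stop_suvfdg("file not found: ", path, class = "suvfdg_io_error")
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = c(patient_id = "character"),
                           na.strings = c("NA", ""))

  # resolve height column -> height_m
  if ("height_m" %in% names(raw)) {
    height_m <- as.numeric(raw$height_m)
  } else if ("height_cm" %in% names(raw)) {
    height_m <- as.numeric(raw$height_cm) / 100
  } else if ("height" %in% names(raw) && !is.null(units$height)) {
    height_m <- as.numeric(raw$height) /
      switch(units$height, m = 1, cm = 100,
             stop_suvfdg("units$height must be 'm' or 'cm'"))
  } else {
    stop_suvfdg("no height column (height_m, height_cm, or height + units)",
                class = "suvfdg_schema_error")
  }

  # resolve activity column -> injected_bq
  if ("injected_bq" %in% names(raw)) {
    injected_bq <- as.numeric(raw$injected_bq)
  } else if ("injected_mbq" %in% names(raw)) {
    injected_bq <- as.numeric(raw$injected_mbq) * 1e6
  } else if ("injected" %in% names(raw) && !is.null(units$activity)) {
    injected_bq <- as.numeric(raw$injected) *
      switch(units$activity, Bq = 1, MBq = 1e6,
             stop_suvfdg("units$activity must be 'Bq' or 'MBq'"))
  } else {
    stop_suvfdg("no activity column (injected_bq, injected_mbq, or ",
                "injected + units)", class = "suvfdg_schema_error")
  }

  req <- c("patient_id", "sex", "age_y", "weight_kg")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop_suvfdg("missing required column(s): ",
                paste(missing_cols, collapse = ", "),
                class = "suvfdg_schema_error")
  }

  numeric_in <- list(age_y = raw$age_y, weight_kg = raw$weight_kg,
                     height_m = height_m, injected_bq = injected_bq)
  for (nm in names(numeric_in)) {
    # read.table coerces unparseable numerics to NA
    bad <- which(is.na(numeric_in[[nm]]))
    if (length(bad)) {
      stop_suvfdg("unparseable or missing ", nm, " in data row(s) ",
                  paste(bad, collapse = ", "), class = "suvfdg_row_error")
    }
  }

  pat <- data.frame(
    patient_id = as.character(raw$patient_id),
    sex = if ("sex" %in% names(raw)) as.character(raw$sex) else
      NA_character_,
    age_y = as.numeric(raw$age_y),
    height_m = height_m,
    weight_kg = as.numeric(raw$weight_kg),
    injected_bq = injected_bq,
    cohort_role = if ("cohort_role" %in% names(raw))
      as.character(raw$cohort_role) else NA_character_,
    stringsAsFactors = FALSE
  )

  # collapse to one patient row, demanding exact demographic consistency
  first_idx <- !duplicated(pat$patient_id)
  patients <- pat[first_idx, , drop = FALSE]
  rownames(patients) <- NULL
  for (pid in patients$patient_id) {
    rows <- pat[pat$patient_id == pid, , drop = FALSE]
    if (nrow(unique(rows)) != 1L) {
      stop_suvfdg("inconsistent demographics across rows of patient ", pid,
                  class = "suvfdg_row_error")
    }
  }

  has_tissue <- if ("tissue" %in% names(raw)) !is.na(raw$tissue) else
    rep(FALSE, nrow(raw))
  meas <- NULL
  if (any(has_tissue)) {
    mrows <- which(has_tissue)
    if (!"uptake_min" %in% names(raw)) {
      stop_suvfdg("missing required column(s): uptake_min",
                  class = "suvfdg_schema_error")
    }
    conc <- if ("conc_bq_ml" %in% names(raw))
      as.numeric(raw$conc_bq_ml[mrows]) else NA_real_
    pct <- if ("pct_id_ml" %in% names(raw))
      as.numeric(raw$pct_id_ml[mrows]) else NULL
    inj <- injected_bq[mrows]
    if (!is.null(pct) && any(!is.na(conc))) {
      derived <- 100 * conc / inj
      both <- which(!is.na(conc) & !is.na(pct))
      rel <- abs(derived[both] - pct[both]) / pct[both]
      if (any(rel > 1e-3)) {
        stop_suvfdg("conc_bq_ml and pct_id_ml disagree by more than 0.1% ",
                    "in data row(s) ",
                    paste(mrows[both[rel > 1e-3]], collapse = ", "),
                    class = "suvfdg_row_error")
      }
    }
    if (is.null(pct)) pct <- 100 * conc / inj
    pct[is.na(pct)] <- (100 * conc / inj)[is.na(pct)]
    meas <- data.frame(
      patient_id = as.character(raw$patient_id[mrows]),
      tissue = as.character(raw$tissue[mrows]),
      uptake_min = as.numeric(raw$uptake_min[mrows]),
      conc_bq_ml = conc,
      pct_id_ml = pct,
      stringsAsFactors = FALSE
    )
  }
  cohort_table(patients, meas)
}

#' Write a cohort file
#'
#' Inverse of [read_cohort()]: writes one CSV row per measurement with the
#' owning patient's demographics repeated, in canonical units. Patients
#' without measurements are written as a single row with empty tissue
#' fields. `read_cohort(write_cohort(t))` reproduces `t` field for field,
#' and writing the same table twice yields byte-identical files.
#'
#' @param table A [cohort_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  p <- table$patients
  m <- table$measurements
  if (nrow(m)) {
    idx <- match(m$patient_id, p$patient_id)
    out <- data.frame(
      patient_id = m$patient_id,
      sex = p$sex[idx], age_y = p$age_y[idx],
      height_m = p$height_m[idx], weight_kg = p$weight_kg[idx],
      injected_bq = p$injected_bq[idx],
      cohort_role = p$cohort_role[idx],
      tissue = m$tissue, uptake_min = m$uptake_min,
      conc_bq_ml = m$conc_bq_ml, pct_id_ml = m$pct_id_ml,
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      patient_id = character(), sex = character(), age_y = numeric(),
      height_m = numeric(), weight_kg = numeric(),
      injected_bq = numeric(), cohort_role = character(),
      tissue = character(), uptake_min = numeric(),
      conc_bq_ml = numeric(), pct_id_ml = numeric(),
      stringsAsFactors = FALSE
    )
  }
  lone <- setdiff(p$patient_id, m$patient_id)
  if (length(lone)) {
    idx <- match(lone, p$patient_id)
    out <- rbind(out, data.frame(
      patient_id = lone,
      sex = p$sex[idx], age_y = p$age_y[idx],
      height_m = p$height_m[idx], weight_kg = p$weight_kg[idx],
      injected_bq = p$injected_bq[idx],
      cohort_role = p$cohort_role[idx],
      tissue = NA_character_, uptake_min = NA_real_,
      conc_bq_ml = NA_real_, pct_id_ml = NA_real_,
      stringsAsFactors = FALSE
    ))
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_suvfdg("cannot write to ", path, class = "suvfdg_io_error")
  invisible(path)
}

#' Decay-correct a radioactivity concentration
#'
#' References a measured activity concentration back to injection time by
#' undoing radioactive decay over the elapsed interval:
#' `concentration * 2^(elapsed / half_life)`.
#'
#' @param concentration Measured concentration (Bq/ml), vectorized.
#' @param elapsed Minutes between injection and measurement, >= 0.
#' @param half_life Isotope half-life in minutes; defaults to F-18
#'   ([F18_HALF_LIFE_MIN]).
#' @return Decay-corrected concentration (Bq/ml).
#' @export
decay_correct <- function(concentration, elapsed,
                          half_life = F18_HALF_LIFE_MIN) {
  if (any(!is.finite(elapsed)) || any(elapsed < 0)) {
    stop_suvfdg("`elapsed` must be finite and >= 0")
  }
  assert_positive(half_life, "half_life")
  concentration * 2^(elapsed / half_life)
}

#' Percent injected dose per milliliter
#'
#' Converts a decay-corrected concentration into \%ID/ml:
#' `100 * concentration / injected_activity`. This is the dose-normalized
#' quantity every SUV metric is built on.
#'
#' @param concentration Decay-corrected concentration (Bq/ml), vectorized.
#' @param injected_activity Injected activity (Bq), > 0.
#' @return \%ID/ml.
#' @export
pct_id_per_ml <- function(concentration, injected_activity) {
  assert_positive(injected_activity, "injected_activity")
  100 * concentration / injected_activity
}

#' Restrict a cohort to an uptake-time window
#'
#' Keeps only measurements whose uptake time lies within `[low, high]`
#' minutes post injection. The default 55--75 minute window is the
#' EANM/QIBA-recommended acquisition window for FDG SUV measurements.
#' Patients are never dropped, only their out-of-window measurements.
#'
#' @param table A [cohort_table()].
#' @param low,high Window bounds in minutes, `low < high`.
#' @return The filtered [cohort_table()]; the number of removed
#'   measurements is reported via `message()`, and a warning is raised if
#'   no measurements remain.
#' @export
filter_uptake_window <- function(table, low = 55, high = 75) {
  stopifnot(inherits(table, "cohort_table"))
  if (!(low < high)) stop_suvfdg("`low` must be < `high`")
  m <- table$measurements
  keep <- m$uptake_min >= low & m$uptake_min <= high
  removed <- sum(!keep)
  message("filter_uptake_window: removed ", removed, " of ", nrow(m),
          " measurements outside [", low, ", ", high, "] min")
  out <- table
  out$measurements <- m[keep, , drop = FALSE]
  rownames(out$measurements) <- NULL
  if (nrow(out$measurements) == 0L && nrow(m) > 0L) {
    warning("all measurements fall outside the uptake window",
            call. = FALSE)
  }
  out
}
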