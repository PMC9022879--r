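#' Half-life of fluorine-18 in minutes
#'
#' Used as the default half-life for [decay_correct()].
#' @export
F18_HALF_LIFE_MIN <- 109.77

#' Construct a set of BHN model coefficients
#'
#' The body-habitus normalizer (BHN) is the function
#' \deqn{BHN(h, w) = 100 \exp(a h^3 + b h^2 + c h + d w + e)}
#' in milliliters, with height \eqn{h} in meters and weight \eqn{w} in
#' kilograms. It predicts the inverse of the normal-liver \%ID/ml of an
#' FDG-PET patient and defines the SUVfdg metric (see [suv_fdg()]).
#'
#' @param a,b,c,d,e Real coefficients of the exponent polynomial:
#'   `a`, `b`, `c` multiply height cubed, squared and linear terms, `d`
#'   multiplies weight, `e` is the intercept.
#' @param ci95 Optional named list of length-2 numeric vectors
#'   (`lower, upper`) giving 95\% confidence intervals per coefficient.
#' @param provenance Free-text origin label carried through to output files.
#' @return An object of class `bhn_coefficients`: a named list with
#'   elements `a`..`e`, `ci95` and `provenance`.
#' @seealso [published_coefficients()], [bhn_evaluate()]
#' @export
bhn_coefficients <- function(a, b, c, d, e, ci95 = NULL, provenance = "user") {
  vals <- c(a = a, b = b, c = c, d = d, e = e)
  if (any(!is.finite(vals))) {
    stop_suvfdg("BHN coefficients must all be finite")
  }
  if (!is.null(ci95)) {
    if (!all(names(ci95) %in% names(vals))) {
      stop_suvfdg("ci95 names must be among a, b, c, d, e")
    }
    for (nm in names(ci95)) {
      ci <- ci95[[nm]]
      if (length(ci) != 2L || ci[1] > ci[2]) {
        stop_suvfdg("ci95 entries must be (lower, upper) pairs")
      }
      if (vals[[nm]] < ci[1] || vals[[nm]] > ci[2]) {
        stop_suvfdg("coefficient ", nm, " lies outside its own ci95")
      }
    }
  }
  structure(
    list(a = a, b = b, c = c, d = d, e = e, ci95 = ci95,
         provenance = provenance),
    class = "bhn_coefficients"
  )
}

#' Published BHN coefficient set
#'
#' The reference coefficient values for the body-habitus normalizer,
#' determined from a 330-patient training cohort, together with their
#' printed 95\% confidence intervals. With these coefficients, normal
#' liver at about 60 minutes post injection has SUVfdg near 1.0 with a
#' coefficient of variation near 0.16, which is what makes SUVfdg usable
#' as a quick quality-assurance check on dose, timing and height/weight
#' data entry.
#'
#' @param set Name of the built-in set; only `"published-2022"` exists.
#' @return A [bhn_coefficients()] object.
#' @export
published_coefficients <- function(set = "published-2022") {
  if (!identical(set, "published-2022")) {
    stop_suvfdg("unknown built-in coefficient set: ", set)
  }
  bhn_coefficients(
    a = 2.03, b = -9.07, c = 13.94, d = 0.00539, e = -2.04,
    ci95 = list(
      a = c(1.13, 2.93),
      b = c(-12.92, -5.22),
      c = c(8.56, 19.33),
      d = c(0.00438, 0.00641),
      e = c(-4.49, 0.41)
    ),
    provenance = "published-2022"
  )
}

#' @export
print.bhn_coefficients <- function(x, ...) {
  cat("BHN coefficients (", x$provenance, ")\n", sep = "")
  for (nm in c("a", "b", "c", "d", "e")) {
    ci <- x$ci95[[nm]]
    cat(sprintf("  %s = %g", nm, x[[nm]]))
    if (!is.null(ci)) cat(sprintf("  [95%% CI %g, %g]", ci[1], ci[2]))
    cat("\n")
  }
  invisible(x)
}

#' Read or write BHN coefficients as JSON
#'
#' The on-disk form is a JSON object with keys `a`..`e`, optional `ci95`
#' (object of `[lower, upper]` pairs) and `provenance`.
#'
#' @param path File path.
#' @return `read_coefficients()` returns a [bhn_coefficients()] object;
#'   `write_coefficients()` returns `path` invisibly.
#' @export
read_coefficients <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ci95 <- NULL
  if (!is.null(obj$ci95)) {
    ci95 <- lapply(obj$ci95, as.numeric)
  }
  bhn_coefficients(
    a = obj$a, b = obj$b, c = obj$c, d = obj$d, e = obj$e,
    ci95 = ci95,
    provenance = if (is.null(obj$provenance)) "file" else obj$provenance
  )
}

#' @rdname read_coefficients
#' @param coeffs A [bhn_coefficients()] object.
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "bhn_coefficients"))
  obj <- list(a = coeffs$a, b = coeffs$b, c = coeffs$c, d = coeffs$d,
              e = coeffs$e)
  if (!is.null(coeffs$ci95)) obj$ci95 <- coeffs$ci95
  obj$provenance <- coeffs$provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
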