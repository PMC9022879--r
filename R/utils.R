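# Internal helpers shared across the package.

#' @keywords internal
#' @noRd
stop_suvfdg <- function(..., class = "suvfdg_error", call. = FALSE) {
  stop(structure(
    class = c(class, "suvfdg_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

# Run code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library code never perturbs it.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_suvfdg("`seed` must be a single finite number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed from a base seed, kept within 32-bit range.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset)
}

#' @keywords internal
#' @noRd
assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_suvfdg("`", name, "` must be finite and > 0")
  }
  invisible(x)
}

# FNV-1a hash of a character scalar, hex string; used to fingerprint CLI
# configurations in logs (no cryptographic intent).
#' @keywords internal
#' @noRd
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
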