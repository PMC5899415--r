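# Shared numerical helpers and condition classes.
#
# Error classes (all inherit "ssblend_error"):
#   ssblend_error_parse      malformed input file
#   ssblend_error_structure  dimension mismatch / pedigree cycle
#   ssblend_error_ids        id-mapping problems
#   ssblend_error_singular   numerically singular SPD input (names the role)
#   ssblend_error_non_psd    blend combination outside the valid region
#   ssblend_error_degenerate degenerate input (e.g. all markers monomorphic)

ss_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("ssblend_error_", class), "ssblend_error"), ...)
}

#' Empirical variance with denominator n
#'
#' Population-style variance \eqn{\frac{1}{n}\sum x_i^2 - \bar{x}^2}, the
#' definition used throughout the variance-ordering results (deliberately not
#' the sample variance with denominator n - 1).
#'
#' @param x numeric vector.
#' @return A single number.
#' @export
empirical_var <- function(x) {
  mean(x^2) - mean(x)^2
}

# Symmetry check with relative tolerance; errors beyond tolerance.
check_symmetric <- function(M, tol = 1e-8, what = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    ss_abort(sprintf("%s must be a square matrix", what), "structure")
  }
  scale <- max(1, max(abs(M)))
  dev <- max(abs(M - t(M)))
  if (dev > tol * scale) {
    ss_abort(
      sprintf("%s is not symmetric (max deviation %.3g, tolerance %.3g)",
              what, dev, tol * scale),
      "structure"
    )
  }
  (M + t(M)) / 2
}

# Relative max-abs difference used by equivalence checks.
rel_maxabs <- function(X, Y) {
  max(abs(X - Y)) / max(1e-300, max(abs(Y)))
}

scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ss_abort(sprintf("%s must be a single finite number", what), "structure")
  }
  as.numeric(x)
}

# Format a number the way all text outputs do (%.12g, locale-independent).
fmt_num <- function(x) sprintf("%.12g", x)
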