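#' VanRaden genomic relationship matrix
#'
#' Computes \eqn{G = (Z - P)(Z - P)^T / \sum_j c\, p_j (1 - p_j)}, where P
#' holds the observed column means of Z in every row. Two marker codings are
#' supported:
#'
#' * `presence01`: dominant presence/absence markers (DArT-like), entries in
#'   \{0, 1\}; `c = 1` and `p_j` is the column mean.
#' * `dosage012`: biallelic allele dosages, entries in \{0, 1, 2\}; `c = 2`
#'   and `p_j` is half the column mean.
#'
#' Because the columns are centered at their observed means, every row and
#' column of G sums to zero, so G is structurally singular; see [g_adjust()]
#' for the blending used before inversion.
#'
#' @param Z marker matrix, rows = genotyped individuals (with rownames),
#'   columns = markers. No missing values are accepted.
#' @param coding `"presence01"` (default) or `"dosage012"`.
#' @return Symmetric genomic relationship matrix with the ids of `Z`.
#' @examples
#' Z <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "m1"))
#' g_vanraden(Z)  # [[1, -1], [-1, 1]]
#' @export
g_vanraden <- function(Z, coding = c("presence01", "dosage012")) {
  coding <- match.arg(coding)
  if (!is.matrix(Z) || is.null(rownames(Z))) {
    ss_abort("marker matrix must be a matrix with individual rownames", "structure")
  }
  if (anyNA(Z)) {
    ss_abort("missing genotypes are not accepted; impute or drop beforehand",
             "parse")
  }
  allowed <- if (coding == "presence01") c(0, 1) else c(0, 1, 2)
  if (!all(Z %in% allowed)) {
    ss_abort(sprintf("marker values outside {%s} for coding '%s'",
                     paste(allowed, collapse = ","), coding), "parse")
  }
  cm <- colMeans(Z)
  p <- if (coding == "presence01") cm else cm / 2
  cc <- if (coding == "presence01") 1 else 2
  den <- sum(cc * p * (1 - p))
  if (den <= 0) {
    ss_abort("all markers are monomorphic; genomic relationship undefined",
             "degenerate")
  }
  W <- sweep(Z, 2, cm)
  G <- tcrossprod(W) / den
  dimnames(G) <- list(rownames(Z), rownames(Z))
  (G + t(G)) / 2
}

#' Blend the genomic matrix towards A22 before inversion
#'
#' The centered VanRaden matrix is singular, while the single-step inverse
#' needs an invertible G. The standard remedy is
#' `G* = (1 - beta) * G + beta * A22 + ridge * I` with a small `beta`
#' (default 0.05). With `beta = 0` and `ridge = 0` the matrix is returned
#' unchanged and a later [invert_spd()] will raise the singularity error.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationships of the genotyped group, same ids.
#' @param beta weight on A22, in `[0, 1)`; default 0.05.
#' @param ridge additional diagonal added after blending; default 0.
#' @return The adjusted matrix, with `beta` and `ridge` recorded in
#'   attributes `"beta"` and `"ridge"`.
#' @export
g_adjust <- function(G, A22, beta = 0.05, ridge = 0) {
  beta <- scalar_number(beta, "beta")
  ridge <- scalar_number(ridge, "ridge")
  if (beta < 0 || beta >= 1) ss_abort("beta must be in [0, 1)", "structure")
  if (!identical(dim(G), dim(A22))) {
    ss_abort("G and A22 must have identical dimensions", "structure")
  }
  if (!is.null(rownames(G)) && !is.null(rownames(A22)) &&
      !identical(rownames(G), rownames(A22))) {
    ss_abort("G and A22 id order differs", "ids")
  }
  out <- (1 - beta) * G + beta * A22
  if (ridge != 0) out <- out + diag(ridge, nrow(out))
  attr(out, "beta") <- beta
  attr(out, "ridge") <- ridge
  out
}
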