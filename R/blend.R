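# The blended single-step matrix H_{tau,omega}.
#
# On the inverse level the blend is
#   H^-1 = A^-1 + blockdiag(0, tau * G^-1 - omega * A22^-1),
# and on the covariance level
#   H = A + [ A12 B D B A21 , A12 B D ; D B A21 , D ],
#   D = H22 - A22,  B = A22^-1,  H22 = (tau G^-1 + (1 - omega) A22^-1)^-1.
# The two forms are exact inverses of each other; the package always builds H
# from the covariance-level formula (cheaper and stabler) and reserves the
# numeric inversion of the inverse-level form for cross-checks.

#' Blending parameters and their special-case classification
#'
#' Validates a `(tau, omega)` pair and classifies it. Positive
#' semi-definiteness of the blended matrix is guaranteed for positive
#' definite A and G whenever `tau >= 0` and `omega <= 1`, excluding the joint
#' boundary `tau = 0, omega = 1`; outside that region (in particular
#' `omega > 1`) the covariance model may be indefinite.
#'
#' @param tau non-negative scaling of the genomic inverse.
#' @param omega scaling of the pedigree-block inverse; may be negative.
#' @return A one-row tibble with `tau`, `omega`, `case` (see
#'   [classify_blend()]) and `psd_guaranteed`.
#' @export
blend_params <- function(tau, omega) {
  tau <- scalar_number(tau, "tau")
  omega <- scalar_number(omega, "omega")
  if (tau < 0) ss_abort("tau must be >= 0", "structure")
  tibble::tibble(
    tau = tau, omega = omega,
    case = classify_blend(tau, omega),
    psd_guaranteed = tau >= 0 && omega <= 1 && !(tau == 0 && omega == 1)
  )
}

#' Classify a (tau, omega) combination
#'
#' Returns the special-case label: `"original"` for (1, 1) (the classical
#' single-step matrix), `"pedigree"` for (0, 0) (H = A, pedigree BLUP),
#' `"harmonic(x)"` for tau = omega = x > 0 (weighted harmonic mean of G and
#' A22), `"scaledG"` for omega = 1 (H22 = G / tau), `"tau1"` for tau = 1, and
#' `"general"` otherwise.
#'
#' @inheritParams blend_params
#' @return A single string.
#' @export
classify_blend <- function(tau, omega) {
  tau <- scalar_number(tau, "tau")
  omega <- scalar_number(omega, "omega")
  if (tau == 1 && omega == 1) return("original")
  if (tau == 0 && omega == 0) return("pedigree")
  if (tau == omega && tau > 0) return(sprintf("harmonic(%g)", tau))
  if (omega == 1) return("scaledG")
  if (tau == 1) return("tau1")
  "general"
}

#' Inverse-level blended single-step matrix
#'
#' Builds `H^-1 = A^-1 + blockdiag(0, tau * Ginv - omega * A22inv)`. Note the
#' distinct roles of the two pedigree inverses: `Ainv` is the inverse of the
#' full A, while `A22inv` is the inverse of the genotyped sub-block, which in
#' general differs from the corresponding block of `Ainv`.
#'
#' @param Ainv inverse of the full pedigree relationship matrix, ids in
#'   Group-1-first order.
#' @param A22inv inverse of the genotyped block of A (ids as dimnames,
#'   matching the trailing block of `Ainv`).
#' @param Ginv inverse of the (adjusted) genomic relationship matrix, same
#'   ids/order as `A22inv`.
#' @inheritParams blend_params
#' @return Symmetric matrix of full dimension.
#' @export
h_inverse <- function(Ainv, A22inv, Ginv, tau, omega) {
  tau <- scalar_number(tau, "tau")
  omega <- scalar_number(omega, "omega")
  if (!identical(dim(A22inv), dim(Ginv))) {
    ss_abort("A22inv and Ginv dimensions differ", "structure")
  }
  ids <- rownames(Ainv)
  ids2 <- rownames(A22inv)
  if (is.null(ids) || is.null(ids2)) {
    ss_abort("h_inverse needs id dimnames to locate the genotyped block", "ids")
  }
  idx <- match(ids2, ids)
  if (anyNA(idx)) ss_abort("genotyped ids absent from Ainv", "ids")
  Hinv <- Ainv
  Hinv[idx, idx] <- Hinv[idx, idx] + tau * Ginv - omega * A22inv
  if (any(!is.finite(Hinv))) ss_abort("non-finite entries in H inverse", "structure")
  (Hinv + t(Hinv)) / 2
}

#' Genotyped block of the blended matrix
#'
#' The covariance-level genotyped block is
#' \deqn{H_{22} = (\tau G^{-1} + (1-\omega) A_{22}^{-1})^{-1},}
#' in which the weights appear "reversed" relative to the inverse-level
#' definition. Special cases are evaluated in closed form: `tau = 0` gives
#' `A22 / (1 - omega)` and `omega = 1` gives `G / tau` exactly. The
#' combination `tau = 0, omega = 1` is rejected, and any combination for
#' which the inner sum has an eigenvalue at or below the tolerance (possible
#' when `omega > 1`) fails with a `non_psd` signal.
#'
#' @param G invertible genomic relationship matrix (adjust first if needed).
#' @param A22 pedigree relationships of the genotyped group.
#' @inheritParams blend_params
#' @param tol relative eigenvalue tolerance for the positivity screen.
#' @return Symmetric matrix of genotyped dimension.
#' @examples
#' G <- matrix(c(2, 1, 1, 2), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' h22_block(G, diag(2), tau = 1, omega = 0.5)  # entries 14/15 and 4/15
#' @export
h22_block <- function(G, A22, tau, omega, tol = 1e-8) {
  tau <- scalar_number(tau, "tau")
  omega <- scalar_number(omega, "omega")
  if (tau < 0) ss_abort("tau must be >= 0", "structure")
  if (!identical(dim(G), dim(A22))) {
    ss_abort("G and A22 dimensions differ", "structure")
  }
  if (tau == 0 && omega == 1) {
    ss_abort("tau = 0 with omega = 1 leaves no positive weight in H22",
             "non_psd")
  }
  if (tau == 0) {
    out <- A22 / (1 - omega)
  } else if (omega == 1) {
    out <- G / tau
  } else {
    M <- tau * invert_spd(G, tol = tol, role = "G") +
      (1 - omega) * invert_spd(A22, tol = tol, role = "A22")
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= tol * max(abs(ev))) {
      ss_abort(
        sprintf(paste0("tau * Ginv + (1 - omega) * A22inv is not positive ",
                       "definite at (tau, omega) = (%g, %g)"), tau, omega),
        "non_psd", category = "non_psd_combination"
      )
    }
    out <- chol2inv(chol(M))
    dimnames(out) <- dimnames(G)
  }
  (out + t(out)) / 2
}

#' Covariance-level blended single-step matrix
#'
#' Builds the full blended matrix from A, G and the genotyped-id set:
#' \deqn{H = A + \begin{pmatrix} A_{12}B\Delta B A_{21} & A_{12}B\Delta \\
#'   \Delta B A_{21} & \Delta \end{pmatrix}},
#' with \eqn{B = A_{22}^{-1}} and \eqn{\Delta = H_{22} - A_{22}}. Individuals
#' are ordered with the non-genotyped group first. The genotyped block of the
#' result is exactly the [h22_block()] output (same code path).
#'
#' @param A full pedigree relationship matrix with id dimnames.
#' @param G invertible genomic relationship matrix over `genotyped_ids`.
#' @param genotyped_ids character vector of genotyped ids.
#' @inheritParams h22_block
#' @return An object of class `ss_hmat`: a list with `H`, `H22`, `tau`,
#'   `omega`, `case`, `ids1`, `ids2`, `ids` (the permuted order).
#' @export
h_matrix <- function(A, G, genotyped_ids, tau, omega, tol = 1e-8) {
  part <- partition_relmat(A, genotyped_ids)
  if (!is.null(rownames(G)) && !identical(rownames(G), part$ids2)) {
    G <- G[part$ids2, part$ids2, drop = FALSE]
  }
  H22 <- h22_block(G, part$A22, tau, omega, tol = tol)
  D <- H22 - part$A22
  n1 <- length(part$ids1)
  if (n1 == 0) {
    H <- H22
  } else {
    B <- invert_spd(part$A22, tol = tol, role = "A22")
    TT <- part$A12 %*% B               # A12 A22^-1
    H11 <- part$A11 + TT %*% D %*% t(TT)
    H12 <- part$A12 + TT %*% D
    H <- rbind(cbind(H11, H12), cbind(t(H12), H22))
  }
  dimnames(H) <- list(part$order, part$order)
  structure(
    list(H = (H + t(H)) / 2, H22 = H22, tau = tau, omega = omega,
         case = classify_blend(tau, omega),
         ids1 = part$ids1, ids2 = part$ids2, ids = part$order),
    class = "ss_hmat"
  )
}

#' @export
print.ss_hmat <- function(x, ...) {
  cat(sprintf(
    "Blended single-step matrix H (tau = %g, omega = %g, case: %s)\n",
    x$tau, x$omega, x$case))
  cat(sprintf("  %d individuals (%d non-genotyped + %d genotyped)\n",
              length(x$ids), length(x$ids1), length(x$ids2)))
  invisible(x)
}

#' Limit behaviour of the blend at omega = 1
#'
#' With `omega = 1` the genotyped block is `G / tau`, so as tau grows the
#' genotyped block and the cross blocks shrink towards zero while the
#' non-genotyped block approaches the Schur complement
#' `A11 - A12 A22^-1 A21`. This reports, for each tau in the sequence, the
#' largest absolute entries of H12 and H22 and the distance of H11 from the
#' Schur complement; all three are expected to decrease along an increasing
#' tau sequence.
#'
#' @inheritParams h_matrix
#' @param tau_seq increasing vector of positive tau values.
#' @return A tibble with columns `tau`, `max_abs_h12`, `max_abs_h22`,
#'   `dist_h11_schur`.
#' @export
schur_limit_profile <- function(A, G, genotyped_ids, tau_seq, tol = 1e-8) {
  if (is.unsorted(tau_seq, strictly = TRUE)) {
    ss_abort("tau_seq must be strictly increasing", "structure")
  }
  part <- partition_relmat(A, genotyped_ids)
  B <- invert_spd(part$A22, tol = tol, role = "A22")
  S <- schur_complement(part$A11, part$A12, B)
  purrr::map_dfr(tau_seq, function(tau) {
    hm <- h_matrix(A, G, genotyped_ids, tau = tau, omega = 1, tol = tol)
    n1 <- length(hm$ids1)
    i1 <- seq_len(n1)
    i2 <- n1 + seq_along(hm$ids2)
    tibble::tibble(
      tau = tau,
      max_abs_h12 = if (n1 > 0) max(abs(hm$H[i1, i2, drop = FALSE])) else 0,
      max_abs_h22 = max(abs(hm$H[i2, i2, drop = FALSE])),
      dist_h11_schur = if (n1 > 0) max(abs(hm$H[i1, i1, drop = FALSE] - S)) else 0
    )
  })
}
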