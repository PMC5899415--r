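#' Assemble a single-step dataset
#'
#' Bundles a pedigree, a marker matrix for the genotyped subset, and a
#' phenotype table into one object, precomputing the relationship matrices
#' and inverses every downstream step needs: A (topological order, then
#' permuted Group-1-first), its partition, A22 and its inverse, the VanRaden
#' G, the invertibility adjustment `G* = (1 - beta) G + beta A22 + ridge I`,
#' and the inverses of A and G*.
#'
#' @param pedigree data frame with columns `id`, `sire`, `dam`.
#' @param markers matrix of marker codes for the genotyped individuals (rows
#'   named by id) or `NULL` for a pedigree-only dataset.
#' @param phenotypes data frame with columns `id`, `y` (`NA` allowed).
#' @param genotyped_ids ids forming Group 2; defaults to `rownames(markers)`.
#' @param coding marker coding, see [g_vanraden()].
#' @param beta,ridge invertibility adjustment, see [g_adjust()].
#' @param sentinel unknown-parent code.
#' @return An object of class `ss_data`.
#' @export
ss_data <- function(pedigree, markers = NULL, phenotypes = NULL,
                    genotyped_ids = rownames(markers),
                    coding = c("presence01", "dosage012"),
                    beta = 0.05, ridge = 0, sentinel = "0") {
  coding <- match.arg(coding)
  ped <- validate_pedigree(pedigree, sentinel)
  A <- a_matrix(ped, sentinel)
  if (is.null(genotyped_ids)) {
    ss_abort("genotyped_ids (or marker rownames) are required", "ids")
  }
  part <- partition_relmat(A, genotyped_ids)
  A <- A[part$order, part$order]
  Ainv <- invert_spd(A, role = "A")
  A22inv <- invert_spd(part$A22, role = "A22")

  G_raw <- NULL; G <- NULL; Ginv <- NULL
  if (!is.null(markers)) {
    miss <- setdiff(part$ids2, rownames(markers))
    if (length(miss) > 0) {
      ss_abort(sprintf("no marker row for genotyped id '%s'", miss[1]), "ids")
    }
    markers <- markers[part$ids2, , drop = FALSE]
    G_raw <- g_vanraden(markers, coding)
    G <- g_adjust(G_raw, part$A22, beta = beta, ridge = ridge)
    Ginv <- invert_spd(G, role = "G")
  }

  pheno <- NULL
  if (!is.null(phenotypes)) {
    if (!all(c("id", "y") %in% names(phenotypes))) {
      ss_abort("phenotypes must have columns id, y", "structure")
    }
    pheno <- tibble::tibble(id = as.character(phenotypes$id),
                            y = as.numeric(phenotypes$y))
    unknown <- setdiff(pheno$id, part$order)
    if (length(unknown) > 0) {
      ss_abort(sprintf("phenotyped id '%s' absent from pedigree", unknown[1]),
               "ids")
    }
    pheno <- pheno[match(part$order, pheno$id), , drop = FALSE]
    pheno$id <- part$order   # unphenotyped individuals get NA rows
  }

  structure(
    list(pedigree = ped, ids = part$order, ids1 = part$ids1, ids2 = part$ids2,
         A = A, Ainv = Ainv, A11 = part$A11, A12 = part$A12, A22 = part$A22,
         A22inv = A22inv, markers = markers, coding = coding,
         G_raw = G_raw, G = G, Ginv = Ginv,
         beta = beta, ridge = ridge, phenotypes = pheno),
    class = "ss_data"
  )
}

#' @export
print.ss_data <- function(x, ...) {
  cat(sprintf("Single-step dataset: %d individuals (%d non-genotyped + %d genotyped)\n",
              length(x$ids), length(x$ids1), length(x$ids2)))
  if (!is.null(x$markers)) {
    cat(sprintf("  %d markers (%s), G adjusted with beta = %g, ridge = %g\n",
                ncol(x$markers), x$coding, x$beta, x$ridge))
  }
  if (!is.null(x$phenotypes)) {
    cat(sprintf("  %d phenotype records\n", sum(!is.na(x$phenotypes$y))))
  }
  invisible(x)
}

#' Inverse of the blended matrix for a dataset
#'
#' Convenience wrapper assembling `H^-1` from the dataset's precomputed
#' inverses via [h_inverse()]. With `tau = omega = 0` this is exactly the
#' pedigree inverse (pedigree BLUP). Outside the guaranteed-PSD region
#' (`omega > 1`) the blend is additionally screened: if
#' `tau * Ginv + (1 - omega) * A22inv` has an eigenvalue at or below the
#' tolerance, the combination does not define a valid covariance model and
#' the dedicated `non_psd` signal is raised.
#'
#' @param data an [ss_data] object with markers.
#' @inheritParams blend_params
#' @param tol eigenvalue tolerance for the validity screen.
#' @return Symmetric matrix over all individuals (Group-1-first order).
#' @export
h_inverse_for <- function(data, tau, omega, tol = 1e-8) {
  stopifnot(inherits(data, "ss_data"))
  if (is.null(data$Ginv)) ss_abort("dataset has no genomic information", "structure")
  if (tau == 0 && omega == 1) {
    ss_abort("tau = 0 with omega = 1 leaves no positive weight in H22",
             "non_psd")
  }
  if (omega > 1) {
    M <- tau * data$Ginv + (1 - omega) * data$A22inv
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= tol * max(abs(ev))) {
      ss_abort(
        sprintf(paste0("tau * Ginv + (1 - omega) * A22inv is not positive ",
                       "definite at (tau, omega) = (%g, %g)"), tau, omega),
        "non_psd", category = "non_psd_combination"
      )
    }
  }
  h_inverse(data$Ainv, data$A22inv, data$Ginv, tau, omega)
}

#' Swap the genotyped and non-genotyped groups of a dataset
#'
#' Rebuilds the dataset with the complementary set of individuals treated as
#' genotyped, provided marker data covering them is supplied. Used for
#' scenario robustness checks in which either half of a population plays the
#' genotyped group.
#'
#' @param data an [ss_data] object.
#' @param markers_all marker matrix covering every individual.
#' @return A new [ss_data] object.
#' @export
swap_genotyped <- function(data, markers_all) {
  stopifnot(inherits(data, "ss_data"))
  new_g <- data$ids1
  ss_data(data$pedigree, markers_all[new_g, , drop = FALSE],
          phenotypes = data$phenotypes, genotyped_ids = new_g,
          coding = data$coding, beta = data$beta, ridge = data$ridge)
}
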