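#' Validate and topologically sort a pedigree
#'
#' A pedigree is a data frame with columns `id`, `sire`, `dam` (character).
#' Unknown parents are coded with the sentinel (default `"0"`) and are treated
#' as unrelated, non-inbred founders. Every known parent must itself appear as
#' an `id` and the parent graph must be acyclic; records are re-ordered so
#' that parents always precede their offspring (with a warning if the input
#' order had to change).
#'
#' @param ped data frame with columns `id`, `sire`, `dam`.
#' @param sentinel unknown-parent code, default `"0"`.
#' @return A tibble with columns `id`, `sire`, `dam` (`NA` for unknown
#'   parents) in topological order.
#' @export
validate_pedigree <- function(ped, sentinel = "0") {
  if (!is.data.frame(ped) || !all(c("id", "sire", "dam") %in% names(ped))) {
    ss_abort("pedigree must be a data frame with columns id, sire, dam",
             "structure")
  }
  ped <- tibble::tibble(
    id = as.character(ped$id),
    sire = as.character(ped$sire),
    dam = as.character(ped$dam)
  )
  ped$sire[ped$sire == sentinel] <- NA_character_
  ped$dam[ped$dam == sentinel] <- NA_character_
  if (anyDuplicated(ped$id)) {
    dup <- ped$id[duplicated(ped$id)][1]
    ss_abort(sprintf("duplicate pedigree id '%s'", dup), "parse")
  }
  if (any(ped$id == ped$sire | ped$id == ped$dam, na.rm = TRUE)) {
    ss_abort("an individual is listed as its own parent", "structure")
  }
  parents <- stats::na.omit(c(ped$sire, ped$dam))
  missing <- setdiff(parents, ped$id)
  if (length(missing) > 0) {
    ss_abort(sprintf("parent '%s' never appears as an id", missing[1]), "ids")
  }

  # Kahn topological sort on the parent -> offspring graph.
  n <- nrow(ped)
  idx <- seq_len(n)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- idx[indeg == 0]
  order <- integer(0)
  while (length(queue) > 0) {
    # keep input order among available records for determinism
    queue <- sort(queue)
    i <- queue[1]
    queue <- queue[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    ss_abort("pedigree contains a cycle (an individual is its own ancestor)",
             "structure")
  }
  if (any(order != idx)) {
    warn("pedigree was not in parents-first order; records re-sorted")
    ped <- ped[order, ]
  }
  ped
}

#' Pedigree numerator relationship matrix
#'
#' Builds the additive (numerator) relationship matrix A from a pedigree by
#' the tabular recursion, including inbreeding: processing individuals in
#' parents-first order,
#' \deqn{a_{ij} = \tfrac12 (a_{s_i j} + a_{d_i j}), \qquad
#'       a_{ii} = 1 + \tfrac12 a_{s_i d_i},}
#' with unknown parents contributing zero relationship. The diagonal is
#' therefore 1 plus the inbreeding coefficient.
#'
#' @inheritParams validate_pedigree
#' @return A dense symmetric matrix with ids as dimnames, in topological
#'   order.
#' @examples
#' ped <- tibble::tibble(id = c("S", "D", "O"),
#'                       sire = c("0", "0", "S"),
#'                       dam  = c("0", "0", "D"))
#' a_matrix(ped)["O", ]
#' @export
a_matrix <- function(ped, sentinel = "0") {
  ped <- validate_pedigree(ped, sentinel)
  n <- nrow(ped)
  ids <- ped$id
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rs <- if (is.na(si[i])) 0 else A[si[i], j]
      rd <- if (is.na(di[i])) 0 else A[di[i], j]
      v <- 0.5 * (rs + rd)
      A[i, j] <- v
      A[j, i] <- v
    }
    A[i, i] <- 1 + if (is.na(si[i]) || is.na(di[i])) 0 else 0.5 * A[si[i], di[i]]
  }
  A
}

#' Partition a relationship matrix by genotyping status
#'
#' Permutes and splits a relationship matrix into the conventional single-step
#' block layout: Group 1 (non-genotyped) first, Group 2 (genotyped) second.
#' The relative input order is preserved within each group. The block between
#' groups is returned once (`A12`); its transpose plays the role of `A21`.
#'
#' @param A symmetric relationship matrix with id dimnames.
#' @param genotyped_ids character vector of genotyped ids (Group 2).
#' @return A list with `A11`, `A12`, `A22`, `ids1`, `ids2`, and `order` (the
#'   permutation of the input ids). `A11`/`A12` have zero extent when all
#'   individuals are genotyped.
#' @export
partition_relmat <- function(A, genotyped_ids) {
  ids <- rownames(A)
  if (is.null(ids)) ss_abort("relationship matrix must have id dimnames", "ids")
  genotyped_ids <- as.character(genotyped_ids)
  absent <- setdiff(genotyped_ids, ids)
  if (length(absent) > 0) {
    ss_abort(sprintf("genotyped id '%s' absent from the pedigree", absent[1]),
             "ids")
  }
  if (length(genotyped_ids) == 0) {
    ss_abort("at least one genotyped individual is required", "ids")
  }
  ids2 <- ids[ids %in% genotyped_ids]
  ids1 <- ids[!ids %in% genotyped_ids]
  ord <- c(ids1, ids2)
  Ap <- A[ord, ord, drop = FALSE]
  n1 <- length(ids1)
  list(
    A11 = Ap[seq_len(n1), seq_len(n1), drop = FALSE],
    A12 = Ap[seq_len(n1), n1 + seq_along(ids2), drop = FALSE],
    A22 = Ap[n1 + seq_along(ids2), n1 + seq_along(ids2), drop = FALSE],
    ids1 = ids1, ids2 = ids2, order = ord
  )
}

#' Invert a symmetric positive-definite matrix
#'
#' Inversion through the Cholesky factorization after an eigenvalue
#' screen: if the smallest eigenvalue does not exceed `tol` times the largest,
#' the matrix is declared singular and the error names the `role` so that a
#' singular G is distinguishable from a singular A22.
#'
#' @param M symmetric matrix.
#' @param tol relative eigenvalue tolerance, default `1e-8`.
#' @param role label used in error messages (e.g. `"G"`, `"A22"`).
#' @return The inverse, with dimnames preserved.
#' @export
invert_spd <- function(M, tol = 1e-8, role = "matrix") {
  M <- check_symmetric(M, tol = 1e-8, what = role)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol * max(abs(ev))) {
    ss_abort(
      sprintf("%s is numerically singular (min eigenvalue %.3g vs max %.3g)",
              role, min(ev), max(ev)),
      "singular", role = role
    )
  }
  inv <- chol2inv(chol(M))
  dimnames(inv) <- dimnames(M)
  inv
}

#' Schur complement of the genotyped block
#'
#' Computes `A11 - A12 %*% A22inv %*% t(A12)`, the relationships among
#' non-genotyped individuals conditional on the genotyped group. This is the
#' limit of the (1,1) block of the blended matrix as tau grows with omega = 1.
#'
#' @param A11,A12 pedigree blocks (Group 1 x Group 1 and Group 1 x Group 2).
#' @param A22inv inverse of the genotyped block.
#' @return Symmetric matrix of Group 1 dimension.
#' @export
schur_complement <- function(A11, A12, A22inv) {
  if (nrow(A11) != nrow(A12) || ncol(A12) != nrow(A22inv) ||
      nrow(A22inv) != ncol(A22inv)) {
    ss_abort("non-conformable blocks in Schur complement", "structure")
  }
  S <- A11 - A12 %*% A22inv %*% t(A12)
  (S + t(S)) / 2
}
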