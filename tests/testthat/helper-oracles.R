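# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: kinship by Wright's path counting, and the
# classical single-step matrix written out directly from its defining
# block formula with plain solve().

# --- Wright path-counting numerator relationship (exact, tiny pedigrees) ---

# All ancestral chains starting at i (each chain is i, parent, grandparent,
# ...), including the trivial chain c(i).
chains_up <- function(si, di, i) {
  res <- list(c(i))
  for (p in c(si[i], di[i])) {
    if (!is.na(p)) {
      for (ch in chains_up(si, di, p)) res <- c(res, list(c(i, ch)))
    }
  }
  res
}

oracle_inbreeding <- function(si, di, i) {
  if (is.na(si[i]) || is.na(di[i])) return(0)
  0.5 * oracle_relationship(si, di, si[i], di[i])
}

oracle_relationship <- function(si, di, i, j) {
  if (i == j) return(1 + oracle_inbreeding(si, di, i))
  tot <- 0
  for (ci in chains_up(si, di, i)) {
    for (cj in chains_up(si, di, j)) {
      anc <- ci[length(ci)]
      if (cj[length(cj)] != anc) next
      # the two legs may share no individual besides the common ancestor
      if (length(intersect(setdiff(ci, anc), setdiff(cj, anc))) > 0) next
      tot <- tot + 0.5^(length(ci) + length(cj) - 2) *
        (1 + oracle_inbreeding(si, di, anc))
    }
  }
  tot
}

oracle_a_matrix <- function(ped) {
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      A[i, j] <- A[j, i] <- oracle_relationship(si, di, i, j)
    }
  }
  A
}

# --- classical single-step matrix, straight from its block formula ---

original_h_oracle <- function(A, G, genotyped_ids) {
  ids <- rownames(A)
  g2 <- ids[ids %in% genotyped_ids]
  g1 <- setdiff(ids, g2)
  ord <- c(g1, g2)
  A <- A[ord, ord]
  i1 <- seq_along(g1)
  i2 <- length(g1) + seq_along(g2)
  A11 <- A[i1, i1, drop = FALSE]
  A12 <- A[i1, i2, drop = FALSE]
  A22 <- A[i2, i2, drop = FALSE]
  B <- solve(A22)
  D <- G[g2, g2] - A22
  H <- A + rbind(
    cbind(A12 %*% B %*% D %*% B %*% t(A12), A12 %*% B %*% D),
    cbind(t(A12 %*% B %*% D), D)
  )
  dimnames(H) <- list(ord, ord)
  H
}

# --- small fixed pedigrees ---

trio_ped <- function() {
  tibble::tibble(id = c("S", "D", "O"),
                 sire = c("0", "0", "S"),
                 dam = c("0", "0", "D"))
}

# sire S mated to two dams; the two half sibs mated to each other
halfsib_ped <- function() {
  tibble::tibble(
    id = c("S", "D1", "D2", "O1", "O2", "X"),
    sire = c("0", "0", "0", "S", "S", "O1"),
    dam = c("0", "0", "0", "D1", "D2", "O2")
  )
}

# random positive definite matrix with unit-scale diagonal
random_pd <- function(n, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm((n + 5) * n), n + 5)
    W <- crossprod(X) / (n + 5)
    W / mean(diag(W))
  })
}
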