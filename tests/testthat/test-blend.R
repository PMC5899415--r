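two_by_two <- function() {
  G <- matrix(c(2, 1, 1, 2), 2, dimnames = list(c("a", "b"), c("a", "b")))
  A22 <- diag(2); dimnames(A22) <- dimnames(G)
  list(G = G, A22 = A22)
}

test_that("H22 reproduces the worked 2x2 example exactly", {
  m <- two_by_two()
  H22 <- h22_block(m$G, m$A22, tau = 1, omega = 0.5)
  expect_lt(max(abs(H22 - matrix(c(14, 4, 4, 14) / 15, 2))), 1e-12)
})

test_that("omega is not a pure pedigree weight: off-diagonals shift", {
  m <- two_by_two()
  H22 <- h22_block(m$G, m$A22, tau = 1, omega = 0.5)
  # A22 off-diagonal is 0, yet H22 off-diagonal differs from G's entry 1
  expect_gt(abs(H22[1, 2] - m$G[1, 2]), 0.5)
})

test_that("H22 special cases hold exactly", {
  m <- two_by_two()
  expect_equal(h22_block(m$G, m$A22, 1, 1), m$G)            # original
  expect_equal(h22_block(m$G, m$A22, 2, 1), m$G / 2)        # scaled G
  expect_equal(h22_block(m$G, m$A22, 0, 0), m$A22)          # pedigree
  expect_equal(h22_block(m$G, m$A22, 0, 0.5), m$A22 / 0.5)  # tau = 0
  # equal weights: weighted harmonic mean
  lam <- 0.5
  expect_equal(h22_block(m$G, m$A22, lam, lam),
               solve(lam * solve(m$G) + (1 - lam) * solve(m$A22)),
               ignore_attr = TRUE)
  expect_error(h22_block(m$G, m$A22, 0, 1), class = "ssblend_error_non_psd")
})

test_that("blend combinations outside the valid region are signalled", {
  m <- two_by_two()
  err <- expect_error(h22_block(m$G, m$A22, 0.1, 2),
                      class = "ssblend_error_non_psd")
  expect_equal(err$category, "non_psd_combination")
})

test_that("special-case classification is deterministic", {
  expect_equal(classify_blend(1, 1), "original")
  expect_equal(classify_blend(0, 0), "pedigree")
  expect_equal(classify_blend(0.7, 0.7), "harmonic(0.7)")
  expect_equal(classify_blend(2, 1), "scaledG")
  expect_equal(classify_blend(1, -0.3), "tau1")
  expect_equal(classify_blend(0.5, 0.2), "general")
  expect_true(blend_params(0.8, -0.3)$psd_guaranteed)
  expect_false(blend_params(0.5, 1.2)$psd_guaranteed)
  expect_false(blend_params(0, 1)$psd_guaranteed)
  expect_error(blend_params(-0.1, 0), class = "ssblend_error_structure")
})

test_that("covariance-level H agrees with special cases and the block path", {
  inst <- sim_blend_instance(7, seed = 21)
  ord <- partition_relmat(inst$A, inst$genotyped_ids)$order
  # tau = omega = 0 gives back A
  h0 <- h_matrix(inst$A, inst$G, inst$genotyped_ids, 0, 0)
  expect_equal(h0$H, inst$A[ord, ord], tolerance = 1e-12)
  # tau = omega = 1 equals the classical formula computed independently
  h1 <- h_matrix(inst$A, inst$G, inst$genotyped_ids, 1, 1)
  expect_lt(max(abs(h1$H - original_h_oracle(inst$A, inst$G,
                                             inst$genotyped_ids))), 1e-10)
  # the genotyped block of H is exactly the h22_block output
  A22 <- inst$A[h1$ids2, h1$ids2]
  expect_identical(h1$H22, h22_block(inst$G, A22, 1, 1))
  n1 <- length(h1$ids1)
  expect_identical(unname(h1$H[n1 + seq_along(h1$ids2),
                               n1 + seq_along(h1$ids2)]),
                   unname(h1$H22))
})

test_that("inverse-level and covariance-level forms are numerical inverses", {
  eq <- sweep_equivalence(n_reps = 40, n_max = 10, seed = 101)
  expect_equal(nrow(eq), 40)
  expect_lt(max(eq$rel_err), 1e-6)
})

test_that("H times its inverse-level form is the identity", {
  inst <- sim_blend_instance(8, seed = 31)
  hm <- h_matrix(inst$A, inst$G, inst$genotyped_ids, 1.3, 0.4)
  Ainv <- invert_spd(inst$A[hm$ids, hm$ids], role = "A")
  A22inv <- invert_spd(inst$A[hm$ids2, hm$ids2], role = "A22")
  Ginv <- invert_spd(inst$G[hm$ids2, hm$ids2], role = "G")
  Hinv <- h_inverse(Ainv, A22inv, Ginv, 1.3, 0.4)
  expect_lt(max(abs(hm$H %*% Hinv - diag(nrow(Hinv)))), 1e-6)
})

test_that("with omega = 1 the blend shrinks towards the Schur complement", {
  inst <- sim_blend_instance(8, seed = 41)
  prof <- schur_limit_profile(inst$A, inst$G, inst$genotyped_ids,
                              tau_seq = c(1, 10, 100, 1000))
  expect_false(is.unsorted(rev(prof$max_abs_h12)))
  expect_false(is.unsorted(rev(prof$max_abs_h22)))
  expect_false(is.unsorted(rev(prof$dist_h11_schur)))
  # H22 = G / tau exactly
  expect_equal(prof$max_abs_h22, max(abs(inst$G)) / prof$tau)
  # far limit: H11 within 1e-3 * |A| of the Schur complement
  far <- schur_limit_profile(inst$A, inst$G, inst$genotyped_ids,
                             tau_seq = c(1e5, 1e6))
  expect_lt(far$dist_h11_schur[2], 1e-3 * max(abs(inst$A)))
})

test_that("G equal to A22 with original weights leaves H = A", {
  inst <- sim_blend_instance(6, seed = 51)
  part <- partition_relmat(inst$A, inst$genotyped_ids)
  hm <- h_matrix(inst$A, part$A22, inst$genotyped_ids, 1, 1)
  expect_equal(hm$H, inst$A[part$order, part$order], tolerance = 1e-10)
})
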