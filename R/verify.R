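# Randomized numerical verification sweeps for the structural results:
# inverse/covariance-level equivalence, the PSD region of (tau, omega), and
# the Loewner monotonicity chains. Used by the test suite, the acceptance
# script, and the `verify` CLI subcommand.

#' Inverse-level vs covariance-level equivalence sweep
#'
#' For random pedigree-derived A and Wishart-style G instances and
#' `(tau, omega)` sampled uniformly over a region where both forms exist,
#' numerically inverts the inverse-level blend and compares it entrywise with
#' the covariance-level matrix. The relative error is
#' `max|solve(Hinv) - H| / max|H|`.
#'
#' @param n_reps number of random instances (default 200).
#' @param n_max maximal instance size; n is sampled in `[4, n_max]`.
#' @param seed RNG seed.
#' @param tau_range,omega_range sampling intervals (defaults `[0.05, 2]` and
#'   `[-1, 0.95]`).
#' @return A tibble with `rep`, `n`, `n_genotyped`, `tau`, `omega`,
#'   `rel_err`.
#' @export
sweep_equivalence <- function(n_reps = 200, n_max = 10, seed = 1L,
                              tau_range = c(0.05, 2),
                              omega_range = c(-1, 0.95)) {
  draws <- withr::with_seed(seed, tibble::tibble(
    rep = seq_len(n_reps),
    n = sample(4:n_max, n_reps, replace = TRUE),
    tau = runif(n_reps, tau_range[1], tau_range[2]),
    omega = runif(n_reps, omega_range[1], omega_range[2])
  ))
  purrr::pmap_dfr(draws, function(rep, n, tau, omega) {
    inst <- sim_blend_instance(n, seed = seed + rep)
    hm <- h_matrix(inst$A, inst$G, inst$genotyped_ids, tau, omega)
    Ainv <- invert_spd(inst$A[hm$ids, hm$ids], role = "A")
    A22inv <- invert_spd(inst$A[hm$ids2, hm$ids2], role = "A22")
    Ginv <- invert_spd(inst$G[hm$ids2, hm$ids2], role = "G")
    Hinv <- h_inverse(Ainv, A22inv, Ginv, tau, omega)
    Hnum <- solve(Hinv)
    tibble::tibble(rep = rep, n = n,
                   n_genotyped = length(hm$ids2), tau = tau, omega = omega,
                   rel_err = max(abs(Hnum - hm$H)) / max(abs(hm$H)))
  })
}

#' PSD-region sweep
#'
#' Samples `(tau, omega)` in `[0, 2] x [-1, 1]` (excluding the joint
#' boundary `tau = 0, omega = 1`) on random positive definite instances and
#' records whether the blended matrix is positive semi-definite. Inside the
#' guaranteed region (`tau >= 0`, `omega <= 1`) no violations are expected.
#'
#' @inheritParams sweep_equivalence
#' @param tol PSD tolerance.
#' @return A tibble with `rep`, `n`, `tau`, `omega`, `psd`, `min_eig`.
#' @export
sweep_psd_region <- function(n_reps = 200, n_max = 10, seed = 1L, tol = 1e-8) {
  draws <- withr::with_seed(seed, {
    tb <- tibble::tibble(
      rep = seq_len(n_reps),
      n = sample(4:n_max, n_reps, replace = TRUE),
      tau = runif(n_reps, 0, 2),
      omega = runif(n_reps, -1, 1)
    )
    # the excluded joint boundary has probability zero, but guard anyway
    tb$tau[tb$tau == 0 & tb$omega == 1] <- 0.1
    tb
  })
  purrr::pmap_dfr(draws, function(rep, n, tau, omega) {
    inst <- sim_blend_instance(n, seed = seed + rep)
    hm <- h_matrix(inst$A, inst$G, inst$genotyped_ids, tau, omega)
    psd <- is_psd(hm$H, tol = tol)
    tibble::tibble(rep = rep, n = n, tau = tau, omega = omega,
                   psd = as.logical(psd), min_eig = attr(psd, "min_eig"))
  })
}

#' Loewner monotonicity sweep
#'
#' Random instances with `tau <= tau2` and `omega >= omega2` drawn inside the
#' PSD-guaranteed region; every instance runs the full chain of block-level
#' orderings, the block/full-matrix equivalence, and the BLUP-kernel
#' equivalence, counting violations.
#'
#' @inheritParams sweep_equivalence
#' @param lambda variance ratio for the kernel-level check.
#' @param tol eigenvalue tolerance.
#' @return A tibble with one row per instance: the sampled parameters,
#'   `chain_ok` (all block orderings hold), `block_full_agree`, and
#'   `kernel_agree`.
#' @export
sweep_loewner_chains <- function(n_reps = 200, n_max = 10, seed = 1L,
                                 lambda = 1, tol = 1e-8) {
  draws <- withr::with_seed(seed, {
    t1 <- runif(n_reps, 0.05, 1.5)
    w2 <- runif(n_reps, -1, 0.9)
    tibble::tibble(
      rep = seq_len(n_reps),
      n = sample(4:n_max, n_reps, replace = TRUE),
      tau = t1, tau2 = t1 + runif(n_reps, 0, 0.5),
      omega2 = w2, omega = w2 + runif(n_reps, 0, 0.5)
    )
  })
  draws$omega <- pmin(draws$omega, 1)
  purrr::pmap_dfr(draws, function(rep, n, tau, tau2, omega, omega2) {
    inst <- sim_blend_instance(n, seed = seed + rep)
    chain <- loewner_chain(inst$A, inst$G, inst$genotyped_ids,
                           tau, tau2, omega, omega2, tol = tol)
    block_end <- chain$relation[chain$step == "endpoints" & chain$level == "block"]
    full_end <- chain$relation[chain$step == "endpoints" & chain$level == "full"]
    h1 <- h_matrix(inst$A, inst$G, inst$genotyped_ids, tau, omega)
    h2 <- h_matrix(inst$A, inst$G, inst$genotyped_ids, tau2, omega2)
    ko <- kernel_order(h1$H, h2$H, lambda = lambda, tol = tol)
    tibble::tibble(
      rep = rep, n = n, tau = tau, tau2 = tau2,
      omega = omega, omega2 = omega2,
      chain_ok = all(chain$holds[chain$level == "block"]),
      block_full_agree =
        (block_end %in% c("geq", "equal")) == (full_end %in% c("geq", "equal")),
      kernel_agree = all(ko$verdicts$agree)
    )
  })
}
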