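# BLUP for the single-step mixed model and the evaluation metrics.

#' Simple BLUP with every individual phenotyped
#'
#' For the model `y = g + e` with `g ~ N(0, sigma_g^2 H)` and i.i.d. errors,
#' the BLUP of g is `(I + lambda * H^-1)^-1 y` with
#' `lambda = sigma_e^2 / sigma_g^2`.
#'
#' @param y phenotype vector, one entry per individual of H.
#' @param Hinv inverse of the relationship matrix.
#' @param lambda positive variance ratio.
#' @return The EBV vector (named like `Hinv` if it carries dimnames).
#' @export
blup_simple <- function(y, Hinv, lambda) {
  lambda <- scalar_number(lambda, "lambda")
  if (lambda <= 0) ss_abort("lambda must be > 0", "structure")
  if (length(y) != nrow(Hinv)) ss_abort("length(y) != nrow(Hinv)", "structure")
  ghat <- solve(diag(nrow(Hinv)) + lambda * Hinv, y)
  setNames(as.vector(ghat), rownames(Hinv))
}

#' Solve the single-step mixed model equations
#'
#' Generalizes [blup_simple()] to partial phenotyping and an optional
#' intercept. With `W` the 0/1 incidence of phenotype records onto
#' individuals, the system is
#' \deqn{\begin{pmatrix} n_{obs} & \mathbf{1}^T W \\ W^T \mathbf{1} &
#'   W^T W + \lambda H^{-1} \end{pmatrix}
#'   \begin{pmatrix} \hat\mu \\ \hat g \end{pmatrix} =
#'   \begin{pmatrix} \mathbf{1}^T y \\ W^T y \end{pmatrix}.}
#' Unphenotyped individuals receive EBVs through the off-diagonal structure
#' of `H^-1`. With the intercept off and all individuals phenotyped this
#' reduces exactly to [blup_simple()].
#'
#' @param y named phenotype vector over the observed individuals (names must
#'   match rownames of `Hinv`), or a full-length vector with `NA` for
#'   missing records.
#' @param Hinv inverse relationship matrix with id dimnames.
#' @param lambda positive variance ratio `sigma_e^2 / sigma_g^2`.
#' @param intercept include a single mean fixed effect (default `TRUE`).
#' @param solver `"direct"` (dense Cholesky/LU) or `"pcg"` (preconditioned
#'   conjugate gradient with Jacobi preconditioner).
#' @param pcg_tol relative residual tolerance for PCG, default `1e-12`.
#' @param pcg_maxit PCG iteration cap, default `10000`.
#' @return An object of class `ss_blup`: list with `ghat` (named, all
#'   individuals), `mu_hat` (or `NA` without intercept), `iterations` (0 for
#'   the direct solver), `converged`, `lambda`, `solver`, `n_obs`.
#' @export
solve_mme <- function(y, Hinv, lambda, intercept = TRUE,
                      solver = c("direct", "pcg"),
                      pcg_tol = 1e-12, pcg_maxit = 10000L) {
  solver <- match.arg(solver)
  lambda <- scalar_number(lambda, "lambda")
  if (lambda <= 0) ss_abort("lambda must be > 0", "structure")
  ids <- rownames(Hinv)
  if (is.null(ids)) ss_abort("Hinv must carry id dimnames", "ids")
  n <- length(ids)

  if (length(y) == n && is.null(names(y))) names(y) <- ids
  if (is.null(names(y))) ss_abort("y must be named or full-length", "ids")
  y <- y[!is.na(y)]
  if (length(y) == 0) ss_abort("no phenotype records", "degenerate")
  obs <- match(names(y), ids)
  if (anyNA(obs)) ss_abort("phenotyped id absent from Hinv", "ids")

  w <- numeric(n); w[obs] <- 1          # diag of W'W = counts per individual
  wy <- numeric(n); wy[obs] <- y
  Cgg <- diag(w) + lambda * Hinv

  if (intercept) {
    C <- rbind(c(length(y), w), cbind(w, Cgg))
    rhs <- c(sum(y), wy)
  } else {
    C <- Cgg
    rhs <- wy
  }

  if (solver == "direct") {
    sol <- solve(C, rhs)
    iterations <- 0L
    converged <- TRUE
  } else {
    res <- pcg_solve(C, rhs, tol = pcg_tol, maxit = pcg_maxit)
    sol <- res$x
    iterations <- res$iterations
    converged <- res$converged
    if (!converged) {
      warn(sprintf("PCG did not converge in %d iterations", pcg_maxit))
    }
  }

  structure(
    list(
      ghat = setNames(as.vector(if (intercept) sol[-1] else sol), ids),
      mu_hat = if (intercept) unname(sol[1]) else NA_real_,
      iterations = iterations, converged = converged,
      lambda = lambda, solver = solver, n_obs = length(y)
    ),
    class = "ss_blup"
  )
}

# Jacobi-preconditioned conjugate gradient for an SPD dense system.
pcg_solve <- function(A, b, tol = 1e-12, maxit = 10000L) {
  x <- numeric(length(b))
  r <- b
  minv <- 1 / diag(A)
  z <- minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(list(x = x, iterations = 0L, converged = TRUE))
  for (it in seq_len(maxit)) {
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol * bnorm) {
      return(list(x = x, iterations = it, converged = TRUE))
    }
    z <- minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iterations = maxit, converged = FALSE)
}

#' @export
print.ss_blup <- function(x, ...) {
  cat(sprintf(
    "Single-step BLUP fit: %d EBVs, %d phenotypes, lambda = %g (%s solver)\n",
    length(x$ghat), x$n_obs, x$lambda, x$solver))
  if (!is.na(x$mu_hat)) cat(sprintf("  intercept: %.6g\n", x$mu_hat))
  if (x$solver == "pcg") {
    cat(sprintf("  %d iterations, converged: %s\n", x$iterations, x$converged))
  }
  invisible(x)
}

#' @export
tidy.ss_blup <- function(x, ...) {
  tibble::tibble(id = names(x$ghat), ebv = unname(x$ghat))
}

#' @export
glance.ss_blup <- function(x, ...) {
  tibble::tibble(
    n = length(x$ghat), n_obs = x$n_obs, lambda = x$lambda,
    mu_hat = x$mu_hat, solver = x$solver,
    iterations = x$iterations, converged = x$converged
  )
}

#' Predictive ability
#'
#' Pearson's correlation between observed phenotypes and EBVs in a test set.
#' Returns `NA` with a warning when fewer than 3 pairs are available or
#' either variance is zero.
#'
#' @param y_test observed phenotypes.
#' @param ghat_test matching EBVs.
#' @return A single correlation (or `NA`).
#' @export
predictive_ability <- function(y_test, ghat_test) {
  if (length(y_test) != length(ghat_test)) {
    ss_abort("y_test and ghat_test lengths differ", "structure")
  }
  if (length(y_test) < 3) {
    warn("fewer than 3 test pairs; predictive ability undefined")
    return(NA_real_)
  }
  if (var(y_test) == 0 || var(ghat_test) == 0) {
    warn("zero variance in test pairs; predictive ability undefined")
    return(NA_real_)
  }
  cor(y_test, ghat_test)
}

#' Inflation (dispersion) slope
#'
#' Slope of the regression of observed phenotypes (y-axis) on EBVs (x-axis),
#' `b = Cov(y, ghat) / Var(ghat)`. A slope below 1 indicates inflated
#' (over-dispersed) predictions, above 1 deflated ones. The regression
#' direction (observations on predictions) is the validated choice for model
#' evaluation.
#'
#' @inheritParams predictive_ability
#' @return The slope, with a `"direction"` attribute in
#'   `{"inflated", "deflated", "calibrated"}` (or `NA` with a warning).
#' @export
inflation_slope <- function(y_test, ghat_test) {
  if (length(y_test) != length(ghat_test)) {
    ss_abort("y_test and ghat_test lengths differ", "structure")
  }
  if (length(y_test) < 3) {
    warn("fewer than 3 test pairs; slope undefined")
    return(NA_real_)
  }
  if (var(ghat_test) == 0) {
    warn("zero EBV variance; slope undefined")
    return(NA_real_)
  }
  b <- stats::cov(y_test, ghat_test) / var(ghat_test)
  attr(b, "direction") <- if (b < 1) "inflated" else if (b > 1) "deflated" else "calibrated"
  b
}

#' Heritability to variance ratio
#'
#' Converts a narrow-sense heritability into the mixed-model variance ratio
#' `lambda = (1 - h2) / h2`.
#'
#' @param h2 heritability in (0, 1).
#' @return The variance ratio.
#' @export
h2_to_lambda <- function(h2) {
  h2 <- scalar_number(h2, "h2")
  if (h2 <= 0 || h2 >= 1) ss_abort("h2 must be in (0, 1)", "structure")
  (1 - h2) / h2
}
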