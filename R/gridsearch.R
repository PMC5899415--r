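# (tau, omega) grid construction, cross-validation, and the grid screen.

#' Build a (tau, omega) grid
#'
#' Cartesian product of two inclusive fixed-decimal lattices. Grid values are
#' rounded to the lattice (no floating-point drift), so e.g. the default
#' tau in \[0.1, 2\] by 0.1 and omega in \[-1, 1\] by 0.1 gives exactly
#' 20 x 21 = 420 combinations.
#'
#' @param tau_min,tau_max,tau_step tau lattice (defaults 0.1, 2, 0.1).
#' @param omega_min,omega_max,omega_step omega lattice (defaults -1, 1, 0.1).
#' @return A tibble with columns `tau`, `omega`, one row per combination.
#' @export
make_grid <- function(tau_min = 0.1, tau_max = 2, tau_step = 0.1,
                      omega_min = -1, omega_max = 1, omega_step = 0.1) {
  lattice <- function(lo, hi, step, what) {
    step <- scalar_number(step, paste(what, "step"))
    if (step <= 0) ss_abort(sprintf("%s step must be > 0", what), "structure")
    if (lo > hi) ss_abort(sprintf("%s min exceeds max", what), "structure")
    if (lo < hi && step > (hi - lo) + 1e-12) {
      ss_abort(sprintf("%s step larger than range", what), "structure")
    }
    k <- floor((hi - lo) / step + 1e-9)
    round(lo + step * (0:k), 10)
  }
  tidyr::expand_grid(
    tau = lattice(tau_min, tau_max, tau_step, "tau"),
    omega = lattice(omega_min, omega_max, omega_step, "omega")
  )
}

#' Cross-validation fold assignment
#'
#' Random near-equal partition of ids into `n_folds` disjoint folds (sizes
#' differ by at most one; 599 ids in 10 folds gives sizes 59 and 60), or the
#' verbatim assignment from a two-column fold table.
#'
#' @param ids character vector of individual ids.
#' @param n_folds number of folds (>= 2), default 10.
#' @param seed RNG seed for the shuffle; required for reproducibility.
#' @param fold_table optional data frame with columns `id`, `fold`; when
#'   given it is used verbatim and must cover exactly `ids`.
#' @return A tibble with columns `id`, `fold` (integer).
#' @export
make_folds <- function(ids, n_folds = 10, seed = NULL, fold_table = NULL) {
  ids <- as.character(ids)
  if (!is.null(fold_table)) {
    if (!all(c("id", "fold") %in% names(fold_table))) {
      ss_abort("fold table must have columns id, fold", "structure")
    }
    plan <- tibble::tibble(id = as.character(fold_table$id),
                           fold = as.integer(fold_table$fold))
    if (!setequal(plan$id, ids) || anyDuplicated(plan$id)) {
      ss_abort("fold table ids do not match the phenotyped ids", "ids")
    }
    return(plan)
  }
  if (n_folds < 2 || n_folds > length(ids)) {
    ss_abort("n_folds must be in [2, number of ids]", "structure")
  }
  n <- length(ids)
  base <- n %/% n_folds
  sizes <- base + (seq_len(n_folds) <= n %% n_folds)
  shuffled <- if (is.null(seed)) sample(ids) else {
    withr::with_seed(seed, sample(ids))
  }
  tibble::tibble(id = shuffled, fold = rep(seq_len(n_folds), times = sizes)) |>
    dplyr::arrange(match(.data$id, ids))
}

#' Cross-validate one (tau, omega) combination
#'
#' For each fold, the phenotypes of its individuals are withheld (the
#' individuals themselves stay in H, so test EBVs arise through relationship
#' coupling), the mixed model is solved on the remaining records, and
#' predictive ability, inflation slope and solver iterations are recorded on
#' the test fold. Folds with fewer than 3 phenotyped test individuals get
#' missing metrics.
#'
#' @param data an [ss_data] object with phenotypes.
#' @param tau,omega blend weights, or `Hinv` given directly.
#' @param folds fold assignment from [make_folds()].
#' @param h2 assumed heritability, converted to `lambda = (1 - h2)/h2`;
#'   default 0.5.
#' @param intercept,solver passed to [solve_mme()].
#' @param Hinv optional precomputed inverse relationship matrix (overrides
#'   `tau`/`omega`; used e.g. to run plain pedigree BLUP with `data$Ainv`).
#' @return A tibble with one row per fold: `tau`, `omega`, `fold`, `n_test`,
#'   `r`, `b`, `iterations`, `converged`.
#' @export
run_cv <- function(data, tau = NULL, omega = NULL, folds, h2 = 0.5,
                   intercept = TRUE, solver = "direct", Hinv = NULL) {
  stopifnot(inherits(data, "ss_data"))
  if (is.null(data$phenotypes)) ss_abort("dataset has no phenotypes", "structure")
  if (is.null(Hinv)) {
    Hinv <- h_inverse_for(data, tau, omega)
  } else {
    tau <- tau %||% NA_real_; omega <- omega %||% NA_real_
  }
  lambda <- h2_to_lambda(h2)
  ph <- data$phenotypes
  yfull <- setNames(ph$y, ph$id)

  purrr::map_dfr(sort(unique(folds$fold)), function(f) {
    test_ids <- folds$id[folds$fold == f]
    ytrain <- yfull
    ytrain[names(ytrain) %in% test_ids] <- NA
    fit <- solve_mme(ytrain, Hinv, lambda, intercept = intercept,
                     solver = solver)
    keep <- test_ids[!is.na(yfull[test_ids])]
    yt <- unname(yfull[keep])
    gt <- unname(fit$ghat[keep])
    if (length(keep) < 3) {
      r <- NA_real_; b <- NA_real_
    } else {
      r <- suppressWarnings(predictive_ability(yt, gt))
      b <- suppressWarnings(as.numeric(inflation_slope(yt, gt)))
    }
    tibble::tibble(tau = tau, omega = omega, fold = f,
                   n_test = length(keep), r = r, b = b,
                   iterations = fit$iterations, converged = fit$converged)
  })
}

#' Cross-validated screen over a (tau, omega) grid
#'
#' Runs [run_cv()] for every grid combination and summarizes per-combination
#' mean predictive ability, mean inflation slope and mean iterations.
#' Combinations whose H inverse cannot be built (e.g. indefinite blends with
#' omega > 1 on an unadjusted G) are recorded as failed cells rather than
#' aborting the sweep. Ties at the optimum are broken towards the original
#' single-step weights: smallest `(tau - 1)^2 + omega^2`, then lexicographic.
#'
#' @inheritParams run_cv
#' @param grid tibble of `tau`, `omega` combinations from [make_grid()].
#' @return A tibble of class `ss_grid` with columns `tau`, `omega`, `mean_r`,
#'   `mean_b`, `mean_iterations`, `n_failed_folds`, `failed`; per-fold detail
#'   in `attr(, "folds")`, argmax rows in `attr(, "best_r")` and
#'   `attr(, "best_b")`.
#' @export
grid_search <- function(data, grid = make_grid(), folds, h2 = 0.5,
                        intercept = TRUE, solver = "direct") {
  detail <- purrr::pmap_dfr(grid, function(tau, omega) {
    tryCatch(
      run_cv(data, tau, omega, folds, h2 = h2, intercept = intercept,
             solver = solver),
      ssblend_error = function(e) {
        tibble::tibble(tau = tau, omega = omega, fold = NA_integer_,
                       n_test = 0L, r = NA_real_, b = NA_real_,
                       iterations = NA_integer_, converged = FALSE)
      }
    )
  })
  summary <- detail |>
    dplyr::group_by(.data$tau, .data$omega) |>
    dplyr::summarise(
      mean_r = mean(.data$r, na.rm = TRUE),
      mean_b = mean(.data$b, na.rm = TRUE),
      mean_iterations = mean(.data$iterations, na.rm = TRUE),
      n_failed_folds = sum(is.na(.data$r)),
      failed = all(is.na(.data$fold)),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean_r = ifelse(is.nan(.data$mean_r), NA_real_, .data$mean_r),
                  mean_b = ifelse(is.nan(.data$mean_b), NA_real_, .data$mean_b))
  # restore grid order
  summary <- summary[match(paste(grid$tau, grid$omega),
                           paste(summary$tau, summary$omega)), ]

  pick_best <- function(metric) {
    ok <- summary[!is.na(summary[[metric]]), ]
    if (nrow(ok) == 0) return(ok)
    ok <- ok[ok[[metric]] == max(ok[[metric]]), ]
    ok[order((ok$tau - 1)^2 + ok$omega^2, ok$tau, ok$omega), ][1, ]
  }
  structure(summary,
            class = c("ss_grid", class(summary)),
            folds = detail, h2 = h2,
            best_r = pick_best("mean_r"), best_b = pick_best("mean_b"))
}

#' @export
tidy.ss_grid <- function(x, ...) {
  attr(x, "folds")
}

#' @export
glance.ss_grid <- function(x, ...) {
  br <- attr(x, "best_r"); bb <- attr(x, "best_b")
  tibble::tibble(
    n_cells = nrow(x), n_failed = sum(x$failed), h2 = attr(x, "h2"),
    best_r_tau = br$tau, best_r_omega = br$omega, best_r = br$mean_r,
    best_b_tau = bb$tau, best_b_omega = bb$omega, best_b = bb$mean_b
  )
}

#' Heat plot of a grid screen
#'
#' Tile plot of a grid-search metric over the (tau, omega) plane, the usual
#' way these screens are displayed.
#'
#' @param object an `ss_grid` result.
#' @param metric column to plot, default `"mean_r"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ss_grid <- function(object, metric = "mean_r", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$tau, y = .data$omega,
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = metric) +
    ggplot2::labs(x = expression(tau), y = expression(omega)) +
    ggplot2::theme_minimal()
}
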