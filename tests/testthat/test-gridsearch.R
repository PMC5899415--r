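small_sim <- function(seed = 3, ...) {
  cfg <- sim_config(n_founders = 10, n_generations = 2,
                    offspring_per_generation = 15, n_markers = 100,
                    n_qtl = 20, seed = seed, ...)
  simulate_population(cfg)
}

test_that("the default lattice has 420 combinations and small grids enumerate", {
  expect_equal(nrow(make_grid()), 420)
  expect_equal(nrow(make_grid(1, 1, 0.1, 0, 0, 0.1)), 1)
  g <- make_grid(0.1, 0.3, 0.1, 0, 0.1, 0.1)
  expect_equal(nrow(g), 6)
  expect_equal(sort(unique(g$tau)), c(0.1, 0.2, 0.3))
  expect_error(make_grid(0.1, 0.2, 0.5), class = "ssblend_error_structure")
  # values sit exactly on the decimal lattice
  expect_true(all(make_grid()$tau %in% round(seq(0.1, 2, 0.1), 10)))
})

test_that("fold assignment is near-equal, seeded, and file round-trippable", {
  ids <- sprintf("L%03d", 1:599)
  plan <- make_folds(ids, 10, seed = 42)
  sizes <- table(plan$fold)
  expect_true(all(sizes %in% c(59, 60)))
  expect_equal(sort(unique(plan$fold)), 1:10)
  expect_identical(plan, make_folds(ids, 10, seed = 42))
  expect_false(identical(plan, make_folds(ids, 10, seed = 43)))

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_folds(plan, tmp)
  expect_equal(make_folds(ids, fold_table = read_folds(tmp)), plan)
  bad <- plan; bad$id[1] <- "stranger"
  expect_error(make_folds(ids, fold_table = bad), class = "ssblend_error_ids")
})

test_that("cross-validation recovers a near-noiseless trait", {
  # all-causal dosage markers, h2 ~ 1, everyone (but one) genotyped
  cfg <- sim_config(h2 = 0.999, coding = "dosage012", n_markers = 80,
                    n_qtl = 80, seed = 11)
  ped <- simulate_pedigree(cfg)
  drop <- gene_drop(ped, cfg)
  phen <- simulate_phenotypes(ped, drop$dosage, cfg)
  d <- ss_data(ped[, c("id", "sire", "dam")], drop$dosage,
               tibble::tibble(id = ped$id, y = unname(phen$y[ped$id])),
               genotyped_ids = ped$id[-1], coding = "dosage012")
  folds <- make_folds(d$phenotypes$id, 10, seed = 1)
  cv <- run_cv(d, 1, 1, folds, h2 = 0.999)
  expect_equal(nrow(cv), 10)
  expect_gt(mean(cv$r), 0.95)
})

test_that("permuted phenotypes have no predictive ability", {
  sim <- small_sim(seed = 3)
  d <- sim$data
  folds <- make_folds(d$phenotypes$id, 5, seed = 4)
  rs <- sapply(1:20, function(k) {
    dp <- d
    dp$phenotypes$y <- withr::with_seed(100 + k, sample(dp$phenotypes$y))
    mean(run_cv(dp, 1, 1, folds)$r)
  })
  expect_lt(abs(mean(rs)), 3 * stats::sd(rs) / sqrt(length(rs)))
})

test_that("zero blend weights reproduce pedigree BLUP exactly", {
  sim <- small_sim(seed = 5)
  d <- sim$data
  folds <- make_folds(d$phenotypes$id, 5, seed = 6)
  cv_blend <- run_cv(d, 0, 0, folds)
  cv_ped <- run_cv(d, folds = folds, Hinv = d$Ainv)
  expect_lt(max(abs(cv_blend$r - cv_ped$r)), 1e-8)
  expect_lt(max(abs(cv_blend$b - cv_ped$b)), 1e-8)
})

test_that("grid search bookkeeping is exact and ties break towards (1, 0)", {
  sim <- small_sim(seed = 7)
  d <- sim$data
  folds <- make_folds(d$phenotypes$id, 4, seed = 8)
  grid <- make_grid(0.5, 1, 0.5, 0, 0.5, 0.5)  # 2 x 2
  res <- grid_search(d, grid, folds)
  expect_s3_class(res, "ss_grid")
  expect_equal(nrow(res), 4)
  detail <- tidy(res)
  recomputed <- detail |>
    dplyr::group_by(tau, omega) |>
    dplyr::summarise(mean_r = mean(r), mean_b = mean(b), .groups = "drop")
  merged <- dplyr::left_join(as.data.frame(res)[c("tau", "omega", "mean_r", "mean_b")],
                             recomputed, by = c("tau", "omega"))
  expect_equal(merged$mean_r.x, merged$mean_r.y)
  expect_equal(merged$mean_b.x, merged$mean_b.y)
  gl <- glance(res)
  expect_equal(gl$n_cells, 4)
  expect_true(is.finite(gl$best_r))

  # results do not depend on cell evaluation order
  res_rev <- grid_search(d, grid[4:1, ], folds)
  expect_equal(as.data.frame(res)[c("tau", "omega", "mean_r")] |>
                 dplyr::arrange(tau, omega),
               as.data.frame(res_rev)[c("tau", "omega", "mean_r")] |>
                 dplyr::arrange(tau, omega))
})

test_that("an over-optimistic variance ratio shows the inflation trend", {
  sim <- small_sim(seed = 9)
  d <- sim$data
  folds <- make_folds(d$phenotypes$id, 5, seed = 10)
  # true h2 is 0.5; fitting with h2 = 0.8 under-shrinks and inflates
  b_tau <- sapply(c(0.5, 1, 1.5, 2),
                  function(t) mean(run_cv(d, t, 0.5, folds, h2 = 0.8)$b))
  expect_false(is.unsorted(b_tau + 1e-8))
})

test_that("failed cells are recorded without aborting the sweep", {
  sim <- small_sim(seed = 13)
  d <- sim$data
  folds <- make_folds(d$phenotypes$id, 4, seed = 14)
  grid <- tibble::tibble(tau = c(1, 0.1), omega = c(0.5, 2))  # second is invalid
  res <- grid_search(d, grid, folds)
  expect_false(res$failed[1])
  expect_true(res$failed[2])
  expect_true(is.na(res$mean_r[2]))
})

test_that("swapping which half is genotyped yields a complete second table", {
  sim <- small_sim(seed = 15)
  d1 <- sim$data
  d2 <- swap_genotyped(d1, sim$markers_all)
  expect_setequal(d2$ids2, d1$ids1)
  folds <- make_folds(d1$phenotypes$id, 4, seed = 16)
  grid <- make_grid(1, 1, 0.1, 0, 0.5, 0.5)
  r1 <- grid_search(d1, grid, folds)
  r2 <- grid_search(d2, grid, folds)
  expect_equal(dim(r1), dim(r2))
  expect_true(all(is.finite(r2$mean_r)))
})

test_that("autoplot renders a heat tile per grid cell", {
  sim <- small_sim(seed = 17)
  folds <- make_folds(sim$data$phenotypes$id, 4, seed = 18)
  res <- grid_search(sim$data, make_grid(0.5, 1, 0.5, 0, 0.5, 0.5), folds)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  expect_equal(nrow(ggplot2::layer_data(p)), 4)
})
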