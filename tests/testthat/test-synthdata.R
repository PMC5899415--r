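test_that("simulated pedigrees are topological, seeded, and accumulate kinship", {
  cfg <- sim_config(n_founders = 20, n_generations = 3,
                    offspring_per_generation = 40, n_markers = 2, n_qtl = 1,
                    seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_identical(ped, simulate_pedigree(cfg))
  expect_false(identical(ped, simulate_pedigree(cfg, seed = 2)))
  # parents precede offspring and never self
  expect_silent(validate_pedigree(ped[, c("id", "sire", "dam")]))
  expect_true(all(ped$sire[ped$generation > 0] != ped$dam[ped$generation > 0]))

  # founders only
  ped0 <- simulate_pedigree(sim_config(n_founders = 5, n_generations = 1,
                                       offspring_per_generation = 1,
                                       n_markers = 2, n_qtl = 1, seed = 1))
  A0 <- a_matrix(ped0[ped0$generation == 0, c("id", "sire", "dam")])
  expect_equal(unname(A0), diag(5))

  # relatedness accumulates in the last generation
  A <- a_matrix(ped[, c("id", "sire", "dam")])
  last <- ped$id[ped$generation == max(ped$generation)]
  off <- A[last, last][upper.tri(diag(length(last)))]
  expect_gt(mean(off), 0)
})

test_that("gene dropping is Mendelian, seeded, and frequency-faithful", {
  cfg <- sim_config(n_founders = 500, n_generations = 1,
                    offspring_per_generation = 1, n_markers = 60, n_qtl = 5,
                    seed = 2)
  ped <- simulate_pedigree(cfg)
  drop <- gene_drop(ped, cfg)
  expect_identical(drop$dosage, gene_drop(ped, cfg)$dosage)
  expect_true(all(drop$dosage %in% 0:2))
  expect_true(all(drop$presence %in% 0:1))
  expect_identical(unname(drop$presence), unname((drop$dosage > 0) + 0L))
  # founder dosage column means track 2 p_j within ~4 binomial SEs (n = 500)
  founders <- ped$id[ped$generation == 0]
  cm <- colMeans(drop$dosage[founders, ])
  se <- sqrt(2 * drop$freq * (1 - drop$freq) / length(founders))
  expect_true(all(abs(cm - 2 * drop$freq) < 4.5 * se))
  # founder heterozygosity matches 2p(1-p) in aggregate
  het <- colMeans(drop$dosage[founders, ] == 1)
  expect_lt(abs(mean(het - 2 * drop$freq * (1 - drop$freq))), 0.01)
})

test_that("fixed allele frequencies give monomorphic markers downstream", {
  cfg <- sim_config(n_founders = 5, n_generations = 1,
                    offspring_per_generation = 2, n_markers = 10, n_qtl = 2,
                    p_lo = 0.999, p_hi = 0.999, seed = 3)
  ped <- simulate_pedigree(cfg)
  drop <- gene_drop(ped, cfg)
  # overwhelmingly fixed; with every marker monomorphic G must refuse
  Zc <- drop$presence
  Zc[] <- 1L
  expect_error(g_vanraden(Zc), class = "ssblend_error_degenerate")
})

test_that("phenotypes hit the target heritability and separate their seeds", {
  cfg <- sim_config(n_founders = 30, n_generations = 3,
                    offspring_per_generation = 90, n_markers = 200,
                    n_qtl = 50, h2 = 0.5, seed = 4)
  ped <- simulate_pedigree(cfg)
  drop <- gene_drop(ped, cfg)
  ph <- simulate_phenotypes(ped, drop$dosage, cfg)
  realized <- empirical_var(ph$g_true) / empirical_var(ph$y)
  expect_gt(realized, 0.35)
  expect_lt(realized, 0.65)

  # near-noiseless limit
  cfg99 <- sim_config(n_founders = 30, n_generations = 2,
                      offspring_per_generation = 60, n_markers = 200,
                      n_qtl = 50, h2 = 0.999, seed = 5)
  ped99 <- simulate_pedigree(cfg99)
  d99 <- gene_drop(ped99, cfg99)
  ph99 <- simulate_phenotypes(ped99, d99$dosage, cfg99)
  expect_gt(cor(ph99$y, ph99$g_true), 0.99)

  # changing the noise seed leaves the genetic values untouched
  ph2 <- simulate_phenotypes(ped, drop$dosage, cfg, seed_noise = 777)
  expect_identical(ph$g_true, ph2$g_true)
  expect_false(identical(ph$y, ph2$y))
})

test_that("group splits follow the wheat-style rules", {
  ids <- sprintf("L%03d", 1:599)
  sp <- split_groups(ids, "first_half_ungenotyped")
  expect_equal(length(sp$group1), 300)
  expect_equal(length(sp$group2), 299)
  expect_identical(sp$group1, ids[1:300])

  sw <- split_groups(ids, "second_half_ungenotyped")
  expect_identical(sw$group1, sp$group2)
  expect_identical(sw$group2, sp$group1)

  ex <- split_groups(ids, "explicit", genotyped = ids[5:10])
  expect_identical(ex$group2, ids[5:10])
  expect_error(split_groups(ids, "fraction", fraction = 0),
               class = "ssblend_error_structure")
})

test_that("the full simulator is deterministic given its config", {
  cfg <- sim_config(n_founders = 8, n_generations = 2,
                    offspring_per_generation = 10, n_markers = 50,
                    n_qtl = 10, seed = 6)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$data$G, s2$data$G)
  expect_identical(s1$data$phenotypes, s2$data$phenotypes)
})

test_that("genomic information beats pedigree-only prediction on average", {
  wins <- sapply(1:10, function(seed) {
    cfg <- sim_config(seed = seed, coding = "dosage012",
                      n_markers = 200, n_qtl = 50,
                      n_founders = 20, n_generations = 2,
                      offspring_per_generation = 40)
    ped <- simulate_pedigree(cfg)
    drop <- gene_drop(ped, cfg)
    phen <- simulate_phenotypes(ped, drop$dosage, cfg)
    d <- ss_data(ped[, c("id", "sire", "dam")], drop$dosage,
                 tibble::tibble(id = ped$id, y = unname(phen$y[ped$id])),
                 genotyped_ids = ped$id[-1], coding = "dosage012")
    yv <- setNames(d$phenotypes$y, d$phenotypes$id)
    lambda <- 1  # matches the simulated h2 = 0.5
    g_gen <- blup_simple(yv, h_inverse_for(d, 1, 1), lambda)
    g_ped <- blup_simple(yv, d$Ainv, lambda)
    gt <- setNames(phen$g_true, names(phen$g_true))[d$ids]
    cor(g_gen, gt) - cor(g_ped, gt)
  })
  expect_gt(mean(wins), 0)
})

test_that("simulator configs are validated", {
  expect_error(sim_config(h2 = 1.2), class = "ssblend_error_structure")
  expect_error(sim_config(n_qtl = 10, n_markers = 5),
               class = "ssblend_error_structure")
  expect_error(sim_config(p_lo = 0), class = "ssblend_error_structure")
})
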