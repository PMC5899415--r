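# Pedigree-linked population simulator: random mating pedigree, Mendelian
# gene dropping of biallelic markers, and marker-effect phenotypes. The
# defaults emulate, at desk scale, a selfed-line panel genotyped with
# dominant presence/absence markers and split into a non-genotyped Group 1
# and a genotyped Group 2.

#' Simulation configuration
#'
#' Validated parameter bundle for the population simulator. Defaults give a
#' population of 30 unrelated founders plus 3 generations of 40 offspring
#' (n = 150), 500 biallelic markers with founder allele frequencies uniform
#' on \[0.1, 0.9\], 50 of which are causal, heritability 0.5, DArT-like
#' presence/absence marker output, and the first half of the population
#' treated as non-genotyped.
#'
#' @param n_founders number of unrelated founders.
#' @param n_generations number of non-founder generations.
#' @param offspring_per_generation offspring produced per generation.
#' @param n_markers number of biallelic markers.
#' @param n_qtl number of causal markers (<= `n_markers`).
#' @param h2 narrow-sense heritability in (0, 1).
#' @param p_lo,p_hi founder allele-frequency range.
#' @param coding marker output coding, `"presence01"` or `"dosage012"`.
#' @param genotyped_rule group split rule, see [split_groups()].
#' @param genotyped_fraction fraction genotyped under the `"fraction"` rule.
#' @param mu phenotype mean.
#' @param seed base RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 30, n_generations = 3,
                       offspring_per_generation = 40,
                       n_markers = 500, n_qtl = 50, h2 = 0.5,
                       p_lo = 0.1, p_hi = 0.9,
                       coding = c("presence01", "dosage012"),
                       genotyped_rule = "first_half_ungenotyped",
                       genotyped_fraction = 0.5, mu = 0, seed = 1L) {
  coding <- match.arg(coding)
  counts <- c(n_founders = n_founders, n_generations = n_generations,
              offspring_per_generation = offspring_per_generation,
              n_markers = n_markers, n_qtl = n_qtl)
  if (any(counts <= 0) || any(counts != round(counts))) {
    ss_abort("all simulator counts must be positive integers", "structure")
  }
  if (n_founders < 2) ss_abort("need at least 2 founders", "structure")
  if (n_qtl > n_markers) ss_abort("n_qtl exceeds n_markers", "structure")
  if (h2 <= 0 || h2 >= 1) ss_abort("h2 must be in (0, 1)", "structure")
  if (p_lo <= 0 || p_hi >= 1 || p_lo > p_hi) {
    ss_abort("need 0 < p_lo <= p_hi < 1", "structure")
  }
  structure(
    list(n_founders = as.integer(n_founders),
         n_generations = as.integer(n_generations),
         offspring_per_generation = as.integer(offspring_per_generation),
         n_markers = as.integer(n_markers), n_qtl = as.integer(n_qtl),
         h2 = h2, p_lo = p_lo, p_hi = p_hi, coding = coding,
         genotyped_rule = genotyped_rule,
         genotyped_fraction = genotyped_fraction, mu = mu,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a random-mating pedigree
#'
#' Founders are unrelated and non-inbred; each offspring in generation g
#' draws two distinct parents uniformly from generation g - 1 (no selfing).
#' Records are produced in topological order by construction.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed, defaults to `cfg$seed`.
#' @return A tibble with columns `id`, `sire`, `dam`, `generation`.
#' @export
simulate_pedigree <- function(cfg, seed = cfg$seed) {
  withr::with_seed(seed, {
    ids <- sprintf("F%03d", seq_len(cfg$n_founders))
    ped <- tibble::tibble(id = ids, sire = "0", dam = "0", generation = 0L)
    prev <- ids
    counter <- 0L
    for (g in seq_len(cfg$n_generations)) {
      off <- purrr::map_dfr(seq_len(cfg$offspring_per_generation), function(k) {
        parents <- sample(prev, 2, replace = FALSE)
        tibble::tibble(id = sprintf("G%d_%03d", g, k),
                       sire = parents[1], dam = parents[2],
                       generation = g)
      })
      ped <- dplyr::bind_rows(ped, off)
      prev <- off$id
      counter <- counter + nrow(off)
    }
    ped
  })
}

#' Mendelian gene dropping of biallelic markers
#'
#' Each marker j gets a founder allele frequency drawn from
#' `U(p_lo, p_hi)`; founders receive two alleles i.i.d. Bernoulli(p_j) and
#' every offspring inherits one uniformly chosen allele from each parent.
#' The diploid dosage (0/1/2) is always tracked; the presence coding is its
#' indicator (>= 1 copy), emulating dominant presence/absence markers.
#'
#' @param ped pedigree tibble (topological order) from [simulate_pedigree()].
#' @param cfg a [sim_config()].
#' @param seed RNG seed, defaults to `cfg$seed + 1`.
#' @return A list with `dosage` (n x p matrix, 0/1/2), `presence` (0/1),
#'   `freq` (founder allele frequencies).
#' @export
gene_drop <- function(ped, cfg, seed = cfg$seed + 1L) {
  withr::with_seed(seed, {
    n <- nrow(ped)
    p <- cfg$n_markers
    freq <- runif(p, cfg$p_lo, cfg$p_hi)
    si <- match(ped$sire, ped$id)
    di <- match(ped$dam, ped$id)
    M1 <- matrix(0L, n, p)   # allele inherited via sire side
    M2 <- matrix(0L, n, p)   # allele inherited via dam side
    for (i in seq_len(n)) {
      if (is.na(si[i])) {
        M1[i, ] <- rbinom(p, 1, freq)
        M2[i, ] <- rbinom(p, 1, freq)
      } else {
        pick1 <- rbinom(p, 1, 0.5) == 1L
        M1[i, ] <- ifelse(pick1, M1[si[i], ], M2[si[i], ])
        pick2 <- rbinom(p, 1, 0.5) == 1L
        M2[i, ] <- ifelse(pick2, M1[di[i], ], M2[di[i], ])
      }
    }
    dosage <- M1 + M2
    dimnames(dosage) <- list(ped$id, sprintf("M%04d", seq_len(p)))
    presence <- (dosage > 0) + 0L
    dimnames(presence) <- dimnames(dosage)
    list(dosage = dosage, presence = presence, freq = freq)
  })
}

#' Marker-effect phenotypes
#'
#' Draws a QTL subset and i.i.d. normal allele-substitution effects, forms
#' the true breeding values `g = Z_qtl alpha` (centered, from the diploid
#' dosages regardless of the marker output coding), and adds environmental
#' noise with variance `Var(g) (1 - h2) / h2` so the expected heritability
#' is `h2`. Phenotypes exist for every pedigree member, genotyped or not.
#' The genetic architecture (QTL, effects) and the noise use separate seeds
#' so the noise can be re-drawn without changing `g`.
#'
#' @param ped pedigree tibble.
#' @param dosage diploid dosage matrix over all individuals.
#' @param cfg a [sim_config()].
#' @param seed_genetic seed for QTL positions and effects
#'   (default `cfg$seed + 2`).
#' @param seed_noise seed for the environmental noise
#'   (default `cfg$seed + 3`).
#' @return A list with `y` (named), `g_true` (named), `qtl`, `effects`,
#'   `sigma_g2`, `sigma_e2`.
#' @export
simulate_phenotypes <- function(ped, dosage, cfg,
                                seed_genetic = cfg$seed + 2L,
                                seed_noise = cfg$seed + 3L) {
  gen <- withr::with_seed(seed_genetic, {
    qtl <- sort(sample(ncol(dosage), cfg$n_qtl))
    effects <- rnorm(cfg$n_qtl)
    list(qtl = qtl, effects = effects)
  })
  g <- as.vector(dosage[, gen$qtl, drop = FALSE] %*% gen$effects)
  g <- g - mean(g)
  sigma_g2 <- empirical_var(g)
  sigma_e2 <- sigma_g2 * (1 - cfg$h2) / cfg$h2
  eps <- withr::with_seed(seed_noise, rnorm(nrow(ped), 0, sqrt(sigma_e2)))
  y <- cfg$mu + g + eps
  list(y = setNames(y, ped$id), g_true = setNames(g, ped$id),
       qtl = gen$qtl, effects = gen$effects,
       sigma_g2 = sigma_g2, sigma_e2 = sigma_e2)
}

#' Split ids into non-genotyped (Group 1) and genotyped (Group 2)
#'
#' Deterministic rules mirroring the scenario mechanism of splitting a line
#' panel by its order: `"first_half_ungenotyped"` puts the first
#' `ceiling(n/2)` ids into Group 1 (599 ids give 300 | 299),
#' `"second_half_ungenotyped"` swaps the halves, `"fraction"` samples
#' Group 2 of size `round(fraction * n)` with a seed, and `"explicit"` uses
#' the supplied id list.
#'
#' @param ids all individual ids, in panel order.
#' @param rule one of `"first_half_ungenotyped"`,
#'   `"second_half_ungenotyped"`, `"fraction"`, `"explicit"`.
#' @param fraction genotyped fraction for the `"fraction"` rule.
#' @param seed seed for the `"fraction"` rule.
#' @param genotyped explicit Group 2 ids for the `"explicit"` rule.
#' @return A list with `group1` (non-genotyped) and `group2` (genotyped).
#' @export
split_groups <- function(ids, rule = c("first_half_ungenotyped",
                                       "second_half_ungenotyped",
                                       "fraction", "explicit"),
                         fraction = 0.5, seed = NULL, genotyped = NULL) {
  rule <- match.arg(rule)
  ids <- as.character(ids)
  n <- length(ids)
  half <- ceiling(n / 2)
  out <- switch(rule,
    first_half_ungenotyped = list(group1 = ids[seq_len(half)],
                                  group2 = ids[-seq_len(half)]),
    second_half_ungenotyped = list(group1 = ids[-seq_len(half)],
                                   group2 = ids[seq_len(half)]),
    fraction = {
      k <- round(fraction * n)
      if (k <= 0 || k >= n) {
        ss_abort("fraction rule would leave an empty group", "structure")
      }
      g2 <- if (is.null(seed)) sample(ids, k) else
        withr::with_seed(seed, sample(ids, k))
      list(group1 = setdiff(ids, g2), group2 = ids[ids %in% g2])
    },
    explicit = {
      if (is.null(genotyped)) ss_abort("explicit rule needs genotyped ids", "ids")
      if (!all(genotyped %in% ids)) ss_abort("unknown genotyped id", "ids")
      list(group1 = setdiff(ids, genotyped),
           group2 = ids[ids %in% genotyped])
    }
  )
  out
}

#' Simulate a complete single-step study population
#'
#' One-stop wrapper chaining [simulate_pedigree()], [gene_drop()],
#' [simulate_phenotypes()] and [split_groups()], and assembling the result
#' into an [ss_data()] object plus the simulation truth. Sub-seeds are
#' derived from `cfg$seed` by fixed small offsets.
#'
#' @param cfg a [sim_config()].
#' @param beta,ridge genomic-matrix adjustment passed to [ss_data()].
#' @return A list of class `ss_sim`: `data` (an `ss_data`), `truth` (tibble
#'   `id`, `g_true`), `y` (named vector over all individuals), `qtl`,
#'   `effects`, `sigma_g2`, `sigma_e2`, `markers_all` (all-individual marker
#'   matrix in the output coding), `dosage`, `config`.
#' @export
simulate_population <- function(cfg = sim_config(), beta = 0.05, ridge = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  ped <- simulate_pedigree(cfg)
  drop <- gene_drop(ped, cfg)
  phen <- simulate_phenotypes(ped, drop$dosage, cfg)
  groups <- split_groups(ped$id, rule = cfg$genotyped_rule,
                         fraction = cfg$genotyped_fraction,
                         seed = cfg$seed + 4L)
  Zout <- if (cfg$coding == "presence01") drop$presence else drop$dosage
  data <- ss_data(
    ped[, c("id", "sire", "dam")],
    markers = Zout[groups$group2, , drop = FALSE],
    phenotypes = tibble::tibble(id = ped$id, y = unname(phen$y[ped$id])),
    genotyped_ids = groups$group2,
    coding = cfg$coding, beta = beta, ridge = ridge
  )
  structure(
    list(data = data,
         truth = tibble::tibble(id = names(phen$g_true),
                                g_true = unname(phen$g_true)),
         y = phen$y, qtl = phen$qtl, effects = phen$effects,
         sigma_g2 = phen$sigma_g2, sigma_e2 = phen$sigma_e2,
         markers_all = Zout, dosage = drop$dosage, founder_freq = drop$freq,
         config = cfg),
    class = "ss_sim"
  )
}

#' @export
print.ss_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Simulated single-step population (seed %d): n = %d, %d markers, %d QTL, h2 = %g\n",
    cfg$seed, length(x$y), cfg$n_markers, cfg$n_qtl, cfg$h2))
  print(x$data)
  invisible(x)
}

#' Random (A, G) instance for property sweeps
#'
#' Small random instance used by the numerical verification sweeps: A comes
#' from a simulated pedigree (realistic block structure), and G is a
#' Wishart-style matrix `crossprod(X)/p` (with `p = n + 5` normal rows, so
#' almost surely positive definite) rescaled to mean diagonal 1 over the
#' genotyped subset.
#'
#' @param n total number of individuals (>= 4).
#' @param n_genotyped size of Group 2 (default `floor(n/2)`).
#' @param seed RNG seed.
#' @return A list with `A`, `G`, `genotyped_ids`, `ids`.
#' @export
sim_blend_instance <- function(n = 8, n_genotyped = max(2L, floor(n / 2)),
                               seed = 1L) {
  if (n < 4) ss_abort("need n >= 4", "structure")
  nf <- max(2L, floor(n / 2))
  noff <- n - nf
  cfg <- sim_config(n_founders = nf, n_generations = 1,
                    offspring_per_generation = max(1L, noff),
                    n_markers = 2, n_qtl = 1, seed = seed)
  ped <- simulate_pedigree(cfg)
  ped <- ped[seq_len(n), ]
  A <- a_matrix(ped[, c("id", "sire", "dam")])
  gids <- ped$id[seq.int(n - n_genotyped + 1L, n)]
  G <- withr::with_seed(seed + 1000L, {
    X <- matrix(rnorm((n_genotyped + 5) * n_genotyped), n_genotyped + 5)
    W <- crossprod(X) / (n_genotyped + 5)
    W / mean(diag(W))
  })
  dimnames(G) <- list(gids, gids)
  list(A = A, G = G, genotyped_ids = gids, ids = ped$id)
}
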