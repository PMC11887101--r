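test_that("pedigrees have litters of full sibs and are reproducible", {
  cfg <- sim_config(n_founders = 10, n_generations = 1, litter_size = 3,
                    seed = 1)
  ped <- simulate_pedigree(cfg)
  kids <- ped[ped$generation == 1, ]
  expect_gte(nrow(kids), 3)
  fam <- paste(kids$sire, kids$dam)
  expect_true(any(table(fam) == 3))     # at least one full-sib triplet

  # founders only
  cfg0 <- sim_config(n_founders = 2, n_generations = 0, seed = 1)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(ped0$generation, c(0L, 0L))

  # same seed, same pedigree; config validation
  expect_identical(simulate_pedigree(cfg), simulate_pedigree(cfg))
  expect_error(sim_config(litter_size = 0), "litter_size")
})

test_that("founder genotypes are Hardy-Weinberg with tunable adjacent LD", {
  # near-zero LD parameter: adjacent r2 averages close to 0
  cfg <- sim_config(n_founders = 300, n_generations = 0, n_snps = 1000,
                    n_chromosomes = 1, ld_decay = 1e-6, seed = 3)
  g <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  D <- g$dosages
  r2 <- vapply(seq_len(ncol(D) - 1), function(j) {
    suppressWarnings(cor(D[, j], D[, j + 1])^2)
  }, numeric(1))
  expect_lt(mean(r2, na.rm = TRUE), 0.05)

  # strong LD parameter raises adjacent r2 well above that
  cfg2 <- sim_config(n_founders = 300, n_generations = 0, n_snps = 1000,
                     n_chromosomes = 1, ld_decay = 0.9, seed = 3)
  g2 <- simulate_genotypes(simulate_pedigree(cfg2), cfg2)
  r2b <- vapply(seq_len(999), function(j) {
    suppressWarnings(cor(g2$dosages[, j], g2$dosages[, j + 1])^2)
  }, numeric(1))
  expect_gt(mean(r2b, na.rm = TRUE), 0.3)

  # genotype frequencies near Hardy-Weinberg for a mid-frequency SNP
  cfg3 <- sim_config(n_founders = 2000, n_generations = 0, n_snps = 50,
                     n_chromosomes = 1, maf_range = c(0.3, 0.3), seed = 5)
  g3 <- simulate_genotypes(simulate_pedigree(cfg3), cfg3)
  freq <- table(factor(g3$dosages[, 25], levels = 0:2)) / 2000
  expect_equal(as.numeric(freq), c(0.49, 0.42, 0.09), tolerance = 0.05)

  expect_identical(simulate_genotypes(simulate_pedigree(cfg3), cfg3)$dosages,
                   g3$dosages)
})

test_that("gene dropping gives sib GRM near 0.5 and founder GRM near identity", {
  cfg <- sim_config(n_founders = 60, n_generations = 1, n_snps = 5000,
                    n_chromosomes = 10, seed = 7)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  K <- centered_grm(g)
  kids <- ped[ped$generation == 1, ]
  fam <- split(kids$id, paste(kids$sire, kids$dam))
  sib_vals <- unlist(lapply(fam, function(ids) {
    if (length(ids) < 2) return(NULL)
    kk <- K[ids, ids] / mean(diag(K))      # relationship scale
    kk[upper.tri(kk)]
  }))
  expect_lt(abs(mean(sib_vals) - 0.5), 0.05)

  # unrelated founders: empirical GRM concentrates on the identity
  cfg2 <- sim_config(n_founders = 100, n_generations = 0, n_snps = 20000,
                     n_chromosomes = 18, ld_decay = 0.3, seed = 8)
  g2 <- simulate_genotypes(simulate_pedigree(cfg2), cfg2)
  K2 <- centered_grm(g2)
  K2n <- K2 / mean(diag(K2))
  expect_lt(max(abs(K2n[upper.tri(K2n)])), 0.06)
})

test_that("the metabolome generator honours its declared shares and rates", {
  cfg <- sim_config(n_founders = 400, n_generations = 0, n_snps = 200,
                    n_chromosomes = 2, n_metabolites = 10, zero_rate = 0,
                    outlier_rate = 0, n_plates = 4, n_dates = 4, seed = 17)
  geno <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  # h2 = 0, no mQTL, lambda = 1: latent trait is covariates + noise
  truth_in <- list(h2 = rep(0, 10), lambda = rep(1, 10),
                   covariate_share = 0.3)
  sim <- simulate_metabolome(geno, cfg, truth = truth_in, n_mqtl = 0)
  biol <- sim$metabolome[!sim$metabolome$is_pool, ]
  vals <- met_matrix_for_test(biol)
  expect_false(any(vals == 0))           # zero_rate 0
  expect_false(anyNA(vals))
  r2 <- vapply(1:10, function(j) {
    summary(lm(vals[, j] ~ sex + weight + factor(date),
               data = sim$covariates))$r.squared
  }, numeric(1))
  expect_equal(mean(r2), 0.3, tolerance = 0.06)

  # zero-masking censors exactly the smallest fraction per metabolite
  cfgz <- sim_config(n_founders = 200, n_generations = 0, n_snps = 100,
                     n_chromosomes = 2, n_metabolites = 5, zero_rate = 0.1,
                     outlier_rate = 0, n_plates = 2, n_dates = 3, seed = 18)
  genoz <- simulate_genotypes(simulate_pedigree(cfgz), cfgz)
  simz <- simulate_metabolome(genoz, cfgz, n_mqtl = 0)
  valsz <- met_matrix_for_test(simz$metabolome[!simz$metabolome$is_pool, ])
  expect_equal(unname(colSums(valsz == 0)), rep(20, 5))

  # determinism under the same config
  simz2 <- simulate_metabolome(genoz, cfgz, n_mqtl = 0)
  expect_equal(valsz, met_matrix_for_test(simz2$metabolome[!simz2$metabolome$is_pool, ]))
})

test_that("planted mQTL are recovered genome-wide significant", {
  # PVE 0.10 at n = 800: the scan flags the planted SNP in most replicates
  hits <- logical(10)
  for (r in 1:10) {
    cfg <- sim_config(n_founders = 800, n_generations = 0, n_snps = 300,
                      n_chromosomes = 3, n_metabolites = 4, zero_rate = 0,
                      outlier_rate = 0, n_dates = 4, seed = 600 + r)
    geno <- simulate_genotypes(simulate_pedigree(cfg), cfg)
    truth_in <- list(h2 = rep(0.3, 4), lambda = rep(0, 4),
                     planted_mqtl = tibble::tibble(
                       snp_id = geno$map$snp_id[150], metabolite = "met_002",
                       pve = 0.10))
    sim <- simulate_metabolome(geno, cfg, truth = truth_in)
    norm <- normalize_metabolites(
      sim$metabolome[!sim$metabolome$is_pool,
                     c("sample_id", "met_002")],
      sim$covariates, grid = seq(-3, 3, length.out = 301))
    K <- centered_grm(geno)
    sc <- lmm_scan(norm, geno, K, mode = "null_vc")
    thr <- 0.05 / 10000                  # genome-wide scale threshold
    hits[r] <- sc$p_wald[sc$snp_id == geno$map$snp_id[150]] < thr
  }
  expect_gte(mean(hits), 0.9)
})

test_that("large-sample partial correlations recover the precision sign pattern", {
  m <- 12
  omega <- make_chain_precision(m, 0.35)
  cfg <- sim_config(n_founders = 5000, n_generations = 0, n_snps = 10,
                    n_chromosomes = 1, n_metabolites = m, zero_rate = 0,
                    outlier_rate = 0, n_dates = 2, seed = 23)
  geno <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  truth_in <- list(h2 = rep(0, m), lambda = rep(1, m), omega = omega,
                   covariate_share = 0.01)
  sim <- simulate_metabolome(geno, cfg, truth = truth_in, n_mqtl = 0)
  norm <- normalize_metabolites(
    sim$metabolome[!sim$metabolome$is_pool, ],
    sim$covariates, grid = seq(-1, 2, length.out = 31))
  pcc <- partial_correlation_matrix(norm)
  strong <- which(abs(pcc) > 0.1 & upper.tri(pcc), arr.ind = TRUE)
  expect_gt(nrow(strong), 5)
  expect_true(all(sign(pcc[strong]) == -sign(omega[strong])))
})
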