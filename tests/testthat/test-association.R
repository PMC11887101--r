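test_that("with no kinship the scan equals ordinary least squares", {
  geno <- make_founder_geno(50, runif(30, 0.15, 0.5), seed = 20)
  set.seed(21)
  y <- rnorm(50) + 0.4 * geno$dosages[, 3]
  sc <- lmm_scan(y, geno, K = NULL)
  for (j in c(1, 3, 10)) {
    fit <- summary(lm(y ~ geno$dosages[, j]))
    expect_equal(sc$beta[j], coef(fit)[2, 1], tolerance = 1e-8)
    expect_equal(sc$se[j], coef(fit)[2, 2], tolerance = 1e-8)
  }
  # Wald P uses the normal approximation of beta/se
  expect_equal(sc$p_wald, 2 * pnorm(-abs(sc$beta / sc$se)))
})

test_that("exact-mode estimates match dense GLS at the fitted variances", {
  n <- 40
  geno <- make_founder_geno(n, runif(60, 0.1, 0.5), seed = 22)
  K <- centered_grm(geno)
  y <- polygenic_trait(K, 0.4, seed = 23) + 0.5 * geno$dosages[, 7]
  sc <- lmm_scan(y, geno, K, mode = "exact")
  for (j in c(2, 7, 41)) {
    V <- sc$sigma_g2[j] * (K + sc$delta[j] * diag(n))
    Vi <- solve(V)
    X <- cbind(1, geno$dosages[, j])
    XtViX <- t(X) %*% Vi %*% X
    b <- solve(XtViX, t(X) %*% Vi %*% y)
    expect_equal(sc$beta[j], b[2], tolerance = 1e-8)
    expect_equal(sc$se[j], sqrt(solve(XtViX)[2, 2]), tolerance = 1e-8)
  }
  # monomorphic SNP yields NA statistics
  dos <- geno$dosages; dos[, 1] <- 0
  g2 <- genotype_matrix(dos, geno$map, polarize = FALSE)
  sc2 <- lmm_scan(y, g2, K, mode = "null_vc")
  expect_true(is.na(sc2$beta[1]) && is.na(sc2$p_wald[1]))
})

test_that("exact and null-variance modes agree closely under polygenicity", {
  # the fixed-variance approximation tracks the exact scan for almost every
  # SNP; chance-associated SNPs that absorb polygenic variance can shift the
  # per-SNP variance ratio and move P by somewhat more than 1.5x
  cfg <- sim_config(n_founders = 234, n_generations = 2, n_snps = 300,
                    n_chromosomes = 3, seed = 51)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  ids <- ped$id[ped$generation == 2]
  gph <- genotype_matrix(g$dosages[ids, , drop = FALSE], g$map,
                         polarize = FALSE)
  K <- centered_grm(gph)
  y <- polygenic_trait(K, 0.3, seed = 52)
  pe <- lmm_scan(y, gph, K, mode = "exact")$p_wald
  pn <- lmm_scan(y, gph, K, mode = "null_vc")$p_wald
  ok <- !is.na(pe) & !is.na(pn)
  ratio <- pe[ok] / pn[ok]
  expect_gte(mean(ratio < 1.5 & ratio > 1 / 1.5), 0.99)
  expect_true(all(ratio < 3 & ratio > 1 / 3))
})

test_that("PVE follows the published formula and cancels the MAF", {
  expect_equal(pve(0, 1, 0.3, 100), 0)
  expect_equal(pve(1, 1, 0.5, 1), 0.5)
  expect_equal(pve(0.4, 0.1, 0.1, 500), pve(0.4, 0.1, 0.4, 500))
  b <- 0.4; s <- 0.08; n <- 350; p <- 0.22
  expect_equal(pve(b, s, p, n),
               (2 * b^2 * p * (1 - p)) /
                 (2 * b^2 * p * (1 - p) + s^2 * 2 * n * p * (1 - p)))
  expect_error(pve(1, 0, 0.3, 10), "positive")
})

test_that("LD pruning counts independent SNPs correctly", {
  # independent SNPs at low LD all survive
  geno <- make_founder_geno(400, runif(40, 0.2, 0.5), seed = 30)
  expect_equal(effective_tests_ld(geno)$m_eff, 40)

  # a duplicated SNP column loses exactly one member
  dos <- geno$dosages
  dos <- cbind(dos, dup = dos[, 5])
  map <- dplyr::bind_rows(geno$map,
                          tibble::tibble(snp_id = "dup", chromosome = "1",
                                         position_bp = 41000L,
                                         allele_ref = "A", allele_alt = "B"))
  g2 <- genotype_matrix(dos, map, polarize = FALSE)
  expect_equal(effective_tests_ld(g2)$m_eff, 40)
  expect_true(xor("snp5" %in% effective_tests_ld(g2)$kept,
                  "dup" %in% effective_tests_ld(g2)$kept))

  # 50 blocks of 10 perfectly correlated SNPs -> 50 survivors
  set.seed(31)
  base <- vapply(runif(50, 0.2, 0.5), function(p) rbinom(300, 2, p),
                 numeric(300))
  dos3 <- base[, rep(1:50, each = 10)]
  colnames(dos3) <- sprintf("s%03d", 1:500)
  map3 <- tibble::tibble(snp_id = colnames(dos3), chromosome = "1",
                         position_bp = seq_len(500) * 1000L)
  g3 <- genotype_matrix(dos3, map3, polarize = FALSE)
  expect_equal(effective_tests_ld(g3)$m_eff, 50)
})

test_that("p-gain follows its definition and critical level", {
  ra <- tibble::tibble(trait_id = "A/B", snp_id = "s1", chromosome = "1",
                       position_bp = 100L, p_wald = 1e-8)
  sa <- tibble::tibble(trait_id = c("A", "B"), snp_id = "s1",
                       p_wald = c(1e-3, 1e-2))
  pg <- pgain_scan(ra, sa, n_ratios = 14196)
  expect_equal(pg$p_gain, 1e5)
  expect_equal(pg$pgain_critical, 141960)
  expect_false(pg$significant)     # 1e5 < 141960

  # p_ratio equal to the best single P gives p-gain 1, never significant
  ra$p_wald <- 1e-3
  expect_equal(pgain_scan(ra, sa, 10)$p_gain, 1)
  expect_false(pgain_scan(ra, sa, 10)$significant)

  # underflow maps to +Inf
  ra$p_wald <- 0
  expect_equal(pgain_scan(ra, sa, 10)$p_gain, Inf)

  # conjunction with the single-trait threshold
  ra$p_wald <- 1e-9
  expect_true(pgain_scan(ra, sa, 10, p_threshold = 1e-5)$significant)
  expect_false(pgain_scan(ra, sa, 10, p_threshold = 1e-12)$significant)
})

test_that("weighted Z-score meta-analysis matches closed forms", {
  z2p <- function(z) 2 * pnorm(-abs(z))
  two <- tibble::tibble(snp_id = "s", trait_id = "m",
                        p = z2p(2), beta = 1, n = 400)
  mt <- meta_weighted_z(dplyr::bind_rows(two, two))
  expect_equal(mt$z_meta, 2 * sqrt(2), tolerance = 1e-10)
  expect_equal(mt$direction, "++")

  # opposite signs with equal weight cancel
  opp <- dplyr::bind_rows(two, dplyr::mutate(two, beta = -1))
  expect_equal(meta_weighted_z(opp)$z_meta, 0, tolerance = 1e-12)

  # single study is the identity
  one <- meta_weighted_z(two)
  expect_equal(one$z_meta, 2, tolerance = 1e-10)
  expect_equal(one$p_meta, z2p(2), tolerance = 1e-10)

  # K identical studies scale Z by sqrt(K)
  five <- dplyr::bind_rows(rep(list(two), 5))
  expect_equal(meta_weighted_z(five)$z_meta, 2 * sqrt(5), tolerance = 1e-10)

  expect_error(meta_weighted_z(dplyr::mutate(two, p = 0)), "representable")
})

test_that("mQTL region calling applies the 1 Mb and 0.5 Mb rules", {
  # same context: 1.0, 1.2, 3.5 Mb -> two regions
  hits <- tibble::tibble(snp_id = c("a", "b", "c"), trait_id = "m",
                         chromosome = "1",
                         position_bp = c(1.0e6, 1.2e6, 3.5e6),
                         context = "LW", p = c(1e-8, 1e-9, 1e-7))
  rg <- call_mqtl_regions(hits)
  expect_equal(nrow(rg), 2)
  expect_equal(rg$lead_snp[1], "b")
  expect_equal(rg$end_bp[2] - rg$start_bp[2], 0)

  # exactly 1 Mb apart stays split (separated by at least 1 Mb)
  h2 <- tibble::tibble(snp_id = c("a", "b"), trait_id = "m", chromosome = "1",
                       position_bp = c(1e6, 2e6), context = "LW",
                       p = c(1e-8, 1e-8))
  expect_equal(nrow(call_mqtl_regions(h2)), 2)

  # different contexts 0.4 Mb apart merge into one region
  h3 <- tibble::tibble(snp_id = c("a", "b"), trait_id = c("m1", "m2"),
                       chromosome = "1", position_bp = c(1.0e6, 1.4e6),
                       context = c("LW", "D"), p = c(1e-8, 1e-9))
  rg3 <- call_mqtl_regions(h3)
  expect_equal(nrow(rg3), 1)
  expect_equal(rg3$contexts, "D,LW")
  expect_equal(rg3$lead_snp, "b")

  # different contexts exactly 0.5 Mb apart stay separate
  h4 <- dplyr::mutate(h3, position_bp = c(1.0e6, 1.5e6))
  expect_equal(nrow(call_mqtl_regions(h4)), 2)

  # input order does not matter
  rg_rev <- call_mqtl_regions(h3[2:1, ])
  expect_equal(rg_rev$start_bp, rg3$start_bp)
  expect_equal(rg_rev$lead_snp, rg3$lead_snp)

  # ratio-only members are led by the largest p-gain
  h5 <- tibble::tibble(snp_id = c("r1", "r2"), trait_id = c("x/y", "x/z"),
                       chromosome = "2", position_bp = c(5e6, 5.1e6),
                       context = "LW", p_gain = c(1e6, 1e8))
  expect_equal(call_mqtl_regions(h5)$lead_snp, "r2")
})

test_that("gene annotation windows are closed +/- 500 kb around the lead", {
  genes <- tibble::tibble(
    gene_id = c("inside", "edge", "outside", "otherchr"),
    chromosome = c("1", "1", "1", "2"),
    start_bp = c(10.2e6, 9.0e6, 11.6e6, 10.2e6),
    end_bp = c(10.3e6, 9.5e6, 11.7e6, 10.3e6),
    strand = "+", name = c("inside", "edge", "outside", "otherchr"))
  rg <- tibble::tibble(region_id = "r1", chromosome = "1",
                       start_bp = 10e6, end_bp = 10e6,
                       lead_snp = "s", lead_trait = "m",
                       lead_pos_bp = 10e6)
  ann <- annotate_regions(rg, genes)
  got <- ann$genes[[1]]$gene_id
  expect_setequal(got, c("inside", "edge"))  # edge ends exactly at lead-500kb
  expect_equal(got[1], "inside")             # sorted by distance

  empty <- annotate_regions(rg, genes[0, ])
  expect_equal(empty$n_genes, 0L)
})

test_that("the 2-D ratio profile is symmetric bookkeeping of -log10 P", {
  ra <- tibble::tibble(
    trait_id = c("A/B", "A/C", "B/C"), snp_id = "s1",
    chromosome = "1", position_bp = 1L,
    p_wald = c(1e-4, 1, 1e-2))
  m <- ratio_profile_2d("s1", ra)
  expect_true(isSymmetric(m))
  expect_equal(m["A", "B"], 4)
  expect_equal(m["A", "C"], 0)
  expect_equal(m["C", "B"], 2)
  expect_equal(diag(m), setNames(rep(0, 3), c("A", "B", "C")))
})
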