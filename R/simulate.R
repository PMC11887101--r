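# Synthetic cohort generator: pedigree, LD-structured SNP genotypes by gene
# dropping, covariate-confounded metabolomes with planted mQTL, polygenic
# heritability and network-structured residuals, and the two-genotype
# kynurenine-pathway nutrigenetic cohort. A ground-truth record accompanies
# every simulated metabolome for recovery testing.

#' Simulation configuration
#'
#' Defaults emulate the structure of a performance-tested pig cohort
#' genotyped on a medium-density SNP panel: a few hundred founders, three
#' offspring generations (four generations of records), litters contributing
#' triplets of full sibs, ~60k-chip-scale SNP density scaled by `n_snps`,
#' moderate adjacent-marker LD, and a metabolite panel with plate batches and
#' occasional below-LOD zeros.
#'
#' @param n_founders Founder count (default 250, growing to a final
#'   generation of roughly 800 phenotyped animals).
#' @param n_generations Offspring generations (default 3).
#' @param litter_size Full sibs per litter (default 3).
#' @param n_snps Total SNPs (default 5000).
#' @param n_chromosomes Chromosomes (default 18, autosomes of the pig).
#' @param maf_range Founder minor-allele-frequency range (default
#'   c(0.05, 0.5), the post-QC MAF filter).
#' @param ld_decay Adjacent-SNP latent haplotype correlation (first-order
#'   Markov LD; default 0.7).
#' @param n_metabolites Metabolite panel size (default 169).
#' @param zero_rate Below-LOD zero fraction per metabolite (default 0.02).
#' @param outlier_rate Fraction of samples turned into technical outliers
#'   (default 0.01).
#' @param n_plates Analytical plates assigned round-robin (default 20).
#' @param n_dates Blood-collection dates (default 26).
#' @param seed Global seed fanned out deterministically to the stages.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 250, n_generations = 3, litter_size = 3,
                       n_snps = 5000, n_chromosomes = 18,
                       maf_range = c(0.05, 0.5), ld_decay = 0.7,
                       n_metabolites = 169, zero_rate = 0.02,
                       outlier_rate = 0.01, n_plates = 20, n_dates = 26,
                       seed = 1L) {
  cfg <- list(n_founders = n_founders, n_generations = n_generations,
              litter_size = litter_size, n_snps = n_snps,
              n_chromosomes = n_chromosomes, maf_range = maf_range,
              ld_decay = ld_decay, n_metabolites = n_metabolites,
              zero_rate = zero_rate, outlier_rate = outlier_rate,
              n_plates = n_plates, n_dates = n_dates, seed = seed)
  stopifnot(n_founders >= 2, n_generations >= 0, n_snps >= 1,
            n_chromosomes >= 1, all(maf_range > 0), all(maf_range <= 0.5),
            ld_decay >= 0, ld_decay < 1, zero_rate >= 0, zero_rate < 1)
  if (litter_size < 1) abort("litter_size must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Founders are unrelated (generation 0, half of each sex). In each
#' offspring generation, sires and dams of the previous generation are
#' paired at random; every pair produces one litter of `litter_size` full
#' sibs with random sex.
#'
#' @param config [sim_config()].
#' @return Pedigree tibble `id`, `sire`, `dam`, `generation`, `sex`
#'   (`"M"`/`"F"`), topologically ordered.
#' @export
simulate_pedigree <- function(config = sim_config()) {
  if (config$litter_size < 1) abort("litter_size must be >= 1")
  with_seed(stage_seed(config$seed, "pedigree"), {
    n0 <- config$n_founders
    ped <- tibble(id = sprintf("G0_%04d", seq_len(n0)),
                  sire = NA_character_, dam = NA_character_,
                  generation = 0L,
                  sex = rep_len(c("M", "F"), n0)[sample.int(n0)])
    prev <- ped
    for (g in seq_len(config$n_generations)) {
      sires <- sample(prev$id[prev$sex == "M"])
      dams <- sample(prev$id[prev$sex == "F"])
      np <- min(length(sires), length(dams))
      if (np == 0) break
      kids <- tibble(
        id = sprintf("G%d_%04d", g, seq_len(np * config$litter_size)),
        sire = rep(sires[seq_len(np)], each = config$litter_size),
        dam = rep(dams[seq_len(np)], each = config$litter_size),
        generation = g,
        sex = sample(c("M", "F"), np * config$litter_size, replace = TRUE)
      )
      ped <- dplyr::bind_rows(ped, kids)
      prev <- kids
    }
    ped
  })
}

# SNP map: chromosomes of equal SNP count, 50 kb spacing
make_snp_map <- function(n_snps, n_chromosomes) {
  per <- diff(round(seq(0, n_snps, length.out = n_chromosomes + 1)))
  chr <- rep(seq_len(n_chromosomes), per)
  pos <- unlist(lapply(per, function(k) seq_len(k) * 50000L), use.names = FALSE)
  tibble(snp_id = sprintf("snp_%05d", seq_len(n_snps)),
         chromosome = as.character(chr), position_bp = pos,
         allele_ref = "A", allele_alt = "B")
}

#' Simulate LD-structured genotypes on a pedigree
#'
#' Founder haplotypes follow a first-order Markov model: per-SNP allele
#' frequencies drawn from `maf_range` and a latent Gaussian AR(1) process
#' with adjacent correlation `ld_decay` inducing LD that decays with marker
#' distance (restarting at chromosome boundaries). Offspring haplotypes are
#' produced by Mendelian gene dropping with recombination (on average one
#' crossover per chromosome per meiosis), so pedigree relationship and
#' genomic kinship agree in expectation.
#'
#' @param pedigree From [simulate_pedigree()].
#' @param config [sim_config()].
#' @return A [genotype_matrix()] for every pedigree member.
#' @export
simulate_genotypes <- function(pedigree, config = sim_config()) {
  map <- make_snp_map(config$n_snps, config$n_chromosomes)
  ped <- pedigree
  n <- nrow(ped)
  p_snp <- with_seed(stage_seed(config$seed, "haplotypes"), {
    runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  })
  chr_index <- split(seq_len(config$n_snps), map$chromosome)
  founder_rows <- which(ped$generation == 0)
  hap <- vector("list", n)          # each: 2 x n_snps 0/1 matrix
  with_seed(stage_seed(config$seed, "genedrop"), {
    # founder haplotypes: latent AR(1) -> thresholded binary
    nh <- 2 * length(founder_rows)
    Z <- matrix(rnorm(nh * config$n_snps), nh, config$n_snps)
    lat <- matrix(0, nh, config$n_snps)
    rho <- config$ld_decay
    for (idx in chr_index) {
      lat[, idx[1]] <- Z[, idx[1]]
      if (length(idx) > 1) for (j in 2:length(idx)) {
        lat[, idx[j]] <- rho * lat[, idx[j - 1]] + sqrt(1 - rho^2) * Z[, idx[j]]
      }
    }
    thr <- qnorm(p_snp)
    H <- t(t(lat) < thr) * 1L
    for (i in seq_along(founder_rows)) {
      hap[[founder_rows[i]]] <- H[c(2 * i - 1, 2 * i), , drop = FALSE]
    }
    # gene dropping with recombination
    sire_i <- match(ped$sire, ped$id)
    dam_i <- match(ped$dam, ped$id)
    r_per <- lapply(chr_index, function(idx) min(0.5, 1 / length(idx)))
    gamete <- function(parent_hap) {
      sel <- integer(config$n_snps)
      for (ci in seq_along(chr_index)) {
        idx <- chr_index[[ci]]
        m <- length(idx)
        sw <- c(sample(0:1, 1), rbinom(m - 1, 1, r_per[[ci]]))
        sel[idx] <- cumsum(sw) %% 2L
      }
      ifelse(sel == 0L, parent_hap[1, ], parent_hap[2, ])
    }
    for (i in which(ped$generation > 0)) {
      hap[[i]] <- rbind(gamete(hap[[sire_i[i]]]), gamete(hap[[dam_i[i]]]))
    }
  })
  dos <- t(vapply(hap, colSums, numeric(config$n_snps)))
  rownames(dos) <- ped$id
  colnames(dos) <- map$snp_id
  genotype_matrix(dos, map)
}

#' Chain-structured precision matrix
#'
#' Tridiagonal precision with unit diagonal and off-diagonal chosen so the
#' generating partial correlation of adjacent variables is `pcc`; a
#' convenient network-structured residual model for the metabolome
#' generator.
#'
#' @param m Number of variables.
#' @param pcc Adjacent partial correlation (|pcc| < 0.5 guarantees positive
#'   definiteness).
#' @return m x m precision matrix.
#' @export
make_chain_precision <- function(m, pcc = 0.3) {
  omega <- diag(m)
  for (i in seq_len(m - 1)) omega[i, i + 1] <- omega[i + 1, i] <- -pcc
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) abort("precision matrix not positive definite; reduce |pcc|")
  omega
}

#' Simulate a covariate-confounded metabolome with planted genetics
#'
#' Generative inverse of the analysis pipeline. Each metabolite's latent
#' trait is
#' `beta_0 + beta_w w + beta_s s + sum(beta_C d) + x beta_snp + g + eps`
#' with `g ~ N(0, sigma_g2 K)` (K the centered GRM of the supplied
#' genotypes), residual rows drawn from `N(0, Omega^-1)` (network-structured
#' across metabolites), `sigma_g2/(sigma_g2 + sigma_e2)` equal to the
#' planted heritability on the latent scale, and planted SNP effects sized
#' to a target PVE. Observed concentrations are the inverse Box-Cox
#' transform of the latent trait at the metabolite's lambda, after which the
#' smallest `zero_rate` fraction per metabolite is censored to zero
#' (below-LOD) and `outlier_rate` of the samples are multiplied by a shared
#' factor across >30% of metabolites (technical outliers). Plates are
#' assigned round-robin and each plate carries one QC pool row.
#'
#' @param geno [genotype_matrix()] of the phenotyped samples.
#' @param config [sim_config()].
#' @param truth Optional partial truth list overriding the generated
#'   defaults; recognised elements `h2`, `lambda`, `omega`,
#'   `planted_mqtl` (tibble snp_id, metabolite, pve), `covariate_share`.
#' @param n_mqtl Planted mQTL count when `truth$planted_mqtl` absent
#'   (default 5).
#' @return List with `metabolome` (tibble: sample_id, plate, is_pool,
#'   metabolites), `covariates` (sample_id, sex, weight, date), and `truth`
#'   (h2, lambda, omega, covariate effects, planted mQTL with effect sizes,
#'   seed).
#' @export
simulate_metabolome <- function(geno, config = sim_config(), truth = NULL,
                                n_mqtl = 5) {
  G <- geno$dosages
  n <- nrow(G)
  m <- config$n_metabolites
  mets <- sprintf("met_%03d", seq_len(m))
  with_seed(stage_seed(config$seed, "metabolome"), {
    h2 <- truth$h2 %||% pmin(pmax(rnorm(m, 0.22, 0.15), 0), 0.75)
    lambda <- truth$lambda %||% sample(c(0, 0.25, 0.5, 1), m, replace = TRUE)
    omega <- truth$omega %||% make_chain_precision(m, 0.3)
    cov_share <- truth$covariate_share %||% 0.2
    names(h2) <- names(lambda) <- mets
    if (is.null(truth$planted_mqtl) && n_mqtl > 0) {
      maf_ok <- which(geno$map$maf >= 0.1)
      planted <- tibble(
        snp_id = geno$map$snp_id[sample(maf_ok, min(n_mqtl, length(maf_ok)))],
        metabolite = sample(mets, min(n_mqtl, length(maf_ok))),
        pve = runif(min(n_mqtl, length(maf_ok)), 0.05, 0.15)
      )
    } else {
      planted <- truth$planted_mqtl %||%
        tibble(snp_id = character(), metabolite = character(), pve = numeric())
    }
    # covariates
    sex <- sample(c(0, 1), n, replace = TRUE, prob = c(0.33, 0.67))
    weight <- rnorm(n, 120, 10)
    date <- sample(sprintf("d%02d", seq_len(config$n_dates)), n, replace = TRUE)
    covariates <- tibble(sample_id = rownames(G), sex = sex, weight = weight,
                         date = date)
    Xc <- stats::model.matrix(~ sex + weight + date,
                              data = data.frame(sex = sex, weight = weight,
                                                date = factor(date)))
    beta_cov <- matrix(rnorm(ncol(Xc) * m, 0, 1), ncol(Xc), m)
    beta_cov[1, ] <- 0
    beta_cov[2, ] <- beta_cov[2, ] * 0.5      # sex
    beta_cov[3, ] <- beta_cov[3, ] * 0.02     # weight (per kg)
    if (ncol(Xc) > 3) beta_cov[4:ncol(Xc), ] <- beta_cov[4:ncol(Xc), ] * 0.4
    cov_part <- Xc %*% beta_cov
    # scale covariate contribution to the requested share of latent variance
    for (j in seq_len(m)) {
      v <- var(cov_part[, j])
      tgt <- cov_share / (1 - cov_share)   # latent genetic+residual variance is 1
      if (v > 0) cov_part[, j] <- cov_part[, j] * sqrt(tgt / v)
    }
    # polygenic effect via the centered GRM of the same genotypes
    K <- centered_grm(geno)
    L <- chol(K + diag(1e-6, n))
    g_mat <- crossprod(L, matrix(rnorm(n * m), n, m))
    g_sd <- apply(g_mat, 2, sd)
    # planted SNP effects; their variance counts toward the genetic share
    snp_part <- matrix(0, n, m)
    planted$beta <- NA_real_
    for (r in seq_len(nrow(planted))) {
      x <- G[, planted$snp_id[r]]
      p <- mean(x) / 2
      b <- sqrt(planted$pve[r] / (2 * p * (1 - p)))
      planted$beta[r] <- b
      j <- match(planted$metabolite[r], mets)
      snp_part[, j] <- snp_part[, j] + x * b
    }
    snp_var <- apply(snp_part, 2, var)
    sg2 <- pmax(h2 - snp_var, 0)
    se2 <- 1 - h2
    for (j in seq_len(m)) {
      g_mat[, j] <- g_mat[, j] / max(g_sd[j], 1e-12) * sqrt(sg2[j])
    }
    # network-structured residuals
    sigma <- solve(omega)
    s <- 1 / sqrt(diag(sigma))
    sigma_corr <- sigma * tcrossprod(s)
    Le <- chol(sigma_corr)
    eps <- matrix(rnorm(n * m), n, m) %*% Le
    eps <- sweep(eps, 2, sqrt(se2), "*")
    intercept <- 3
    latent <- intercept + cov_part + snp_part + g_mat + eps
    # observed concentrations: inverse Box-Cox per metabolite
    conc <- vapply(seq_len(m), function(j) inv_boxcox(latent[, j], lambda[j]),
                   numeric(n))
    colnames(conc) <- mets
    # technical outliers: whole-sample multiplicative shift in >30% of mets
    n_out <- rbinom(1, n, config$outlier_rate)
    outlier_ids <- character(0)
    if (n_out > 0) {
      rows <- sample.int(n, n_out)
      outlier_ids <- rownames(G)[rows]
      for (r in rows) {
        hit <- sample.int(m, ceiling(0.4 * m))
        conc[r, hit] <- conc[r, hit] * 5
      }
    }
    # below-LOD censoring: smallest zero_rate fraction per metabolite
    n_zero <- floor(config$zero_rate * n)
    if (n_zero > 0) {
      for (j in seq_len(m)) {
        conc[order(conc[, j])[seq_len(n_zero)], j] <- 0
      }
    }
    plate <- rep_len(sprintf("plate%02d", seq_len(config$n_plates)), n)
    metab <- dplyr::bind_cols(
      tibble(sample_id = rownames(G), plate = plate, is_pool = FALSE),
      as_tibble(conc))
    # one QC pool aliquot per plate: grand mean profile with 5% noise
    pool_mu <- colMeans(conc[rowSums(conc == 0) == 0, , drop = FALSE])
    pools <- dplyr::bind_rows(lapply(unique(plate), function(pl) {
      dplyr::bind_cols(
        tibble(sample_id = paste0("pool_", pl), plate = pl, is_pool = TRUE),
        as_tibble(matrix(pool_mu * exp(rnorm(m, 0, 0.05)), 1,
                         dimnames = list(NULL, mets))))
    }))
    list(
      metabolome = dplyr::bind_rows(metab, pools),
      covariates = covariates,
      truth = list(h2 = h2, lambda = lambda, omega = omega,
                   planted_mqtl = planted,
                   covariate_effects = beta_cov, covariate_share = cov_share,
                   outlier_samples = outlier_ids, seed = config$seed)
    )
  })
}

#' Simulate a full cohort (pedigree, genotypes, metabolome)
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_genotypes()] and [simulate_metabolome()], phenotyping the
#' final generation.
#'
#' @param config [sim_config()].
#' @param truth,n_mqtl Passed to [simulate_metabolome()].
#' @return List `pedigree`, `genotypes` (all animals), `phenotyped_ids`,
#'   `geno_phenotyped`, `metabolome`, `covariates`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config(), truth = NULL, n_mqtl = 5) {
  ped <- simulate_pedigree(config)
  geno <- simulate_genotypes(ped, config)
  pheno_ids <- ped$id[ped$generation == max(ped$generation)]
  gph <- genotype_matrix(geno$dosages[pheno_ids, , drop = FALSE], geno$map,
                         polarize = FALSE)
  sim <- simulate_metabolome(gph, config, truth = truth, n_mqtl = n_mqtl)
  list(pedigree = ped, genotypes = geno, phenotyped_ids = pheno_ids,
       geno_phenotyped = gph, metabolome = sim$metabolome,
       covariates = sim$covariates, truth = sim$truth)
}

#' Simulate the kynurenine-pathway nutrigenetic cohort
#'
#' Two genotype groups (differing only in `k_kmo`) of piglets sampled at a
#' basal and a tryptophan-supplemented timepoint. Each animal's metabolite
#' concentrations are the analytic steady state at its group's parameters
#' and the timepoint's Trp level, multiplied by lognormal noise with
#' coefficient of variation `noise_cv` (mean-one noise).
#'
#' @param n_per_group Animals per genotype group (default 8).
#' @param params_by_genotype Named list of two [kp_params()] (e.g.
#'   `list(AA = ..., GG = ...)`).
#' @param trp_levels Length-2 vector of clamped Trp concentrations (mM) for
#'   the basal and supplemented timepoints.
#' @param noise_cv Biological/analytical coefficient of variation
#'   (default 0.1).
#' @param seed Seed.
#' @return Tibble `animal`, `genotype`, `timepoint` (`"basal"`,
#'   `"supplemented"`) and the eight KP metabolite columns.
#' @export
simulate_kp_cohort <- function(n_per_group = 8,
                               params_by_genotype,
                               trp_levels = c(0.04, 0.08),
                               noise_cv = 0.1, seed = 1L) {
  if (length(params_by_genotype) != 2 || is.null(names(params_by_genotype))) {
    abort("params_by_genotype must be a named list of two kp_params")
  }
  if (any(trp_levels <= 0)) abort("Trp levels must be positive")
  if (length(trp_levels) != 2) abort("supply basal and supplemented Trp levels")
  tp <- c("basal", "supplemented")
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(stage_seed(seed, "kp"), {
    rows <- list()
    for (gi in seq_along(params_by_genotype)) {
      gname <- names(params_by_genotype)[gi]
      for (a in seq_len(n_per_group)) {
        for (ti in 1:2) {
          ss <- analytic_steady_state(params_by_genotype[[gi]], trp_levels[ti])$state
          noise <- if (noise_cv == 0) rep(1, length(ss)) else {
            exp(rnorm(length(ss), -sdlog^2 / 2, sdlog))
          }
          rows[[length(rows) + 1]] <- dplyr::bind_cols(
            tibble(animal = sprintf("%s_%02d", gname, a), genotype = gname,
                   timepoint = tp[ti]),
            as_tibble(as.list(ss * noise)))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
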