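# Linear mixed model association scan (Wald test), per-SNP variance
# explained, LD-based effective test counts, the p-gain statistic for
# metabolite ratios, weighted Z-score meta-analysis, mQTL region calling and
# gene annotation.

dosage_matrix <- function(geno) {
  if (inherits(geno, "genotype_matrix")) geno$dosages else as.matrix(geno)
}

geno_map <- function(geno) {
  if (inherits(geno, "genotype_matrix")) return(geno$map)
  tibble(snp_id = colnames(geno) %||% paste0("snp", seq_len(ncol(geno))),
         chromosome = "1", position_bp = seq_len(ncol(geno)),
         maf = pmin(colMeans(geno, na.rm = TRUE) / 2,
                    1 - colMeans(geno, na.rm = TRUE) / 2))
}

#' Mixed-model association scan with the Wald test
#'
#' For each SNP fits `y = W a + x b + g + e` with `g ~ N(0, sigma_g2 K)` and
#' `e ~ N(0, sigma_e2 I)`, where `y` holds normalized metabolite (or ratio)
#' residuals and `x` counts copies of the minor allele. The null hypothesis
#' `b = 0` is tested with the Wald statistic using the normal approximation.
#'
#' Two modes are offered: `"exact"` re-optimizes the variance ratio
#' `delta = sigma_e2/sigma_g2` under each SNP's model (the slower, standard
#' mixed-model scan), `"null_vc"` fixes `delta` at the no-SNP fit and runs
#' fully vectorized generalized least squares (the common large-scan
#' approximation).
#'
#' @param traits Numeric vector, or tibble with `sample_id` plus one column
#'   per trait (residuals from [normalize_metabolites()]).
#' @param geno [genotype_matrix()] (or dosage matrix) aligned with the
#'   trait rows.
#' @param K Relationship matrix from [centered_grm()]; `NULL` fits ordinary
#'   least squares (equivalent to `sigma_g2 = 0`).
#' @param mode `"exact"` or `"null_vc"`.
#' @return Tibble with columns `trait_id`, `snp_id`, `chromosome`,
#'   `position_bp`, `maf`, `n`, `beta`, `se`, `p_wald`, `pve`. Monomorphic
#'   SNPs carry `NA` statistics.
#' @export
lmm_scan <- function(traits, geno, K = NULL, mode = c("exact", "null_vc")) {
  mode <- match.arg(mode)
  G <- dosage_matrix(geno)
  map <- geno_map(geno)
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  if (is.data.frame(traits)) {
    ids <- setdiff(names(traits), "sample_id")
    ylist <- lapply(ids, function(m) traits[[m]])
  } else {
    ids <- "trait"
    ylist <- list(as.numeric(traits))
  }
  n <- nrow(G)
  if (length(ylist[[1]]) != n) abort("traits and genotypes must be sample-aligned")
  mono <- apply(G, 2, var) == 0
  if (is.null(K)) {
    eig <- list(values = rep(0, n), vectors = diag(n))
  } else {
    eig <- eigen(K, symmetric = TRUE)
  }
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  Gs <- crossprod(U, G)
  ones <- crossprod(U, matrix(1, n, 1))
  out <- purrr::map2(ids, ylist, function(trait_id, y) {
    ys <- as.numeric(crossprod(U, y))
    if (is.null(K)) {
      delta0 <- NULL # pure OLS; weights all 1
      w0 <- rep(1, n)
    } else {
      null_fit <- reml_fit(y, K)
      # delta can be huge at the boundary (h2 ~ 0); weights stay finite
      w0 <- d + null_fit$delta
      delta0 <- null_fit$delta
    }
    if (mode == "null_vc" || is.null(K)) {
      res <- gls_scan_fixed(ys, Gs, ones, w0, n)
      res$delta <- rep(if (is.null(K)) Inf else delta0, ncol(Gs))
      res$sigma_g2 <- if (is.null(K)) rep(NA_real_, ncol(Gs)) else
        res$sigma2 # residual-scale estimate under fixed weights
    } else {
      res <- gls_scan_exact(ys, Gs, ones, d, n, delta0)
    }
    beta <- res$beta; se <- res$se
    beta[mono] <- NA_real_; se[mono] <- NA_real_
    p <- 2 * pnorm(-abs(beta / se))
    pve_v <- ifelse(is.na(beta), NA_real_,
                    pve(beta, se, pmax(map$maf, 1e-12), n))
    tibble(trait_id = trait_id, snp_id = map$snp_id,
           chromosome = map$chromosome, position_bp = map$position_bp,
           maf = map$maf, n = n, beta = beta, se = se, p_wald = p,
           pve = pve_v, sigma_g2 = res$sigma_g2, delta = res$delta)
  })
  dplyr::bind_rows(out)
}

# vectorized weighted GLS of y on [1, x] at fixed weights w (= d + delta):
# closed-form 2x2 normal equations per SNP
gls_scan_fixed <- function(ys, Gs, ones, w, n) {
  a <- 1 / w
  one_a <- as.numeric(ones) * a
  s11 <- sum(as.numeric(ones)^2 * a)
  s1y <- sum(one_a * ys)
  syy <- sum(ys^2 * a)
  s1x <- as.numeric(crossprod(Gs, one_a))
  sxx <- as.numeric(colSums(Gs^2 * a))
  sxy <- as.numeric(crossprod(Gs, ys * a))
  det <- s11 * sxx - s1x^2
  beta <- (s11 * sxy - s1x * s1y) / det
  alpha <- (sxx * s1y - s1x * sxy) / det
  rss <- syy - 2 * (alpha * s1y + beta * sxy) +
    alpha^2 * s11 + 2 * alpha * beta * s1x + beta^2 * sxx
  sigma2 <- rss / (n - 2)
  se <- sqrt(pmax(sigma2 * s11 / det, 0))
  list(beta = beta, se = se, sigma2 = sigma2)
}

# per-SNP re-optimization of delta under the SNP-inclusive model
gls_scan_exact <- function(ys, Gs, ones, d, n, delta0) {
  p <- ncol(Gs)
  beta <- se <- sigma_g2 <- delta <- numeric(p)
  ld0 <- log(max(delta0, 1e-10))
  for (j in seq_len(p)) {
    Xs <- cbind(as.numeric(ones), Gs[, j])
    obj <- function(ld) profile_reml(ld, d, ys, Xs, 0)$loglik
    lo <- max(-10, ld0 - 4); hi <- min(10, ld0 + 4)
    opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-6)
    # guard against a local window: also check the full range ends
    cand <- c(opt$maximum,
              if (lo > -10) -10, if (hi < 10) 10)
    lls <- vapply(cand, obj, numeric(1))
    ldelta <- cand[which.max(lls)]
    fit <- profile_reml(ldelta, d, ys, Xs, 0)
    w <- d + fit$delta
    XtVX <- crossprod(Xs, Xs / w)
    vb <- fit$sigma_g2 * solve(XtVX)[2, 2]
    beta[j] <- fit$beta[2]
    se[j] <- sqrt(max(vb, 0))
    sigma_g2[j] <- fit$sigma_g2
    delta[j] <- fit$delta
  }
  list(beta = beta, se = se, sigma_g2 = sigma_g2, delta = delta)
}

#' Per-SNP percentage of variance explained
#'
#' `PVE = 2 b^2 pq / (2 b^2 pq + se^2 * 2 N * pq)` with `p` the minor allele
#' frequency and `q = 1 - p`; algebraically the MAF cancels, leaving
#' `b^2 / (b^2 + se^2 N)`, but the full published form is evaluated.
#'
#' @param beta,se Effect size and its standard error on the transformed
#'   scale.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param n Sample size.
#' @return PVE fraction in [0, 1].
#' @export
pve <- function(beta, se, maf, n) {
  if (any(se <= 0, na.rm = TRUE)) abort("se must be positive")
  num <- 2 * beta^2 * maf * (1 - maf)
  den <- num + se^2 * 2 * n * maf * (1 - maf)
  num / den
}

#' Effective number of independent tests by LD pruning
#'
#' Windowed greedy pruning in the style of PLINK `--indep-pairwise`: within
#' sliding windows of `window` SNPs (advanced by `step`), one SNP of every
#' pair with composite-LD r^2 at or above `r2_threshold` is removed — the
#' lower-MAF SNP goes, position breaking ties. The survivor count is the
#' LD-based Bonferroni denominator.
#'
#' @param geno [genotype_matrix()] (map must be position-sorted per
#'   chromosome) or dosage matrix.
#' @param r2_threshold Pairwise r^2 above which SNPs are considered
#'   dependent (default 0.25).
#' @param window,step Window size and slide in SNP count.
#' @return List with `m_eff` (count) and `kept` (surviving snp ids).
#' @export
effective_tests_ld <- function(geno, r2_threshold = 0.25, window = 100, step = 5) {
  G <- dosage_matrix(geno)
  map <- geno_map(geno)
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  keep_all <- character(0)
  for (chr in unique(map$chromosome)) {
    sel <- which(map$chromosome == chr)
    sel <- sel[order(map$position_bp[sel])]
    alive <- rep(TRUE, length(sel))
    maf <- map$maf[sel]
    pos <- map$position_bp[sel]
    start <- 1
    repeat {
      end <- min(start + window - 1, length(sel))
      idx <- start:end
      live <- idx[alive[idx]]
      if (length(live) > 1) {
        cm <- suppressWarnings(cor(G[, sel[live], drop = FALSE]))
        cm[is.na(cm)] <- 0
        repeat {
          r2 <- cm^2; diag(r2) <- 0
          mx <- which(r2 >= r2_threshold, arr.ind = TRUE)
          if (!nrow(mx)) break
          i <- mx[1, 1]; j <- mx[1, 2]
          # drop the lower-MAF member; tie -> larger position goes
          gi <- live[i]; gj <- live[j]
          drop_local <- if (maf[gi] != maf[gj]) {
            if (maf[gi] < maf[gj]) i else j
          } else if (pos[gi] != pos[gj]) {
            if (pos[gi] > pos[gj]) i else j
          } else j
          alive[live[drop_local]] <- FALSE
          cm <- cm[-drop_local, -drop_local, drop = FALSE]
          live <- live[-drop_local]
          if (length(live) < 2) break
        }
      }
      if (end >= length(sel)) break
      start <- start + step
    }
    keep_all <- c(keep_all, map$snp_id[sel[alive]])
  }
  list(m_eff = length(keep_all), kept = keep_all)
}

#' Significance thresholds for the scan
#'
#' @param m_eff LD-independent SNP count (from [effective_tests_ld()]).
#' @param n_ratios Number of tested ratios (for the p-gain critical level).
#' @param m_shared SNPs shared across cohorts (plain Bonferroni for the
#'   meta-analysis); optional.
#' @param alpha Family-wise level (default 0.05).
#' @return Tibble with `alpha`, `m_eff`, `threshold_single` (= alpha/m_eff),
#'   `threshold_meta_bonferroni` (= alpha/m_shared, NA if not given) and
#'   `pgain_critical` (= 10 * n_ratios, NA if not given).
#' @export
significance_thresholds <- function(m_eff, n_ratios = NA, m_shared = NA,
                                    alpha = 0.05) {
  tibble(alpha = alpha, m_eff = m_eff,
         threshold_single = alpha / m_eff,
         threshold_meta_bonferroni = ifelse(is.na(m_shared), NA, alpha / m_shared),
         pgain_critical = ifelse(is.na(n_ratios), NA, 10 * n_ratios))
}

#' p-gain evaluation for ratio associations
#'
#' The p-gain of a ratio a/b at a SNP is `min(p_a, p_b) / p_ratio`: how much
#' the association strengthens when the pair is analyzed as a ratio. A ratio
#' association is flagged significant when its p-gain reaches the critical
#' level `10 * n_ratios` and (by default) the ratio's own P passes the
#' single-trait significance threshold.
#'
#' @param ratio_assocs [lmm_scan()] output for ratio traits named `"a/b"`.
#' @param single_assocs [lmm_scan()] output for the component metabolites on
#'   the same SNPs and samples.
#' @param n_ratios Number of ratios tested (sets the critical p-gain).
#' @param p_threshold Single-trait significance threshold applied to
#'   `p_ratio`; `NULL` drops that requirement.
#' @return Tibble `snp_id`, `trait_id`, `a`, `b`, `p_a`, `p_b`, `p_ratio`,
#'   `p_gain`, `significant`. An underflowing `p_ratio = 0` yields
#'   `p_gain = Inf`.
#' @export
pgain_scan <- function(ratio_assocs, single_assocs, n_ratios,
                       p_threshold = NULL) {
  ra <- as_tibble(ratio_assocs)
  parts <- strsplit(ra$trait_id, "/", fixed = TRUE)
  ra$a <- vapply(parts, `[`, character(1), 1)
  ra$b <- vapply(parts, `[`, character(1), 2)
  singles <- as_tibble(single_assocs)[c("trait_id", "snp_id", "p_wald")]
  ra <- ra |>
    dplyr::left_join(dplyr::rename(singles, a = "trait_id", p_a = "p_wald"),
                     by = c("snp_id", "a")) |>
    dplyr::left_join(dplyr::rename(singles, b = "trait_id", p_b = "p_wald"),
                     by = c("snp_id", "b"))
  p_gain <- ifelse(ra$p_wald == 0, Inf, pmin(ra$p_a, ra$p_b) / ra$p_wald)
  crit <- 10 * n_ratios
  sig <- p_gain >= crit
  if (!is.null(p_threshold)) sig <- sig & ra$p_wald < p_threshold
  tibble(snp_id = ra$snp_id, trait_id = ra$trait_id, a = ra$a, b = ra$b,
         chromosome = ra$chromosome, position_bp = ra$position_bp,
         p_a = ra$p_a, p_b = ra$p_b, p_ratio = ra$p_wald,
         p_gain = p_gain, pgain_critical = crit, significant = sig)
}

#' Sample-size-weighted Z-score meta-analysis
#'
#' Combines per-study association P-values and effect directions:
#' `Z_i = sign(beta_i) * qnorm(1 - p_i/2)`, weights `w_i = sqrt(N_i)`,
#' `Z_meta = sum(w_i Z_i) / sqrt(sum(w_i^2))`, two-sided
#' `p_meta = 2 * pnorm(-|Z_meta|)`.
#'
#' @param per_study Tibble with columns `snp_id`, `trait_id`, `p`, `beta`
#'   (only its sign is used) and `n`, one row per study; or a list of
#'   [lmm_scan()] outputs (joined on snp and trait, using `p_wald`).
#' @return Tibble `snp_id`, `trait_id`, `k_studies`, `z_meta`, `p_meta`,
#'   `direction` (e.g. `"++"`).
#' @export
meta_weighted_z <- function(per_study) {
  if (is.list(per_study) && !is.data.frame(per_study)) {
    per_study <- dplyr::bind_rows(lapply(per_study, function(s) {
      s <- as_tibble(s)
      if ("p_wald" %in% names(s)) s <- dplyr::rename(s, p = "p_wald")
      s[c("snp_id", "trait_id", "p", "beta", "n")]
    }))
  }
  ps <- as_tibble(per_study)
  if (any(ps$p <= 0, na.rm = TRUE)) abort("p = 0 is not representable; cannot form Z")
  ps$z <- sign(ps$beta) * qnorm(1 - ps$p / 2)
  ps |>
    dplyr::group_by(.data$snp_id, .data$trait_id) |>
    dplyr::summarise(
      k_studies = dplyr::n(),
      z_meta = sum(sqrt(.data$n) * .data$z) / sqrt(sum(.data$n)),
      direction = paste0(ifelse(.data$z >= 0, "+", "-"), collapse = ""),
      .groups = "drop"
    ) |>
    dplyr::mutate(p_meta = 2 * pnorm(-abs(.data$z_meta)))
}

#' Call mQTL regions from significant SNP-trait pairs
#'
#' Per chromosome, significant SNPs belonging to the same analysis context
#' (breed / meta-analysis) are clustered whenever consecutive positions lie
#' closer than `same_context_gap` (1 Mb: runs separated by at least 1 Mb of
#' non-significant genome become distinct mQTL). Clusters from different
#' contexts whose spans approach within `cross_context_gap` (0.5 Mb) are then
#' merged into one locus. The lead SNP-trait pair is the most significant
#' member (smallest P; among ratio members ranked by largest p-gain when no P
#' is available).
#'
#' @param hits Tibble of significant pairs with columns `snp_id`,
#'   `trait_id`, `chromosome`, `position_bp`, `context`, and `p` and/or
#'   `p_gain`.
#' @param same_context_gap,cross_context_gap Gap rules in bp.
#' @return Tibble, one row per region: `region_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `lead_snp`, `lead_trait`, `lead_p`,
#'   `lead_p_gain`, `n_members`, `contexts`.
#' @export
call_mqtl_regions <- function(hits, same_context_gap = 1e6,
                              cross_context_gap = 5e5) {
  h <- as_tibble(hits)
  if (!"context" %in% names(h)) h$context <- "all"
  if (!"p" %in% names(h)) h$p <- NA_real_
  if (!"p_gain" %in% names(h)) h$p_gain <- NA_real_
  h <- dplyr::arrange(h, .data$chromosome, .data$position_bp)
  regions <- list()
  for (chr in unique(h$chromosome)) {
    hc <- h[h$chromosome == chr, , drop = FALSE]
    # stage 1: per-context clustering by the 1 Mb rule
    clusters <- list()
    for (ctx in unique(hc$context)) {
      pos <- sort(unique(hc$position_bp[hc$context == ctx]))
      brk <- c(0, cumsum(diff(pos) >= same_context_gap))
      for (g in unique(brk)) {
        p_g <- pos[brk == g]
        clusters[[length(clusters) + 1]] <- list(
          context = ctx, start = min(p_g), end = max(p_g))
      }
    }
    # stage 2: union-find merge across contexts within 0.5 Mb
    k <- length(clusters)
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (k > 1) {
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        gap <- max(clusters[[i]]$start, clusters[[j]]$start) -
          min(clusters[[i]]$end, clusters[[j]]$end)
        if (gap < cross_context_gap) parent[find(j)] <- find(i)
      }
    }
    roots <- vapply(seq_len(k), find, integer(1))
    for (r in unique(roots)) {
      members <- clusters[roots == r]
      start <- min(vapply(members, `[[`, numeric(1), "start"))
      end <- max(vapply(members, `[[`, numeric(1), "end"))
      ctxs <- unique(vapply(members, `[[`, character(1), "context"))
      rows <- hc[hc$position_bp >= start & hc$position_bp <= end &
                   hc$context %in% ctxs, , drop = FALSE]
      lead <- if (any(is.finite(rows$p))) {
        rows[which.min(rows$p), ]
      } else {
        rows[which.max(rows$p_gain), ]
      }
      regions[[length(regions) + 1]] <- tibble(
        chromosome = chr, start_bp = start, end_bp = end,
        lead_snp = lead$snp_id, lead_trait = lead$trait_id,
        lead_p = lead$p, lead_p_gain = lead$p_gain,
        n_members = nrow(rows), contexts = paste(sort(ctxs), collapse = ","))
    }
  }
  out <- dplyr::bind_rows(regions)
  if (!nrow(out)) {
    return(tibble(region_id = character(), chromosome = character(),
                  start_bp = numeric(), end_bp = numeric(),
                  lead_snp = character(), lead_trait = character(),
                  lead_p = numeric(), lead_p_gain = numeric(),
                  n_members = integer(), contexts = character()))
  }
  out <- dplyr::arrange(out, .data$chromosome, .data$start_bp)
  dplyr::bind_cols(tibble(region_id = paste0("mQTL_", seq_len(nrow(out)))), out)
}

#' Annotate mQTL regions with nearby genes
#'
#' Attaches genes overlapping the closed interval
#' `[lead - window, lead + window]` around each region's lead SNP, sorted by
#' distance from the lead (0 for genes spanning it).
#'
#' @param regions Output of [call_mqtl_regions()]; needs a `lead_pos_bp`
#'   column or is joined with `snp_map`.
#' @param gene_table [read_gene_annotation()] output.
#' @param snp_map SNP map supplying lead positions (columns `snp_id`,
#'   `position_bp`) when `regions` lacks `lead_pos_bp`.
#' @param window Flank size in bp (default 500 kb).
#' @return `regions` with list-column `genes` (tibbles gene_id, name,
#'   start_bp, end_bp, distance_bp) and `n_genes`.
#' @export
annotate_regions <- function(regions, gene_table, snp_map = NULL, window = 5e5) {
  rg <- as_tibble(regions)
  if (!"lead_pos_bp" %in% names(rg)) {
    if (is.null(snp_map)) abort("supply snp_map or a lead_pos_bp column")
    rg$lead_pos_bp <- snp_map$position_bp[match(rg$lead_snp, snp_map$snp_id)]
  }
  gt <- as_tibble(gene_table)
  rg$genes <- purrr::pmap(list(rg$chromosome, rg$lead_pos_bp), function(chr, pos) {
    g <- gt[gt$chromosome == chr &
              gt$end_bp >= pos - window & gt$start_bp <= pos + window, , drop = FALSE]
    if (!nrow(g)) {
      return(tibble(gene_id = character(), name = character(),
                    start_bp = integer(), end_bp = integer(),
                    distance_bp = numeric()))
    }
    dist <- pmax(0, pmax(g$start_bp - pos, pos - g$end_bp))
    dplyr::arrange(tibble(gene_id = g$gene_id, name = g$name,
                          start_bp = g$start_bp, end_bp = g$end_bp,
                          distance_bp = dist), dist)
  })
  rg$n_genes <- vapply(rg$genes, nrow, integer(1))
  rg
}

#' Two-dimensional ratio-association profile for one SNP
#'
#' Arranges `-log10(p_ratio)` of every metabolite pair at a given SNP into a
#' symmetric metabolite-by-metabolite matrix, ready for heatmap display.
#'
#' @param snp_id SNP to profile.
#' @param ratio_assocs [lmm_scan()] output for ratio traits (`"a/b"` names).
#' @return Symmetric numeric matrix (diagonal 0) with metabolite dimnames.
#' @export
ratio_profile_2d <- function(snp_id, ratio_assocs) {
  ra <- as_tibble(ratio_assocs)
  ra <- ra[ra$snp_id == snp_id, , drop = FALSE]
  if (!nrow(ra)) abort(paste0("no ratio associations for SNP ", snp_id))
  parts <- strsplit(ra$trait_id, "/", fixed = TRUE)
  a <- vapply(parts, `[`, character(1), 1)
  b <- vapply(parts, `[`, character(1), 2)
  mets <- unique(c(a, b))
  m <- matrix(0, length(mets), length(mets), dimnames = list(mets, mets))
  v <- -log10(ra$p_wald)
  m[cbind(a, b)] <- v
  m[cbind(b, a)] <- v
  m
}
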