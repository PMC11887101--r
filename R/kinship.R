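# Relationship matrices (pedigree tabular method, centered GRM) and REML
# variance components / heritability for the model y = mu + g + e with
# g ~ N(0, sigma_g^2 K), e ~ N(0, sigma_e^2 I).

#' Additive relationship matrix from a pedigree (tabular method)
#'
#' Computes the numerator relationship matrix A over the pedigree:
#' `A[i,i] = 1 + F_i` (F = inbreeding coefficient, half the parents'
#' relationship) and `A[i,j] = (A[j,sire(i)] + A[j,dam(i)]) / 2`.
#' Ancestors more than `max_generations` back from the youngest generation
#' are treated as founders (their parent links are cut), mirroring
#' heritability estimation from a fixed number of recorded generations.
#'
#' @param pedigree Tibble `id`, `sire`, `dam` (NA = unknown), topologically
#'   ordered as returned by [read_pedigree()] or [simulate_pedigree()].
#' @param max_generations Depth of pedigree actually used (default 4).
#' @return Symmetric matrix with sample ids as dimnames.
#' @export
additive_relationship_from_pedigree <- function(pedigree, max_generations = 4) {
  ped <- ped_order(as_tibble(pedigree)[c("id", "sire", "dam")])
  gmax <- max(ped$generation)
  cutoff <- gmax - max_generations
  if (cutoff >= 0) {
    founders <- ped$generation <= cutoff
    ped$sire[founders] <- NA
    ped$dam[founders] <- NA
  }
  n <- nrow(ped)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) A[si, di] / 2 else 0
    if (i > 1) {
      j <- seq_len(i - 1)
      aij <- (if (!is.na(si)) A[j, si] else 0) + (if (!is.na(di)) A[j, di] else 0)
      A[j, i] <- A[i, j] <- aij / 2
    }
  }
  A
}

#' Centered genomic relationship matrix
#'
#' `K = Wc %*% t(Wc) / p` where `Wc` is the dosage matrix with each SNP
#' column mean-centered and `p` the number of SNPs (the centered GRM used by
#' mixed-model association software). Missing dosages are mean-imputed per
#' SNP before centering; the stored genotype data are never modified.
#'
#' @param geno A [genotype_matrix()] or a plain dosage matrix
#'   (samples x SNPs).
#' @return Symmetric n x n matrix with sample ids as dimnames.
#' @export
centered_grm <- function(geno) {
  W <- if (inherits(geno, "genotype_matrix")) geno$dosages else as.matrix(geno)
  if (anyNA(W)) {
    mu <- colMeans(W, na.rm = TRUE)
    idx <- which(is.na(W), arr.ind = TRUE)
    W[idx] <- mu[idx[, 2]]
  }
  keep <- apply(W, 2, function(v) var(v) > 0)
  if (!any(keep)) abort("all SNPs are monomorphic; GRM undefined")
  W <- W[, keep, drop = FALSE]
  Wc <- scale(W, center = TRUE, scale = FALSE)
  tcrossprod(Wc) / ncol(Wc)
}

# Restricted log-likelihood via the spectral decomposition of K.
# X is the fixed-effect design (default intercept); eig may be precomputed.
#' Restricted log-likelihood of the variance-component model
#'
#' Evaluates the REML log-likelihood of `y = X b + g + e`,
#' `g ~ N(0, sigma_g2 K)`, `e ~ N(0, sigma_e2 I)` at given variances using
#' the eigendecomposition of K.
#'
#' @param y Trait vector.
#' @param K Relationship matrix.
#' @param sigma_g2,sigma_e2 Variance components (non-negative, not both 0).
#' @param X Fixed-effect design matrix (default: intercept).
#' @param eig Optional precomputed `eigen(K, symmetric = TRUE)`.
#' @return Scalar restricted log-likelihood.
#' @export
restricted_loglik <- function(y, K, sigma_g2, sigma_e2, X = NULL, eig = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  w <- sigma_g2 * d + sigma_e2
  if (any(w <= 0)) return(-Inf)
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  XtVX <- crossprod(Xs, Xs / w)
  beta <- solve(XtVX, crossprod(Xs, ys / w))
  r <- ys - Xs %*% beta
  quad <- sum(r^2 / w)
  c_ <- ncol(X)
  as.numeric(-0.5 * ((n - c_) * log(2 * pi) + sum(log(w)) +
                       determinant(XtVX, logarithm = TRUE)$modulus -
                       determinant(crossprod(X), logarithm = TRUE)$modulus + quad))
}

# Profile REML pieces for delta = sigma_e2 / sigma_g2 on the rotated data.
# Returns profiled sigma_g2 and the profile restricted loglik.
profile_reml <- function(log_delta, d, ys, Xs, XtX_logdet) {
  delta <- exp(log_delta)
  n <- length(ys)
  c_ <- ncol(Xs)
  w <- d + delta
  XtVX <- crossprod(Xs, Xs / w)
  beta <- solve(XtVX, crossprod(Xs, ys / w))
  r <- ys - Xs %*% beta
  rss <- sum(r^2 / w)
  sg2 <- rss / (n - c_)
  ll <- -0.5 * ((n - c_) * log(2 * pi * sg2) + (n - c_) + sum(log(w)) +
                  determinant(XtVX, logarithm = TRUE)$modulus - XtX_logdet)
  list(loglik = as.numeric(ll), sigma_g2 = sg2, delta = delta, beta = beta)
}

#' REML estimation of heritability
#'
#' Fits `y = mu + g + e` by restricted maximum likelihood, profiling the
#' genetic variance and optimizing the ratio `delta = sigma_e2 / sigma_g2`
#' by golden-section/Brent search on `log(delta)` in [-10, 10] after a grid
#' pre-scan. The heritability is `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`
#' with an approximate standard error from the curvature of the profile
#' restricted likelihood in h2. Estimates at the search boundary (h2
#' effectively 0 or 1) and flat likelihoods (e.g. `K = I`) are flagged.
#'
#' @param y Trait vector (typically normalized residuals), or a tibble of
#'   traits with a `sample_id` column (each trait fitted separately).
#' @param K Relationship matrix ([centered_grm()] or
#'   [additive_relationship_from_pedigree()]), aligned with `y`.
#' @param X Optional fixed-effect design (default intercept-only).
#' @return For a single trait, a `reml_fit` object with elements
#'   `sigma_g2`, `sigma_e2`, `h2`, `se_h2`, `loglik`, `delta`, `flag`
#'   (`"ok"`, `"boundary"` or `"flat"`), `n`. For a trait tibble, a tibble
#'   with one row per trait (see [tidy.reml_fit()]).
#' @export
reml_fit <- function(y, K, X = NULL) {
  if (is.data.frame(y)) {
    ids <- setdiff(names(y), "sample_id")
    fits <- lapply(ids, function(m) reml_fit(y[[m]], K, X = X))
    return(dplyr::bind_rows(lapply(seq_along(fits), function(i) {
      f <- fits[[i]]
      tibble(trait_id = ids[i], sigma_g2 = f$sigma_g2, sigma_e2 = f$sigma_e2,
             h2 = f$h2, se_h2 = f$se_h2, loglik = f$loglik, flag = f$flag)
    })))
  }
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- as.numeric(crossprod(U, y))
  Xs <- crossprod(U, X)
  XtX_logdet <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  obj <- function(ld) profile_reml(ld, d, ys, Xs, XtX_logdet)$loglik
  grid <- seq(-10, 10, length.out = 41)
  vals <- vapply(grid, obj, numeric(1))
  i0 <- which.max(vals)
  lo <- grid[max(1, i0 - 1)]
  hi <- grid[min(length(grid), i0 + 1)]
  opt <- optimize(obj, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  best <- profile_reml(opt$maximum, d, ys, Xs, XtX_logdet)
  sg2 <- best$sigma_g2
  se2 <- sg2 * best$delta
  h2 <- sg2 / (sg2 + se2)
  flag <- "ok"
  if (opt$maximum <= -10 + 1e-3 || opt$maximum >= 10 - 1e-3) flag <- "boundary"
  if (max(vals) - min(vals) < 1e-6) flag <- "flat"
  # curvature of the profile loglik in h2 (delta = (1-h2)/h2)
  se_h2 <- NA_real_
  h <- 1e-4
  h2c <- min(max(h2, 2 * h), 1 - 2 * h)
  ll_h2 <- function(hh) obj(log((1 - hh) / hh))
  curv <- (ll_h2(h2c + h) - 2 * ll_h2(h2c) + ll_h2(h2c - h)) / h^2
  if (is.finite(curv) && curv < 0) se_h2 <- sqrt(-1 / curv)
  if (h2 < 0) { h2 <- 0; flag <- "boundary" }
  structure(list(sigma_g2 = sg2, sigma_e2 = se2, h2 = h2, se_h2 = se_h2,
                 loglik = best$loglik, delta = best$delta, flag = flag, n = n),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> h2 =", format(round(x$h2, 4)),
      "(se", format(round(x$se_h2, 4)), ")",
      " sigma_g2 =", format(signif(x$sigma_g2, 4)),
      " sigma_e2 =", format(signif(x$sigma_e2, 4)),
      " [", x$flag, "]\n")
  invisible(x)
}
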