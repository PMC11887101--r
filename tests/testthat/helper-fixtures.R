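# fixture builders shared across test files; everything is generated in code

met_matrix_for_test <- function(data) {
  ids <- setdiff(names(data), c("sample_id", "plate", "is_pool"))
  m <- as.matrix(data[ids])
  rownames(m) <- data$sample_id
  m
}

# small metabolite tibble with optional plate/pool structure
make_met_table <- function(values, plate = NULL, pools = NULL) {
  m <- as.matrix(values)
  if (is.null(colnames(m))) colnames(m) <- paste0("M", seq_len(ncol(m)))
  out <- tibble::tibble(sample_id = paste0("s", seq_len(nrow(m))))
  if (!is.null(plate)) out$plate <- plate
  if (!is.null(pools)) out$is_pool <- pools
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

# founder-only genotypes: independent SNPs at given frequencies
make_founder_geno <- function(n, p_vec, seed = 1) {
  set.seed(seed)
  dos <- vapply(p_vec, function(p) rbinom(n, 2, p), numeric(n))
  rownames(dos) <- paste0("s", seq_len(n))
  colnames(dos) <- paste0("snp", seq_along(p_vec))
  genotype_matrix(dos, tibble::tibble(
    snp_id = colnames(dos), chromosome = "1",
    position_bp = seq_along(p_vec) * 1000L,
    allele_ref = "A", allele_alt = "B"), polarize = FALSE)
}

# multivariate normal rows with a given correlation matrix
rmvn_rows <- function(n, sigma, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * ncol(sigma)), n, ncol(sigma)) %*% chol(sigma)
}

# correlation-scaled inverse of a precision matrix
sigma_from_omega <- function(omega) {
  sigma <- solve(omega)
  s <- 1 / sqrt(diag(sigma))
  sigma * tcrossprod(s)
}

# polygenic trait from a relationship matrix
polygenic_trait <- function(K, h2, seed = 1) {
  n <- nrow(K)
  set.seed(seed)
  L <- chol(K + diag(1e-6, n))
  as.numeric(crossprod(L, rnorm(n))) * sqrt(h2) + rnorm(n) * sqrt(1 - h2)
}
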