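# Box-Cox normalization within a covariate regression, residualization, the
# common-lambda variant used for network construction, and all-pairs
# metabolite ratios.

#' Box-Cox power transform
#'
#' `(y^lambda - 1) / lambda` for `lambda != 0`, `log(y)` for `lambda == 0`.
#'
#' @param y Strictly positive numeric vector.
#' @param lambda Power parameter.
#' @return Transformed vector.
#' @export
boxcox_transform <- function(y, lambda) {
  if (any(y <= 0)) abort("Box-Cox requires strictly positive values")
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

# inverse transform used by the synthetic generator
inv_boxcox <- function(z, lambda) {
  if (lambda == 0) exp(z) else pmax(lambda * z + 1, 1e-8)^(1 / lambda)
}

# design matrix from a covariate tibble: characters/factors expanded to
# treatment dummies (a date factor with J levels yields J-1 columns),
# numerics kept; sample_id dropped; intercept included
covariate_design <- function(covariates, n = NULL) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0)) {
    if (is.null(n)) abort("need sample count for intercept-only design")
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  cv <- as_tibble(covariates)
  cv$sample_id <- NULL
  cv <- dplyr::mutate(cv, dplyr::across(dplyr::where(is.character), as.factor))
  if (anyNA(cv)) abort("covariates must be complete (no NA)")
  stats::model.matrix(~ ., data = cv)
}

check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 toString(dropped)))
  }
  qr_x
}

#' Fit the Box-Cox transformation within a covariate regression
#'
#' Selects the power parameter lambda by maximum profile likelihood over a
#' regular grid (by default 3001 values on [-3, 3], spacing 0.002) for the
#' linear model of the transformed trait on the covariates (intercept, sex,
#' carcass weight, collection-date dummies, ...). The profile log-likelihood
#' includes the Jacobian term `(lambda - 1) * sum(log y)`. The 95% interval
#' contains every grid lambda within 1.92 log-likelihood units
#' (`qchisq(0.95, 1) / 2`) of the maximum.
#'
#' @param y Strictly positive trait vector (concentrations or ratios).
#' @param covariates Tibble of per-sample covariates (may be `NULL` for an
#'   intercept-only model).
#' @param grid Lambda grid; default `seq(-3, 3, length.out = 3001)`.
#' @return A `boxcox_fit` object: `lambda` (MLE), `ci95` (c(lo, hi)),
#'   `grid` tibble (lambda, loglik), `betas` (covariate estimates at the
#'   MLE), `n`.
#' @export
boxcox_fit <- function(y, covariates = NULL, grid = seq(-3, 3, length.out = 3001)) {
  if (any(!is.finite(y)) || any(y <= 0)) abort("y must be finite and strictly positive")
  n <- length(y)
  X <- covariate_design(covariates, n = n)
  if (nrow(X) != n) abort("covariate rows must match length(y)")
  qr_x <- check_full_rank(X)
  slog <- sum(log(y))
  logy <- log(y)
  ll <- vapply(grid, function(lam) {
    z <- if (lam == 0) logy else (y^lam - 1) / lam
    rss <- sum(qr.resid(qr_x, z)^2)
    -n / 2 * log(rss / n) + (lam - 1) * slog
  }, numeric(1))
  best <- which.max(ll)
  lam_hat <- grid[best]
  in_ci <- ll >= ll[best] - stats::qchisq(0.95, 1) / 2
  z <- boxcox_transform(y, lam_hat)
  betas <- qr.coef(qr_x, z)
  structure(list(
    lambda = lam_hat,
    ci95 = range(grid[in_ci]),
    grid = tibble(lambda = grid, loglik = ll),
    betas = betas,
    n = n
  ), class = "boxcox_fit")
}

#' @export
print.boxcox_fit <- function(x, ...) {
  cat("<boxcox_fit> lambda =", format(x$lambda),
      " 95% CI [", format(x$ci95[1]), ",", format(x$ci95[2]), "]  n =", x$n, "\n")
  invisible(x)
}

#' Residualize a trait on covariates
#'
#' Ordinary least squares of the (transformed) trait on the covariate design
#' (intercept + sex + weight + date dummies); returns the residuals
#' `e = y - y_hat`, which are orthogonal to every design column and sum to
#' zero.
#'
#' @param y Numeric trait vector (already transformed).
#' @param covariates Covariate tibble (or `NULL` for centering only).
#' @return Residual vector.
#' @export
residualize <- function(y, covariates = NULL) {
  X <- covariate_design(covariates, n = length(y))
  if (nrow(X) != length(y)) abort("covariate rows must match length(y)")
  qr_x <- check_full_rank(X)
  as.numeric(qr.resid(qr_x, y))
}

#' Pick the lambda shared by the most per-metabolite confidence intervals
#'
#' For the common-lambda normalization used before network construction:
#' returns the grid value contained in the largest number of per-metabolite
#' 95% intervals; ties are broken toward the median of the per-metabolite
#' lambda estimates.
#'
#' @param fits List of [boxcox_fit()] objects.
#' @return A single lambda value.
#' @export
select_common_lambda <- function(fits) {
  if (!length(fits)) abort("need at least one fit")
  if (inherits(fits, "boxcox_fit")) fits <- list(fits)
  grid <- fits[[1]]$grid$lambda
  counts <- rowSums(vapply(fits, function(f) {
    grid >= f$ci95[1] & grid <= f$ci95[2]
  }, logical(length(grid))))
  top <- which(counts == max(counts))
  med <- median(vapply(fits, function(f) f$lambda, numeric(1)))
  grid[top[which.min(abs(grid[top] - med))]]
}

#' Normalize a metabolite table for association or network analysis
#'
#' Per metabolite: Box-Cox transform (lambda by per-trait profile-likelihood
#' grid search, or one common lambda), then residualization on the covariates.
#' The residuals are what enters the mixed-model association scan and the
#' correlation networks.
#'
#' @param data Complete, imputed metabolite tibble.
#' @param covariates Covariate tibble aligned with `data$sample_id` (a
#'   `sample_id` column, if present, is used to align).
#' @param mode `"per-trait"` (default) or `"common-lambda"`.
#' @param grid Lambda grid passed to [boxcox_fit()].
#' @return Tibble `sample_id` + one residual column per metabolite, with
#'   attributes `lambdas` (named vector) and `mode`.
#' @export
normalize_metabolites <- function(data, covariates = NULL,
                                  mode = c("per-trait", "common-lambda"),
                                  grid = seq(-3, 3, length.out = 3001)) {
  mode <- match.arg(mode)
  ids <- metabolite_ids(data)
  vals <- met_matrix(data)
  if (anyNA(vals)) abort("normalize after QC: no missing values allowed")
  cov_aligned <- align_covariates(covariates, data$sample_id)
  fits <- lapply(ids, function(m) boxcox_fit(vals[, m], cov_aligned, grid = grid))
  names(fits) <- ids
  lambdas <- vapply(fits, `[[`, numeric(1), "lambda")
  if (mode == "common-lambda") {
    lam <- select_common_lambda(fits)
    lambdas[] <- lam
  }
  res <- vapply(ids, function(m) {
    residualize(boxcox_transform(vals[, m], lambdas[[m]]), cov_aligned)
  }, numeric(nrow(vals)))
  out <- dplyr::bind_cols(tibble(sample_id = data$sample_id),
                          as_tibble(matrix(res, nrow = nrow(vals),
                                           dimnames = list(NULL, ids))))
  attr(out, "lambdas") <- lambdas
  attr(out, "mode") <- mode
  attr(out, "fits") <- fits
  out
}

align_covariates <- function(covariates, sample_ids) {
  if (is.null(covariates)) return(NULL)
  cv <- as_tibble(covariates)
  if ("sample_id" %in% names(cv)) {
    idx <- match(sample_ids, cv$sample_id)
    if (anyNA(idx)) abort("covariates missing for some samples")
    cv <- cv[idx, , drop = FALSE]
  } else if (nrow(cv) != length(sample_ids)) {
    abort("covariate rows must match samples (or carry sample_id)")
  }
  cv
}

#' Build all pairwise metabolite ratios
#'
#' Forms every unordered metabolite pair (a, b) with a before b in the input
#' column order, and the ratio a/b on the raw (imputed) concentration scale.
#' With m metabolites this yields m(m-1)/2 ratio traits, each subsequently
#' normalized like a single metabolite.
#'
#' @param data Complete, imputed metabolite tibble (all values > 0).
#' @param pairs Optional two-column tibble/matrix restricting the pairs.
#' @return Tibble `sample_id` + one column per ratio named `"a/b"`, with
#'   attribute `pairs` (tibble a, b).
#' @export
build_ratios <- function(data, pairs = NULL) {
  ids <- metabolite_ids(data)
  if (length(ids) < 2) abort("need at least two metabolites")
  vals <- met_matrix(data)
  if (any(vals <= 0, na.rm = TRUE) || anyNA(vals)) {
    abort("ratios need complete, strictly positive concentrations (impute zeros first)")
  }
  if (is.null(pairs)) {
    idx <- utils::combn(length(ids), 2)
    pairs <- tibble(a = ids[idx[1, ]], b = ids[idx[2, ]])
  } else {
    pairs <- tibble(a = as.character(pairs[[1]]), b = as.character(pairs[[2]]))
  }
  if (any(pairs$a == pairs$b)) abort("self-ratios are not allowed")
  ratios <- vals[, pairs$a, drop = FALSE] / vals[, pairs$b, drop = FALSE]
  colnames(ratios) <- paste0(pairs$a, "/", pairs$b)
  out <- dplyr::bind_cols(tibble(sample_id = data$sample_id), as_tibble(ratios))
  attr(out, "pairs") <- pairs
  out
}
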