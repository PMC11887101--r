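# Metabolite quality control: pool-based metabolite filters, sample outlier
# and missingness filters, below-LOD zero imputation. All functions take the
# tidy metabolite table (sample_id [, plate, is_pool], metabolite columns),
# return the filtered table, and accumulate a QC report retrievable with
# qc_report().

new_qc_report <- function() {
  list(
    removed_metabolites = tibble(metabolite = character(), reason = character()),
    removed_samples = tibble(sample_id = character(), reason = character()),
    imputed_cells = 0L,
    cv = tibble(metabolite = character(), cv = double())
  )
}

get_report <- function(data) attr(data, "qc_report") %||% new_qc_report()

set_report <- function(data, report) {
  attr(data, "qc_report") <- report
  data
}

#' Retrieve the accumulated QC report
#'
#' @param data A metabolite tibble that has passed through one or more QC
#'   steps.
#' @return A list with tibbles `removed_metabolites` (id, reason) and
#'   `removed_samples` (id, reason), the count `imputed_cells`, and the
#'   per-metabolite inter-plate `cv` table (filled by
#'   [filter_metabolites_cv()]).
#' @export
qc_report <- function(data) get_report(data)

pool_rows <- function(data, pool_samples) {
  if (!is.null(pool_samples)) return(data$sample_id %in% pool_samples)
  if ("is_pool" %in% names(data)) return(data$is_pool %in% TRUE)
  rep(FALSE, nrow(data))
}

#' Remove metabolites undetected in a quality-control pool
#'
#' A metabolite is excluded when, within the pool measurements of at least
#' one plate, all its values are missing or all are zero (rule (i) of the QC
#' cascade): such a metabolite was not reliably measured on that plate.
#'
#' @param data Metabolite tibble.
#' @param pool_samples Character vector of sample ids that are QC pools;
#'   defaults to rows flagged by an `is_pool` column.
#' @return The table without failing metabolites (QC report updated).
#' @export
filter_metabolites_pools <- function(data, pool_samples = NULL) {
  isp <- pool_rows(data, pool_samples)
  if (!any(isp)) abort("no pool samples identified; supply pool_samples or an is_pool column")
  pools <- data[isp, , drop = FALSE]
  plate <- if ("plate" %in% names(pools)) pools$plate else pools$sample_id
  ids <- metabolite_ids(data)
  vals <- met_matrix(pools)
  fails <- vapply(ids, function(m) {
    v <- vals[, m]
    any(vapply(split(v, plate), function(pv) all(is.na(pv) | pv == 0), logical(1)))
  }, logical(1))
  report <- get_report(data)
  if (any(fails)) {
    report$removed_metabolites <- dplyr::bind_rows(
      report$removed_metabolites,
      tibble(metabolite = ids[fails], reason = "pool-missing")
    )
  }
  set_report(data[, !(names(data) %in% ids[fails]), drop = FALSE], report)
}

#' Remove outlier samples by the interquartile-range rule
#'
#' A sample is removed when its concentration deviates more than
#' `iqr_mult` times the interquartile range below or above the per-metabolite
#' median for strictly more than `max_frac` of the metabolites (rule (ii)).
#' With a degenerate IQR of zero, a value only counts as deviant when it
#' differs from the median. Pool rows are excluded from both the reference
#' statistics and the removal.
#'
#' @param data Metabolite tibble.
#' @param iqr_mult IQR multiplier (default 1.5).
#' @param max_frac Tolerated fraction of deviant metabolites (default 0.30,
#'   strict `>`).
#' @return Filtered table with updated QC report.
#' @export
flag_outlier_samples <- function(data, iqr_mult = 1.5, max_frac = 0.30) {
  isp <- pool_rows(data, NULL)
  biol <- data[!isp, , drop = FALSE]
  ids <- metabolite_ids(data)
  vals <- met_matrix(biol)
  med <- apply(vals, 2, median, na.rm = TRUE)
  iqr <- apply(vals, 2, function(v) diff(quantile(v, c(0.25, 0.75), na.rm = TRUE)))
  lo <- med - iqr_mult * iqr
  hi <- med + iqr_mult * iqr
  dev <- sweep(vals, 2, lo, "<") | sweep(vals, 2, hi, ">")
  zero_iqr <- iqr == 0
  if (any(zero_iqr)) {
    dev[, zero_iqr] <- sweep(vals[, zero_iqr, drop = FALSE], 2, med[zero_iqr], "!=")
  }
  frac <- rowMeans(dev, na.rm = TRUE)
  frac[is.nan(frac)] <- 0
  out <- biol$sample_id[frac > max_frac]
  report <- get_report(data)
  if (length(out)) {
    report$removed_samples <- dplyr::bind_rows(
      report$removed_samples, tibble(sample_id = out, reason = "outlier")
    )
  }
  set_report(data[!(data$sample_id %in% out), , drop = FALSE], report)
}

#' Remove samples with any missing metabolite value
#'
#' Rule (iii): after metabolite-level filtering, animals with a missing value
#' for at least one retained metabolite are eliminated, leaving a complete
#' matrix. Pool rows are not removed.
#'
#' @param data Metabolite tibble.
#' @return Filtered table with updated QC report.
#' @export
drop_incomplete_samples <- function(data) {
  ids <- metabolite_ids(data)
  if (!nrow(data) || !length(ids)) {
    warn("empty metabolite table")
    return(data)
  }
  isp <- pool_rows(data, NULL)
  incomplete <- !complete.cases(data[ids]) & !isp
  report <- get_report(data)
  if (any(incomplete)) {
    report$removed_samples <- dplyr::bind_rows(
      report$removed_samples,
      tibble(sample_id = data$sample_id[incomplete], reason = "missing-value")
    )
  }
  set_report(data[!incomplete, , drop = FALSE], report)
}

#' Remove metabolites with high inter-plate coefficient of variation
#'
#' Rule (iv): the inter-plate CV of a metabolite is sd/mean of its per-plate
#' pool means. Metabolites with CV at or above `cv_threshold` are removed
#' (the stated rule removes unstable metabolites; the direction is exposed
#' for completeness). A zero pool mean makes the CV undefined and removes the
#' metabolite with reason `"undefined CV"`.
#'
#' @param data Metabolite tibble.
#' @param pool_samples Optional explicit pool sample ids (default: `is_pool`
#'   column).
#' @param cv_threshold CV threshold (default 0.30; removal at `>=`).
#' @param direction `"remove_high"` (default) removes CV >= threshold;
#'   `"remove_low"` applies the literal opposite rule.
#' @return Filtered table; the QC report gains the per-metabolite CV table.
#' @export
filter_metabolites_cv <- function(data, pool_samples = NULL, cv_threshold = 0.30,
                                  direction = c("remove_high", "remove_low")) {
  direction <- match.arg(direction)
  isp <- pool_rows(data, pool_samples)
  if (!any(isp)) abort("no pool samples identified")
  pools <- data[isp, , drop = FALSE]
  if (!"plate" %in% names(pools)) abort("inter-plate CV requires a plate column")
  if (length(unique(pools$plate)) < 2) abort("need pool measurements on >= 2 plates")
  ids <- metabolite_ids(data)
  vals <- met_matrix(pools)
  cvs <- vapply(ids, function(m) {
    pm <- vapply(split(vals[, m], pools$plate), mean, numeric(1), na.rm = TRUE)
    mu <- mean(pm, na.rm = TRUE)
    if (!is.finite(mu) || mu == 0) return(NA_real_)
    sd(pm, na.rm = TRUE) / mu
  }, numeric(1))
  undefined <- is.na(cvs)
  fails <- if (direction == "remove_high") !undefined & cvs >= cv_threshold
           else !undefined & cvs < cv_threshold
  report <- get_report(data)
  report$cv <- tibble(metabolite = ids, cv = unname(cvs))
  drop <- c(ids[fails], ids[undefined])
  if (length(drop)) {
    report$removed_metabolites <- dplyr::bind_rows(
      report$removed_metabolites,
      tibble(metabolite = c(ids[fails], ids[undefined]),
             reason = c(rep("cv", sum(fails)), rep("undefined CV", sum(undefined))))
    )
  }
  set_report(data[, !(names(data) %in% drop), drop = FALSE], report)
}

#' Impute below-LOD zeros from a uniform distribution
#'
#' Every zero concentration is replaced by a draw from
#' Uniform(0, minimum non-zero value of that metabolite); non-zero values are
#' untouched. Run after [drop_incomplete_samples()] so no `NA` remain.
#'
#' @param data Complete metabolite tibble.
#' @param seed Seed making the imputation reproducible.
#' @return Table with all zeros imputed (QC report counts the cells).
#' @export
impute_zeros <- function(data, seed = 1L) {
  ids <- metabolite_ids(data)
  vals <- met_matrix(data)
  if (anyNA(vals)) abort("missing values present; run drop_incomplete_samples() first")
  report <- get_report(data)
  n_imputed <- 0L
  with_seed(seed, {
    for (m in ids) {
      v <- vals[, m]
      z <- v == 0
      if (!any(z)) next
      nz <- v[!z]
      if (!length(nz)) abort(paste0("metabolite '", m, "' is entirely zero; no minimum non-zero value"))
      vals[z, m] <- runif(sum(z), min = 0, max = min(nz))
      n_imputed <- n_imputed + sum(z)
    }
  })
  report$imputed_cells <- report$imputed_cells + n_imputed
  out <- rebuild_met(data, vals)
  set_report(out, report)
}

#' Run the full QC cascade
#'
#' Applies the four cleaning rules in their canonical order — pool-based
#' metabolite exclusion, IQR sample outliers, incomplete samples, inter-plate
#' CV — followed by zero imputation, and drops the pool rows from the result.
#'
#' @param data Metabolite tibble with `plate` and `is_pool` columns.
#' @param cv_threshold,iqr_mult,outlier_frac Thresholds of rules (iv) and (ii).
#' @param seed Imputation seed.
#' @param impute Impute zeros after filtering (default `TRUE`).
#' @return Cleaned biological-sample table with the accumulated QC report.
#' @export
qc_pipeline <- function(data, cv_threshold = 0.30, iqr_mult = 1.5,
                        outlier_frac = 0.30, seed = 1L, impute = TRUE) {
  out <- data |>
    filter_metabolites_pools() |>
    flag_outlier_samples(iqr_mult = iqr_mult, max_frac = outlier_frac) |>
    drop_incomplete_samples() |>
    filter_metabolites_cv(cv_threshold = cv_threshold)
  rep <- get_report(out)
  out <- out[!pool_rows(out, NULL), , drop = FALSE]
  out$is_pool <- NULL
  out <- set_report(out, rep)
  if (impute) out <- impute_zeros(out, seed = seed)
  out
}
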