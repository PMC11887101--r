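# broom-style tidy()/glance() methods for the package's fitted objects.

#' Tidy a Box-Cox fit
#'
#' @param x A [boxcox_fit()] object.
#' @param ... Unused.
#' @return Tibble of covariate estimates (term, estimate).
#' @export
tidy.boxcox_fit <- function(x, ...) {
  tibble(term = names(x$betas), estimate = unname(x$betas))
}

#' @describeIn tidy.boxcox_fit One-row model summary: lambda, its 95%
#'   interval and the sample size.
#' @export
glance.boxcox_fit <- function(x, ...) {
  tibble(lambda = x$lambda, ci_low = x$ci95[1], ci_high = x$ci95[2],
         loglik = max(x$grid$loglik), n = x$n)
}

#' Tidy a REML variance-component fit
#'
#' @param x A [reml_fit()] object.
#' @param ... Unused.
#' @return Tibble with one row per component (genetic, residual) plus the
#'   heritability.
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble(term = c("sigma_g2", "sigma_e2", "h2"),
         estimate = c(x$sigma_g2, x$sigma_e2, x$h2),
         std.error = c(NA, NA, x$se_h2))
}

#' @describeIn tidy.reml_fit One-row summary: h2, its standard error, the
#'   restricted log-likelihood, convergence flag, n.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble(h2 = x$h2, se_h2 = x$se_h2, sigma_g2 = x$sigma_g2,
         sigma_e2 = x$sigma_e2, loglik = x$loglik, flag = x$flag, n = x$n)
}

#' Tidy a Gaussian graphical model
#'
#' @param x A `ggm` object from [build_ggm()].
#' @param ... Unused.
#' @return The edge tibble (from, to, pcc).
#' @export
tidy.ggm <- function(x, ...) x$edges

#' @describeIn tidy.ggm One-row summary: node, edge and singleton counts,
#'   threshold, correction flag.
#' @export
glance.ggm <- function(x, ...) {
  tibble(n_nodes = length(x$nodes),
         n_connected = length(x$nodes) - length(x$singletons),
         n_edges = nrow(x$edges), n_singletons = length(x$singletons),
         threshold = x$threshold, mode = x$mode, corrected = x$corrected)
}

#' Tidy a kynurenine-pathway steady state
#'
#' @param x A `kp_steady_state` object.
#' @param ... Unused.
#' @return Tibble metabolite, concentration (mM).
#' @export
tidy.kp_steady_state <- function(x, ...) {
  tibble(metabolite = names(x$state), concentration = unname(x$state))
}

#' @describeIn tidy.kp_steady_state One-row summary: method, residual,
#'   clamped Trp.
#' @export
glance.kp_steady_state <- function(x, ...) {
  tibble(method = x$method, residual = x$residual, trp = x$trp)
}
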