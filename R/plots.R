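# ggplot2 display functions for the pipeline's result types.

#' Manhattan plot of an association scan
#'
#' @param assoc [lmm_scan()] output (optionally several traits; facetted).
#' @param threshold Optional significance threshold drawn as a line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(assoc, threshold = NULL) {
  d <- as_tibble(assoc)
  d <- d[is.finite(d$p_wald), , drop = FALSE]
  d$chromosome <- factor(d$chromosome, levels = unique(d$chromosome))
  chr_off <- d |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(len = max(.data$position_bp), .groups = "drop") |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
  d <- dplyr::left_join(d, chr_off, by = "chromosome")
  d$x <- d$position_bp + d$offset
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = -log10(.data$p_wald),
                                       colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "genome position", y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal()
  if (length(unique(d$trait_id)) > 1) {
    p <- p + ggplot2::facet_wrap(~trait_id)
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed")
  }
  p
}

#' @export
autoplot.boxcox_fit <- function(object, ...) {
  ci <- object$ci95
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$lambda, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lambda) +
    ggplot2::geom_vline(xintercept = ci, linetype = "dotted") +
    ggplot2::labs(x = expression(lambda), y = "profile log-likelihood") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ggm <- function(object, ...) {
  # simple circular layout; singletons on an outer ring
  nodes <- object$nodes
  k <- length(nodes)
  ang <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  lay <- tibble(node = nodes, x = cos(ang), y = sin(ang),
                singleton = nodes %in% object$singletons)
  e <- object$edges
  seg <- tibble(
    x = lay$x[match(e$from, lay$node)], y = lay$y[match(e$from, lay$node)],
    xend = lay$x[match(e$to, lay$node)], yend = lay$y[match(e$to, lay$node)],
    pcc = e$pcc)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$pcc),
                          colour = "grey50", show.legend = FALSE) +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$singleton)) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2)) +
    ggplot2::theme_void()
}

#' @export
autoplot.kp_steady_state <- function(object, ...) {
  d <- tidy(object)
  d$metabolite <- factor(d$metabolite, levels = d$metabolite)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metabolite, y = .data$concentration)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "steady-state concentration (mM)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a two-dimensional ratio-association profile
#'
#' @param profile Matrix from [ratio_profile_2d()].
#' @return A ggplot object.
#' @export
plot_ratio_profile <- function(profile) {
  d <- as_tibble(as.table(profile), .name_repair = "minimal")
  names(d) <- c("a", "b", "neglog10p")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b,
                                  fill = .data$neglog10p)) +
    ggplot2::geom_tile() +
    ggplot2::labs(fill = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
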