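# ggplot2 views of the result objects

#' @describeIn balance Flow-web diagram: groups placed by domain (x) and
#'   trophic level (y), node area proportional to biomass, segment width to
#'   consumption flow.
#' @param object An `fw_balanced` object.
#' @param min_flow Smallest flow drawn (t km\eqn{^{-2}} yr\eqn{^{-1}}).
#' @method autoplot fw_balanced
#' @export
autoplot.fw_balanced <- function(object, min_flow = 0, ...) {
  tl <- suppressWarnings(trophic_levels(object))
  g <- dplyr::left_join(object$groups, tl[, c("group", "TL")], by = "group")
  set_x <- function(dom) match(dom, DOMAINS)
  g$x <- set_x(g$domain) + stats::runif(nrow(g), -0.25, 0.25)
  fl <- compute_flows(object, long = TRUE)
  fl <- dplyr::filter(fl, .data$prey != "import", .data$flow >= min_flow)
  fl$x <- g$x[match(fl$prey, g$group)]
  fl$y <- g$TL[match(fl$prey, g$group)]
  fl$xend <- g$x[match(fl$consumer, g$group)]
  fl$yend <- g$TL[match(fl$consumer, g$group)]
  ggplot2::ggplot(g, ggplot2::aes(x = .data$x, y = .data$TL)) +
    ggplot2::geom_segment(
      data = fl,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$flow),
      alpha = 0.25, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$B, colour = .data$domain)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$group), size = 2.4,
                       vjust = -1) +
    ggplot2::scale_x_continuous(breaks = seq_along(DOMAINS),
                                labels = DOMAINS) +
    ggplot2::scale_linewidth(range = c(0.1, 2), guide = "none") +
    ggplot2::labs(x = NULL, y = "trophic level", size = "B (t/km2)",
                  colour = "domain") +
    ggplot2::theme_minimal()
}

#' @describeIn mti Heat map of the total impact matrix (impacting components
#'   as rows).
#' @param object An `fw_mti` object.
#' @method autoplot fw_mti
#' @export
autoplot.fw_mti <- function(object, ...) {
  d <- tidy(object)
  d$impactor <- factor(d$impactor, levels = rev(rownames(object$M)))
  d$impacted <- factor(d$impacted, levels = colnames(object$M))
  ggplot2::ggplot(d, ggplot2::aes(.data$impacted, .data$impactor,
                                  fill = .data$total)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy", midpoint = 0) +
    ggplot2::labs(x = "impacted", y = "impacting", fill = "MTI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Exploitation plots
#'
#' Bar charts of the direct fishing pressure: exploitation rate by group
#' (coloured by domain) or cumulative exploitation rate by fleet.
#'
#' @param x An `fw_exploitation` object.
#' @param which `"groups"` (E by group) or `"fleets"` (CumE by fleet).
#' @param top_n Show only the `top_n` largest bars.
#' @return A ggplot.
#' @export
plot_exploitation <- function(x, which = c("groups", "fleets"), top_n = 25) {
  stopifnot(inherits(x, "fw_exploitation"))
  which <- match.arg(which)
  if (which == "groups") {
    d <- dplyr::slice_max(dplyr::filter(x$groups, .data$E > 0), .data$E,
                          n = top_n)
    ggplot2::ggplot(d, ggplot2::aes(.data$E,
                                    stats::reorder(.data$group, .data$E),
                                    fill = .data$domain)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "exploitation rate E = F/Z", y = NULL,
                    fill = "domain") +
      ggplot2::theme_minimal()
  } else {
    d <- dplyr::slice_max(x$fleets, .data$CumE, n = top_n)
    ggplot2::ggplot(d, ggplot2::aes(.data$CumE,
                                    stats::reorder(.data$fleet, .data$CumE))) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "cumulative exploitation rate", y = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Cross-domain flux plot
#'
#' Paired bars of each group's consumption from, and predation loss to, the
#' other domains — the flux view of benthic–pelagic coupling.
#'
#' @param x Result of [cross_domain_flux()].
#' @param top_n Show the `top_n` groups by combined cross-domain flux.
#' @return A ggplot.
#' @export
plot_bpc_flux <- function(x, top_n = 20) {
  d <- dplyr::mutate(x, total = .data$consumer_flux + .data$source_flux)
  d <- dplyr::slice_max(dplyr::filter(d, .data$total > 0), .data$total,
                        n = top_n)
  long <- tidyr::pivot_longer(d, c("consumer_flux", "source_flux"),
                              names_to = "role", values_to = "flux")
  long$role <- ifelse(long$role == "consumer_flux", "as consumer",
                      "as source")
  ggplot2::ggplot(long, ggplot2::aes(.data$flux,
                                     stats::reorder(.data$group,
                                                    .data$flux),
                                     fill = .data$domain)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~role, scales = "free_x") +
    ggplot2::labs(x = "cross-domain flux (t km-2 yr-1)", y = NULL,
                  fill = "domain") +
    ggplot2::theme_minimal()
}
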