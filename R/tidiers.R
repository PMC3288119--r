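#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a LOD scan or QTL table
#'
#' Flattens the per-parent list-columns: one row per (trait, marker,
#' parent) with the parent's effect and drop-one LOD next to the overall
#' record.
#'
#' @param x a `gg_scan` or `gg_qtl`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.gg_scan <- function(x, ...) {
  x |>
    dplyr::mutate(parent = purrr::map(.data$effects, names)) |>
    tidyr::unnest(c("parent", "effects", "parent_lod")) |>
    dplyr::rename(effect = "effects")
}

#' @rdname tidy.gg_scan
#' @export
tidy.gg_qtl <- tidy.gg_scan

#' @export
glance.gg_scan <- function(x, ...) {
  tibble(
    n_traits = dplyr::n_distinct(x$trait),
    n_markers = dplyr::n_distinct(x$marker_id),
    max_lod = max(x$lod),
    n_above_384 = sum(x$lod >= 3.84)
  )
}

#' @export
tidy.gg_network <- function(x, ...) x$edges

#' @export
glance.gg_network <- function(x, ...) {
  tibble(
    n_nodes = length(x$nodes), n_edges = nrow(x$edges),
    cutoff = x$cutoff, lambda = x$lambda, eta0 = x$eta0, kappa = x$kappa
  )
}

#' @export
glance.gg_hotspots <- function(x, ...) {
  tibble(
    n_markers = nrow(x), n_eqtls = sum(x$eqtl_count),
    threshold = attr(x, "threshold") %||% NA_integer_,
    n_hotspots = sum(x$hotspot)
  )
}

#' LOD profile plot
#'
#' LOD versus map position, one facet per linkage group, with the
#' significance threshold drawn as a horizontal line.
#'
#' @param object a `gg_scan`.
#' @param threshold LOD threshold line (default 3.84).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gg_scan <- function(object, threshold = 3.84, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$position_cm, .data$lod, group = .data$trait)
  ) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~linkage_group, scales = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD")
}

#' eQTL density / hotspot plot
#'
#' Per-marker eQTL counts along the map with the randomization threshold;
#' hotspot markers are highlighted.
#'
#' @param object a `gg_hotspots`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gg_hotspots <- function(object, ...) {
  thr <- attr(object, "threshold")
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(.data$position_cm, .data$eqtl_count, fill = .data$hotspot)
  ) +
    ggplot2::geom_col(width = 2) +
    ggplot2::facet_wrap(~linkage_group, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(x = "position (cM)", y = "eQTL count")
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = 2)
  }
  p
}

#' Network degree plot
#'
#' Degree distribution of the thresholded co-expression network.
#'
#' @param object a `gg_network`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gg_network <- function(object, ...) {
  deg <- table(factor(
    c(object$edges$gene_a, object$edges$gene_b),
    levels = object$nodes
  ))
  ggplot2::ggplot(
    tibble(degree = as.integer(deg)),
    ggplot2::aes(.data$degree)
  ) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = "node degree",
      y = "genes",
      title = sprintf("edges at probability >= %.2f", object$cutoff)
    )
}
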