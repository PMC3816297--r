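#' Plot a provenance graph with ggplot2
#'
#' Lays the account's graph out with igraph (Sugiyama layering, which suits
#' the generated-from flow) and draws nodes colored by kind and edges styled
#' by relation kind. Intended for quick interactive inspection; publication
#' rendering goes through [to_dot()] and GraphViz.
#'
#' @param object A `prov_account`.
#' @param groups Group selection passed to [filter_by_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prov_account
#' @export
autoplot.prov_account <- function(object, groups = "all", ...) {
  object <- filter_by_groups(object, groups)
  nd <- object$nodes
  ed <- object$edges
  if (!nrow(nd)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle(sprintf("%s (empty graph)", object$name)))
  }
  g <- igraph::graph_from_data_frame(
    d = if (nrow(ed)) ed[, c("source", "target")] else data.frame(source = character(), target = character()),
    directed = TRUE, vertices = nd$id
  )
  xy <- igraph::layout_with_sugiyama(g)$layout
  pos <- tibble(id = nd$id, x = xy[, 1], y = xy[, 2], kind = nd$kind,
                label = nd$name)
  seg <- NULL
  if (nrow(ed)) {
    seg <- ed
    seg$x <- pos$x[match(ed$source, pos$id)]
    seg$y <- pos$y[match(ed$source, pos$id)]
    seg$xend <- pos$x[match(ed$target, pos$id)]
    seg$yend <- pos$y[match(ed$target, pos$id)]
  }
  p <- ggplot2::ggplot()
  if (!is.null(seg)) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$kind),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      color = "grey40"
    )
  }
  p +
    ggplot2::geom_point(data = pos,
                        ggplot2::aes(x = .data$x, y = .data$y, color = .data$kind),
                        size = 4) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                       vjust = -1, size = 2.8) +
    ggplot2::scale_linetype_manual(values = c(
      used = "solid", wasGeneratedBy = "solid", wasAssociatedWith = "dotted",
      wasDerivedFrom = "dashed", memberOf = "solid"), drop = TRUE) +
    ggplot2::labs(title = object$name, color = "element", linetype = "relation") +
    ggplot2::theme_void()
}

#' Plot a validity report
#'
#' One bar per restriction axis, colored by verdict, with violation counts.
#'
#' @param object A `prov_validity` (from [infer_account_validity()] or
#'   [infer_project_validity()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prov_validity
#' @export
autoplot.prov_validity <- function(object, ...) {
  counts <- table(factor(object$violations$axis,
                         levels = c("structural", "temporal", "functional")))
  df <- tibble(
    axis = names(counts),
    n_violations = as.integer(counts),
    verdict = ifelse(as.integer(counts) == 0, "valid", "invalid")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis, y = .data$n_violations,
                                   fill = .data$verdict)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(valid = "#2a9d8f", invalid = "#e76f51")) +
    ggplot2::labs(title = sprintf("Validity of %s '%s'", object$scope, object$id),
                  x = NULL, y = "violations") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
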