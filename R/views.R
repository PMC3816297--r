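#' View options for filtered graph rendering
#'
#' @param groups `"all"`, or a nonempty character vector of group labels: a
#'   node is kept when it belongs to at least one selected group.
#' @param show_roles Label edges with their `Role` attribute.
#' @param show_annotations Attach annotations as gray label boxes.
#' @return A `prov_view_options` list.
#' @export
view_options <- function(groups = "all", show_roles = FALSE,
                         show_annotations = FALSE) {
  if (!identical(groups, "all")) {
    groups <- as.character(groups)
    if (!length(groups)) abort("select at least one group (or \"all\")")
  }
  structure(list(groups = groups, show_roles = show_roles,
                 show_annotations = show_annotations),
            class = "prov_view_options")
}

#' Filter an account to the subgraph of selected groups
#'
#' Keeps every node belonging to at least one of the selected groups and
#' every edge whose two endpoints are kept, giving a personalized view of a
#' workflow execution (one chain of the experiment, one processing phase,
#' ...). With `groups = "all"` the account is returned unchanged — that is
#' the only view in which nodes belonging to no group are visible. Unknown
#' group names select nothing and raise a warning.
#'
#' @param account A `prov_account`.
#' @param groups `"all"` or a character vector of group labels (also accepts
#'   a [view_options()] list).
#' @return A `prov_account` restricted to the selected subgraph (annotations
#'   of dropped elements are dropped too).
#' @examples
#' prj <- build_case_study(payload_dir = tempfile("payloads"))
#' fam57 <- filter_by_groups(get_account(prj, "Multiple Alignment"), "Family 57")
#' nodes(fam57)$id
#' @export
filter_by_groups <- function(account, groups = "all") {
  stopifnot(inherits(account, "prov_account"))
  if (inherits(groups, "prov_view_options")) groups <- groups$groups
  if (identical(groups, "all")) return(account)
  groups <- as.character(groups)
  known <- unique(unlist(account$nodes$groups))
  unknown <- setdiff(groups, known)
  if (length(unknown)) {
    warn(sprintf("unknown group(s) select nothing: %s",
                 paste(unknown, collapse = ", ")))
  }
  keep <- map_lgl(account$nodes$groups, function(g) any(g %in% groups))
  account$nodes <- account$nodes[keep, ]
  kept_ids <- account$nodes$id
  account$edges <- account$edges[account$edges$source %in% kept_ids &
                                   account$edges$target %in% kept_ids, ]
  live <- c(account$id, account$nodes$id, account$edges$id)
  account$annotations <- account$annotations[account$annotations$element %in% live, ]
  account
}

DOT_SHAPES <- c(agent = "house", activity = "box", entity = "ellipse",
                collection = "ellipse")

dot_quote <- function(x) {
  paste0('"', gsub('"', '\\\\"', x), '"')
}

#' Emit a GraphViz DOT rendering of an account
#'
#' Deterministic DOT text (nodes and edges in sorted id order, so identical
#' input gives byte-identical output). Shapes follow the community
#' convention: agents are house-shaped, activities rectangles, entities and
#' collections ellipses (collections drawn with a double border).
#' wasAssociatedWith edges are dotted; automatic wasDerivedFrom edges are
#' dashed to mark machine-maintained lineage. With `show_roles`, edge role
#' text becomes the edge label; with `show_annotations`, each annotation is
#' attached to its element as a gray rectangle.
#'
#' @param account A `prov_account`.
#' @param options A [view_options()] list; its group selection is applied
#'   via [filter_by_groups()] first.
#' @return DOT source as a single character scalar.
#' @export
to_dot <- function(account, options = view_options()) {
  stopifnot(inherits(account, "prov_account"))
  account <- filter_by_groups(account, options)
  nd <- account$nodes[order(account$nodes$id), ]
  ed <- account$edges[order(account$edges$id), ]
  out <- c(
    sprintf("digraph %s {", dot_quote(account$id)),
    sprintf("  label=%s;", dot_quote(account$name)),
    "  rankdir=BT;",
    "  node [fontsize=10];"
  )
  for (i in seq_len(nrow(nd))) {
    extra <- if (nd$kind[[i]] == "collection") ", peripheries=2" else ""
    out <- c(out, sprintf("  %s [shape=%s, label=%s%s];",
                          dot_quote(nd$id[[i]]), DOT_SHAPES[[nd$kind[[i]]]],
                          dot_quote(nd$name[[i]]), extra))
  }
  for (i in seq_len(nrow(ed))) {
    attrs <- character()
    if (ed$kind[[i]] == "wasAssociatedWith") attrs <- c(attrs, "style=dotted")
    if (ed$kind[[i]] == "wasDerivedFrom" && ed$auto_derived[[i]]) {
      attrs <- c(attrs, "style=dashed")
    }
    if (isTRUE(options$show_roles) && !is.na(ed$role[[i]])) {
      attrs <- c(attrs, sprintf("label=%s", dot_quote(ed$role[[i]])))
    }
    attr_txt <- if (length(attrs)) sprintf(" [%s]", paste(attrs, collapse = ", ")) else ""
    out <- c(out, sprintf("  %s -> %s%s;", dot_quote(ed$source[[i]]),
                          dot_quote(ed$target[[i]]), attr_txt))
  }
  if (isTRUE(options$show_annotations) && nrow(account$annotations)) {
    an <- account$annotations
    an <- an[an$element %in% nd$id, ]
    an <- an[order(an$element, an$key), ]
    for (i in seq_len(nrow(an))) {
      aid <- sprintf("annot_%s_%d", an$element[[i]], i)
      out <- c(out, sprintf("  %s [shape=box, style=filled, fillcolor=gray90, fontsize=8, label=%s];",
                            dot_quote(aid),
                            dot_quote(paste0(an$key[[i]], ": ", an$text[[i]]))),
               sprintf("  %s -> %s [style=dotted, arrowhead=none];",
                       dot_quote(an$element[[i]]), dot_quote(aid)))
    }
  }
  paste(c(out, "}"), collapse = "\n")
}
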