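# fixed 12-colour palette; assignment order is lexical linkset tag order
ctl_palette <- c("#9467bd", "#1f77b4", "#2ca02c", "#d62728", "#ff7f0e",
                 "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
                 "#aec7e8", "#ffbb78")
ctl_gray <- "#c8c8c8"

type_shape_map <- c(compound = "diamond", disease = "octagon",
                    pathway = "rectangle")
default_shape <- "round-rectangle"

#' Assign the visual style to an extended network
#'
#' Deterministic, attribute-based styling: pre-existing nodes become gray
#' ellipses; added nodes are coloured by their contributing linkset (fixed
#' 12-colour palette, assigned in lexical order of `"name (version)"` tags,
#' cycling with a warning beyond 12) and shaped by entity type (`compound`
#' becomes diamond, `disease` octagon, `pathway` rectangle, anything else a
#' round-rectangle). Extension edges take their linkset's colour; original
#' edges stay gray and solid; edges hidden by [filter_overlap()] are dotted.
#'
#' Style is written as plain attribute columns (`style.fill`, `style.shape`
#' on nodes; `style.color`, `style.line` on edges) plus a legend table, so
#' it survives any network format and viewer.
#'
#' @param net A [network()].
#' @return The network with style columns and a `$style_legend` tibble
#'   (`category`, `kind`, `color`, `shape`); see [style_legend()].
#' @export
apply_style <- function(net) {
  pk <- provenance_keys()
  added <- if (pk[["added"]] %in% names(net$nodes)) {
    purrr::map_lgl(net$nodes[[pk[["added"]]]], isTRUE)
  } else rep(FALSE, nrow(net$nodes))
  node_tags <- if (pk[["linksets"]] %in% names(net$nodes)) {
    net$nodes[[pk[["linksets"]]]]
  } else rep(list(character()), nrow(net$nodes))
  edge_tags <- if (pk[["linkset"]] %in% names(net$edges)) {
    net$edges[[pk[["linkset"]]]]
  } else rep(list(character()), nrow(net$edges))

  tags <- sort(unique(c(unlist(node_tags), unlist(edge_tags))))
  if (length(tags) > length(ctl_palette)) {
    warn(sprintf("%d linksets exceed the %d-colour palette; colours cycle",
                 length(tags), length(ctl_palette)))
  }
  tag_color <- setNames(
    ctl_palette[((seq_along(tags) - 1) %% length(ctl_palette)) + 1], tags)
  first_tag_color <- function(tg) {
    if (length(tg) == 0) ctl_gray else unname(tag_color[sort(tg)[1]])
  }

  types <- if (pk[["type"]] %in% names(net$nodes)) {
    as.character(net$nodes[[pk[["type"]]]])
  } else rep(NA_character_, nrow(net$nodes))
  shapes <- ifelse(added,
                   purrr::map_chr(types, ~ {
                     s <- type_shape_map[.x]
                     if (is.na(s)) default_shape else unname(s)
                   }),
                   "ellipse")
  net$nodes[["style.fill"]] <- ifelse(added,
                                      purrr::map_chr(node_tags,
                                                     first_tag_color),
                                      ctl_gray)
  net$nodes[["style.shape"]] <- shapes

  is_ext <- if (pk[["overlap"]] %in% names(net$edges)) {
    !is.na(net$edges[[pk[["overlap"]]]])
  } else rep(FALSE, nrow(net$edges))
  hidden <- if (pk[["hidden"]] %in% names(net$edges)) {
    purrr::map_lgl(net$edges[[pk[["hidden"]]]], isTRUE)
  } else rep(FALSE, nrow(net$edges))
  net$edges[["style.color"]] <- ifelse(is_ext,
                                       purrr::map_chr(edge_tags,
                                                      first_tag_color),
                                       ctl_gray)
  net$edges[["style.line"]] <- ifelse(hidden, "dotted", "solid")

  used_types <- sort(unique(types[added & !is.na(types)]))
  legend <- bind_rows(
    tibble(category = "original", kind = "node", color = ctl_gray,
           shape = "ellipse"),
    tibble(category = tags, kind = "linkset",
           color = unname(tag_color[tags]), shape = NA_character_),
    tibble(category = used_types, kind = "node type", color = NA_character_,
           shape = purrr::map_chr(used_types, ~ {
             s <- type_shape_map[.x]
             if (is.na(s)) default_shape else unname(s)
           }))
  )
  net$style_legend <- legend
  net
}

#' @rdname apply_style
#' @export
style_legend <- function(net) net$style_legend

ggplot_shape_codes <- c(ellipse = 21, diamond = 23, octagon = 22,
                        rectangle = 22, `round-rectangle` = 24)

#' Plot a network
#'
#' ggplot2 rendering of an (optionally extended) network: applies the
#' deterministic layout and visual style first when missing, then draws
#' edges as segments and nodes as filled points; hidden edges are dotted.
#'
#' @param object A [network()].
#' @param label_nodes Draw node labels (default for <= 50 nodes).
#' @param seed,iterations Passed to [apply_layout()] when no coordinates
#'   are present.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ctl_network
#' @export
autoplot.ctl_network <- function(object, label_nodes = NULL, seed = 42,
                                 iterations = 100, ...) {
  net <- object
  if (!all(c("x", "y") %in% names(net$nodes))) {
    net <- apply_layout(net, seed = seed, iterations = iterations)
  }
  if (!"style.fill" %in% names(net$nodes)) net <- apply_style(net)
  label_nodes <- label_nodes %||% (nrow(net$nodes) <= 50)

  coords <- select(net$nodes, key, x, y)
  ed <- net$edges |>
    left_join(rename(coords, xs = x, ys = y), by = c(source = "key")) |>
    left_join(rename(coords, xt = x, yt = y), by = c(target = "key"))
  nd <- mutate(net$nodes,
               pch = unname(ggplot_shape_codes[.data$style.shape]))

  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$xs, y = .data$ys, xend = .data$xt,
                   yend = .data$yt, linetype = .data$style.line),
      color = ed$style.color, linewidth = 0.4, show.legend = FALSE) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y),
      fill = nd$style.fill, shape = nd$pch, size = 4, color = "grey30") +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void() +
    ggplot2::labs(title = net$name)
  if (label_nodes && "label" %in% names(nd)) {
    p <- p + ggplot2::geom_text(
      data = nd, ggplot2::aes(x = .data$x, y = .data$y,
                              label = .data$label),
      size = 2.6, vjust = -1.2)
  }
  p
}

#' @rdname autoplot.ctl_network
#' @param x A [network()].
#' @param y Ignored.
#' @export
plot.ctl_network <- function(x, y, ...) print(autoplot.ctl_network(x, ...))

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
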