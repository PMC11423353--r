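tree_layouts <- c("phylogram", "cladogram", "fan", "radial")

# children-of list indexed by node id
node_children <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    ch[[p]] <- c(ch[[p]], tree$edge[e, 2L])
  }
  ch
}

# tip order by depth-first traversal; internal position = mean of children
node_positions <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  ch <- node_children(tree)
  pos <- numeric(ntip + tree$Nnode)
  counter <- 0L
  walk <- function(v) {
    if (v <= ntip) {
      counter <<- counter + 1L
      pos[v] <<- counter
    } else {
      for (w in ch[[v]]) walk(w)
      pos[v] <<- mean(pos[ch[[v]]])
    }
  }
  walk(root)
  pos
}

# edge count from root per node
node_rank_depth <- function(tree) {
  ntip <- length(tree$tip.label)
  depth <- numeric(ntip + tree$Nnode)
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    depth[tree$edge[e, 2L]] <- depth[tree$edge[e, 1L]] + 1
  }
  depth
}

#' Compute a static layout for a phylogenetic tree
#'
#' Supported layouts:
#' \describe{
#'   \item{phylogram}{tips at consecutive integer y positions, x = root-to-
#'     node path length (branch lengths).}
#'   \item{cladogram}{same y, x = depth in edges from the root, branch
#'     lengths ignored.}
#'   \item{fan}{tips at equal angular spacing `2*pi/ntip`, radius =
#'     root-to-node path length; edges drawn as arc + radial segment.}
#'   \item{radial}{same angles, radius = depth rank; edges drawn as
#'     straight segments.}
#' }
#' Unrooted trees with branch lengths are midpoint-rooted for display only.
#'
#' @param tree An [ape::phylo] tree.
#' @param layout One of `"phylogram"`, `"cladogram"`, `"fan"`, `"radial"`.
#' @param use_lengths Use branch lengths where the layout calls for them;
#'   falls back to edge depth when the tree has none.
#' @return A `tree_layout`: list with `layout`, `tree` (as displayed),
#'   `nodes` (tibble: `node`, `label`, `is_tip`, `x`, `y`, `angle`,
#'   `radius`) and `edges` (tibble: `parent`, `child`).
#' @export
layout_tree <- function(tree, layout = "phylogram", use_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop_parameter("`tree` must be a phylo object")
  if (length(layout) != 1L || !layout %in% tree_layouts) {
    stop_parameter(sprintf(
      "unknown layout `%s`; supported layouts: %s",
      paste(layout, collapse = ","), paste(tree_layouts, collapse = ", ")
    ))
  }
  if (!ape::is.rooted(tree) && !is.null(tree$edge.length)) {
    tree <- phangorn::midpoint(tree)
  }
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  pos <- node_positions(tree)
  rankd <- node_rank_depth(tree)
  pathd <- if (!is.null(tree$edge.length) && use_lengths) {
    ape::node.depth.edgelength(tree)
  } else {
    rankd
  }
  is_tip <- seq_len(n_nodes) <= ntip
  label <- c(tree$tip.label, tree$node.label %||% rep(NA_character_, tree$Nnode))

  if (layout %in% c("phylogram", "cladogram")) {
    x <- if (layout == "phylogram") pathd else rankd
    nodes <- tibble(node = seq_len(n_nodes), label = label, is_tip = is_tip,
                    x = x, y = pos, angle = NA_real_, radius = NA_real_)
  } else {
    angle <- (pos - 1) * 2 * pi / ntip
    radius <- if (layout == "fan") pathd else rankd
    nodes <- tibble(node = seq_len(n_nodes), label = label, is_tip = is_tip,
                    x = radius * cos(angle), y = radius * sin(angle),
                    angle = angle, radius = radius)
  }
  structure(
    list(layout = layout, tree = tree, nodes = nodes,
         edges = tibble(parent = tree$edge[, 1L], child = tree$edge[, 2L])),
    class = "tree_layout"
  )
}

#' @export
print.tree_layout <- function(x, ...) {
  cat(sprintf("Tree layout (%s): %d tips, %d nodes, %d edges\n",
              x$layout, sum(x$nodes$is_tip), nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Plot a tree layout with ggplot2
#'
#' A quick diagnostic plot of a computed layout; for publication-quality
#' vector output use [render_svg()].
#'
#' @param object A `tree_layout`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tree_layout <- function(object, ...) {
  nodes <- object$nodes
  seg <- dplyr::left_join(object$edges,
                          dplyr::select(nodes, "node", xend = "x", yend = "y"),
                          by = c(child = "node")) %>%
    dplyr::left_join(dplyr::select(nodes, "node", "x", "y"), by = c(parent = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = dplyr::filter(nodes, .data$is_tip),
      ggplot2::aes(x = .data$x, y = .data$y)
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::ggtitle(object$layout)
}
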