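# Fixed 12-color categorical cycle; assigned to sorted category names so
# identical inputs always render identically.
.palette12 <- c(
  "#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd", "#8c564b",
  "#e377c2", "#7f7f7f", "#bcbd22", "#17becf", "#aec7e8", "#ffbb78"
)

#' Deterministic categorical palette
#' @param categories Character vector of category values.
#' @return Named vector of hex colors, one per sorted unique category.
#' @export
category_palette <- function(categories) {
  cats <- sort(unique(as.character(categories[!is.na(categories)])))
  stats::setNames(rep_len(.palette12, length(cats)), cats)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

fmt2 <- function(x) sprintf("%.2f", x)

#' Render a tree layout to SVG
#'
#' Produces a standalone SVG 1.1 document: one path per tree edge, one
#' circle marker per tip, tip labels, and — when coloring by a metadata
#' column — a legend with one entry per category. Output is deterministic:
#' identical inputs give byte-identical SVG.
#'
#' @param layout A `tree_layout` from [layout_tree()].
#' @param file Optional output path.
#' @param annotations Optional `annotated_tree` from [annotate_tips()]
#'   providing tip metadata.
#' @param color_by Optional metadata column used to color tip markers;
#'   requires `annotations`. Tips without metadata are drawn grey.
#' @param width,height Canvas size in pixels.
#' @return The SVG document as a single string (invisibly when written to
#'   `file`).
#' @export
render_svg <- function(layout, file = NULL, annotations = NULL, color_by = NULL,
                       width = 800, height = 600) {
  if (!inherits(layout, "tree_layout")) stop_parameter("`layout` must be a tree_layout")
  nodes <- layout$nodes
  tip_color <- rep("#333333", sum(nodes$is_tip))
  legend <- NULL
  if (!is.null(color_by)) {
    if (is.null(annotations)) stop_parameter("`color_by` requires `annotations`")
    if (!color_by %in% names(annotations$data)) {
      stop_parameter(sprintf("column `%s` not present in annotations", color_by))
    }
    ann <- annotations$data
    vals <- ann[[color_by]][match(nodes$label[nodes$is_tip], ann$label)]
    pal <- category_palette(vals)
    tip_color <- ifelse(is.na(vals), "#999999", pal[vals])
    legend <- pal
  }

  margin <- 40
  lab_space <- 150
  xr <- range(nodes$x); yr <- range(nodes$y)
  sx <- (width - 2 * margin - lab_space) / max(xr[2] - xr[1], 1e-9)
  sy <- (height - 2 * margin) / max(yr[2] - yr[1], 1e-9)
  if (layout$layout %in% c("fan", "radial")) sx <- sy <- min(sx, sy)
  px <- margin + (nodes$x - xr[1]) * sx
  py <- margin + (nodes$y - yr[1]) * sy

  edge_path <- function(p, ch) {
    if (layout$layout %in% c("phylogram", "cladogram")) {
      # elbow: vertical drop at the parent's x, then horizontal to the child
      sprintf('<path class="edge" d="M %s %s V %s H %s" fill="none" stroke="#444444" stroke-width="1"/>',
              fmt2(px[p]), fmt2(py[p]), fmt2(py[ch]), fmt2(px[ch]))
    } else if (layout$layout == "fan") {
      # arc at the parent radius to the child's angle, then a radial segment
      r_px <- nodes$radius[p] * sx
      ax <- margin + (nodes$radius[p] * cos(nodes$angle[ch]) - xr[1]) * sx
      ay <- margin + (nodes$radius[p] * sin(nodes$angle[ch]) - yr[1]) * sy
      dtheta <- nodes$angle[ch] - nodes$angle[p]
      sweep <- if (dtheta >= 0) 1 else 0
      large <- if (abs(dtheta) > pi) 1 else 0
      sprintf('<path class="edge" d="M %s %s A %s %s 0 %d %d %s %s L %s %s" fill="none" stroke="#444444" stroke-width="1"/>',
              fmt2(px[p]), fmt2(py[p]), fmt2(r_px), fmt2(r_px), large, sweep,
              fmt2(ax), fmt2(ay), fmt2(px[ch]), fmt2(py[ch]))
    } else {
      sprintf('<path class="edge" d="M %s %s L %s %s" fill="none" stroke="#444444" stroke-width="1"/>',
              fmt2(px[p]), fmt2(py[p]), fmt2(px[ch]), fmt2(py[ch]))
    }
  }

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#ffffff"/>', width, height),
    sprintf('<g class="edges">'),
    vapply(seq_len(nrow(layout$edges)),
           function(i) edge_path(layout$edges$parent[i], layout$edges$child[i]),
           character(1)),
    "</g>",
    '<g class="tips">'
  )
  tip_idx <- which(nodes$is_tip)
  for (j in seq_along(tip_idx)) {
    i <- tip_idx[j]
    out <- c(out,
      sprintf('<circle class="tip" cx="%s" cy="%s" r="3.5" fill="%s"/>',
              fmt2(px[i]), fmt2(py[i]), tip_color[j]),
      sprintf('<text class="tip-label" x="%s" y="%s" font-family="sans-serif" font-size="11">%s</text>',
              fmt2(px[i] + 6), fmt2(py[i] + 4), xml_escape(nodes$label[i]))
    )
  }
  out <- c(out, "</g>")
  if (!is.null(legend)) {
    out <- c(out, '<g class="legend">')
    for (j in seq_along(legend)) {
      y0 <- margin + (j - 1) * 18
      out <- c(out,
        sprintf('<g class="legend-entry"><rect x="%s" y="%s" width="12" height="12" fill="%s"/><text x="%s" y="%s" font-family="sans-serif" font-size="11">%s</text></g>',
                fmt2(width - 130), fmt2(y0), legend[j],
                fmt2(width - 112), fmt2(y0 + 10), xml_escape(names(legend)[j]))
      )
    }
    out <- c(out, "</g>")
  }
  out <- c(out, "</svg>")
  svg <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(svg, file)
    return(invisible(svg))
  }
  svg
}
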