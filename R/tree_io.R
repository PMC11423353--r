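#' Read a phylogenetic tree from Newick text or file
#'
#' Accepts a file path (`.nwk`, `.tre`, `.txt` — `.tre` files are treated
#' as the Newick dialect) or a literal Newick string. Quoted labels and
#' underscore conventions follow standard Newick rules.
#'
#' @param x Path to a Newick file, or a Newick string.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(x) {
  txt <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    paste(x, collapse = "")
  }
  txt <- trimws(txt)
  if (!nzchar(txt)) stop_parse("empty tree input")
  # balance check first, to report a position ape would swallow
  unquoted <- gsub("'[^']*'", "", txt)
  depth <- cumsum((strsplit(unquoted, "", fixed = TRUE)[[1L]] == "(") -
                  (strsplit(unquoted, "", fixed = TRUE)[[1L]] == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    pos <- if (any(depth < 0)) which(depth < 0)[1L] else length(depth)
    stop_parse(sprintf("unbalanced parentheses in Newick input near character %d", pos))
  }
  if (!grepl(";", txt, fixed = TRUE)) stop_parse("Newick input lacks terminating ';'")
  # ape's reader does not honor single-quoted labels: swap them for
  # placeholders before parsing and restore afterwards
  quoted <- regmatches(txt, gregexpr("'(?:[^']|'')*'", txt))[[1L]]
  restored <- character(0)
  if (length(quoted)) {
    restored <- gsub("''", "'", substr(quoted, 2L, nchar(quoted) - 1L))
    for (i in seq_along(quoted)) {
      txt <- sub(quoted[i], sprintf("QLBL%04d", i), txt, fixed = TRUE)
    }
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop_parse("malformed Newick input")
  unplace <- function(labs) {
    hit <- grepl("^QLBL\\d{4}$", labs)
    labs[hit] <- restored[as.integer(substr(labs[hit], 5L, 8L))]
    labs
  }
  if (length(restored)) {
    tree$tip.label <- unplace(tree$tip.label)
    if (!is.null(tree$node.label)) tree$node.label <- unplace(tree$node.label)
  }
  tree
}

# quote labels ape would mangle (spaces, parens, etc.) for serialization
nwk_safe_tree <- function(tree) {
  needs <- grepl("[][ ():;,']", tree$tip.label)
  if (!any(needs)) return(list(tree = tree, map = NULL))
  map <- stats::setNames(tree$tip.label[needs],
                         sprintf("QLBL%04d", which(needs)))
  tree$tip.label[needs] <- names(map)
  list(tree = tree, map = map)
}

requote_newick <- function(txt, map) {
  if (is.null(map)) return(txt)
  for (ph in names(map)) {
    quoted <- paste0("'", gsub("'", "''", map[[ph]]), "'")
    txt <- gsub(ph, quoted, txt, fixed = TRUE)
  }
  txt
}

#' Read a tree from Newick, `.tre`, or NEXUS files
#'
#' Dispatches on content: files starting with `#NEXUS` are read as NEXUS,
#' everything else as Newick.
#'
#' @param path Tree file path.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("tree file not found: %s", path), class = "phagetools_io_error")
  }
  first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
  if (length(first) && startsWith(first, "#NEXUS")) {
    tr <- ape::read.nexus(path)
    if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
    return(tr)
  }
  read_newick(path)
}

#' Serialize a tree as Newick
#'
#' Branch lengths are written with 12 significant digits so repeated
#' read/write round trips do not drift.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo") || is.null(tree$tip.label) || !length(tree$tip.label)) {
    stop_parameter("`tree` must be a non-empty phylo object")
  }
  safe <- nwk_safe_tree(tree)
  txt <- requote_newick(ape::write.tree(safe$tree, digits = 12), safe$map)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Serialize a tree as NEXUS
#'
#' Writes a `#NEXUS` file with a TAXA block and a TREES block carrying a
#' translate table.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional output file; when `NULL` the NEXUS text is returned
#'   as a character vector of lines.
#' @return The NEXUS lines (invisibly when written to `path`).
#' @export
write_nexus <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo") || is.null(tree$tip.label) || !length(tree$tip.label)) {
    stop_parameter("`tree` must be a non-empty phylo object")
  }
  if (is.null(path)) {
    return(utils::capture.output(ape::write.nexus(tree, file = "", translate = TRUE)))
  }
  ape::write.nexus(tree, file = path, translate = TRUE)
  invisible(readLines(path, warn = FALSE))
}
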