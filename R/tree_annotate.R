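#' Attach tip metadata to a tree
#'
#' Joins a metadata table onto the tree's tip labels by exact string match.
#' Tips without a metadata row are reported, never dropped; metadata rows
#' without a matching tip are ignored (no tips are invented).
#'
#' @param tree An [ape::phylo] tree.
#' @param meta Metadata tibble (e.g. from [read_metadata_csv()]).
#' @param key Name of the column in `meta` holding the tip labels; defaults
#'   to the first column.
#' @return An `annotated_tree`: a list with `tree`, `data` (one row per
#'   tip, label column `label` plus the metadata columns, `NA` where
#'   unmatched) and `unmatched` (character vector of tip labels with no
#'   metadata row).
#' @export
annotate_tips <- function(tree, meta, key = names(meta)[1L]) {
  if (!inherits(tree, "phylo")) stop_parameter("`tree` must be a phylo object")
  if (!key %in% names(meta)) {
    stop_parameter(sprintf("key column `%s` not found in metadata", key))
  }
  tips <- tibble(label = tree$tip.label)
  meta2 <- dplyr::rename(meta, label = dplyr::all_of(key))
  data <- dplyr::left_join(tips, meta2, by = "label")
  unmatched <- tips$label[!tips$label %in% meta2$label]
  structure(list(tree = tree, data = data, unmatched = unmatched),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  n <- length(x$tree$tip.label)
  cat(sprintf("Annotated tree: %d tips, %d with metadata (%d unmatched)\n",
              n, n - length(x$unmatched), length(x$unmatched)))
  cat("Columns:", paste(setdiff(names(x$data), "label"), collapse = ", "), "\n")
  if (length(x$unmatched)) {
    cat("Unmatched tips:", paste(x$unmatched, collapse = ", "), "\n")
  }
  invisible(x)
}
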