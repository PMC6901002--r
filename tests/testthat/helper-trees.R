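# Topology comparison helpers: canonical bipartitions (unrooted) and clades
# (rooted), independent of child ordering and of the root placement.

# Non-trivial bipartitions of the leaf set, each canonicalised to the side
# not containing the alphabetically first leaf.
tree_splits <- function(tree) {
  all_leaves <- sort(tree_leaves(tree))
  ref <- all_leaves[1L]
  splits <- character(0)
  walk <- function(node) {
    if (length(node$children) == 0L) return(invisible())
    lv <- sort(tree_leaves(node))
    if (length(lv) >= 2L && length(lv) <= length(all_leaves) - 2L) {
      side <- if (ref %in% lv) sort(setdiff(all_leaves, lv)) else lv
      splits <<- c(splits, paste(side, collapse = "|"))
    }
    for (ch in node$children) walk(ch$node)
  }
  walk(tree)
  sort(unique(splits))
}

same_unrooted_topology <- function(a, b) {
  setequal(tree_leaves(a), tree_leaves(b)) &&
    identical(tree_splits(a), tree_splits(b))
}

# Rooted clades (leaf sets below every internal node, root included).
tree_clades <- function(tree) {
  clades <- character(0)
  walk <- function(node) {
    if (length(node$children) == 0L) return(invisible())
    clades <<- c(clades, paste(sort(tree_leaves(node)), collapse = "|"))
    for (ch in node$children) walk(ch$node)
  }
  walk(tree)
  sort(clades)
}

same_rooted_topology <- function(a, b) {
  identical(tree_clades(a), tree_clades(b))
}

# Root-to-leaf path lengths.
leaf_depths <- function(tree) {
  depths <- numeric(0)
  walk <- function(node, acc) {
    if (length(node$children) == 0L) {
      depths[node$label] <<- acc
      return(invisible())
    }
    for (ch in node$children) walk(ch$node, acc + ch$length)
  }
  walk(tree, 0)
  depths
}
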