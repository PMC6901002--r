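# Tree construction from a pairwise distance matrix: rooted ultrametric
# UPGMA and classical (Saitou-Nei) neighbour-joining, plus Newick
# serialization and a minimal Newick parser used for round-trip checks.
#
# Trees are plain recursive lists: a leaf has a label and no children; an
# internal node has >= 2 children, each carried with its branch length.

leaf_node <- function(label) {
  structure(list(label = label, children = list(), height = 0),
            class = "pop_tree")
}

join_nodes <- function(nodes, lengths, height = NA_real_) {
  structure(list(label = NULL,
                 children = Map(function(n, l) list(node = n, length = l),
                                nodes, as.list(lengths)),
                 height = height),
            class = "pop_tree")
}

is_leaf <- function(node) length(node$children) == 0L

#' Leaf labels of a tree
#' @param tree A `pop_tree`.
#' @return Character vector of leaf labels in serialization order.
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  unlist(lapply(tree$children, function(ch) tree_leaves(ch$node)))
}

#' Leaf-to-leaf path-length matrix of a tree
#'
#' Sums branch lengths along the path between every pair of leaves. For an
#' ultrametric tree this equals twice the height of the pair's most recent
#' common ancestor; for a tree built from an additive matrix it reproduces
#' that matrix exactly.
#'
#' @param tree A `pop_tree` with branch lengths.
#' @return Symmetric numeric matrix with leaf labels as dimnames.
#' @export
tree_distances <- function(tree) {
  labs <- tree_leaves(tree)
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  walk <- function(node) {
    if (is_leaf(node)) {
      return(stats::setNames(0, node$label))
    }
    depths <- lapply(node$children, function(ch) walk(ch$node) + ch$length)
    for (i in seq_along(depths)[-1L]) {
      for (j in seq_len(i - 1L)) {
        cross <- outer(depths[[j]], depths[[i]], "+")
        d[names(depths[[j]]), names(depths[[i]])] <<- cross
        d[names(depths[[i]]), names(depths[[j]])] <<- t(cross)
      }
    }
    unlist(depths)
  }
  walk(tree)
  d
}

# Shared validation for tree builders. Returns a plain numeric matrix.
check_tree_matrix <- function(m, min_n = 4L) {
  d <- unclass(as.matrix(m))
  n <- nrow(d)
  if (n < min_n) {
    stop("tree construction requires genotype data from at least ", min_n,
         " genomes (got ", n, ")")
  }
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("S", seq_len(n)), paste0("S", seq_len(n)))
  }
  if (ncol(d) != n) stop("distance matrix must be square")
  if (any(is.na(d))) stop("distance matrix contains missing values")
  if (any(d < 0)) stop("distance matrix contains negative entries")
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d)))) {
    stop("distance matrix is not symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  d
}

# Smallest (i, j), i < j, among the positions where `crit` attains its
# minimum: ties break to the smallest i, then the smallest j.
argmin_pair <- function(crit) {
  diag(crit) <- Inf
  crit[lower.tri(crit)] <- Inf
  hits <- which(crit == min(crit), arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  c(hits[1L, 1L], hits[1L, 2L])
}

#' Build a rooted ultrametric tree by UPGMA
#'
#' Agglomerative average-linkage clustering: the closest pair of clusters is
#' joined at height d/2, and distances from the merged cluster to the rest
#' are size-weighted arithmetic means, so every original pair contributes
#' equally (unweighted pair-group method). The result is ultrametric: all
#' leaves lie at the same distance from the root.
#'
#' @param m Symmetric distance matrix (a `pop_dist` or plain matrix) with at
#'   least 4 samples.
#' @return A rooted binary `pop_tree`; node heights are distances to the
#'   leaves below.
#' @details When several pairs are equally close, the pair `(i, j)` with the
#'   smallest `i`, then smallest `j`, in the current cluster ordering is
#'   joined, which makes the output deterministic.
#' @export
upgma <- function(m) {
  d <- check_tree_matrix(m)
  nodes <- lapply(rownames(d), leaf_node)
  heights <- rep(0, length(nodes))
  sizes <- rep(1L, length(nodes))
  while (length(nodes) > 1L) {
    ij <- argmin_pair(d)
    i <- ij[1L]; j <- ij[2L]
    h <- d[i, j] / 2
    merged <- join_nodes(list(nodes[[i]], nodes[[j]]),
                         c(h - heights[i], h - heights[j]), height = h)
    keep <- setdiff(seq_along(nodes), c(i, j))
    newd <- (sizes[i] * d[i, keep] + sizes[j] * d[j, keep]) / (sizes[i] + sizes[j])
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd), c(newd, 0))
    nodes <- c(nodes[keep], list(merged))
    heights <- c(heights[keep], h)
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  nodes[[1L]]
}

#' Build an unrooted tree by classical neighbour-joining
#'
#' The Saitou-Nei algorithm: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, branch
#' lengths to the new node follow the classical formulas, and the run ends
#' with a three-way join, so the returned tree has a trifurcating root that
#' encodes an unrooted topology. Negative branch lengths, which classical NJ
#' can produce on non-additive matrices, are reported as computed.
#'
#' @inheritParams upgma
#' @return A `pop_tree` whose root has three children.
#' @details On an exactly additive matrix the generating topology and all
#'   branch lengths are recovered, so leaf-to-leaf path sums equal the input
#'   distances. Ties in Q break to the smallest pair indices.
#' @export
neighbor_joining <- function(m) {
  d <- check_tree_matrix(m)
  nodes <- lapply(rownames(d), leaf_node)
  while (length(nodes) > 3L) {
    n <- length(nodes)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    ij <- argmin_pair(q)
    i <- ij[1L]; j <- ij[2L]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    merged <- join_nodes(list(nodes[[i]], nodes[[j]]), c(li, lj))
    keep <- setdiff(seq_len(n), c(i, j))
    newd <- (d[i, keep] + d[j, keep] - d[i, j]) / 2
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd), c(newd, 0))
    nodes <- c(nodes[keep], list(merged))
  }
  la <- (d[1L, 2L] + d[1L, 3L] - d[2L, 3L]) / 2
  lb <- (d[1L, 2L] + d[2L, 3L] - d[1L, 3L]) / 2
  lc <- (d[1L, 3L] + d[2L, 3L] - d[1L, 2L]) / 2
  join_nodes(nodes, c(la, lb, lc))
}

# Quote a leaf label if it contains Newick-reserved characters.
newick_label <- function(label) {
  if (grepl("[][\\s():;,']", label, perl = TRUE)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else {
    label
  }
}

#' Serialize a tree to Newick text
#'
#' Children are written in construction order; branch lengths are fixed-point
#' with `precision` decimals; labels containing reserved characters are
#' single-quoted. The string ends with a semicolon.
#'
#' @param tree A `pop_tree`.
#' @param precision Decimal places for branch lengths.
#' @param file Optional path; when given, the tree is written there followed
#'   by a newline.
#' @return The Newick string, invisibly when `file` is given.
#' @export
to_newick <- function(tree, precision = 6L, file = NULL) {
  fmt <- paste0("%.", as.integer(precision), "f")
  ser <- function(node) {
    if (is_leaf(node)) return(newick_label(node$label))
    inner <- vapply(node$children, function(ch) {
      paste0(ser(ch$node), ":", sprintf(fmt, ch$length))
    }, character(1L))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  out <- paste0(ser(tree), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Parse a Newick string into a tree
#'
#' Minimal recursive-descent parser for the Newick dialect produced by
#' [to_newick()]: nested parentheses, optional branch lengths after `:`,
#' single-quoted labels with `''` escapes. Internal node labels are ignored.
#'
#' @param text A Newick string ending in `;`.
#' @return A `pop_tree`.
#' @export
parse_newick <- function(text) {
  s <- trimws(text)
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos > n) "" else substr(s, pos, pos)
  advance <- function() pos <<- pos + 1L

  read_label <- function() {
    if (peek() == "'") {
      advance()
      out <- character(0)
      repeat {
        ch <- peek()
        if (ch == "") stop("unterminated quoted label in Newick string")
        advance()
        if (ch == "'") {
          if (peek() == "'") { out <- c(out, "'"); advance() } else break
        } else out <- c(out, ch)
      }
      return(paste(out, collapse = ""))
    }
    start <- pos
    while (pos <= n && !(peek() %in% c(",", ")", "(", ":", ";"))) advance()
    substr(s, start, pos - 1L)
  }
  read_length <- function() {
    if (peek() != ":") return(NA_real_)
    advance()
    start <- pos
    while (pos <= n && grepl("[-+0-9.eE]", peek())) advance()
    as.numeric(substr(s, start, pos - 1L))
  }
  read_clade <- function() {
    if (peek() == "(") {
      advance()
      kids <- list()
      lens <- numeric(0)
      repeat {
        child <- read_clade()
        kids <- c(kids, list(child$node))
        lens <- c(lens, child$length)
        ch <- peek()
        if (ch == ",") { advance(); next }
        if (ch == ")") { advance(); break }
        stop("malformed Newick string near position ", pos)
      }
      read_label()  # internal label, discarded
      len <- read_length()
      node <- join_nodes(kids, lens)
      return(list(node = node, length = len))
    }
    lab <- read_label()
    len <- read_length()
    list(node = leaf_node(lab), length = len)
  }

  root <- read_clade()
  if (peek() != ";") stop("Newick string must end with ';'")
  root$node
}

#' @export
print.pop_tree <- function(x, ...) {
  cat(to_newick(x), "\n")
  invisible(x)
}
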