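#' Rooted labelled tree container
#'
#' `rtree` is the backbone structure shared by species trees, MUL trees and
#' gene trees: a flat node table with parent pointers and ordered child lists.
#' Node 0 does not exist; nodes are addressed by integer index. The root is the
#' unique node with `NA` parent. Leaves carry non-empty labels; internal labels
#' (e.g. bootstrap values read from Newick) are retained but ignored by every
#' computation. Branch lengths are discarded at parse time: all scoring in this
#' package is topology-only.
#'
#' @param parent integer vector, `NA` for the root.
#' @param children list of integer vectors (ordered children per node).
#' @param label character vector of node labels (`""` allowed for internals).
#' @return An object of class `rtree`.
#' @keywords internal
new_rtree <- function(parent, children, label) {
  t <- list(
    parent = as.integer(parent),
    children = children,
    label = as.character(label)
  )
  class(t) <- "rtree"
  t
}

rt_root <- function(t) which(is.na(t$parent))

rt_n_nodes <- function(t) length(t$label)

rt_is_leaf <- function(t) lengths(t$children) == 0L

#' Number of leaves of a tree
#' @param tree an `rtree`.
#' @return Integer count of leaves.
#' @export
n_leaves <- function(tree) sum(rt_is_leaf(tree))

#' Leaf labels of a tree
#' @param tree an `rtree`.
#' @return Character vector of leaf labels, in node-index order.
#' @export
leaf_labels <- function(tree) tree$label[rt_is_leaf(tree)]

rt_leaves <- function(t) which(rt_is_leaf(t))

# preorder: parent before children, children in stored order
rt_preorder <- function(t) {
  n <- rt_n_nodes(t)
  out <- integer(n)
  stack <- rt_root(t)
  k <- 0L
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    k <- k + 1L
    out[k] <- v
    kids <- t$children[[v]]
    if (length(kids)) stack <- c(kids, stack)
  }
  out[seq_len(k)]
}

rt_postorder <- function(t) rev_postorder_from_pre(rt_preorder(t), t)

# postorder with children in stored order: reverse of preorder with reversed kids
rev_postorder_from_pre <- function(pre, t) {
  n <- length(pre)
  out <- integer(n)
  stack <- rt_root(t)
  k <- 0L
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    k <- k + 1L
    out[k] <- v
    kids <- t$children[[v]]
    if (length(kids)) stack <- c(rev(kids), stack)
  }
  rev(out[seq_len(k)])
}

rt_depths <- function(t) {
  d <- integer(rt_n_nodes(t))
  for (v in rt_preorder(t)) {
    p <- t$parent[v]
    d[v] <- if (is.na(p)) 0L else d[p] + 1L
  }
  d
}

# leaf indices below each node (list), computed in postorder
rt_leafsets <- function(t) {
  sets <- vector("list", rt_n_nodes(t))
  leaf <- rt_is_leaf(t)
  for (v in rt_postorder(t)) {
    sets[[v]] <- if (leaf[v]) v else unlist(sets[t$children[[v]]], use.names = FALSE)
  }
  sets
}

rt_subtree_nodes <- function(t, node) {
  out <- node
  i <- 1L
  while (i <= length(out)) {
    out <- c(out, t$children[[out[i]]])
    i <- i + 1L
  }
  out
}

#' Test whether a tree is strictly bifurcating
#' @param tree an `rtree`.
#' @return `TRUE` if every internal node (root included) has exactly two children.
#' @export
is_binary_tree <- function(tree) {
  nk <- lengths(tree$children)
  all(nk[nk > 0L] == 2L)
}

rt_validate <- function(t) {
  n <- rt_n_nodes(t)
  mr_assert(n >= 1L, "mr_parse_error", "empty tree")
  mr_assert(sum(is.na(t$parent)) == 1L, "mr_parse_error", "tree must have exactly one root")
  for (v in seq_len(n)) {
    for (k in t$children[[v]]) {
      mr_assert(identical(t$parent[k], v), "mr_parse_error", "inconsistent parent/child links")
    }
  }
  mr_assert(length(rt_preorder(t)) == n, "mr_parse_error", "tree contains unreachable nodes or cycles")
  mr_assert(all(nzchar(t$label[rt_is_leaf(t)])), "mr_parse_error", "every leaf needs a non-empty label")
  invisible(t)
}

# --- emitter used by copy / prune / graft --------------------------------

rt_new_acc <- function() {
  acc <- new.env(parent = emptyenv())
  acc$parent <- integer(0)
  acc$children <- list()
  acc$label <- character(0)
  acc
}

acc_add <- function(acc, parent, label) {
  i <- length(acc$label) + 1L
  acc$parent[i] <- parent
  acc$children[[i]] <- integer(0)
  acc$label[i] <- label
  if (!is.na(parent)) acc$children[[parent]] <- c(acc$children[[parent]], i)
  i
}

acc_tree <- function(acc) new_rtree(acc$parent, acc$children, acc$label)

# deep-copy subtree(node) of t into acc under `parent`; relabel applied to leaves
rt_copy_into <- function(t, node, acc, parent, relabel = identity) {
  leaf <- length(t$children[[node]]) == 0L
  lab <- if (leaf) relabel(t$label[node]) else t$label[node]
  i <- acc_add(acc, parent, lab)
  for (k in t$children[[node]]) rt_copy_into(t, k, acc, i, relabel)
  i
}

# rebuild keeping the given leaf indices, suppressing unary internals.
# Returns NULL if nothing is kept.
rt_keep_leaves <- function(t, keep_idx) {
  keep <- logical(rt_n_nodes(t))
  keep[keep_idx] <- TRUE
  leaf <- rt_is_leaf(t)
  nkept <- integer(rt_n_nodes(t))
  for (v in rt_postorder(t)) {
    nkept[v] <- if (leaf[v]) as.integer(keep[v]) else sum(nkept[t$children[[v]]])
  }
  if (nkept[rt_root(t)] == 0L) return(NULL)
  acc <- rt_new_acc()
  emit <- function(v, parent) {
    if (leaf[v]) {
      acc_add(acc, parent, t$label[v])
      return(invisible(NULL))
    }
    kids <- t$children[[v]][nkept[t$children[[v]]] > 0L]
    if (length(kids) == 1L) {
      emit(kids, parent)  # suppress unary node
    } else {
      i <- acc_add(acc, parent, t$label[v])
      for (k in kids) emit(k, i)
    }
  }
  emit(rt_root(t), NA_integer_)
  acc_tree(acc)
}

rt_suppress_unary <- function(t) rt_keep_leaves(t, rt_leaves(t))

# canonical form: child order normalised by sorting serialized subtrees
rt_canonical <- function(t, node = rt_root(t)) {
  kids <- t$children[[node]]
  if (!length(kids)) return(t$label[node])
  sub <- vapply(kids, function(k) rt_canonical(t, k), character(1))
  paste0("(", paste(sort(sub), collapse = ","), ")")
}

#' Labelled-topology isomorphism
#'
#' Two rooted trees are considered isomorphic when they have identical labelled
#' shape up to reordering of children (internal labels ignored). Duplicate leaf
#' labels (as in MUL trees) are handled correctly via multiset comparison.
#'
#' @param a,b `rtree` objects.
#' @return Logical scalar.
#' @export
tree_isomorphic <- function(a, b) identical(rt_canonical(a), rt_canonical(b))

#' @export
print.rtree <- function(x, ...) {
  cat(sprintf(
    "rooted tree: %d leaves, %d nodes%s\n  %s\n",
    n_leaves(x), rt_n_nodes(x),
    if (is_binary_tree(x)) " (binary)" else "",
    write_newick(x)
  ))
  invisible(x)
}
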