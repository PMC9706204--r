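#' MUL-tree candidate construction and enumeration
#'
#' A candidate reconciliation reference is either the singly-labelled species
#' tree itself or a multi-labelled (MUL) tree defined by a pair of placements
#' (H1, H2): H1 is the putative polyploid clade, whose species appear twice in
#' the MUL tree, and H2 marks where the second subgenome's lineage attaches.
#' Copies retained at H1's original position are tagged `*`; the copy grafted
#' at H2 is tagged `+`. H2 = H1 encodes the autopolyploid form (the copy is
#' grafted as sister to H1); H2 = root attaches the copy as sister to the whole
#' tree. This tag orientation is fixed: the scenario formulas key on it.
#'
#' @name candidates
NULL

mul_tag_of <- function(label) {
  last <- substring(label, nchar(label), nchar(label))
  ifelse(last %in% c("*", "+"), last, "")
}

mul_species_of <- function(label) {
  tag <- mul_tag_of(label)
  ifelse(tag == "", label, substring(label, 1L, nchar(label) - 1L))
}

#' Build a MUL tree from a species tree and an (H1, H2) placement
#'
#' A deep copy of the subtree rooted at `h1`, with leaves tagged `+`, is
#' grafted onto the edge above `h2` (a new node subdivides that edge); the
#' original H1-subtree leaves are tagged `*`. `h2 = "self"` grafts the copy as
#' sister to H1; `h2 = "root"` creates a new root joining the copy to the whole
#' tree. The result is strictly bifurcating whenever the input is.
#'
#' @param species_tree a binary `rtree` with unique species labels on leaves.
#' @param h1 node index of the polyploid clade (must not be the root), or a
#'   character vector of species naming that clade's leaves exactly.
#' @param h2 `"self"`, `"root"`, a node index outside the subtree of `h1`, or a
#'   character vector of species naming such a clade.
#' @return An `rtree` in which every H1-subtree species appears twice (tags
#'   `*` and `+`) and every other species once.
#' @export
build_mul_tree <- function(species_tree, h1, h2 = "self") {
  t <- species_tree
  root <- rt_root(t)
  h1 <- resolve_node(t, h1)
  mr_assert(h1 != root, "mr_placement_error", "h1 must not be the root")
  h1_nodes <- rt_subtree_nodes(t, h1)
  h2_root <- identical(h2, "root")
  h2_self <- identical(h2, "self")
  if (!h2_root && !h2_self) {
    h2 <- resolve_node(t, h2)
    if (h2 == h1) h2_self <- TRUE
    else if (h2 == root) h2_root <- TRUE
    else mr_assert(!(h2 %in% h1_nodes), "mr_placement_error",
                   "h2 must not lie strictly inside the subtree of h1")
  }
  acc <- rt_new_acc()
  star <- function(lab) paste0(lab, "*")
  plus <- function(lab) paste0(lab, "+")
  # plain copy of subtree(v), h1-subtree leaves starred, no graft logic
  emit_plain <- function(v, parent) {
    kids <- t$children[[v]]
    lab <- if (!length(kids) && v %in% h1_nodes) star(t$label[v]) else t$label[v]
    i <- acc_add(acc, parent, lab)
    for (k in kids) emit_plain(k, i)
  }
  target <- if (h2_self) h1 else h2  # edge above `target` is subdivided
  emit <- function(v, parent) {
    if (!h2_root && v == target) {
      g <- acc_add(acc, parent, "")
      if (h2_self) {
        emit_plain(h1, g)                    # original copy first: (A*, A+)
        rt_copy_into(t, h1, acc, g, plus)
      } else {
        rt_copy_into(t, h1, acc, g, plus)    # grafted copy first: (A+, B)
        emit_plain(v, g)                     # h2 subtree (may itself contain h1)
      }
      return(invisible(NULL))
    }
    kids <- t$children[[v]]
    lab <- if (!length(kids) && v %in% h1_nodes) star(t$label[v]) else t$label[v]
    i <- acc_add(acc, parent, lab)
    for (k in kids) emit(k, i)
  }
  if (h2_root) {
    nr <- acc_add(acc, NA_integer_, "")
    emit_plain(root, nr)                     # whole tree, h1 leaves starred
    rt_copy_into(t, h1, acc, nr, plus)
  } else {
    emit(root, NA_integer_)
  }
  out <- acc_tree(acc)
  rt_validate(out)
  out
}

# resolve a node reference: integer index, or character vector of species
# labelling exactly one clade's leaf set
resolve_node <- function(t, ref) {
  if (is.numeric(ref)) {
    ref <- as.integer(ref)
    mr_assert(length(ref) == 1L && ref >= 1L && ref <= rt_n_nodes(t),
              "mr_placement_error", "node index out of range")
    return(ref)
  }
  mr_assert(is.character(ref), "mr_placement_error",
            "node reference must be an index or a character vector of species")
  sets <- rt_leafsets(t)
  want <- paste(sort(ref), collapse = ",")
  for (v in seq_len(rt_n_nodes(t))) {
    have <- paste(sort(t$label[sets[[v]]]), collapse = ",")
    if (have == want) return(v)
  }
  mr_error("mr_placement_error",
           sprintf("no clade with leaf set {%s}", paste(ref, collapse = ",")))
}

#' Enumerate the full candidate reference set for a species tree
#'
#' Produces the singly-labelled species tree plus one MUL candidate for every
#' placement pair: H1 ranges over all non-root nodes in preorder, and for each
#' H1, H2 ranges over H1 itself (the autopolyploid form) followed by every node
#' outside the subtree of H1 (root included), in preorder. Placements are not
#' deduplicated by topology: the candidate count is a count of placements. For
#' a binary tree on 8 leaves (15 nodes) this yields 181 candidates.
#'
#' @param species_tree a binary `rtree`, at least 2 leaves.
#' @return A list of candidate objects (class `mul_candidate`), the first being
#'   the singly-labelled candidate with id `"SINGLE"`.
#' @export
enumerate_candidates <- function(species_tree) {
  t <- species_tree
  mr_assert(is_binary_tree(t), "mr_placement_error", "species tree must be binary")
  mr_assert(n_leaves(t) >= 2L, "mr_placement_error", "species tree needs >= 2 leaves")
  mr_assert(!anyDuplicated(leaf_labels(t)), "mr_placement_error",
            "species tree has duplicate leaf labels")
  root <- rt_root(t)
  pre <- rt_preorder(t)
  sets <- rt_leafsets(t)
  out <- list(single_candidate(t))
  for (h1 in pre) {
    if (h1 == root) next
    inside <- rt_subtree_nodes(t, h1)
    h2s <- c(h1, pre[!(pre %in% inside)])
    for (h2 in h2s) {
      out[[length(out) + 1L]] <- mul_candidate(t, h1, h2, sets)
    }
  }
  out
}

single_candidate <- function(t) {
  structure(list(kind = "singly_labelled", id = "SINGLE",
                 h1 = NA_integer_, h2 = NA_integer_,
                 h1_species = character(0), ref_tree = t),
            class = "mul_candidate")
}

mul_candidate <- function(t, h1, h2, sets = rt_leafsets(t)) {
  h1_species <- sort(t$label[sets[[h1]]])
  h2_arg <- if (h2 == h1) "self" else if (h2 == rt_root(t)) "root" else h2
  mul <- build_mul_tree(t, h1, h2_arg)
  h2_desc <- if (h2 == h1) "SELF" else if (h2 == rt_root(t)) "ROOT" else
    paste(sort(t$label[sets[[h2]]]), collapse = ",")
  id <- sprintf("H1=%s|H2=%s", paste(h1_species, collapse = ","), h2_desc)
  structure(list(kind = "mul", id = id, h1 = h1, h2 = h2,
                 h1_species = h1_species, ref_tree = mul),
            class = "mul_candidate")
}

#' Stable identifier of a candidate placement
#' @param candidate a `mul_candidate`.
#' @return `"SINGLE"` for the singly-labelled candidate, otherwise
#'   `"H1=<sorted clade species>|H2=<sorted clade species|ROOT|SELF>"`.
#' @export
candidate_id <- function(candidate) candidate$id

#' Species duplicated in a candidate's reference tree
#' @param candidate a `mul_candidate`.
#' @return Character vector (empty for the singly-labelled candidate).
#' @export
duplicated_species <- function(candidate) candidate$h1_species

#' Tabulate candidates as a 3-column data frame
#' @param candidates list from [enumerate_candidates()].
#' @return Data frame with columns `candidate_id`, `kind`, `newick` (MUL tags
#'   appended to species tokens, e.g. `A*`, `A+`).
#' @export
candidates_table <- function(candidates) {
  data.frame(
    candidate_id = vapply(candidates, candidate_id, character(1)),
    kind = vapply(candidates, function(x) x$kind, character(1)),
    newick = vapply(candidates, function(x) write_newick(x$ref_tree), character(1))
  )
}

#' @export
print.mul_candidate <- function(x, ...) {
  cat(sprintf("candidate %s\n  %s\n", x$id, write_newick(x$ref_tree)))
  invisible(x)
}
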