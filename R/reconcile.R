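#' LCA reconciliation of gene trees against singly-labelled or MUL references
#'
#' Reconciliation embeds a rooted binary gene tree into a rooted reference
#' (species or MUL) tree by mapping every gene node to the least common
#' ancestor of its children's images. A gene node is a duplication when its
#' image equals the image of one of its children; losses are charged per child
#' edge as the number of reference edges skipped on the path from the child's
#' image up to the node's image, minus one free edge at speciation nodes. No
#' losses are charged above the gene-tree root. The reconciliation score is
#' duplications + losses; lower scores mean the reference explains the gene
#' tree better.
#'
#' Against a MUL reference, leaves of duplicated species can map to either the
#' `*` or the `+` copy. Maximal gene-tree subtrees whose leaves all belong to
#' duplicated species ("polyploid groups") structure this choice: groups are
#' split into single-copy-per-species assignment blocks (see
#' [assignment_blocks()]), each block is assigned to a copy en bloc, and all
#' `2^blocks` assignments are scored exhaustively; the minimum is reported.
#'
#' @name reconcile
NULL

# flatten an rtree for the C++ core; gene trees must be strictly binary
rt_flat <- function(t, binary = TRUE) {
  n <- rt_n_nodes(t)
  nk <- lengths(t$children)
  if (binary) {
    mr_assert(all(nk %in% c(0L, 2L)), "mr_parse_error",
              "tree must be strictly bifurcating for reconciliation")
  }
  child1 <- integer(n)
  child2 <- integer(n)
  for (v in which(nk > 0L)) {
    child1[v] <- t$children[[v]][1L]
    child2[v] <- t$children[[v]][2L]
  }
  post <- rt_postorder(t)
  list(
    parent = ifelse(is.na(t$parent), 0L, t$parent),
    depth = rt_depths(t),
    post_internal = post[nk[post] > 0L],
    child1 = child1,
    child2 = child2,
    is_leaf = nk == 0L
  )
}

# per-species ref-leaf lookup for a candidate: list(star=named int, plus=named int)
ref_leaf_lookup <- function(ref_tree) {
  lv <- rt_leaves(ref_tree)
  lab <- ref_tree$label[lv]
  tag <- mul_tag_of(lab)
  sp <- mul_species_of(lab)
  star <- setNames(lv[tag != "+"], sp[tag != "+"])  # "*" copies and untagged leaves
  plus <- star
  pl <- tag == "+"
  plus[sp[pl]] <- lv[pl]
  list(star = star, plus = plus)
}

#' Map gene-tree nodes to reference nodes by the LCA rule
#'
#' Pure-R reference implementation (root-path LCA); the scoring pipeline uses
#' the compiled equivalent internally.
#'
#' @param gene_tree rooted binary `rtree`.
#' @param ref_tree rooted reference `rtree` (species or MUL tree).
#' @param leaf_assignment named integer vector: gene leaf node index ->
#'   reference leaf node index. If named by gene leaf label instead, labels are
#'   resolved first.
#' @return Integer vector of length `n_nodes(gene_tree)`: reference node image
#'   of every gene node.
#' @export
lca_map <- function(gene_tree, ref_tree, leaf_assignment) {
  lv <- rt_leaves(gene_tree)
  img <- integer(rt_n_nodes(gene_tree))
  if (!is.null(names(leaf_assignment)) &&
      !all(names(leaf_assignment) %in% as.character(lv))) {
    idx <- match(names(leaf_assignment), gene_tree$label)
    mr_assert(!anyNA(idx), "mr_mapping_error", "assignment names not found among gene leaves")
    leaf_assignment <- setNames(as.integer(leaf_assignment), as.character(idx))
  }
  idx <- as.integer(names(leaf_assignment))
  mr_assert(setequal(idx, lv), "mr_mapping_error",
            "leaf_assignment must cover exactly the gene-tree leaves")
  img[idx] <- as.integer(leaf_assignment)
  ref_leaves <- rt_leaves(ref_tree)
  mr_assert(all(img[lv] %in% ref_leaves), "mr_mapping_error",
            "assigned images must be reference leaves")
  # root paths in the reference (naive, quadratic overall)
  path_up <- function(v) {
    p <- v
    while (!is.na(ref_tree$parent[p[length(p)]])) p <- c(p, ref_tree$parent[p[length(p)]])
    p
  }
  nk <- lengths(gene_tree$children)
  for (g in rt_postorder(gene_tree)) {
    if (nk[g] == 0L) next
    ims <- img[gene_tree$children[[g]]]
    common <- path_up(ims[1L])
    for (m in ims[-1L]) common <- common[common %in% path_up(m)]
    img[g] <- common[1L]
  }
  img
}

#' Count duplications and losses from a node map
#'
#' Pure-R counterpart of the compiled scoring kernel, used as the independent
#' oracle in the test-suite: path lengths are measured by explicit parent walks
#' rather than depth arithmetic.
#'
#' @param gene_tree rooted binary `rtree`.
#' @param ref_tree reference `rtree`.
#' @param map integer vector from [lca_map()].
#' @return Named integer vector `c(duplications=, losses=)`.
#' @export
count_dup_loss <- function(gene_tree, ref_tree, map) {
  edges_up <- function(from, to) {
    d <- 0L
    v <- from
    while (v != to) {
      v <- ref_tree$parent[v]
      mr_assert(!is.na(v), "mr_mapping_error",
                "map(child) is not a descendant of map(parent)")
      d <- d + 1L
    }
    d
  }
  dups <- 0L
  losses <- 0L
  nk <- lengths(gene_tree$children)
  for (g in which(nk > 0L)) {
    kids <- gene_tree$children[[g]]
    dup <- any(map[kids] == map[g])
    if (dup) dups <- dups + 1L
    for (k in kids) {
      d <- edges_up(map[k], map[g])
      losses <- losses + d - (if (dup) 0L else 1L)
    }
  }
  c(duplications = dups, losses = losses)
}

#' Find polyploid groups of a gene tree
#'
#' A polyploid group is a maximal gene-tree subtree whose leaves all belong to
#' species duplicated in the MUL reference. Groups are disjoint, cover every
#' duplicated-species leaf, and are returned in preorder of their root nodes.
#'
#' @param gene_tree rooted `rtree`.
#' @param duplicated_species character vector of duplicated species ids.
#' @param scheme a [label_scheme()].
#' @return List of groups, each `list(root=, leaves=)` (node indices).
#' @export
find_polyploid_groups <- function(gene_tree, duplicated_species,
                                  scheme = label_scheme()) {
  sp <- leaf_species_vec(gene_tree, scheme)
  nk <- lengths(gene_tree$children)
  all_dup <- logical(rt_n_nodes(gene_tree))
  for (v in rt_postorder(gene_tree)) {
    all_dup[v] <- if (nk[v] == 0L) !is.na(sp[v]) && sp[v] %in% duplicated_species
    else all(all_dup[gene_tree$children[[v]]])
  }
  roots <- integer(0)
  for (v in rt_preorder(gene_tree)) {
    p <- gene_tree$parent[v]
    if (all_dup[v] && (is.na(p) || !all_dup[p])) roots <- c(roots, v)
  }
  lapply(roots, function(r) {
    nodes <- rt_subtree_nodes(gene_tree, r)
    list(root = r, leaves = nodes[nk[nodes] == 0L])
  })
}

#' Split polyploid groups into single-copy assignment blocks
#'
#' A polyploid group containing several gene copies of one species cannot
#' descend from a single subgenome, so forcing it onto one MUL-tree copy
#' wholesale inflates the score - most visibly for families that retain both
#' homeolog clades, which form one connected all-duplicated subtree. The
#' assignment search therefore operates on blocks: each group is split, top
#' down, until every block holds at most one leaf per species. Blocks refine
#' groups and are refined by single leaves, so block-optimal scores lie
#' between the group-forced score and the per-leaf brute-force optimum.
#'
#' @param gene_tree rooted `rtree`.
#' @param groups output of [find_polyploid_groups()].
#' @param scheme a [label_scheme()].
#' @return List of blocks shaped like the input groups.
#' @export
assignment_blocks <- function(gene_tree, groups, scheme = label_scheme()) {
  sp <- leaf_species_vec(gene_tree, scheme)
  nk <- lengths(gene_tree$children)
  blocks <- list()
  rec <- function(v) {
    nodes <- rt_subtree_nodes(gene_tree, v)
    lv <- nodes[nk[nodes] == 0L]
    if (anyDuplicated(sp[lv])) {
      for (k in gene_tree$children[[v]]) rec(k)
    } else {
      blocks[[length(blocks) + 1L]] <<- list(root = v, leaves = lv)
    }
  }
  for (g in groups) rec(g$root)
  blocks
}

mk_result <- function(candidate_id, dups, losses, assignment = NULL,
                      n_groups = NA_integer_) {
  structure(list(
    candidate_id = candidate_id,
    duplications = as.integer(dups),
    losses = as.integer(losses),
    score = as.integer(dups) + as.integer(losses),
    assignment = assignment,
    n_groups = n_groups
  ), class = "mr_reconciliation")
}

#' @export
print.mr_reconciliation <- function(x, ...) {
  cat(sprintf("reconciliation vs %s: %d duplications + %d losses = score %d\n",
              x$candidate_id, x$duplications, x$losses, x$score))
  if (!is.null(x$assignment))
    cat("  group assignment:", paste(x$assignment, collapse = " "), "\n")
  invisible(x)
}

#' Reconcile a gene tree against the singly-labelled species tree
#'
#' @param gene_tree rooted binary `rtree` with `SPECIES@gene` leaves.
#' @param species_tree singly-labelled `rtree`.
#' @param scheme a [label_scheme()].
#' @return An `mr_reconciliation` with counts and score.
#' @export
reconcile_single <- function(gene_tree, species_tree, scheme = label_scheme()) {
  fl <- rt_flat(gene_tree)
  lookup <- ref_leaf_lookup(species_tree)$star
  sp <- leaf_species_vec(gene_tree, scheme)
  img <- integer(length(sp))
  lv <- which(fl$is_leaf)
  hit <- match(sp[lv], names(lookup))
  if (anyNA(hit)) mr_error("mr_mapping_error",
                           sprintf("species '%s' absent from reference",
                                   sp[lv][which(is.na(hit))[1L]]))
  img[lv] <- unname(lookup[hit])
  rf <- rt_flat(species_tree, binary = FALSE)
  dl <- cpp_dup_loss(rf$parent, rf$depth, fl$post_internal, fl$child1, fl$child2, img)
  mk_result("SINGLE", dl[1L], dl[2L])
}

#' Reconcile a gene tree against a MUL candidate
#'
#' Scores all assignments of the gene tree's assignment blocks (polyploid
#' groups split to one copy per species, see [assignment_blocks()]) to the
#' `*` / `+` subgenome copies and returns the minimum. The polyploid-group
#' cap is checked on the unsplit groups, matching the preliminary filter's
#' semantics. Ties prefer assignments with more `*` blocks, then the first in
#' enumeration order, so runs are reproducible.
#'
#' @param gene_tree rooted binary `rtree`.
#' @param candidate a `mul_candidate` of kind `"mul"` (see
#'   [enumerate_candidates()]); the singly-labelled candidate is dispatched to
#'   [reconcile_single()].
#' @param group_cap maximum number of polyploid groups (default 8, i.e. at
#'   most 256 assignments); exceeding it signals `mr_group_cap_error`, which
#'   callers treat as the preliminary filter does (exclude the tree).
#' @param scheme a [label_scheme()].
#' @return An `mr_reconciliation`; `assignment` holds one `"*"`/`"+"` tag per
#'   assignment block in preorder; `n_groups` counts the unsplit groups.
#' @export
reconcile_mul <- function(gene_tree, candidate, group_cap = 8L,
                          scheme = label_scheme()) {
  if (candidate$kind == "singly_labelled")
    return(reconcile_single(gene_tree, candidate$ref_tree, scheme))
  groups <- find_polyploid_groups(gene_tree, duplicated_species(candidate), scheme)
  if (length(groups) > group_cap)
    mr_error("mr_group_cap_error",
             sprintf("%d polyploid groups exceed the cap of %d",
                     length(groups), group_cap),
             n_groups = length(groups))
  blocks <- assignment_blocks(gene_tree, groups, scheme)
  search_assignments(gene_tree, candidate, blocks, scheme,
                     n_groups = length(groups))
}

# shared by reconcile_mul (per-block) and brute_force_mul (per-leaf)
search_assignments <- function(gene_tree, candidate, groups, scheme,
                               n_groups = length(groups)) {
  fl <- rt_flat(gene_tree)
  lookup <- ref_leaf_lookup(candidate$ref_tree)
  sp <- leaf_species_vec(gene_tree, scheme)
  lv <- which(fl$is_leaf)
  hit <- match(sp[lv], names(lookup$star))
  if (anyNA(hit)) mr_error("mr_mapping_error",
                           sprintf("species '%s' absent from reference",
                                   sp[lv][which(is.na(hit))[1L]]))
  img_star <- integer(length(sp))
  img_plus <- integer(length(sp))
  img_star[lv] <- unname(lookup$star[hit])
  img_plus[lv] <- unname(lookup$plus[hit])
  group_of <- integer(length(sp))
  for (j in seq_along(groups)) group_of[groups[[j]]$leaves] <- j
  rf <- rt_flat(candidate$ref_tree, binary = FALSE)
  res <- cpp_best_assignment(rf$parent, rf$depth, fl$post_internal,
                             fl$child1, fl$child2, img_star, img_plus,
                             group_of, length(groups))
  tags <- ifelse(bitwAnd(bitwShiftL(1L, seq_along(groups) - 1L), res[3L]) > 0L,
                 "+", "*")
  mk_result(candidate$id, res[1L], res[2L],
            assignment = tags, n_groups = n_groups)
}

#' Brute-force MUL reconciliation over per-leaf copy assignments
#'
#' Testing oracle: minimises the score over all `2^L` assignments of the
#' individual duplicated-species leaves (ignoring polyploid groups). Because
#' per-leaf assignments refine per-group ones, its optimum is a lower bound on
#' [reconcile_mul()]'s, with equality whenever every group is a singleton.
#'
#' @inheritParams reconcile_mul
#' @param max_leaves refuse instances with more duplicated-species leaves than
#'   this (default 12, i.e. 4096 assignments).
#' @return An `mr_reconciliation`; `assignment` holds one tag per
#'   duplicated-species leaf in preorder.
#' @export
brute_force_mul <- function(gene_tree, candidate, max_leaves = 12L,
                            scheme = label_scheme()) {
  if (candidate$kind == "singly_labelled")
    return(reconcile_single(gene_tree, candidate$ref_tree, scheme))
  sp <- leaf_species_vec(gene_tree, scheme)
  dup_leaves <- which(!is.na(sp) & sp %in% duplicated_species(candidate))
  if (length(dup_leaves) > max_leaves)
    mr_error("mr_oracle_error",
             sprintf("%d duplicated-species leaves exceed the oracle limit %d",
                     length(dup_leaves), max_leaves))
  singletons <- lapply(dup_leaves, function(l) list(root = l, leaves = l))
  search_assignments(gene_tree, candidate, singletons, scheme)
}

#' Score a set of gene trees against every candidate
#'
#' For each candidate, sums duplications and losses over all gene trees that
#' reconcile without error; trees whose polyploid-group count exceeds the cap
#' (or whose species are unmappable) are skipped and counted per candidate.
#' Candidates are ranked by ascending total score, ties resolved by
#' enumeration order.
#'
#' @param gene_trees list of rooted binary `rtree`.
#' @param candidates list from [enumerate_candidates()] (or any subset).
#' @param group_cap passed to [reconcile_mul()].
#' @param scheme a [label_scheme()].
#' @param details if `TRUE`, also return the per-tree score table.
#' @return A data frame with one row per candidate: `candidate_id`, `kind`,
#'   `n_trees`, `n_skipped`, `sum_dups`, `sum_losses`, `total_score`, `rank`;
#'   with `details = TRUE`, a list `list(table=, details=)` where `details` has
#'   one row per (tree, candidate) scored.
#' @export
score_all <- function(gene_trees, candidates, group_cap = 8L,
                      scheme = label_scheme(), details = FALSE) {
  n_cand <- length(candidates)
  sum_d <- integer(n_cand)
  sum_l <- integer(n_cand)
  n_ok <- integer(n_cand)
  n_skip <- integer(n_cand)
  det <- if (details) vector("list", n_cand * length(gene_trees))
  di <- 0L
  # pre-flatten gene trees once
  flats <- lapply(gene_trees, rt_flat)
  species <- lapply(gene_trees, leaf_species_vec, scheme = scheme)
  for (ci in seq_len(n_cand)) {
    cand <- candidates[[ci]]
    rf <- rt_flat(cand$ref_tree, binary = FALSE)
    lookup <- ref_leaf_lookup(cand$ref_tree)
    dup_sp <- duplicated_species(cand)
    for (ti in seq_along(gene_trees)) {
      fl <- flats[[ti]]
      sp <- species[[ti]]
      lv <- which(fl$is_leaf)
      hit <- match(sp[lv], names(lookup$star))
      if (anyNA(hit)) {
        n_skip[ci] <- n_skip[ci] + 1L
        next
      }
      res <- tryCatch({
        if (cand$kind == "singly_labelled") {
          img <- integer(length(sp))
          img[lv] <- unname(lookup$star[hit])
          dl <- cpp_dup_loss(rf$parent, rf$depth, fl$post_internal,
                             fl$child1, fl$child2, img)
          c(dl[1L], dl[2L])
        } else {
          groups <- find_polyploid_groups(gene_trees[[ti]], dup_sp, scheme)
          if (length(groups) > group_cap)
            mr_error("mr_group_cap_error", "group cap exceeded")
          blocks <- assignment_blocks(gene_trees[[ti]], groups, scheme)
          img_star <- integer(length(sp))
          img_plus <- integer(length(sp))
          img_star[lv] <- unname(lookup$star[hit])
          img_plus[lv] <- unname(lookup$plus[hit])
          group_of <- integer(length(sp))
          for (j in seq_along(blocks)) group_of[blocks[[j]]$leaves] <- j
          r <- cpp_best_assignment(rf$parent, rf$depth, fl$post_internal,
                                   fl$child1, fl$child2, img_star, img_plus,
                                   group_of, length(blocks))
          c(r[1L], r[2L])
        }
      }, mulrec_error = function(e) NULL)
      if (is.null(res)) {
        n_skip[ci] <- n_skip[ci] + 1L
      } else {
        n_ok[ci] <- n_ok[ci] + 1L
        sum_d[ci] <- sum_d[ci] + res[1L]
        sum_l[ci] <- sum_l[ci] + res[2L]
        if (details) {
          di <- di + 1L
          det[[di]] <- data.frame(tree_index = ti, candidate_id = cand$id,
                                  dups = res[1L], losses = res[2L],
                                  score = res[1L] + res[2L])
        }
      }
    }
  }
  total <- sum_d + sum_l
  ord <- order(total, seq_len(n_cand))
  rank <- integer(n_cand)
  rank[ord] <- seq_len(n_cand)
  tab <- data.frame(
    candidate_id = vapply(candidates, candidate_id, character(1)),
    kind = vapply(candidates, function(x) x$kind, character(1)),
    n_trees = n_ok, n_skipped = n_skip,
    sum_dups = sum_d, sum_losses = sum_l,
    total_score = total, rank = rank
  )
  if (details) list(table = tab, details = do.call(rbind, det[seq_len(di)]))
  else tab
}
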