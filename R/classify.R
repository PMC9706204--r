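#' Homeolog retention/loss scenario classification
#'
#' After an allopolyploid origin of the focal clade, each gene family retains
#' or loses homeologous copies per subgenome. Restricted to the two focal
#' lineages (cladeA, the "other"-lineage analog; cladeB, the "core"-lineage
#' analog), four patterns of the induced gene-tree root are distinguished:
#'
#' * `T1` - one side of the root holds only cladeA genes, the other pairs a
#'   cladeA with a cladeB clade: one subgenome copy was lost in cladeB.
#' * `T2` - mirror image: one side only cladeB, the other mixed; one copy was
#'   lost in cladeA.
#' * `T3` - both sides pair a cladeA with a cladeB clade: both subgenome
#'   copies retained in both lineages.
#' * `U`  - anything else (e.g. reciprocal loss), or a degenerate induced tree.
#'
#' Strict mode requires the mixed sides to be exactly a binary node with one
#' all-cladeA and one all-cladeB child, mirroring literal pattern matching on
#' Newick strings; lenient mode only requires them to contain both clades,
#' accommodating multi-copy gene trees. Classification keys on clade
#' composition, never on `*`/`+` tags. Outgroup and `other`-role leaves are
#' ignored (they only anchor rooting).
#'
#' @name classify
NULL

SCENARIOS <- c("T1", "T2", "T3", "U")

#' Induced subtree on a species subset
#'
#' @param gene_tree rooted `rtree`.
#' @param keep_species species ids to retain.
#' @param scheme a [label_scheme()].
#' @return The induced `rtree` (unary nodes suppressed, rooting inherited);
#'   signals `mr_classify_error` if fewer than 2 leaves remain.
#' @export
induced_subtree <- function(gene_tree, keep_species, scheme = label_scheme()) {
  sp <- leaf_species_vec(gene_tree, scheme)
  idx <- which(!is.na(sp) & sp %in% keep_species)
  if (length(idx) < 2L)
    mr_error("mr_classify_error",
             sprintf("induced subtree has %d leaves (need >= 2)", length(idx)))
  rt_keep_leaves(gene_tree, idx)
}

#' Clade composition with respect to the focal lineages
#'
#' @param tree an `rtree`.
#' @param node node index.
#' @param map a [species_map()].
#' @param scheme a [label_scheme()].
#' @return `"A"` if all descendant leaves are cladeA species, `"B"` if all
#'   cladeB, otherwise `"mixed"`.
#' @export
clade_composition <- function(tree, node, map, scheme = label_scheme()) {
  sp <- leaf_species_vec(tree, scheme)
  nodes <- rt_subtree_nodes(tree, node)
  lv <- nodes[rt_is_leaf(tree)[nodes]]
  roles <- map$role[match(sp[lv], map$species)]
  if (all(roles == "cladeA")) "A"
  else if (all(roles == "cladeB")) "B"
  else "mixed"
}

#' Classify one gene tree into a retention/loss scenario
#'
#' @param gene_tree rooted `rtree`.
#' @param map a [species_map()] with non-empty cladeA and cladeB.
#' @param mode `"strict"` or `"lenient"` (see [classify]).
#' @param scheme a [label_scheme()].
#' @return A list `list(label=, left=, right=, reason=)`; `label` is one of
#'   `"T1" "T2" "T3" "U"`, `left`/`right` the root-child compositions (`NA` for
#'   degenerate trees), `reason` non-`NA` only when degeneracy forced `U`.
#' @export
classify_scenario <- function(gene_tree, map, mode = c("strict", "lenient"),
                              scheme = label_scheme()) {
  mode <- match.arg(mode)
  mr_assert(length(map_role(map, "cladeA")) > 0L && length(map_role(map, "cladeB")) > 0L,
            "mr_config_error", "species map needs non-empty cladeA and cladeB")
  u <- function(reason) list(label = "U", left = NA_character_,
                             right = NA_character_, reason = reason)
  ind <- tryCatch(induced_subtree(gene_tree, focal_species(map), scheme),
                  mulrec_error = function(e) NULL)
  if (is.null(ind)) return(u("fewer than 2 focal leaves"))
  root <- rt_root(ind)
  kids <- ind$children[[root]]
  if (length(kids) != 2L) return(u("induced root not binary"))
  comp <- vapply(kids, function(k) clade_composition(ind, k, map, scheme), character(1))
  is_ab_node <- function(k) {
    gk <- ind$children[[k]]
    length(gk) == 2L &&
      setequal(vapply(gk, function(g) clade_composition(ind, g, map, scheme),
                      character(1)), c("A", "B"))
  }
  label <- if (mode == "strict") {
    if (any(comp == "A") && any(comp != "A") && is_ab_node(kids[comp != "A"][1L]) &&
        sum(comp == "A") == 1L) "T1"
    else if (any(comp == "B") && any(comp != "B") && is_ab_node(kids[comp != "B"][1L]) &&
             sum(comp == "B") == 1L) "T2"
    else if (is_ab_node(kids[1L]) && is_ab_node(kids[2L])) "T3"
    else "U"
  } else {
    if (sum(comp == "A") == 1L && sum(comp == "mixed") == 1L) "T1"
    else if (sum(comp == "B") == 1L && sum(comp == "mixed") == 1L) "T2"
    else if (all(comp == "mixed")) "T3"
    else "U"
  }
  list(label = label, left = comp[1L], right = comp[2L], reason = NA_character_)
}

#' Classify many gene trees
#'
#' @param gene_trees list of rooted `rtree`.
#' @inheritParams classify_scenario
#' @return Data frame with columns `tree_index`, `label`, `mode`, `left`,
#'   `right`, `reason`.
#' @export
classify_trees <- function(gene_trees, map, mode = c("strict", "lenient"),
                           scheme = label_scheme()) {
  mode <- match.arg(mode)
  rows <- lapply(seq_along(gene_trees), function(i) {
    r <- classify_scenario(gene_trees[[i]], map, mode, scheme)
    data.frame(tree_index = i, label = r$label, mode = mode,
               left = r$left, right = r$right, reason = r$reason)
  })
  do.call(rbind, rows)
}

#' Tally scenario labels
#'
#' @param labels character vector of labels in `T1 T2 T3 U`.
#' @return Data frame with one row per scenario: `label`, `n`, `fraction`
#'   (fractions of the total; zero total gives zero fractions).
#' @export
tally_scenarios <- function(labels) {
  mr_assert(all(labels %in% SCENARIOS), "mr_config_error",
            "labels must be T1, T2, T3 or U")
  n <- as.integer(table(factor(labels, levels = SCENARIOS)))
  total <- sum(n)
  data.frame(label = SCENARIOS, n = n,
             fraction = if (total > 0L) n / total else rep(0, 4L))
}

#' Fraction of gene trees with more losses than duplications
#'
#' @param results data frame with columns `dups` and `losses` (e.g. the
#'   `details` component of [score_all()] restricted to the best candidate).
#' @return The exact fraction; ties (`losses == duplications`) count as
#'   not-greater. Empty input is an error.
#' @export
loss_vs_retention <- function(results) {
  mr_assert(is.data.frame(results) && nrow(results) > 0L, "mr_config_error",
            "need at least one reconciliation result")
  mean(results$losses > results$dups)
}
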