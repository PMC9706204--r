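#' Leaf label scheme
#'
#' Gene-tree leaves encode both a species and a gene identifier in one token.
#' The default convention is `SPECIES@gene` (delimiter `@`, species first),
#' matching the labelling produced by the simulator. Labels without the
#' delimiter (species-tree leaves) are treated as bare species identifiers.
#'
#' @param delimiter single character separating the two tokens.
#' @param species_position `"prefix"` if the species token comes first,
#'   `"suffix"` if it comes last.
#' @return An object of class `label_scheme`.
#' @export
label_scheme <- function(delimiter = "@", species_position = c("prefix", "suffix")) {
  species_position <- match.arg(species_position)
  mr_assert(is.character(delimiter) && nchar(delimiter) == 1L,
            "mr_config_error", "delimiter must be a single character")
  structure(list(delimiter = delimiter, species_position = species_position),
            class = "label_scheme")
}

default_scheme <- function() label_scheme()

#' Split a leaf label into species and gene tokens
#'
#' @param label character vector of leaf labels.
#' @param scheme a [label_scheme()].
#' @return Data frame with columns `species` and `gene`. Labels lacking the
#'   delimiter yield `species = label`, `gene = label`.
#' @export
split_leaf_label <- function(label, scheme = label_scheme()) {
  parts <- strsplit(label, scheme$delimiter, fixed = TRUE)
  sp <- character(length(label))
  gn <- character(length(label))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L) {
      sp[i] <- label[i]
      gn[i] <- label[i]
    } else if (scheme$species_position == "prefix") {
      sp[i] <- p[1L]
      gn[i] <- paste(p[-1L], collapse = scheme$delimiter)
    } else {
      sp[i] <- p[length(p)]
      gn[i] <- paste(p[-length(p)], collapse = scheme$delimiter)
    }
    mr_assert(nzchar(sp[i]) && nzchar(gn[i]), "mr_parse_error",
              sprintf("leaf label '%s' does not split into species and gene", label[i]))
  }
  data.frame(species = sp, gene = gn)
}

# species of every node (NA for internals)
leaf_species_vec <- function(tree, scheme = label_scheme()) {
  out <- rep(NA_character_, rt_n_nodes(tree))
  lv <- rt_leaves(tree)
  if (length(lv)) out[lv] <- split_leaf_label(tree$label[lv], scheme)$species
  out
}

#' Species identifiers of a tree's leaves
#' @param tree an `rtree`.
#' @param scheme a [label_scheme()].
#' @return Character vector of species ids, one per leaf.
#' @export
leaf_species <- function(tree, scheme = label_scheme()) {
  split_leaf_label(leaf_labels(tree), scheme)$species
}

# --- species map ----------------------------------------------------------

ROLES <- c("outgroup", "cladeA", "cladeB", "other")

#' Species-to-role map
#'
#' Assigns each species one of four analysis roles: `outgroup` (anchors gene
#' tree rooting), `cladeA` (the "other"-lineage analog of the focal clade),
#' `cladeB` (the "core"-lineage analog), or `other`.
#'
#' @param species character vector of species ids.
#' @param role character vector of roles, one of
#'   `"outgroup"`, `"cladeA"`, `"cladeB"`, `"other"`.
#' @return Data frame of class `species_map` with columns `species`, `role`.
#' @export
species_map <- function(species, role) {
  mr_assert(length(species) == length(role), "mr_config_error",
            "species and role must have equal length")
  mr_assert(all(role %in% ROLES), "mr_config_error",
            sprintf("roles must be one of: %s", paste(ROLES, collapse = ", ")))
  mr_assert(!anyDuplicated(species), "mr_config_error", "duplicated species in map")
  out <- data.frame(species = as.character(species), role = as.character(role))
  class(out) <- c("species_map", "data.frame")
  out
}

#' Read / write a species map as 2-column TSV
#' @param path file path; format is `species<TAB>role` with no header.
#' @return [read_species_map()] returns a `species_map`.
#' @export
read_species_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, col.names = c("species", "role"),
                          colClasses = "character", quote = "")
  species_map(df$species, df$role)
}

#' @rdname read_species_map
#' @param map a `species_map`.
#' @export
write_species_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

map_role <- function(map, role) map$species[map$role == role]

#' Focal-clade and outgroup species of a map
#' @param map a `species_map`.
#' @return `focal_species()`: union of cladeA and cladeB species;
#'   `outgroup_species()`: the outgroup species id.
#' @export
focal_species <- function(map) c(map_role(map, "cladeA"), map_role(map, "cladeB"))

#' @rdname focal_species
#' @export
outgroup_species <- function(map) {
  og <- map_role(map, "outgroup")
  mr_assert(length(og) == 1L, "mr_config_error",
            "exactly one outgroup species is required")
  og
}

# --- Newick I/O -----------------------------------------------------------

#' Parse a Newick string into a rooted tree
#'
#' Accepts standard Newick with optional branch lengths and internal labels
#' (both retained in the parse but ignored by all downstream computations).
#' Unary (singleton) internal nodes are suppressed. Trees that should be
#' strictly bifurcating are checked by the caller via [is_binary_tree()] or the
#' `multifurcations` argument.
#'
#' @param text a Newick string terminated by `;`.
#' @param multifurcations if `FALSE`, reject trees with any node of more than
#'   two children (species trees and, by default, gene trees must be binary).
#' @return An `rtree`.
#' @export
parse_newick <- function(text, multifurcations = TRUE) {
  mr_assert(is.character(text) && length(text) == 1L, "mr_parse_error",
            "text must be a single string")
  text <- trimws(text)
  mr_assert(nzchar(text), "mr_parse_error", "empty Newick string")
  mr_assert(endsWith(text, ";"), "mr_parse_error", "Newick string must end in ';'")
  # parenthesis scan with byte offsets, before handing to the parser
  depth <- 0L
  bytes <- charToRaw(text)
  for (i in seq_along(bytes)) {
    ch <- rawToChar(bytes[i])
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) mr_error("mr_parse_error",
                               sprintf("unbalanced ')' at byte %d", i))
    }
  }
  if (depth > 0L) mr_error("mr_parse_error",
                           sprintf("unclosed '(' (%d open at byte %d)", depth, length(bytes)))
  body <- sub(";$", "", text)
  if (!grepl("(", text, fixed = TRUE)) {
    # single-leaf tree; strip any branch length
    lab <- sub(":[^:]*$", "", body)
    mr_assert(nzchar(lab), "mr_parse_error", "empty leaf label")
    return(new_rtree(NA_integer_, list(integer(0)), lab))
  }
  ph <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  mr_assert(!is.null(ph) && inherits(ph, "phylo") && !anyNA(ph$tip.label),
            "mr_parse_error", sprintf("malformed Newick: %s", text))
  t <- rt_from_phylo(ph)
  t <- rt_suppress_unary(t)
  rt_validate(t)
  if (!multifurcations) {
    mr_assert(is_binary_tree(t), "mr_parse_error",
              "tree contains multifurcations but multifurcations are disallowed")
  }
  t
}

rt_from_phylo <- function(ph) {
  nt <- length(ph$tip.label)
  nn <- ph$Nnode
  total <- nt + nn
  parent <- rep(NA_integer_, total)
  children <- rep(list(integer(0)), total)
  for (i in seq_len(nrow(ph$edge))) {
    p <- ph$edge[i, 1L]
    k <- ph$edge[i, 2L]
    parent[k] <- p
    children[[p]] <- c(children[[p]], k)
  }
  lab <- c(ph$tip.label,
           if (!is.null(ph$node.label)) ph$node.label else rep("", nn))
  lab[is.na(lab)] <- ""
  new_rtree(parent, children, lab)
}

rt_to_phylo <- function(t) {
  ape::read.tree(text = write_newick(t))
}

#' Serialize a rooted tree to Newick
#'
#' Leaf labels are written verbatim; internal labels and branch lengths are
#' not emitted (the package is topology-only).
#'
#' @param tree an `rtree`.
#' @return A Newick string ending in `;`.
#' @export
write_newick <- function(tree) {
  rec <- function(v) {
    kids <- tree$children[[v]]
    if (!length(kids)) return(tree$label[v])
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")")
  }
  paste0(rec(rt_root(tree)), ";")
}

#' Read / write gene-tree files (one Newick per line)
#'
#' @param path file path.
#' @param multifurcations passed to [parse_newick()] per tree.
#' @return [read_gene_trees()] returns a list of `rtree`; parse failures abort
#'   with the offending line number.
#' @export
read_gene_trees <- function(path, multifurcations = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    out[[i]] <- tryCatch(parse_newick(lines[i], multifurcations = multifurcations),
                         mulrec_error = function(e) {
                           mr_error("mr_parse_error",
                                    sprintf("line %d: %s", i, conditionMessage(e)))
                         })
  }
  out
}

#' @rdname read_gene_trees
#' @param trees list of `rtree`.
#' @export
write_gene_trees <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(path)
}

#' Read a single species tree from file
#' @param path file containing one Newick tree.
#' @return An `rtree` (must be strictly bifurcating).
#' @export
read_species_tree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  mr_assert(length(lines) == 1L, "mr_parse_error",
            "species tree file must contain exactly one tree")
  parse_newick(lines, multifurcations = FALSE)
}

# --- rooting and pruning --------------------------------------------------

#' Re-root a tree so the outgroup forms one side of the root
#'
#' The outgroup species' leaves must form one block of an unrooted bipartition
#' of the tree (monophyly in the unrooted sense); otherwise a rooting error of
#' class `mr_rooting_error` is signalled, and callers typically log and skip
#' the gene tree. The non-outgroup topology is preserved. Idempotent.
#'
#' @param tree an `rtree`.
#' @param outgroup a species id.
#' @param scheme a [label_scheme()] used to resolve leaf species.
#' @return An `rtree` whose root has the outgroup leaves as one child clade.
#' @export
root_by_outgroup <- function(tree, outgroup, scheme = label_scheme()) {
  sp <- leaf_species_vec(tree, scheme)
  og <- which(!is.na(sp) & sp %in% outgroup)
  mr_assert(length(og) > 0L, "mr_rooting_error",
            sprintf("no leaf of outgroup species '%s' in tree", outgroup[1L]))
  leaves <- rt_leaves(tree)
  mr_assert(length(og) < length(leaves), "mr_rooting_error",
            "outgroup covers every leaf; nothing to root against")
  sets <- rt_leafsets(tree)
  root <- rt_root(tree)
  og_key <- paste(sort(og), collapse = ",")
  rest_key <- paste(sort(setdiff(leaves, og)), collapse = ",")
  # already rooted correctly?
  for (k in tree$children[[root]]) {
    if (paste(sort(sets[[k]]), collapse = ",") == og_key) return(tree)
  }
  # find the edge realising the og | rest bipartition
  v <- NA_integer_
  for (u in seq_len(rt_n_nodes(tree))) {
    if (u == root) next
    key <- paste(sort(sets[[u]]), collapse = ",")
    if (key == og_key || key == rest_key) { v <- u; break }
  }
  if (is.na(v)) mr_error("mr_rooting_error",
                         sprintf("outgroup '%s' is not monophyletic in the unrooted tree",
                                 outgroup[1L]))
  rt_reroot_on_edge(tree, v)
}

# re-root on the edge above v: new root has children (v-side, rest-of-tree)
rt_reroot_on_edge <- function(t, v) {
  parent <- t$parent
  children <- t$children
  label <- t$label
  root <- rt_root(t)
  # path from v's parent up to the old root
  path <- integer(0)
  u <- parent[v]
  while (!is.na(u)) {
    path <- c(path, u)
    u <- parent[u]
  }
  # detach v
  children[[path[1L]]] <- setdiff(children[[path[1L]]], v)
  # reverse edges along the path
  if (length(path) > 1L) {
    for (i in seq_len(length(path) - 1L)) {
      lo <- path[i]; hi <- path[i + 1L]
      children[[hi]] <- setdiff(children[[hi]], lo)
      children[[lo]] <- c(children[[lo]], hi)
      parent[hi] <- lo
    }
  }
  nr <- length(label) + 1L
  parent[nr] <- NA_integer_
  label[nr] <- ""
  children[[nr]] <- c(v, path[1L])
  parent[v] <- nr
  parent[path[1L]] <- nr
  out <- new_rtree(parent, children, label)
  rt_suppress_unary(out)  # old root may now be unary
}

#' Prune a tree to a set of species
#'
#' Retains exactly the leaves whose species id is in `keep`, suppressing unary
#' nodes. A pruned single leaf is returned as a 1-leaf tree.
#'
#' @param tree an `rtree`.
#' @param keep character vector of species ids to retain.
#' @param scheme a [label_scheme()].
#' @return An `rtree`.
#' @export
prune_to <- function(tree, keep, scheme = label_scheme()) {
  sp <- leaf_species_vec(tree, scheme)
  idx <- which(!is.na(sp) & sp %in% keep)
  if (!length(idx)) mr_error("mr_prune_error",
                             "no leaf of the tree belongs to the species kept")
  rt_keep_leaves(tree, idx)
}
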