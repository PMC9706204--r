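#' Gene-tree filters
#'
#' Two filters precede reconciliation. The preliminary filter removes gene
#' trees with more than `group_cap` polyploid groups (default 8), keeping the
#' assignment search tractable. The deep filter additionally bounds the gene
#' copy number per species; the default reading is an inclusive 1-4 copies
#' with every species required to be present. Because the source protocol
#' states the bound ambiguously ("more than one and less than four" in one
#' place, "between one and five" in another), both bounds are configurable so
#' either literal reading can be selected.
#'
#' @name genefilter
NULL

#' Filter configuration
#'
#' @param group_cap maximum polyploid groups per gene tree (preliminary filter).
#' @param min_copies,max_copies inclusive per-species copy-number bounds
#'   (deep filter).
#' @param require_all_species must every species of the universe be present?
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(group_cap = 8L, min_copies = 1L, max_copies = 4L,
                          require_all_species = TRUE) {
  mr_assert(group_cap >= 1L, "mr_config_error", "group_cap must be >= 1")
  mr_assert(min_copies >= 1L && min_copies <= max_copies, "mr_config_error",
            "need 1 <= min_copies <= max_copies")
  structure(list(group_cap = as.integer(group_cap),
                 min_copies = as.integer(min_copies),
                 max_copies = as.integer(max_copies),
                 require_all_species = isTRUE(require_all_species)),
            class = "filter_config")
}

filter_result <- function(kept_index, rejected, trees) {
  list(kept = trees[kept_index],
       kept_index = kept_index,
       rejected = rejected)
}

empty_rejections <- function() {
  data.frame(tree_index = integer(0), filter = character(0),
             reason = character(0), detail = character(0))
}

#' Preliminary filter: cap on polyploid-group count
#'
#' @param gene_trees list of rooted `rtree`.
#' @param duplicated_species species duplicated in the MUL references (for the
#'   standard analysis, the full focal clade).
#' @param cfg a [filter_config()].
#' @param scheme a [label_scheme()].
#' @return `list(kept=, kept_index=, rejected=)`; `rejected` is a data frame
#'   with columns `tree_index`, `filter`, `reason`, `detail` (the group count).
#' @export
preliminary_filter <- function(gene_trees, duplicated_species,
                               cfg = filter_config(), scheme = label_scheme()) {
  counts <- vapply(gene_trees, function(t) {
    length(find_polyploid_groups(t, duplicated_species, scheme))
  }, integer(1))
  bad <- which(counts > cfg$group_cap)
  rejected <- if (length(bad)) {
    data.frame(tree_index = bad, filter = "preliminary",
               reason = "group_cap_exceeded",
               detail = sprintf("groups=%d", counts[bad]))
  } else empty_rejections()
  filter_result(setdiff(seq_along(gene_trees), bad), rejected, gene_trees)
}

#' Deep filter: per-species gene copy-number bounds
#'
#' @param gene_trees list of rooted `rtree`.
#' @param species_universe the species every tree is checked against.
#' @param cfg a [filter_config()].
#' @param scheme a [label_scheme()].
#' @return Same shape as [preliminary_filter()]; rejection `detail` names the
#'   first offending species and its copy count.
#' @export
deep_filter <- function(gene_trees, species_universe, cfg = filter_config(),
                        scheme = label_scheme()) {
  rej <- list()
  bad <- integer(0)
  for (i in seq_along(gene_trees)) {
    sp <- leaf_species(gene_trees[[i]], scheme)
    counts <- table(factor(sp[sp %in% species_universe], levels = species_universe))
    missing <- names(counts)[counts == 0L]
    off <- names(counts)[counts > 0L &
                           (counts < cfg$min_copies | counts > cfg$max_copies)]
    if (cfg$require_all_species && length(missing)) {
      bad <- c(bad, i)
      rej[[length(rej) + 1L]] <- data.frame(
        tree_index = i, filter = "deep", reason = "species_missing",
        detail = paste(missing, collapse = ","))
    } else if (length(off)) {
      bad <- c(bad, i)
      rej[[length(rej) + 1L]] <- data.frame(
        tree_index = i, filter = "deep", reason = "copy_number",
        detail = paste(sprintf("%s=%d", off, as.integer(counts[off])),
                       collapse = ","))
    }
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else empty_rejections()
  filter_result(setdiff(seq_along(gene_trees), bad), rejected, gene_trees)
}

#' Summarise a filter run
#'
#' @param result the list returned by [preliminary_filter()] or [deep_filter()].
#' @return Data frame with one row per (filter, reason) plus a `kept` row,
#'   columns `filter`, `reason`, `n`.
#' @export
filter_report <- function(result) {
  kept_row <- data.frame(filter = "any", reason = "kept",
                         n = length(result$kept_index))
  if (nrow(result$rejected) == 0L) return(kept_row)
  agg <- stats::aggregate(tree_index ~ filter + reason, data = result$rejected,
                          FUN = length)
  names(agg)[names(agg) == "tree_index"] <- "n"
  out <- rbind(kept_row, agg[order(agg$filter, agg$reason), ])
  rownames(out) <- NULL
  out
}
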