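#' End-to-end analysis orchestration
#'
#' [run_all()] chains the full analysis - simulate (or load) gene trees,
#' filter, enumerate candidates, score, classify, enrich - writing every
#' intermediate table as TSV so stages are independently inspectable. Two
#' datasets are scored, mirroring the two filtering modes: the preliminarily
#' filtered trees and the deep-filtered subset; a combined table sums the two.
#' Reruns with identical configuration produce byte-identical outputs.
#'
#' @name pipeline
NULL

#' Run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param sim a [sim_config()] to generate the input dataset, or `NULL` to
#'   read from files.
#' @param gene_trees,species_tree,map paths (Newick, Newick, TSV); used only
#'   when `sim` is `NULL`.
#' @param categories optional annotation table: data frame or path to a
#'   2-column TSV `family<TAB>category`; when absent and `sim` is given,
#'   annotations are simulated with [simulate_categories()].
#' @param filter a [filter_config()].
#' @param mode classification mode, `"strict"` or `"lenient"`.
#' @param candidate_ids optional restriction: character vector of candidate
#'   ids to score (e.g. `"SINGLE"`).
#' @param seed integer seed for every stochastic step.
#' @param scheme a [label_scheme()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, sim = sim_config(), gene_trees = NULL,
                       species_tree = NULL, map = NULL, categories = NULL,
                       filter = filter_config(), mode = "strict",
                       candidate_ids = NULL, seed = 1L,
                       scheme = label_scheme()) {
  if (is.null(sim)) {
    for (p in c(gene_trees, species_tree, map)) {
      mr_assert(file.exists(p), "mr_config_error",
                sprintf("input path does not exist: %s", p))
    }
  }
  structure(list(out_dir = out_dir, sim = sim, gene_trees = gene_trees,
                 species_tree = species_tree, map = map,
                 categories = categories, filter = filter, mode = mode,
                 candidate_ids = candidate_ids, seed = as.integer(seed),
                 scheme = scheme),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis
#'
#' @param cfg a [run_config()].
#' @return Invisibly, `list(status=, tables=, out_dir=)`; `status` is 0 on
#'   success. On stage failure the partial outputs are retained and `MANIFEST`
#'   names the failed stage; `status` is 1.
#' @export
run_all <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("mulrec %s | seed %d\n",
              as.character(utils::packageVersion("mulrec")), cfg$seed),
      file = log_path)
  stage <- "init"
  tables <- list()
  res <- tryCatch({
    stage <- "input"
    if (!is.null(cfg$sim)) {
      sim <- cfg$sim
      sim$seed <- cfg$seed
      dataset <- simulate_dataset(sim)
      trees <- dataset$trees
      stree <- sim$species_tree
      map <- sim$map
      logf("simulated %d families (%d resampled), true candidate %s",
           length(trees), dataset$n_resampled, sim$candidate$id)
    } else {
      trees <- read_gene_trees(cfg$gene_trees)
      stree <- read_species_tree(cfg$species_tree)
      map <- read_species_map(cfg$map)
      dataset <- NULL
      logf("read %d gene trees", length(trees))
    }

    stage <- "candidates"
    cands <- enumerate_candidates(stree)
    if (!is.null(cfg$candidate_ids)) {
      keep <- vapply(cands, candidate_id, character(1)) %in% cfg$candidate_ids
      mr_assert(any(keep), "mr_config_error", "candidate restriction matches nothing")
      cands <- cands[keep]
    }
    tables$candidates <- write_tsv(candidates_table(cands),
                                   file.path(cfg$out_dir, "candidates.tsv"))
    logf("%d candidates", length(cands))

    stage <- "filter"
    prelim <- preliminary_filter(trees, focal_species(map), cfg$filter, cfg$scheme)
    deep <- deep_filter(prelim$kept, c(outgroup_species(map), focal_species(map)),
                        cfg$filter, cfg$scheme)
    rejections <- rbind(prelim$rejected, deep$rejected)
    tables$rejections <- write_tsv(rejections,
                                   file.path(cfg$out_dir, "filter_rejections.tsv"))
    report <- rbind(
      cbind(dataset = "preliminary", filter_report(prelim)),
      cbind(dataset = "deep", filter_report(deep))
    )
    tables$filter_report <- write_tsv(report,
                                      file.path(cfg$out_dir, "filter_report.tsv"))
    logf("preliminary kept %d / %d; deep kept %d",
         length(prelim$kept), length(trees), length(deep$kept))

    stage <- "score"
    sc_prelim <- score_all(prelim$kept, cands, cfg$filter$group_cap, cfg$scheme,
                           details = TRUE)
    sc_deep <- score_all(deep$kept, cands, cfg$filter$group_cap, cfg$scheme,
                         details = TRUE)
    combined <- sc_prelim$table
    for (col in c("n_trees", "n_skipped", "sum_dups", "sum_losses", "total_score")) {
      combined[[col]] <- combined[[col]] + sc_deep$table[[col]]
    }
    ord <- order(combined$total_score, seq_len(nrow(combined)))
    combined$rank[ord] <- seq_len(nrow(combined))
    tables$scores_preliminary <- write_tsv(sc_prelim$table,
                                           file.path(cfg$out_dir, "scores_preliminary.tsv"))
    tables$scores_deep <- write_tsv(sc_deep$table,
                                    file.path(cfg$out_dir, "scores_deep.tsv"))
    tables$scores_combined <- write_tsv(combined,
                                        file.path(cfg$out_dir, "scores_combined.tsv"))
    best_id <- combined$candidate_id[combined$rank == 1L]
    logf("best candidate: %s (combined score %d)",
         best_id, combined$total_score[combined$rank == 1L])

    stage <- "best_detail"
    best_detail <- sc_deep$details[sc_deep$details$candidate_id == best_id, ,
                                   drop = FALSE]
    if (nrow(best_detail) == 0L) {  # deep set may be empty; fall back
      best_detail <- sc_prelim$details[sc_prelim$details$candidate_id == best_id, ,
                                       drop = FALSE]
    }
    tables$best_detail <- write_tsv(best_detail,
                                    file.path(cfg$out_dir, "best_detail.tsv"))

    stage <- "classify"
    cls <- classify_trees(deep$kept, map, cfg$mode, cfg$scheme)
    cls$tree_index <- deep$kept_index[cls$tree_index]
    tables$classification <- write_tsv(cls,
                                       file.path(cfg$out_dir, "classification.tsv"))
    tally <- tally_scenarios(cls$label)
    tables$scenario_tally <- write_tsv(tally,
                                       file.path(cfg$out_dir, "scenario_tally.tsv"))
    lvr <- if (nrow(best_detail)) loss_vs_retention(best_detail) else NA_real_
    tables$loss_vs_retention <- write_tsv(
      data.frame(candidate_id = best_id, fraction_losses_gt_dups = lvr),
      file.path(cfg$out_dir, "loss_vs_retention.tsv"))
    logf("scenario tally: %s",
         paste(sprintf("%s=%d", tally$label, tally$n), collapse = " "))

    stage <- "enrich"
    labels <- data.frame(family = sprintf("fam%d", cls$tree_index),
                         label = cls$label)
    cat_df <- cfg$categories
    if (is.character(cat_df)) {
      cat_df <- utils::read.table(cat_df, sep = "\t", header = FALSE,
                                  col.names = c("family", "category"),
                                  colClasses = "character")
    }
    if (is.null(cat_df) && !is.null(dataset)) {
      set.seed(cfg$seed + 1L)
      cat_df <- simulate_categories(labels)
    }
    if (!is.null(cat_df) && nrow(labels) > 0L) {
      enr <- enrich_scenarios(labels, cat_df)
      tables$enrichment <- write_tsv(enr, file.path(cfg$out_dir, "enrichment.tsv"))
      logf("enrichment rows: %d", nrow(enr))
    }
    0L
  }, error = function(e) {
    logf("FAILED at stage %s: %s", stage, conditionMessage(e))
    writeLines(c(sprintf("status: failed"), sprintf("failed_stage: %s", stage),
                 sprintf("error: %s", conditionMessage(e))),
               file.path(cfg$out_dir, "MANIFEST"))
    1L
  })
  if (identical(res, 0L)) {
    writeLines(c("status: ok",
                 sprintf("tables: %s", paste(names(tables), collapse = " "))),
               file.path(cfg$out_dir, "MANIFEST"))
  }
  invisible(list(status = res, tables = tables, out_dir = cfg$out_dir))
}

#' Random taxon-subsampling designs
#'
#' Draws `n_designs` distinct subsets of the focal-clade species with sizes in
#' `k_range`, each keeping the outgroup and all non-focal species - the
#' sampling-robustness experiment of the standard analysis uses 16 designs of
#' 2 to 6 focal taxa.
#'
#' @param species_tree binary `rtree`.
#' @param map a [species_map()].
#' @param k_range integer range of focal-clade subset sizes.
#' @param n_designs number of distinct designs.
#' @param seed RNG seed (designs are deterministic given the seed).
#' @return List of designs, each `list(k=, focal=, keep_species=, map=)` where
#'   `map` is the pruned [species_map()].
#' @export
subsample_designs <- function(species_tree, map, k_range = 2:6,
                              n_designs = 16L, seed = 1L) {
  focal <- focal_species(map)
  mr_assert(min(k_range) >= 2L && max(k_range) <= length(focal) - 1L,
            "mr_config_error",
            "k_range must lie within [2, number of focal species - 1]")
  n_possible <- sum(choose(length(focal), k_range))
  mr_assert(n_designs <= n_possible, "mr_config_error",
            sprintf("only %d distinct designs exist", n_possible))
  set.seed(seed)
  seen <- character(0)
  designs <- list()
  while (length(designs) < n_designs) {
    k <- k_range[sample.int(length(k_range), 1L)]
    pick <- sort(focal[sample.int(length(focal), k)])
    key <- paste(pick, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    keep <- c(map$species[map$role %in% c("outgroup", "other")], pick)
    designs[[length(designs) + 1L]] <- list(
      k = k, focal = pick, keep_species = keep,
      map = species_map(map$species[map$species %in% keep],
                        map$role[map$species %in% keep])
    )
  }
  designs
}
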