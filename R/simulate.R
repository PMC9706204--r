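#' Synthetic allopolyploid gene-family simulator
#'
#' Generates gene families with the statistical structure the reconciliation
#' analysis assumes: every family descends from the two subgenomes of an
#' allopolyploid focal clade (the true MUL tree), then experiences
#' clade-level homeolog loss with configurable subgenome bias, per-leaf loss
#' noise, small-scale duplication, and optional topological error. Each family
#' records its ground truth (retained copies, scenario label from the
#' clade-level draws, event counts), so parameter-recovery and calibration
#' experiments can compare inferred quantities against the generating model.
#'
#' Clade-level loss indicators are Bernoulli draws:
#' `a = P(lose the "+" copy in cladeB)`, `b = P(lose "*" in cladeB)`,
#' `c = P(lose "+" in cladeA)`, `d = P(lose "*" in cladeA)`. With `b = c = 0`
#' the expected strict scenario fractions are closed form:
#' `T1 = a(1-d)`, `T2 = d(1-a)`, `T3 = (1-a)(1-d)`, `U = ad`.
#'
#' @name simulate
NULL

#' The 8-taxon reference fixture
#'
#' A rooted binary species tree with one outgroup, a 3-taxon ladder
#' (cladeA, the "other"-lineage analog) and a 4-taxon ladder (cladeB, the
#' "core"-lineage analog), mirroring the 7-ingroup + outgroup sampling used
#' in the headline analysis. Enumerating candidates on it yields 181
#' reconciliation references.
#'
#' @return `list(tree=, species_map=)`.
#' @export
make_reference_fixture <- function() {
  tree <- parse_newick("(OUT,((a1,(a2,a3)),(b1,(b2,(b3,b4)))));",
                       multifurcations = FALSE)
  map <- species_map(
    c("OUT", "a1", "a2", "a3", "b1", "b2", "b3", "b4"),
    c("outgroup", rep("cladeA", 3), rep("cladeB", 4))
  )
  list(tree = tree, species_map = map)
}

#' Simulation configuration
#'
#' Defaults encode the standard study conditions: the 8-taxon fixture, the
#' true polyploidy placement at the focal-clade ancestor with the subgenome
#' join immediately basal to it (`h2 = "self"`; with a single sampled outgroup
#' this is the placement identifiable from outgroup-rooted gene trees), biased
#' clade-level loss `a = 0.4`, `d = 0.35`, `b = c = 0`, per-leaf loss noise
#' `eps = 0.05`, no small-scale duplication and no topological error, 500
#' families.
#'
#' @param species_tree binary `rtree`; default the reference fixture.
#' @param map matching [species_map()]; default the fixture's.
#' @param h1 polyploid clade: node index or character vector of species
#'   (default: the whole focal clade, cladeA + cladeB).
#' @param h2 `"self"`, `"root"`, a node index, or species vector.
#' @param a,b,c,d clade-level loss probabilities (see [simulate]); each in
#'   `[0, 1]`, but a clade may not lose both copies surely.
#' @param eps per-leaf loss probability in `[0, 1)` (outgroup exempt).
#' @param delta per-branch small-scale duplication probability in `[0, 1)`
#'   (outgroup branch exempt).
#' @param eta probability of applying one random NNI move per gene tree.
#' @param n_families number of families to generate.
#' @param seed RNG seed recorded and applied by [simulate_dataset()].
#' @param scheme a [label_scheme()] for the emitted leaf labels.
#' @return A list of class `sim_config`; `$candidate` holds the true placement
#'   as a `mul_candidate` (its id names the true candidate in score tables).
#' @export
sim_config <- function(species_tree = NULL, map = NULL, h1 = NULL, h2 = "self",
                       a = 0.4, b = 0, c = 0, d = 0.35, eps = 0.05,
                       delta = 0, eta = 0, n_families = 500L, seed = 1L,
                       scheme = label_scheme()) {
  if (is.null(species_tree)) {
    fix <- make_reference_fixture()
    species_tree <- fix$tree
    if (is.null(map)) map <- fix$species_map
  }
  mr_assert(!is.null(map), "mr_config_error", "a species map is required")
  if (is.null(h1)) h1 <- focal_species(map)
  probs <- c(a = a, b = b, c = c, d = d, eps = eps, delta = delta, eta = eta)
  mr_assert(all(probs >= 0 & probs <= 1), "mr_config_error",
            "probabilities must lie in [0, 1]")
  mr_assert(all(probs[c("eps", "delta", "eta")] < 1), "mr_config_error",
            "eps, delta and eta must be < 1")
  mr_assert(!(a == 1 && b == 1) && !(c == 1 && d == 1), "mr_config_error",
            "a clade cannot surely lose both subgenome copies")
  mr_assert(n_families >= 1L, "mr_config_error", "n_families must be >= 1")
  h1_node <- resolve_node(species_tree, h1)
  h2_node <- if (identical(h2, "self")) h1_node
  else if (identical(h2, "root")) rt_root(species_tree)
  else resolve_node(species_tree, h2)
  cand <- mul_candidate(species_tree, h1_node, h2_node)
  structure(list(
    species_tree = species_tree, map = map, candidate = cand,
    a = a, b = b, c = c, d = d, eps = eps, delta = delta, eta = eta,
    n_families = as.integer(n_families), seed = as.integer(seed),
    scheme = scheme
  ), class = "sim_config")
}

# maximal completely-lost subtrees of `mul` given retained leaf indices
count_lost_clades <- function(mul, retained_idx) {
  lost <- logical(rt_n_nodes(mul))
  leaf <- rt_is_leaf(mul)
  for (v in rt_postorder(mul)) {
    lost[v] <- if (leaf[v]) !(v %in% retained_idx)
    else all(lost[mul$children[[v]]])
  }
  sum(vapply(seq_along(lost), function(v) {
    p <- mul$parent[v]
    lost[v] && (is.na(p) || !lost[p])
  }, logical(1)))
}

# splice duplication nodes above every flagged node; nested flags re-apply in
# both copies (as tandem duplication would). Returns list(tree, n_events).
rt_apply_duplications <- function(t, flags) {
  acc <- rt_new_acc()
  n_events <- 0L
  emit <- function(v, parent, fl) {
    if (fl[v]) {
      n_events <<- n_events + 1L
      g <- acc_add(acc, parent, "")
      fl2 <- fl
      fl2[v] <- FALSE
      emit(v, g, fl2)
      emit(v, g, fl2)
      return(invisible(NULL))
    }
    i <- acc_add(acc, parent, t$label[v])
    for (k in t$children[[v]]) emit(k, i, fl)
  }
  emit(rt_root(t), NA_integer_, flags)
  list(tree = acc_tree(acc), n_events = n_events)
}

# one random NNI move (no-op when no internal edge is eligible)
rt_nni_random <- function(t) {
  nk <- lengths(t$children)
  eligible <- which(nk == 2L & !is.na(t$parent) & nk[ifelse(is.na(t$parent), 1L, t$parent)] == 2L)
  if (!length(eligible)) return(t)
  v <- eligible[sample.int(length(eligible), 1L)]
  p <- t$parent[v]
  s <- setdiff(t$children[[p]], v)[1L]
  g <- t$children[[v]][sample.int(2L, 1L)]
  t$children[[p]][t$children[[p]] == s] <- g
  t$children[[v]][t$children[[v]] == g] <- s
  t$parent[g] <- p
  t$parent[s] <- v
  t
}

# one family draw; NULL when losses emptied the focal clade (caller resamples)
sim_family_once <- function(cfg, fam) {
  mul <- cfg$candidate$ref_tree
  leaf <- rt_is_leaf(mul)
  sp <- mul_species_of(mul$label)
  tag <- mul_tag_of(mul$label)
  role <- cfg$map$role[match(sp, cfg$map$species)]
  role[!leaf] <- NA
  lose <- c(
    Bplus = runif(1) < cfg$a, Bstar = runif(1) < cfg$b,
    Aplus = runif(1) < cfg$c, Astar = runif(1) < cfg$d
  )
  dropped <- leaf & (
    (role %in% "cladeB" & tag == "+" & lose["Bplus"]) |
    (role %in% "cladeB" & tag == "*" & lose["Bstar"]) |
    (role %in% "cladeA" & tag == "+" & lose["Aplus"]) |
    (role %in% "cladeA" & tag == "*" & lose["Astar"])
  )
  keep1 <- which(leaf & !dropped)
  if (!any(role[keep1] %in% c("cladeA", "cladeB"))) return(NULL)
  # scenario truth from the clade-level draws, before noise
  n_copies <- function(cl) length(unique(tag[keep1][role[keep1] %in% cl]))
  nA <- n_copies("cladeA")
  nB <- n_copies("cladeB")
  truth <- if (nA == 2L && nB == 2L) "T3"
  else if (nA == 2L && nB == 1L) "T1"
  else if (nA == 1L && nB == 2L) "T2"
  else "U"
  retained <- paste(sort(mul$label[keep1][role[keep1] %in% c("cladeA", "cladeB")]),
                    collapse = ";")
  t1 <- rt_keep_leaves(mul, keep1)
  # per-leaf loss noise (outgroup exempt: it anchors rooting)
  sp1 <- mul_species_of(t1$label)  # labels still carry copy tags
  role1 <- cfg$map$role[match(sp1, cfg$map$species)]
  lv1 <- rt_leaves(t1)
  noisy <- lv1[role1[lv1] != "outgroup"]
  drop2 <- noisy[runif(length(noisy)) < cfg$eps]
  keep2 <- setdiff(lv1, drop2)
  if (!any(role1[keep2] %in% c("cladeA", "cladeB"))) return(NULL)
  t2 <- rt_keep_leaves(t1, keep2)
  # losses as reconciliation counts them: maximal lost subtrees of the MUL tree
  retained_mul_idx <- match(t2$label[rt_is_leaf(t2)], mul$label)
  n_loss <- count_lost_clades(mul, retained_mul_idx)
  # small-scale duplication per branch (outgroup branch exempt)
  n_dup <- 0L
  if (cfg$delta > 0) {
    sp2 <- mul_species_of(t2$label)
    role2 <- cfg$map$role[match(sp2, cfg$map$species)]
    cand_nodes <- which(!is.na(t2$parent) &
                          !(rt_is_leaf(t2) & role2 %in% "outgroup"))
    flags <- logical(rt_n_nodes(t2))
    flags[cand_nodes] <- runif(length(cand_nodes)) < cfg$delta
    if (any(flags)) {
      dup <- rt_apply_duplications(t2, flags)
      t2 <- dup$tree
      n_dup <- dup$n_events
    }
  }
  if (cfg$eta > 0 && runif(1) < cfg$eta) t2 <- rt_nni_random(t2)
  # relabel leaves SPECIES@famID_copy (preorder numbering within species)
  pre <- rt_preorder(t2)
  lv2 <- pre[rt_is_leaf(t2)[pre]]
  sp2 <- mul_species_of(t2$label[lv2])
  copy_no <- stats::ave(seq_along(sp2), sp2, FUN = seq_along)
  t2$label[lv2] <- sprintf("%s%sfam%d_%d", sp2, cfg$scheme$delimiter, fam, copy_no)
  og <- outgroup_species(cfg$map)
  tree <- root_by_outgroup(t2, og, cfg$scheme)
  list(tree = tree,
       truth = data.frame(family = sprintf("fam%d", fam), label = truth,
                          n_dup = n_dup, n_loss = n_loss, retained = retained))
}

#' Simulate a dataset of gene families
#'
#' Seeds the RNG from `cfg$seed`, so identical configurations yield
#' byte-identical outputs. Families emptied of focal-clade leaves by losses
#' are resampled (counted in `n_resampled`).
#'
#' @param cfg a [sim_config()].
#' @return A list of class `mul_sim`: `trees` (list of rooted `rtree`),
#'   `truth` (data frame: `family`, `label`, `n_dup`, `n_loss`, `retained`),
#'   `species_map`, `config`, `n_resampled`.
#' @export
simulate_dataset <- function(cfg) {
  mr_assert(inherits(cfg, "sim_config"), "mr_config_error",
            "cfg must come from sim_config()")
  set.seed(cfg$seed)
  trees <- vector("list", cfg$n_families)
  rows <- vector("list", cfg$n_families)
  n_resampled <- 0L
  for (i in seq_len(cfg$n_families)) {
    repeat {
      r <- sim_family_once(cfg, i)
      if (!is.null(r)) break
      n_resampled <- n_resampled + 1L
    }
    trees[[i]] <- r$tree
    rows[[i]] <- r$truth
  }
  structure(list(trees = trees, truth = do.call(rbind, rows),
                 species_map = cfg$map, config = cfg,
                 n_resampled = n_resampled),
            class = "mul_sim")
}

#' Write a simulated dataset to a directory
#'
#' Emits `gene_trees.nwk` (one Newick per line), `truth.tsv`,
#' `species_map.tsv` and `config.txt` (key-value echo including the seed).
#'
#' @param sim a `mul_sim` from [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_trees(sim$trees, file.path(dir, "gene_trees.nwk"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_species_map(sim$species_map, file.path(dir, "species_map.tsv"))
  cfg <- sim$config
  keys <- c(true_candidate = cfg$candidate$id,
            a = cfg$a, b = cfg$b, c = cfg$c, d = cfg$d,
            eps = cfg$eps, delta = cfg$delta, eta = cfg$eta,
            n_families = cfg$n_families, seed = cfg$seed,
            n_resampled = sim$n_resampled)
  writeLines(sprintf("%s: %s", names(keys), unname(keys)),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Simulate functional-category annotations
#'
#' Synthetic annotation generator for exercising the enrichment stage: each
#' family acquires each category independently at `base_rate`, except that
#' categories named in `enriched` are `fold` times likelier in families of
#' their designated scenario (probability capped at 1). Uses the current RNG
#' stream; seed before calling for reproducibility.
#'
#' @param family_labels data frame with columns `family`, `label`.
#' @param n_categories number of categories (`C1`, `C2`, ...).
#' @param base_rate baseline per-category annotation probability.
#' @param enriched named character vector mapping scenario labels to enriched
#'   category names.
#' @param fold enrichment factor.
#' @return Data frame with columns `family`, `category` (multi-row per family).
#' @export
simulate_categories <- function(family_labels, n_categories = 8L,
                                base_rate = 0.15,
                                enriched = c(T1 = "C1", T2 = "C2", T3 = "C3"),
                                fold = 4) {
  cats <- sprintf("C%d", seq_len(n_categories))
  mr_assert(all(enriched %in% cats), "mr_config_error",
            "enriched categories must exist")
  out <- list()
  for (i in seq_len(nrow(family_labels))) {
    lab <- family_labels$label[i]
    p <- rep(base_rate, n_categories)
    boost <- enriched[names(enriched) == lab]
    if (length(boost)) p[cats %in% boost] <- pmin(1, base_rate * fold)
    has <- runif(n_categories) < p
    if (any(has)) out[[length(out) + 1L]] <- data.frame(
      family = family_labels$family[i], category = cats[has])
  }
  if (!length(out)) return(data.frame(family = character(0), category = character(0)))
  do.call(rbind, out)
}
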