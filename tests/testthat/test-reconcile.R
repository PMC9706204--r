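# expected duplication/loss counts below were computed with the pure-R
# root-path oracle (lca_map + count_dup_loss) and verified by hand

leaf_assignment_by_species <- function(gene_tree, ref_tree) {
  lv <- which(lengths(gene_tree$children) == 0L)
  sp <- leaf_species(gene_tree)
  ref_lv <- which(lengths(ref_tree$children) == 0L)
  setNames(ref_lv[match(sp, ref_tree$label[ref_lv])], as.character(lv))
}

r_oracle <- function(gene_tree, ref_tree) {
  m <- lca_map(gene_tree, ref_tree, leaf_assignment_by_species(gene_tree, ref_tree))
  count_dup_loss(gene_tree, ref_tree, m)
}

test_that("lca_map maps nodes to the LCA of their children's images", {
  st <- nwk("((A,B),C);")
  g <- nwk("((A@1,B@1),C@1);")
  m <- lca_map(g, st, leaf_assignment_by_species(g, st))
  # isomorphic case: every internal node maps to its namesake clade
  root_g <- which(is.na(g$parent))
  expect_equal(m[root_g], which(is.na(st$parent)))
  cherry_g <- g$parent[match("A@1", g$label)]
  cherry_s <- st$parent[match("A", st$label)]
  expect_equal(m[cherry_g], cherry_s)

  g2 <- nwk("((A@1,A@2),B@1);")
  st2 <- nwk("(A,B);")
  m2 <- lca_map(g2, st2, leaf_assignment_by_species(g2, st2))
  expect_equal(m2[g2$parent[match("A@1", g2$label)]], match("A", st2$label))
  expect_equal(m2[which(is.na(g2$parent))], which(is.na(st2$parent)))

  expect_mr_error(
    lca_map(g2, st2, setNames(c(1L, 1L), c("1", "2"))),
    "mr_mapping_error")
})

test_that("duplication/loss counts match the oracle-derived examples", {
  st <- nwk("((A,B),C);")
  expect_equal(unname(r_oracle(nwk("((A@1,B@1),C@1);"), st)), c(0L, 0L))
  expect_equal(unname(r_oracle(nwk("((A@1,A@2),B@1);"), nwk("(A,B);"))), c(1L, 0L))
  expect_equal(unname(r_oracle(nwk("(A@1,C@1);"), st)), c(0L, 1L))
  expect_equal(unname(r_oracle(nwk("((A@1,A@2),(B@1,C@1));"), st)), c(2L, 3L))
  # compiled path agrees on the same cases
  for (s in c("((A@1,B@1),C@1);", "(A@1,C@1);", "((A@1,A@2),(B@1,C@1));")) {
    r <- reconcile_single(nwk(s), st)
    o <- r_oracle(nwk(s), st)
    expect_equal(c(r$duplications, r$losses), unname(o))
  }
})

test_that("compiled scoring equals the quadratic R oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    st <- random_species_tree(sample(2:6, 1L))
    gt <- random_gene_tree(leaf_labels(st))
    if (n_leaves(gt) < 2L) next
    r <- reconcile_single(gt, st)
    o <- r_oracle(gt, st)
    expect_equal(c(r$duplications, r$losses), unname(o))
  }
})

test_that("polyploid groups are maximal, disjoint and ordered", {
  g1 <- nwk("((P@1,P@2),X@1);")
  gr1 <- find_polyploid_groups(g1, "P")
  expect_length(gr1, 1L)
  expect_length(gr1[[1L]]$leaves, 2L)

  g2 <- nwk("((P@1,X@1),(P@2,Y@1));")
  gr2 <- find_polyploid_groups(g2, c("P"))
  expect_length(gr2, 2L)
  expect_true(all(lengths(lapply(gr2, `[[`, "leaves")) == 1L))

  # alternating polyploid/non-polyploid leaves: 9 groups
  s <- "P@1"
  for (i in 2:9) s <- sprintf("(%s,(X@%d,P@%d))", s, i, i)
  g3 <- parse_newick(paste0("(", s, ",X@1);"))
  expect_length(find_polyploid_groups(g3, "P"), 9L)

  # groups partition the duplicated-species leaves
  all_leaves <- unlist(lapply(gr2, `[[`, "leaves"))
  expect_false(anyDuplicated(all_leaves) > 0)
})

test_that("assignment blocks split multi-copy groups to one copy per species", {
  g <- nwk("((P@1,P@2),X@1);")
  gr <- find_polyploid_groups(g, "P")
  bl <- assignment_blocks(g, gr)
  expect_length(bl, 2L)
  # single-copy group stays whole
  g2 <- nwk("(((P@1,Q@1),X@1),(P@2,Q@2));")
  gr2 <- find_polyploid_groups(g2, c("P", "Q"))
  expect_length(gr2, 2L)
  expect_length(assignment_blocks(g2, gr2), 2L)
})

test_that("MUL reconciliation finds the zero-conflict embedding", {
  st <- nwk("(O,(A,B));")
  cands <- enumerate_candidates(st)
  ids <- vapply(cands, candidate_id, character(1))
  cand <- cands[[which(ids == "H1=A|H2=B")]]
  gt <- nwk("((A@1,(A@2,B@1)),O@1);")
  r <- reconcile_mul(gt, cand)
  expect_equal(r$score, 0L)
  expect_setequal(r$assignment, c("*", "+"))
  # against the singly-labelled tree the same family costs a duplication
  expect_gte(reconcile_single(gt, st)$score, 2L)
  # brute force agrees exactly here (all groups are singleton leaves)
  expect_equal(brute_force_mul(gt, cand)$score, 0L)
})

test_that("the group cap is enforced and brute force refuses huge instances", {
  s <- "P@1"
  for (i in 2:9) s <- sprintf("(%s,(X@%d,P@%d))", s, i, i)
  g9 <- parse_newick(paste0("(", s, ",X@1);"))
  st <- nwk("(X,P);")
  cand <- enumerate_candidates(st)
  ids <- vapply(cand, candidate_id, character(1))
  mul <- cand[[which(ids == "H1=P|H2=SELF")]]
  expect_mr_error(reconcile_mul(g9, mul, group_cap = 8L), "mr_group_cap_error")
  expect_s3_class(reconcile_mul(g9, mul, group_cap = 9L), "mr_reconciliation")
  big <- random_gene_tree(rep("P", 7), max_copies = 2L)
  expect_mr_error(brute_force_mul(big, mul, max_leaves = 5L), "mr_oracle_error")
})

test_that("block-based search never beats per-leaf brute force, ties on singletons", {
  set.seed(202)
  n_equal <- 0L
  for (i in 1:200) {
    inst <- random_mul_instance()
    r_b <- tryCatch(reconcile_mul(inst$gene_tree, inst$candidate, group_cap = 99L),
                    mulrec_error = function(e) NULL)
    if (is.null(r_b)) next
    r_o <- brute_force_mul(inst$gene_tree, inst$candidate, max_leaves = 10L)
    expect_gte(r_b$score, r_o$score)
    groups <- find_polyploid_groups(inst$gene_tree,
                                    duplicated_species(inst$candidate))
    if (all(lengths(lapply(groups, `[[`, "leaves")) == 1L)) {
      expect_equal(r_b$score, r_o$score)
      n_equal <- n_equal + 1L
    }
  }
  expect_gte(n_equal, 20L)  # singleton-only instances actually occurred
})

test_that("scores are invariant under child-order permutation", {
  set.seed(303)
  for (i in 1:30) {
    inst <- random_mul_instance()
    r1 <- reconcile_mul(inst$gene_tree, inst$candidate, group_cap = 99L)
    # swap children at every internal node of the gene tree
    g2 <- inst$gene_tree
    for (v in seq_along(g2$children)) {
      if (length(g2$children[[v]]) == 2L) g2$children[[v]] <- rev(g2$children[[v]])
    }
    r2 <- reconcile_mul(g2, inst$candidate, group_cap = 99L)
    expect_equal(r1$score, r2$score)
  }
})

test_that("adding back a pruned outgroup leaf never decreases the score", {
  set.seed(404)
  for (i in 1:50) {
    st <- random_species_tree(sample(2:5, 1L), outgroup = TRUE)
    gt <- random_gene_tree(setdiff(leaf_labels(st), "OG"))
    if (n_leaves(gt) < 2L) next
    with_og <- parse_newick(sprintf("(%s,OG@1);", sub(";$", "", write_newick(gt))))
    expect_gte(reconcile_single(with_og, st)$score,
               reconcile_single(gt, st)$score)
  }
})

test_that("zero-event simulated families reconcile perfectly against the truth", {
  cfg <- sim_config(a = 0, b = 0, c = 0, d = 0, eps = 0, n_families = 100, seed = 6)
  sim <- simulate_dataset(cfg)
  scores <- vapply(sim$trees, function(tr) {
    reconcile_mul(tr, cfg$candidate)$score
  }, integer(1))
  expect_true(all(scores == 0L))
})

test_that("score_all ranks deterministically and accounts for every tree", {
  st <- nwk("(O,(A,B));")
  cands <- enumerate_candidates(st)
  trees <- list(nwk("((A@1,(A@2,B@1)),O@1);"), nwk("((A@1,B@1),O@1);"))
  tab <- score_all(trees, cands, details = TRUE)
  expect_equal(nrow(tab$table), length(cands))
  expect_true(all(tab$table$n_trees + tab$table$n_skipped == length(trees)))
  expect_equal(sort(tab$table$rank), seq_along(cands))
  tab2 <- score_all(trees, cands, details = TRUE)
  expect_identical(tab$table, tab2$table)
  # empty input: all-zero table
  tab0 <- score_all(list(), cands)
  expect_true(all(tab0$total_score == 0L))
})
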