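test_that("the reference fixture has the documented shape", {
  fix <- make_reference_fixture()
  expect_equal(n_leaves(fix$tree), 8L)
  expect_equal(length(fix$tree$label) - 1L, 14L)  # non-root nodes
  expect_true(is_binary_tree(fix$tree))
  expect_equal(outgroup_species(fix$species_map), "OUT")
})

test_that("identical seeds give byte-identical datasets", {
  cfg <- sim_config(n_families = 30, seed = 123)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(vapply(s1$trees, write_newick, character(1)),
                   vapply(s2$trees, write_newick, character(1)))
  expect_identical(s1$truth, s2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in c("gene_trees.nwk", "truth.tsv", "species_map.tsv", "config.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  s3 <- simulate_dataset(sim_config(n_families = 30, seed = 124))
  expect_false(identical(vapply(s1$trees, write_newick, character(1)),
                         vapply(s3$trees, write_newick, character(1))))
})

test_that("the no-event limit reproduces the true MUL tree with label T3", {
  cfg <- sim_config(a = 0, b = 0, c = 0, d = 0, eps = 0, n_families = 5, seed = 2)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$label == "T3"))
  expect_true(all(sim$truth$n_loss == 0L))
  mul <- cfg$candidate$ref_tree
  mul_sp <- mul
  lv <- which(lengths(mul$children) == 0L)
  mul_sp$label[lv] <- sub("[*+]$", "", mul$label[lv])
  for (tr in sim$trees) {
    tr_sp <- tr
    lvg <- which(lengths(tr$children) == 0L)
    tr_sp$label[lvg] <- sub("@.*$", "", tr$label[lvg])
    expect_true(tree_isomorphic(tr_sp, mul_sp))
  }
})

test_that("forced-loss regimes produce their designed truth labels", {
  t1 <- simulate_dataset(sim_config(a = 1, b = 0, c = 0, d = 0, eps = 0,
                                    n_families = 10, seed = 3))
  expect_true(all(t1$truth$label == "T1"))
  expect_true(all(t1$truth$n_loss == 1L))
  u <- simulate_dataset(sim_config(a = 1, b = 0, c = 0, d = 1, eps = 0,
                                   n_families = 10, seed = 3))
  expect_true(all(u$truth$label == "U"))
  expect_true(all(u$truth$n_loss == 2L))
})

test_that("scenario fractions match the closed-form expectations (99% CI)", {
  a <- 0.4; d <- 0.35; F <- 2000
  cfg <- sim_config(a = a, b = 0, c = 0, d = d, eps = 0, n_families = F, seed = 13)
  sim <- simulate_dataset(cfg)
  expected <- c(T1 = a * (1 - d), T2 = d * (1 - a),
                T3 = (1 - a) * (1 - d), U = a * d)
  cls <- classify_trees(sim$trees, sim$species_map)
  for (lab in names(expected)) {
    p <- expected[[lab]]
    half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / F)
    frac_truth <- mean(sim$truth$label == lab)
    frac_class <- mean(cls$label == lab)
    expect_lt(abs(frac_truth - p), half)
    expect_lt(abs(frac_class - p), half)
  }
  # with eps = 0 classification reproduces the truth exactly
  expect_equal(cls$label, sim$truth$label)
})

test_that("reconciliation against the truth is bounded by the losses applied", {
  cfg <- sim_config(n_families = 100, seed = 17)  # eta = delta = 0 defaults
  sim <- simulate_dataset(cfg)
  for (i in seq_along(sim$trees)) {
    sc <- reconcile_mul(sim$trees[[i]], cfg$candidate)
    expect_lte(sc$score, sim$truth$n_loss[i])
    if (sim$truth$label[i] != "U") {
      expect_equal(sc$score, sim$truth$n_loss[i])
    }
    expect_equal(sc$duplications, 0L)
  }
})

test_that("small-scale duplications are recorded and scored", {
  cfg <- sim_config(a = 0, b = 0, c = 0, d = 0, eps = 0, delta = 0.05,
                    n_families = 50, seed = 19)
  sim <- simulate_dataset(cfg)
  expect_gt(sum(sim$truth$n_dup), 0L)
  for (i in seq_along(sim$trees)) {
    sc <- reconcile_mul(sim$trees[[i]], cfg$candidate, group_cap = 99L)
    expect_equal(sc$duplications, sim$truth$n_dup[i])
  }
})

test_that("high leaf-loss noise yields loss-dominated reconciliations", {
  cfg <- sim_config(eps = 0.3, n_families = 150, seed = 23)
  sim <- simulate_dataset(cfg)
  res <- do.call(rbind, lapply(sim$trees, function(tr) {
    r <- reconcile_mul(tr, cfg$candidate, group_cap = 99L)
    data.frame(dups = r$duplications, losses = r$losses)
  }))
  expect_gt(loss_vs_retention(res), 0.9)
})

test_that("topological noise increases the unclassifiable fraction", {
  u_frac <- function(eta, seed) {
    cfg <- sim_config(eta = eta, n_families = 60, seed = seed)
    sim <- simulate_dataset(cfg)
    mean(classify_trees(sim$trees, sim$species_map)$label == "U")
  }
  seeds <- 1:10
  u0 <- mean(vapply(seeds, function(s) u_frac(0, s), numeric(1)))
  u5 <- mean(vapply(seeds, function(s) u_frac(0.5, s), numeric(1)))
  expect_gt(u5, u0)
})

test_that("simulated categories enrich their designated scenario", {
  set.seed(29)
  labels <- data.frame(family = sprintf("f%d", 1:600),
                       label = rep(c("T1", "T2", "T3"), each = 200))
  cats <- simulate_categories(labels, fold = 5)
  enr <- enrich_scenarios(labels, cats)
  top_t1 <- enr$category[enr$scenario == "T1"][1L]
  expect_equal(top_t1, "C1")
  expect_lt(enr$q[enr$scenario == "T1" & enr$category == "C1"], 0.05)
})

test_that("sim_config validates probabilities", {
  expect_mr_error(sim_config(a = 1.2), "mr_config_error")
  expect_mr_error(sim_config(a = 1, b = 1), "mr_config_error")
  expect_mr_error(sim_config(eps = 1), "mr_config_error")
  expect_mr_error(sim_config(n_families = 0), "mr_config_error")
})
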