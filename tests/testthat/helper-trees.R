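# fixtures are built in code; all randomness goes through the seeds set in
# the individual tests

nwk <- function(s) parse_newick(s)

# random rooted binary tree over the given leaf labels (sequential joins)
random_rtree <- function(labels) {
  items <- labels
  while (length(items) > 1L) {
    i <- sample.int(length(items), 2L)
    items <- c(items[-i], sprintf("(%s,%s)", items[i[1L]], items[i[2L]]))
  }
  parse_newick(paste0(items, ";"))
}

# random binary species tree on k species named S1..Sk (plus optional outgroup)
random_species_tree <- function(k, outgroup = FALSE) {
  labs <- sprintf("S%d", seq_len(k))
  if (outgroup) {
    t <- random_rtree(labs)
    parse_newick(sprintf("(OG,%s);", sub(";$", "", write_newick(t))))
  } else {
    random_rtree(labs)
  }
}

# random gene tree: each species contributes 1..max_copies leaves SP@g<i>
random_gene_tree <- function(species, max_copies = 2L) {
  labs <- unlist(lapply(species, function(s) {
    n <- sample.int(max_copies, 1L)
    sprintf("%s@g%d", s, seq_len(n))
  }))
  if (length(labs) == 1L) parse_newick(paste0(labs, ";")) else random_rtree(labs)
}

# random reconciliation instance against a random MUL candidate
random_mul_instance <- function(max_species = 6L, max_dup_leaves = 10L) {
  repeat {
    k <- sample(2:max_species, 1L)
    st <- random_species_tree(k)
    cands <- enumerate_candidates(st)
    cand <- cands[[sample(2:length(cands), 1L)]]  # skip SINGLE
    gt <- random_gene_tree(leaf_labels(st))
    sp <- leaf_species(gt)
    if (sum(sp %in% duplicated_species(cand)) <= max_dup_leaves)
      return(list(species_tree = st, candidate = cand, gene_tree = gt))
  }
}

# species map for the classification examples: o* = cladeA, c* = cladeB
toy_map <- function() {
  species_map(c("og", "o1", "o2", "o3", "c1", "c2", "c3", "c4"),
              c("outgroup", rep("cladeA", 3), rep("cladeB", 4)))
}

expect_mr_error <- function(expr, class) {
  expect_error(expr, class = class)
}

# 10-tree fixture with designed group counts and copy numbers:
#   trees 1-6  clean (1-2 copies per species, few groups)
#   tree  7    nine polyploid groups (preliminary rejection)
#   tree  8    ten polyploid groups (preliminary rejection)
#   tree  9    species A at 5 copies (deep rejection: copy_number)
#   tree 10    species B absent (deep rejection: species_missing)
filter_fixture <- function() {
  alternating <- function(k) {
    s <- "P@1"
    for (i in 2:k) s <- sprintf("(%s,(X@%d,P@%d))", s, i, i)
    parse_newick(paste0("(", s, ",X@1);"))
  }
  list(
    nwk("((A@1,B@1),X@1);"),
    nwk("((A@1,A@2),(B@1,X@1));"),
    nwk("(((A@1,B@1),(A@2,B@2)),X@1);"),
    nwk("((A@1,(B@1,B@2)),X@1);"),
    nwk("(((A@1,A@2),(B@1,B@2)),X@1);"),
    nwk("((B@1,A@1),X@1);"),
    alternating(9),
    alternating(10),
    nwk("((((A@1,A@2),(A@3,A@4)),(A@5,B@1)),X@1);"),
    nwk("((A@1,A@2),X@1);")
  )
}
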