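#include <Rcpp.h>
using namespace Rcpp;

// LCA by parent-pointer lifting; trees here are tiny (tens of nodes), so the
// O(depth) walk beats any preprocessing.
static inline int lca(const IntegerVector& parent, const IntegerVector& depth,
                      int u, int v) {
  while (depth[u - 1] > depth[v - 1]) u = parent[u - 1];
  while (depth[v - 1] > depth[u - 1]) v = parent[v - 1];
  while (u != v) {
    u = parent[u - 1];
    v = parent[v - 1];
  }
  return u;
}

// Duplication/loss count for one leaf image assignment.
// ref_parent: 1-based parent, 0 for root. post_internal: internal gene nodes
// in postorder. child1/child2: children of internal gene nodes (0 for leaves).
// leaf_img: per gene node, 1-based ref node for leaves, 0 for internals.
// map_buf: scratch of gene-tree size.
static void dup_loss_core(const IntegerVector& ref_parent,
                          const IntegerVector& ref_depth,
                          const IntegerVector& post_internal,
                          const IntegerVector& child1,
                          const IntegerVector& child2,
                          const int* leaf_img,
                          int* map_buf, int& dups, int& losses) {
  int n = child1.size();
  for (int i = 0; i < n; ++i) map_buf[i] = leaf_img[i];
  dups = 0;
  losses = 0;
  for (int k = 0; k < post_internal.size(); ++k) {
    int g = post_internal[k];
    int m1 = map_buf[child1[g - 1] - 1];
    int m2 = map_buf[child2[g - 1] - 1];
    int u = lca(ref_parent, ref_depth, m1, m2);
    map_buf[g - 1] = u;
    bool dup = (u == m1) || (u == m2);
    if (dup) ++dups;
    int l = (ref_depth[m1 - 1] - ref_depth[u - 1]) +
            (ref_depth[m2 - 1] - ref_depth[u - 1]);
    if (!dup) l -= 2;  // one free edge per child at a speciation
    losses += l;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_dup_loss(IntegerVector ref_parent, IntegerVector ref_depth,
                           IntegerVector post_internal, IntegerVector child1,
                           IntegerVector child2, IntegerVector leaf_img) {
  int n = child1.size();
  std::vector<int> map_buf(n);
  int dups, losses;
  dup_loss_core(ref_parent, ref_depth, post_internal, child1, child2,
                INTEGER(leaf_img), map_buf.data(), dups, losses);
  return IntegerVector::create(dups, losses);
}

// Exhaustive search over 2^n_groups subgenome assignments of polyploid groups.
// group_of: per gene node, 1..n_groups for leaves of duplicated species, 0
// otherwise. img_star / img_plus give each leaf's ref image under the two
// copy tags (identical for non-duplicated species). Bit j-1 of the mask set
// means group j takes the "+" copy. Ties broken by fewer "+" assignments
// (prefer "*"), then by the smallest mask, so results are deterministic.
// [[Rcpp::export]]
IntegerVector cpp_best_assignment(IntegerVector ref_parent, IntegerVector ref_depth,
                                  IntegerVector post_internal, IntegerVector child1,
                                  IntegerVector child2, IntegerVector img_star,
                                  IntegerVector img_plus, IntegerVector group_of,
                                  int n_groups) {
  int n = child1.size();
  if (n_groups > 30) stop("too many polyploid groups for exhaustive search");
  std::vector<int> map_buf(n), img(n);
  long best_score = -1;
  int best_dups = 0, best_losses = 0, best_nplus = 0;
  long best_mask = 0;
  long n_masks = 1L << n_groups;
  for (long mask = 0; mask < n_masks; ++mask) {
    int nplus = 0;
    for (long m = mask; m; m >>= 1) nplus += (int)(m & 1);
    for (int i = 0; i < n; ++i) {
      int g = group_of[i];
      if (g > 0 && (mask >> (g - 1)) & 1)
        img[i] = img_plus[i];
      else
        img[i] = img_star[i];
    }
    int dups, losses;
    dup_loss_core(ref_parent, ref_depth, post_internal, child1, child2,
                  img.data(), map_buf.data(), dups, losses);
    long score = dups + losses;
    if (best_score < 0 || score < best_score ||
        (score == best_score && nplus < best_nplus)) {
      best_score = score;
      best_dups = dups;
      best_losses = losses;
      best_nplus = nplus;
      best_mask = mask;
    }
  }
  return IntegerVector::create(best_dups, best_losses, (int)best_mask);
}
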