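#' Per-scenario category enrichment
#'
#' Tests whether functional categories are over-represented among the gene
#' families following each retention/loss scenario. For a category with `K`
#' annotated families in a universe of `N`, and a scenario containing `n`
#' families of which `k` carry the category, the p-value is the exact
#' hypergeometric upper tail `P[X >= k]`. Within each scenario, p-values are
#' adjusted across categories by the Benjamini-Hochberg step-up procedure.
#' Both statistics are computed from first principles (log-binomial sums and
#' the explicit step-up formula).
#'
#' @name enrich
NULL

#' Hypergeometric upper-tail probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' universe of `N` of which `K` are marked. Computed as a sum of
#' `exp(lchoose(...))` terms, which is exact to machine precision at the
#' problem sizes involved.
#'
#' @param k observed marked draws (integer, `0 <= k <= min(K, n)`).
#' @param K marked items in the universe.
#' @param n draws.
#' @param N universe size.
#' @return The upper-tail probability in `(0, 1]`.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  ok <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x)
  mr_assert(ok(k) && ok(K) && ok(n) && ok(N), "mr_config_error",
            "arguments must be single integers")
  mr_assert(K >= 0 && n >= 0 && K <= N && n <= N, "mr_config_error",
            "need 0 <= K, n <= N")
  mr_assert(k >= 0 && k <= min(K, n), "mr_config_error",
            "need 0 <= k <= min(K, n)")
  if (k == 0) return(1)
  i <- k:min(K, n)
  p <- sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
  min(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_i = min_{j: p_j >= p_i} (m * p_j / rank_j)`,
#' capped at 1, with input order preserved.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return Vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  mr_assert(all(p > 0 & p <= 1), "mr_config_error", "p-values must lie in (0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Scenario-wise category enrichment table
#'
#' @param family_labels data frame with columns `family`, `label` (one row per
#'   family; labels in `T1 T2 T3 U`).
#' @param family_categories data frame with columns `family`, `category`
#'   (zero or more rows per family). Families without annotation stay in the
#'   universe but contribute to no category count.
#' @param universe `"all"` (default: every labelled family, U included) or
#'   `"classified"` (only T1/T2/T3 families).
#' @return Data frame of class `enrichment_table`, one row per
#'   (scenario in T1,T2,T3) x (category observed in the universe), columns
#'   `scenario`, `category`, `k`, `n`, `K`, `N`, `p`, `q`; ordered by scenario,
#'   then ascending `p`, then category. BH adjustment is applied within each
#'   scenario. Scenarios with zero families contribute no rows.
#' @export
enrich_scenarios <- function(family_labels, family_categories,
                             universe = c("all", "classified")) {
  universe <- match.arg(universe)
  mr_assert(is.data.frame(family_labels) && nrow(family_labels) > 0L,
            "mr_config_error", "empty universe")
  mr_assert(!anyDuplicated(family_labels$family), "mr_config_error",
            "family_labels must have one row per family")
  mr_assert(all(family_labels$label %in% SCENARIOS), "mr_config_error",
            "labels must be T1, T2, T3 or U")
  fams <- if (universe == "classified") {
    family_labels[family_labels$label != "U", , drop = FALSE]
  } else family_labels
  mr_assert(nrow(fams) > 0L, "mr_config_error", "empty universe after restriction")
  cats <- family_categories[family_categories$family %in% fams$family, , drop = FALSE]
  cats <- unique(cats[, c("family", "category")])
  N <- nrow(fams)
  out <- list()
  for (s in c("T1", "T2", "T3")) {
    in_s <- fams$family[fams$label == s]
    n <- length(in_s)
    if (n == 0L) next
    rows <- lapply(sort(unique(cats$category)), function(cc) {
      with_cat <- cats$family[cats$category == cc]
      data.frame(scenario = s, category = cc,
                 k = sum(with_cat %in% in_s), n = n,
                 K = length(with_cat), N = N)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) next
    tab$p <- mapply(hypergeom_upper, tab$k, tab$K, tab$n, MoreArgs = list(N = N))
    tab$q <- bh_adjust(tab$p)
    tab <- tab[order(tab$p, tab$category), ]
    out[[s]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("enrichment_table", "data.frame")
  res
}
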