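#' Differential-expression screen (Mann-Whitney U + Benjamini-Hochberg)
#'
#' Per-gene two-sided Mann-Whitney U test between two sample groups on
#' log-normalized values, Benjamini-Hochberg correction across all tested
#' genes, and a 2-fold-change style filter: a gene is called significant when
#' `|lfc| >= lfc_min` and the adjusted p-value is below `alpha`.
#'
#' The log2 fold change is the difference of group means on the
#' `log2(count/factor + 1)` scale (a pseudocount-1 geometric-mean ratio).
#'
#' @param normalized log-normalized genes x samples matrix.
#' @param groupA,groupB disjoint sample name/index vectors, each >= 2.
#' @param lfc_min minimal absolute log2 fold change (default 1, i.e. 2-fold).
#' @param alpha adjusted-p significance level.
#' @return data.frame per gene: `lfc`, `p`, `p_adj`, `significant`.
#' @export
de_screen <- function(normalized, groupA, groupB, lfc_min = 1, alpha = 0.05) {
  A <- normalized[, groupA, drop = FALSE]
  B <- normalized[, groupB, drop = FALSE]
  if (ncol(A) < 2 || ncol(B) < 2) stop("each group needs >= 2 samples")
  if (length(intersect(colnames(A), colnames(B))) > 0)
    stop("groups overlap")
  lfc <- rowMeans(B) - rowMeans(A)
  p <- vapply(seq_len(nrow(A)), function(i) {
    suppressWarnings(stats::wilcox.test(B[i, ], A[i, ],
                                        alternative = "two.sided")$p.value)
  }, 0)
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(normalized), lfc = lfc, p = p, p_adj = p_adj,
             significant = abs(lfc) >= lfc_min & p_adj < alpha,
             row.names = NULL)
}

# two-sided Fisher exact p by hypergeometric enumeration: sum of the
# probabilities of all tables (at fixed margins) no more likely than the
# observed one, with the conventional relative tie tolerance
fisher_p_twosided <- function(a, b, c, d) {
  m <- a + b            # size of set A
  n <- c + d            # complement
  k <- a + c            # size of set B
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Overlap of two gene sets with a two-sided Fisher exact test
#'
#' @param setA,setB character vectors of gene ids, subsets of the universe.
#' @param universe character vector (or its size) of all genes considered.
#' @return list: `odds_ratio` (sample odds ratio ad/bc), `p` (two-sided
#'   Fisher exact), `overlap` (|A intersect B|), `overlap_pct_union`
#'   (|A∩B|/|A∪B| * 100), `overlap_pct_min` (|A∩B|/min(|A|,|B|) * 100), and
#'   the 2x2 `table`.
#' @export
overlap_fisher <- function(setA, setB, universe) {
  if (length(universe) == 1 && is.numeric(universe)) {
    N <- universe
  } else {
    if (length(universe) == 0) stop("empty universe")
    if (!all(setA %in% universe) || !all(setB %in% universe))
      stop("sets must be subsets of the universe")
    N <- length(unique(universe))
  }
  if (N == 0) stop("empty universe")
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  c <- length(setB) - a
  d <- N - a - b - c
  if (d < 0) stop("sets exceed universe")
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  if (a == 0 && (b > 0 || c > 0)) or <- 0
  un <- a + b + c
  list(odds_ratio = or,
       p = fisher_p_twosided(a, b, c, d),
       overlap = a,
       overlap_pct_union = if (un > 0) 100 * a / un else NaN,
       overlap_pct_min = if (min(length(setA), length(setB)) > 0)
         100 * a / min(length(setA), length(setB)) else NaN,
       table = matrix(c(a, b, c, d), 2, 2, byrow = TRUE))
}

#' Regulon enrichment among differentially expressed genes
#'
#' Restricts the annotation to the `k_largest` regulons by target count,
#' Fisher-tests each regulon's targets against the DE set, and applies
#' Benjamini-Hochberg across regulons.
#'
#' @param de_genes character vector of DE gene ids.
#' @param regulons a [regulon_set()].
#' @param universe gene universe (vector of ids or its size as a number is
#'   not allowed here: target membership requires ids).
#' @param alpha adjusted-p threshold for the `enriched` flag.
#' @param k_largest number of largest regulons tested (default 40).
#' @return data.frame per tested regulon: `n_targets`, `overlap`,
#'   `odds_ratio`, `p`, `p_adj`, `enriched`.
#' @export
regulon_enrichment <- function(de_genes, regulons, universe, alpha = 0.05,
                               k_largest = 40) {
  sizes <- lengths(regulons$targets)
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(k_largest,
                                                      nrow(regulons)))]
  rows <- lapply(keep, function(i) {
    tg <- intersect(regulons$targets[[i]], universe)
    ov <- overlap_fisher(tg, intersect(de_genes, universe), universe)
    data.frame(regulator = regulons$regulator[i], n_targets = length(tg),
               overlap = ov$overlap, odds_ratio = ov$odds_ratio, p = ov$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  # two-sided p is small for depletion too; enrichment means over-representation
  out$enriched <- out$p_adj < alpha & out$odds_ratio > 1
  out
}

#' PCA of expression profiles
#'
#' Samples are the observations; genes are centered across the selected
#' samples before decomposition, so components describe deviations from the
#' mean expression profile.
#'
#' @param normalized log-normalized genes x samples matrix.
#' @param samples sample names/indices to include (default all; >= 3).
#' @return list with `scores` (samples x PCs), `loadings` (genes x PCs),
#'   `variance_fraction` per component.
#' @export
pca_profiles <- function(normalized, samples = NULL) {
  if (is.null(samples)) samples <- colnames(normalized)
  X <- t(normalized[, samples, drop = FALSE])   # samples x genes
  if (nrow(X) < 3) stop("need >= 3 samples for a PCA of profiles")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, variance_fraction = vf)
}
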