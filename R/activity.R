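#' Median-of-ratios size factors
#'
#' Per-gene geometric means are computed over samples (genes with any zero
#' count are excluded from the reference); each sample's factor is the median
#' ratio of its counts to the reference, rescaled so the factors' geometric
#' mean is 1.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene with positive counts in all samples; consider adding a pseudocount before normalization")
  ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  f <- apply(counts[pos, , drop = FALSE] / ref, 2, stats::median)
  f / exp(mean(log(f)))
}

#' Log2 normalization of counts
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample size factors (> 0).
#' @return matrix of `log2(count/factor + 1)`.
#' @export
normalize_log <- function(counts, factors) {
  if (any(factors <= 0)) stop("size factors must be > 0")
  log2(sweep(as.matrix(counts), 2, factors, "/") + 1)
}

#' Regulon annotation set
#'
#' @param regulator character vector of regulator ids.
#' @param mode `"activator"` or `"repressor"` per regulator.
#' @param targets list of character vectors of target gene ids.
#' @param regulator_gene optional gene id encoding the regulator itself.
#' @return object of class `regulon_set` (a data.frame with a list column).
#' @export
regulon_set <- function(regulator, mode, targets, regulator_gene = NA) {
  mode <- match.arg(mode, c("activator", "repressor"), several.ok = TRUE)
  if (length(mode) == 1) mode <- rep(mode, length(regulator))
  if (anyDuplicated(regulator)) stop("duplicate regulator ids")
  if (any(lengths(targets) < 1)) stop("each regulon needs >= 1 target")
  out <- data.frame(regulator = regulator, mode = mode,
                    regulator_gene = regulator_gene)
  out$targets <- targets
  class(out) <- c("regulon_set", "data.frame")
  out
}

#' Infer regulator activities from target-gene expression
#'
#' Each target gene is z-scored across the reference samples; a regulator's
#' activity in a sample is the mean z-score of its surviving targets, with
#' the sign flipped for repressors (a repressor is considered active when its
#' targets are lowly expressed; an activator when they are highly expressed).
#'
#' @param normalized log-normalized genes x samples matrix (rownames = gene
#'   ids).
#' @param regulons a [regulon_set()].
#' @param sample_subset sample names/indices defining the z-score reference
#'   (default: all samples). At least 3.
#' @return matrix regulators x samples of activities (class
#'   `activity_matrix`), with attributes `dropped_targets` (per regulator,
#'   targets missing or of zero variance) and `undefined` (regulators with no
#'   surviving target, rows set to NA).
#' @export
regulator_activity <- function(normalized, regulons, sample_subset = NULL) {
  if (is.null(sample_subset)) sample_subset <- colnames(normalized)
  sub <- normalized[, sample_subset, drop = FALSE]
  if (ncol(sub) < 3) stop("sample_subset must contain >= 3 samples")
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  z <- (sub - mu) / sdv
  act <- matrix(NA_real_, nrow(regulons), ncol(sub),
                dimnames = list(regulons$regulator, colnames(sub)))
  dropped <- stats::setNames(vector("list", nrow(regulons)),
                             regulons$regulator)
  undef <- character(0)
  for (i in seq_len(nrow(regulons))) {
    tg <- regulons$targets[[i]]
    missing <- setdiff(tg, rownames(sub))
    tg <- intersect(tg, rownames(sub))
    zerovar <- tg[sdv[tg] == 0 | !is.finite(sdv[tg])]
    tg <- setdiff(tg, zerovar)
    dropped[[i]] <- c(missing, zerovar)
    if (length(dropped[[i]]))
      message(sprintf("regulon %s: dropped %d target(s) (missing or zero variance)",
                      regulons$regulator[i], length(dropped[[i]])))
    if (length(tg) == 0) { undef <- c(undef, regulons$regulator[i]); next }
    sign <- if (regulons$mode[i] == "repressor") -1 else 1
    act[i, ] <- sign * colMeans(z[tg, , drop = FALSE])
  }
  structure(act, class = c("activity_matrix", "matrix", "array"),
            dropped_targets = dropped, undefined = undef,
            reference = sample_subset)
}

#' Pairwise coactivation of regulators
#'
#' @param activity an activity matrix (regulators x samples).
#' @param sample_subset samples over which to correlate (default all; >= 3).
#' @return symmetric Pearson correlation matrix (class
#'   `coactivation_matrix`) with attribute `masked` naming regulators with
#'   undefined or constant activity (rows/cols set to NA) and `n_samples`.
#' @export
coactivation <- function(activity, sample_subset = NULL) {
  if (is.null(sample_subset)) sample_subset <- colnames(activity)
  sub <- activity[, sample_subset, drop = FALSE]
  if (ncol(sub) < 3) stop("need >= 3 samples for coactivation")
  sdv <- apply(sub, 1, stats::sd)
  ok <- is.finite(sdv) & sdv > 0 & !apply(sub, 1, anyNA)
  cc <- matrix(NA_real_, nrow(sub), nrow(sub),
               dimnames = list(rownames(sub), rownames(sub)))
  cc[ok, ok] <- stats::cor(t(sub[ok, , drop = FALSE]))
  diag(cc)[ok] <- 1
  structure(cc, class = c("coactivation_matrix", "matrix", "array"),
            masked = rownames(sub)[!ok], n_samples = ncol(sub))
}

#' Partition regulators into activity modules
#'
#' Average-linkage hierarchical clustering on the distance `1 - r`; when `k`
#' is not supplied, the number of modules is chosen in 2..6 by maximal mean
#' silhouette width (ties toward smaller k).
#'
#' @param coact a [coactivation()] matrix without masked rows.
#' @param k optional fixed number of modules.
#' @return list with `modules` (named integer vector regulator -> module
#'   label), `k`, `silhouette` (mean width per candidate k), `degenerate`
#'   (TRUE when the best silhouette is weak, indicating no real module
#'   structure), and the `hclust` tree.
#' @export
partition_modules <- function(coact, k = NULL) {
  if (length(attr(coact, "masked")) > 0)
    stop("coactivation matrix has masked rows; drop them first")
  n <- nrow(coact)
  if (n < 3) stop("need at least 3 regulators")
  d <- stats::as.dist(1 - coact)
  tree <- stats::hclust(d, method = "average")
  ks <- 2:min(6, n - 1)
  sil <- vapply(ks, function(kk) {
    cl <- stats::cutree(tree, k = kk)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, 0)
  names(sil) <- ks
  degenerate <- FALSE
  if (is.null(k)) {
    best <- max(sil)
    k <- ks[which(sil >= best - 1e-12)[1]]   # ties toward smaller k
    if (best < 0.25) {
      degenerate <- TRUE
      warning("silhouette profile is degenerate; module structure is weak")
    }
  }
  modules <- stats::cutree(tree, k = k)
  list(modules = modules, k = as.integer(k), silhouette = sil,
       degenerate = degenerate, linkage = "average", tree = tree)
}

#' Regress regulator activity on a covariate
#'
#' Ordinary least squares of each regulator's activity on either the
#' regulator's own (log-normalized) expression or on an external per-sample
#' covariate such as the fraction of sporulating cells.
#'
#' @param activity activity matrix (regulators x samples).
#' @param covariate either a genes x samples normalized matrix (regulator
#'   expression looked up via `regulator_gene`) or a named numeric vector
#'   keyed by sample.
#' @param regulator_gene named character vector regulator -> gene id; needed
#'   when `covariate` is an expression matrix.
#' @return list with `per_regulator` data.frame (regulator, r_squared,
#'   slope, flag) and `mean_r2`, `se_r2` across regulators with defined fits.
#' @export
activity_fits <- function(activity, covariate, regulator_gene = NULL) {
  regs <- rownames(activity)
  rows <- lapply(regs, function(rg) {
    y <- activity[rg, ]
    x <- if (is.matrix(covariate)) {
      g <- regulator_gene[[rg]]
      if (is.null(g) || is.na(g) || !g %in% rownames(covariate))
        return(data.frame(regulator = rg, r_squared = NA_real_,
                          slope = NA_real_, flag = "no_regulator_gene"))
      covariate[g, colnames(activity)]
    } else covariate[colnames(activity)]
    if (anyNA(y) || anyNA(x))
      return(data.frame(regulator = rg, r_squared = NA_real_,
                        slope = NA_real_, flag = "missing_values"))
    if (stats::sd(x) == 0)
      return(data.frame(regulator = rg, r_squared = NA_real_,
                        slope = NA_real_, flag = "constant_covariate"))
    fit <- stats::lm(y ~ x)
    data.frame(regulator = rg, r_squared = summary(fit)$r.squared,
               slope = stats::coef(fit)[["x"]], flag = "ok")
  })
  per <- do.call(rbind, rows)
  r2 <- per$r_squared[per$flag == "ok"]
  list(per_regulator = per,
       mean_r2 = mean(r2),
       se_r2 = stats::sd(r2) / sqrt(length(r2)))
}
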