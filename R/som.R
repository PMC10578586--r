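#' Hexagonal grid coordinates for a self-organizing map
#'
#' @param h,w grid height and width (units).
#' @return data.frame of unit positions (`x`, `y`) in hexagonal (offset-row)
#'   layout, one row per unit, row-major order.
#' @export
som_grid <- function(h, w) {
  if (h < 1 || w < 1) stop("empty grid")
  ij <- expand.grid(col = seq_len(w), row = seq_len(h))
  data.frame(row = ij$row, col = ij$col,
             x = ij$col + 0.5 * (ij$row %% 2),
             y = ij$row * sqrt(3) / 2)
}

#' Train a batch self-organizing map of expression profiles
#'
#' Batch Kohonen training on a hexagonal grid: each epoch assigns every gene
#' to its best-matching unit (BMU) and replaces each codebook by the
#' neighborhood-weighted mean of all gene profiles, with a Gaussian
#' neighborhood whose radius shrinks linearly over epochs. Deterministic
#' given the seed.
#'
#' @param z_profiles genes x features matrix (standardized expression
#'   profiles; rownames = gene ids).
#' @param grid `c(h, w)` grid dimensions (default `c(10, 10)`).
#' @param epochs number of batch epochs (default 50).
#' @param seed RNG seed for codebook initialization.
#' @return object of class `som_map`: `codebook` (units x features),
#'   `assignment` (named unit index per gene), `grid` (from [som_grid()]),
#'   `qe` (quantization error per epoch, computed after each batch update),
#'   and training metadata.
#' @export
train_som <- function(z_profiles, grid = c(10, 10), epochs = 50, seed = 1) {
  X <- as.matrix(z_profiles)
  h <- grid[1]; w <- grid[2]
  g <- som_grid(h, w)
  n_units <- nrow(g)
  if (n_units > nrow(X))
    warning("more SOM units than genes; some units will stay empty")
  gd2 <- as.matrix(stats::dist(g[, c("x", "y")]))^2   # squared grid distances
  set.seed(seed)
  init_idx <- sample(nrow(X), n_units, replace = n_units > nrow(X))
  codebook <- X[init_idx, , drop = FALSE] +
    matrix(stats::rnorm(n_units * ncol(X), sd = 1e-3), n_units)
  rownames(codebook) <- paste0("u", seq_len(n_units))
  sigma_end <- 0.5
  sigma0 <- max(max(sqrt(gd2)) / 2, sigma_end)
  xsq <- rowSums(X^2)
  bmu_of <- function(cb) {
    # squared Euclidean distances genes x units via the expansion trick
    d2 <- outer(xsq, rowSums(cb^2), "+") - 2 * X %*% t(cb)
    list(bmu = max.col(-d2, ties.method = "first"),
         d2 = pmax(d2, 0))
  }
  qe <- numeric(epochs)
  a <- bmu_of(codebook)
  for (e in seq_len(epochs)) {
    sigma <- sigma0 + (sigma_end - sigma0) * (e - 1) / max(1, epochs - 1)
    H <- exp(-gd2 / (2 * sigma^2))        # units x units neighborhood
    W <- H[a$bmu, , drop = FALSE]         # genes x units weights
    denom <- colSums(W)
    upd <- t(W) %*% X / denom
    nonempty <- denom > 1e-12
    codebook[nonempty, ] <- upd[nonempty, , drop = FALSE]
    a <- bmu_of(codebook)                 # post-update assignment
    qe[e] <- mean(sqrt(a$d2[cbind(seq_len(nrow(X)), a$bmu)]))
  }
  structure(list(codebook = codebook,
                 assignment = stats::setNames(a$bmu, rownames(X)),
                 grid = g, h = h, w = w, qe = qe, epochs = epochs,
                 seed = seed, sigma0 = sigma0, sigma_end = sigma_end),
            class = "som_map")
}

relative_shannon <- function(labels) {
  n <- length(labels)
  if (n < 2) return(NA_real_)
  p <- table(labels) / n
  H <- -sum(p * log(p))
  min(max(H / log(n), 0), 1)   # clamp float round-off at the anchors
}

#' Operon coherence of a self-organizing map
#'
#' Quantifies whether genes mapping to the same meta-gene (SOM unit) tend to
#' come from the same operon: the relative Shannon diversity of operon labels
#' within each unit (0 = all genes from one operon, 1 = all from distinct
#' operons), the converse meta-gene diversity within each operon, observed
#' same-strand pairwise start-codon distances within units against a
#' label-permutation expectation, and a permutation test of same-operon
#' co-assignment.
#'
#' @param som a [train_som()] result.
#' @param operon_map named character vector gene -> operon id.
#' @param gene_starts data.frame with rownames = gene ids and columns
#'   `start_bp`, `strand` (`"+"`/`"-"`).
#' @param n_perm number of permutations (default 200).
#' @param seed RNG seed for the permutations.
#' @return list: `unit_diversity` (per unit: n_genes, relative Shannon
#'   operon diversity; units with < 2 annotated genes are skipped and listed
#'   in `skipped_units`), `operon_diversity` (per operon across units),
#'   `distances` (observed and permutation-expected same-strand start-codon
#'   distances, per strand), `coassignment` (observed same-operon same-unit
#'   pair fraction, permutation values, one-sided p).
#' @export
operon_coherence <- function(som, operon_map, gene_starts, n_perm = 200,
                             seed = 1) {
  genes <- intersect(names(som$assignment), names(operon_map))
  asg <- som$assignment[genes]
  ops <- operon_map[genes]
  units <- sort(unique(asg))
  n_in_unit <- table(asg)
  skipped <- as.integer(names(n_in_unit)[n_in_unit < 2])
  keep_units <- setdiff(units, skipped)
  unit_div <- data.frame(
    unit = keep_units,
    n_genes = as.integer(n_in_unit[as.character(keep_units)]),
    operon_diversity = vapply(keep_units, function(u)
      relative_shannon(ops[asg == u]), 0))
  op_tab <- table(ops)
  keep_ops <- names(op_tab)[op_tab >= 2]
  operon_div <- data.frame(
    operon = keep_ops,
    n_genes = as.integer(op_tab[keep_ops]),
    metagene_diversity = vapply(keep_ops, function(o)
      relative_shannon(asg[ops == o]), 0))

  strand <- as.character(gene_starts[genes, "strand"])
  start <- gene_starts[genes, "start_bp"]
  pair_dists <- function(assignment) {
    out <- list(`+` = numeric(0), `-` = numeric(0))
    for (u in unique(assignment)) {
      for (s in c("+", "-")) {
        sel <- assignment == u & strand == s
        if (sum(sel) >= 2)
          out[[s]] <- c(out[[s]], as.numeric(stats::dist(start[sel])))
      }
    }
    out
  }
  same_operon_coassign <- function(assignment) {
    # fraction of same-operon gene pairs that share a unit
    num <- 0; den <- 0
    for (o in keep_ops) {
      a <- assignment[ops == o]
      den <- den + choose(length(a), 2)
      num <- num + sum(choose(table(a), 2))
    }
    if (den == 0) NA_real_ else num / den
  }
  obs_d <- pair_dists(asg)
  obs_co <- same_operon_coassign(asg)
  set.seed(seed)
  perm_d <- list(`+` = numeric(0), `-` = numeric(0))
  perm_co <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pa <- sample(asg)                     # permute unit labels over genes
    names(pa) <- genes
    pd <- pair_dists(pa)
    perm_d$`+` <- c(perm_d$`+`, pd$`+`)
    perm_d$`-` <- c(perm_d$`-`, pd$`-`)
    perm_co[b] <- same_operon_coassign(pa)
  }
  p_co <- (1 + sum(perm_co >= obs_co)) / (1 + n_perm)
  list(unit_diversity = unit_div, operon_diversity = operon_div,
       skipped_units = skipped,
       distances = list(observed = obs_d, expected = perm_d),
       coassignment = list(observed = obs_co, perm = perm_co, p = p_co))
}

#' Per-meta-gene summaries of the expression map
#'
#' @param som a [train_som()] result.
#' @param normalized log-normalized genes x samples matrix.
#' @param pca optional [pca_profiles()] result (for mean PC loadings).
#' @param categories optional named character vector gene -> functional
#'   category.
#' @param regulons optional [regulon_set()].
#' @return list: `units` data.frame (unit, n_genes, expression SD across
#'   samples of the unit mean profile, mean loadings on the first three PCs),
#'   `mean_expression` (units x samples), `category_fractions` and
#'   `regulon_fractions` (units x labels, fraction of the unit's genes
#'   annotated with each label).
#' @export
metagene_summaries <- function(som, normalized, pca = NULL,
                               categories = NULL, regulons = NULL) {
  genes <- intersect(names(som$assignment), rownames(normalized))
  asg <- som$assignment[genes]
  units <- sort(unique(asg))
  me <- t(vapply(units, function(u)
    colMeans(normalized[genes[asg == u], , drop = FALSE]),
    numeric(ncol(normalized))))
  rownames(me) <- paste0("u", units)
  sdv <- apply(me, 1, stats::sd)
  load3 <- NULL
  if (!is.null(pca)) {
    npc <- min(3, ncol(pca$loadings))
    load3 <- t(vapply(units, function(u)
      colMeans(pca$loadings[genes[asg == u], seq_len(npc), drop = FALSE]),
      numeric(npc)))
  }
  units_df <- data.frame(unit = units,
                         n_genes = as.integer(table(asg)[as.character(units)]),
                         expr_sd = sdv)
  if (!is.null(load3)) units_df <- cbind(units_df, load3)
  frac_table <- function(lab) {
    lab <- lab[intersect(names(lab), genes)]
    lv <- sort(unique(lab))
    vals <- lapply(units, function(u) {
      gs <- genes[asg == u]
      vapply(lv, function(l)
        sum(lab[intersect(gs, names(lab))] == l) / length(gs), 0)
    })
    matrix(unlist(vals), nrow = length(units), byrow = TRUE,
           dimnames = list(paste0("u", units), lv))
  }
  cf <- if (!is.null(categories)) frac_table(categories) else NULL
  rf <- NULL
  if (!is.null(regulons)) {
    vals <- lapply(units, function(u) {
      gs <- genes[asg == u]
      vapply(seq_len(nrow(regulons)), function(i)
        mean(gs %in% regulons$targets[[i]]), 0)
    })
    rf <- matrix(unlist(vals), nrow = length(units), byrow = TRUE,
                 dimnames = list(paste0("u", units), regulons$regulator))
  }
  list(units = units_df, mean_expression = me,
       category_fractions = cf, regulon_fractions = rf)
}
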