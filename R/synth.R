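#' Default synthesis configuration
#'
#' Ground-truthed generator settings emulating the study design: colony
#' transcriptomes sampled over days 1, 2, 4 and 7 at the colony edge and
#' center, with a latent growth-to-dormancy axis driving two antagonistic
#' modules of regulators.
#'
#' @param seed RNG seed.
#' @param n_genes number of genes.
#' @param operon_mean mean operon size (geometric distribution, capped).
#' @param operon_cap maximal operon size.
#' @param n_regulators number of regulators (default 17, split between a
#'   vegetative and a dormancy module).
#' @param frac_repressor fraction of regulators that are repressors.
#' @param p_within probability that an operon member joins the operon's
#'   regulon.
#' @param beta activity-to-expression coupling on the log2 scale.
#' @param baseline_mean,baseline_sd log2 baseline expression distribution.
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2).
#' @param depth sequencing depth per sample.
#' @param days,positions,genotypes,replicates design grid.
#' @param delta suppression of dormancy-axis progression in evolved samples.
#' @param d_jitter_sd jitter of the latent dormancy value per sample.
#' @return list of class `synthesis_config`.
#' @export
synthesis_config <- function(seed = 1, n_genes = 400, operon_mean = 3,
                             operon_cap = 8, n_regulators = 17,
                             frac_repressor = 0.4, p_within = 0.9,
                             beta = 1, baseline_mean = 5, baseline_sd = 1.5,
                             dispersion = 0.05, depth = 5e5,
                             days = c(1, 2, 4, 7),
                             positions = c("edge", "center"),
                             genotypes = "ancestor", replicates = 2,
                             delta = 0.6, d_jitter_sd = 0.02) {
  stopifnot(n_genes > 0, dispersion > 0, depth > 0, replicates >= 1,
            length(days) >= 1)
  structure(as.list(environment()), class = "synthesis_config")
}

#' Generate a regulon annotation with operon structure
#'
#' Genes are partitioned into operons (geometric sizes, capped) laid out
#' sequentially on a synthetic chromosome with one strand per operon.
#' Regulon targets are drawn operon-wise so that operon members tend to share
#' regulons; regulators are alternately assigned to the vegetative or
#' dormancy module.
#'
#' @param config a [synthesis_config()].
#' @return list: `regulons` (a [regulon_set()] with a `module` column),
#'   `annotation` (data.frame gene_id, operon_id, start_bp, strand).
#' @export
gen_regulons_operons <- function(config) {
  set.seed(config$seed)
  if (config$n_genes < 10 * config$n_regulators)
    warning("fewer than 10 genes per regulator; regulons will be small")
  sizes <- integer(0); total <- 0
  while (total < config$n_genes) {
    s <- min(1 + stats::rgeom(1, 1 / config$operon_mean), config$operon_cap)
    sizes <- c(sizes, s); total <- total + s
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (total - config$n_genes)
  sizes <- sizes[sizes > 0]
  gene_id <- sprintf("g%04d", seq_len(config$n_genes))
  operon_id <- rep(sprintf("op%03d", seq_along(sizes)), sizes)
  strand <- rep(sample(c("+", "-"), length(sizes), replace = TRUE), sizes)
  # genes within an operon 200 bp apart; 1500 bp between operons
  within_pos <- stats::ave(seq_along(operon_id), operon_id,
                           FUN = seq_along)
  op_index <- rep(seq_along(sizes), sizes)
  op_starts <- cumsum(c(0, (sizes * 1200 + 1500)[-length(sizes)]))
  start_bp <- op_starts[op_index] + (within_pos - 1) * 1200 + 1
  annotation <- data.frame(gene_id = gene_id, operon_id = operon_id,
                           start_bp = start_bp, strand = strand)
  n_ops <- length(sizes)
  regs <- sprintf("reg%02d", seq_len(config$n_regulators))
  mode <- rep("activator", config$n_regulators)
  mode[seq_len(round(config$frac_repressor * config$n_regulators))] <-
    "repressor"
  mode <- sample(mode)
  module <- rep(c("vegetative", "dormancy"),
                length.out = config$n_regulators)
  # each operon has one primary regulator; a minority of operons also join a
  # second, coherently acting regulon (same product of mode sign and module
  # sign), so regulons overlap the way coherent co-regulation does
  owner <- sample(rep(seq_len(config$n_regulators), length.out = n_ops))
  eff_sign <- ifelse(mode == "repressor", -1, 1) *
    ifelse(module == "dormancy", 1, -1)
  second <- rep(NA_integer_, n_ops)
  shared <- which(stats::runif(n_ops) < 0.15)
  for (o in shared) {
    coherent <- which(eff_sign == eff_sign[owner[o]])
    second[o] <- sample(coherent, 1)
  }
  targets <- lapply(seq_len(config$n_regulators), function(i) {
    ops <- which(owner == i | (!is.na(second) & second == i))
    tg <- unlist(lapply(ops, function(o) {
      members <- gene_id[op_index == o]
      members[stats::runif(length(members)) < config$p_within]
    }))
    if (length(tg) == 0) tg <- gene_id[op_index == ops[1]][1]
    unique(tg)
  })
  reg <- regulon_set(regs, mode, targets,
                     regulator_gene = vapply(targets, `[`, "", 1))
  reg$module <- module
  list(regulons = reg, annotation = annotation)
}

latent_dormancy <- function(config, meta, jitter = TRUE) {
  d <- meta$day / 8 + ifelse(meta$position == "center", 0.1, 0)
  d <- d * ifelse(meta$genotype == "ancestor", 1, 1 - config$delta)
  if (jitter && config$d_jitter_sd > 0)
    d <- d + stats::rnorm(nrow(meta), sd = config$d_jitter_sd)
  pmin(pmax(d, 0), 1)
}

#' Generate a regulon-structured synthetic transcriptome
#'
#' Each sample has a latent dormancy value `d` determined by its design cell
#' (increasing in day, higher at the colony center, suppressed in evolved
#' genotypes) plus a small jitter. Dormancy-module regulators have true
#' activity `2d - 1`, vegetative-module regulators `-(2d - 1)`. Gene log2
#' means are the baseline plus `beta` times the summed signed regulatory
#' input (sign flipped for repressors), and counts are drawn from a negative
#' binomial at the configured depth.
#'
#' @param config a [synthesis_config()].
#' @param regulons optional [gen_regulons_operons()] result (generated from
#'   the config when omitted).
#' @return list: `counts` (genes x samples), `meta` (sample metadata),
#'   `truth` (true activities, latent `d`, regulons, annotation,
#'   composition).
#' @export
gen_transcriptome <- function(config, regulons = NULL) {
  if (is.null(regulons)) regulons <- gen_regulons_operons(config)
  reg <- regulons$regulons
  set.seed(config$seed + 1)
  meta <- expand.grid(replicate = seq_len(config$replicates),
                      position = config$positions,
                      day = config$days,
                      genotype = config$genotypes,
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_d%d_%s_r%d", meta$genotype, meta$day,
                            meta$position, meta$replicate)
  meta <- meta[, c("sample_id", "day", "position", "genotype", "replicate")]
  d <- latent_dormancy(config, meta)
  axis <- 2 * d - 1
  act <- matrix(NA_real_, nrow(reg), nrow(meta),
                dimnames = list(reg$regulator, meta$sample_id))
  for (i in seq_len(nrow(reg)))
    act[i, ] <- if (reg$module[i] == "dormancy") axis else -axis
  gene_id <- regulons$annotation$gene_id
  baseline <- stats::rnorm(length(gene_id), config$baseline_mean,
                           config$baseline_sd)
  signed_input <- matrix(0, length(gene_id), nrow(meta),
                         dimnames = list(gene_id, meta$sample_id))
  for (i in seq_len(nrow(reg))) {
    sgn <- if (reg$mode[i] == "repressor") -1 else 1
    tg <- reg$targets[[i]]
    signed_input[tg, ] <- signed_input[tg, ] +
      sgn * matrix(act[i, ], length(tg), nrow(meta), byrow = TRUE)
  }
  log2mu <- pmin(baseline + config$beta * signed_input, 30)
  mu <- 2^log2mu
  mu <- sweep(mu, 2, colSums(mu), "/") * config$depth
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$dispersion),
                   nrow(mu), dimnames = dimnames(mu))
  comp <- gen_composition(meta, d)
  list(counts = counts, meta = meta,
       truth = list(activity = act, d = d, regulons = reg,
                    annotation = regulons$annotation, composition = comp))
}

#' Cell-type composition along the dormancy axis
#'
#' Smooth parametric map from the latent dormancy value to fractions of
#' filamentous, vegetative and sporulating cells and spores on the simplex:
#' sporulating cells peak at intermediate `d`, spores increase monotonically
#' and dominate at `d = 1`, and there are no spores at `d = 0`.
#'
#' @param meta per-sample design data.frame (carried through to the output).
#' @param d latent dormancy values in `[0, 1]`, one per row of `meta`.
#' @return data.frame `meta` plus columns `filamentous`, `vegetative`,
#'   `sporulating`, `spores` summing to 1 exactly per row.
#' @export
gen_composition <- function(meta, d) {
  if (any(d < 0 | d > 1)) stop("d must lie in [0, 1]")
  raw <- cbind(filamentous = 0.25 * (1 - d),
               vegetative = (1 - d),
               sporulating = 1.2 * d * (1 - d),
               spores = d^2)
  frac <- raw / rowSums(raw)
  cbind(meta, as.data.frame(frac))
}

#' Generate a synthetic colony plate image
#'
#' Dark background, brighter Petri-dish disk, colony disk with a
#' Gaussian-blurred edge, multiplied by a linear shading field and degraded
#' with additive Gaussian noise. The exact radius, center and shading are
#' recorded as ground truth.
#'
#' @param radius true colony radius (px).
#' @param center colony/dish center `c(x, y)` (px).
#' @param dish_radius dish radius (px, > radius).
#' @param size frame side length (px).
#' @param blur_sigma Gaussian edge blur of the colony boundary (px).
#' @param shading peak-to-peak relative amplitude of the linear shading
#'   field across the frame (e.g. 0.2 for 20 percent).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed RNG seed (noise only).
#' @return list: `img` (matrix in `[0, 1]`), `truth` (radius, center,
#'   dish_radius, blur_sigma, shading, noise_sd).
#' @export
gen_colony_image <- function(radius, center = NULL, dish_radius = NULL,
                             size = 512, blur_sigma = 2, shading = 0,
                             noise_sd = 0, seed = 1) {
  if (is.null(center)) center <- c(size / 2, size / 2)
  if (is.null(dish_radius)) dish_radius <- 0.42 * size
  if (!(radius < dish_radius && dish_radius < size))
    stop("need radius < dish_radius < frame size")
  yy <- matrix(seq_len(size), size, size)
  xx <- matrix(seq_len(size), size, size, byrow = TRUE)
  dist <- sqrt((xx - center[1])^2 + (yy - center[2])^2)
  img <- 0.08 + 0.27 * (dist <= dish_radius)
  edge <- if (blur_sigma > 0) stats::pnorm((radius - dist) / blur_sigma) else
    as.numeric(dist <= radius)
  img <- img + 0.5 * edge
  img <- img * (1 + shading * (xx / size - 0.5))
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(size^2, sd = noise_sd), size)
  }
  img <- pmin(pmax(img, 0), 1)
  list(img = img,
       truth = list(radius = radius, center = center,
                    dish_radius = dish_radius, blur_sigma = blur_sigma,
                    shading = shading, noise_sd = noise_sd))
}

#' Generate a colony image time series
#'
#' One image per time point from [gen_colony_image()] with a shared dish and
#' center, plus a series manifest. With `out_dir` set, images are written as
#' PNG and the manifest as CSV.
#'
#' @param radii_px increasing colony radii (px).
#' @param times_h acquisition times (h), same length.
#' @param pixel_size_mm pixel size recorded in the manifest.
#' @param out_dir optional output directory.
#' @param ... forwarded to [gen_colony_image()].
#' @return list: `images` (list of matrices), `manifest` (data.frame path,
#'   time_h, pixel_size_mm), `truth` (per-image ground truth).
#' @export
gen_image_series <- function(radii_px, times_h = seq_along(radii_px) * 24,
                             pixel_size_mm = NA_real_, out_dir = NULL, ...) {
  if (length(radii_px) == 0)
    return(list(images = list(),
                manifest = data.frame(path = character(0),
                                      time_h = numeric(0),
                                      pixel_size_mm = numeric(0)),
                truth = list()))
  if (is.unsorted(radii_px, strictly = FALSE))
    stop("radii must be non-decreasing")
  gen <- lapply(radii_px, function(r) gen_colony_image(r, ...))
  paths <- rep(NA_character_, length(radii_px))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, sprintf("colony_%03d.png",
                                        seq_along(radii_px)))
    for (i in seq_along(gen)) png::writePNG(gen[[i]]$img, paths[i])
  }
  manifest <- data.frame(path = paths, time_h = times_h,
                         pixel_size_mm = pixel_size_mm)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  list(images = lapply(gen, `[[`, "img"), manifest = manifest,
       truth = lapply(gen, `[[`, "truth"))
}
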