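#' Read a gene count table from TSV
#'
#' First column = gene id, remaining columns = samples.
#'
#' @param path TSV file.
#' @return integer matrix genes x samples.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  storage.mode(m) <- "integer"
  if (any(m < 0) || anyNA(m)) stop("counts must be non-negative integers")
  m
}

#' Write a gene count table as TSV
#' @param counts genes x samples matrix.
#' @param path output file.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read counts from MatrixMarket with row/column label files
#'
#' @param mtx_path .mtx file; `rows_path` and `cols_path` are plain text,
#'   one label per line (gene ids, sample ids).
#' @return integer matrix genes x samples.
#' @export
read_counts_mtx <- function(mtx_path, rows_path, cols_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(rows_path)
  colnames(m) <- readLines(cols_path)
  storage.mode(m) <- "integer"
  m
}

#' Read sample metadata TSV
#'
#' Requires columns sample_id, day, position, genotype, replicate (lineage
#' optional); positions must be edge or center.
#'
#' @param path TSV file.
#' @return data.frame keyed by sample_id.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "day", "position", "genotype", "replicate")
  if (!all(need %in% names(df)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (!all(df$position %in% c("edge", "center")))
    stop("position must be 'edge' or 'center'")
  if (anyNA(df[need])) stop("incomplete sample metadata")
  df
}

#' Read a regulon table from TSV
#'
#' Columns: regulator, mode (activator/repressor), regulator_gene (may be
#' empty), targets (comma-separated gene ids).
#'
#' @param path TSV file.
#' @return a [regulon_set()].
#' @export
read_regulons_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  regulon_set(df$regulator, df$mode,
              strsplit(df$targets, ","),
              regulator_gene = ifelse(nzchar(df$regulator_gene),
                                      df$regulator_gene, NA))
}

#' Write a regulon table as TSV
#' @param regulons a [regulon_set()].
#' @param path output file.
#' @export
write_regulons_tsv <- function(regulons, path) {
  df <- data.frame(regulator = regulons$regulator, mode = regulons$mode,
                   regulator_gene = ifelse(is.na(regulons$regulator_gene),
                                           "", regulons$regulator_gene),
                   targets = vapply(regulons$targets, paste, "",
                                    collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write regulons in GMT format (mode encoded in the description field)
#' @param regulons a [regulon_set()].
#' @param path output file.
#' @export
write_gmt <- function(regulons, path) {
  lines <- vapply(seq_len(nrow(regulons)), function(i)
    paste(c(regulons$regulator[i], regulons$mode[i],
            regulons$targets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
}

#' Read regulons from GMT format (mode taken from the description field)
#' @param path GMT file.
#' @return a [regulon_set()].
#' @export
read_gmt <- function(path) {
  parts <- strsplit(readLines(path), "\t")
  regulon_set(vapply(parts, `[`, "", 1),
              vapply(parts, `[`, "", 2),
              lapply(parts, function(p) p[-(1:2)]))
}

#' Read operon/coordinate annotation TSV
#'
#' Columns: gene_id, operon_id, start_bp, strand (+/-).
#'
#' @param path TSV file.
#' @return data.frame with rownames = gene ids.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  rownames(df) <- df$gene_id
  df
}

#' Load a simulation configuration from YAML
#'
#' Blocks `domain`, `genotypes` (list of genotype parameter sets) and
#' `protocol`; missing entries fall back to the package defaults.
#'
#' @param path YAML file.
#' @return list with `domain` ([radial_domain()]), `genotypes` (list of
#'   [genotype_params()]), `protocol` ([passage_protocol()]).
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  dom <- do.call(radial_domain, cfg$domain %||% list())
  gts <- lapply(cfg$genotypes %||% list(list(id = "wt")),
                function(g) do.call(genotype_params, g))
  prot <- do.call(passage_protocol, cfg$protocol %||% list())
  list(domain = dom, genotypes = gts, protocol = prot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write colony profile snapshots as CSV
#'
#' One row per radial node and recorded time: r, per-genotype V and S
#' columns, and N.
#'
#' @param snapshots list of `radial_state` (from [simulate_colony()]).
#' @param path output CSV.
#' @export
write_snapshots_csv <- function(snapshots, path) {
  rows <- lapply(snapshots, function(s) {
    df <- data.frame(t = s$t, r = s$r)
    for (g in colnames(s$V)) {
      df[[paste0("V_", g)]] <- s$V[, g]
      df[[paste0("S_", g)]] <- s$S[, g]
    }
    df$N <- s$N
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Write per-cycle passaging summaries as CSV
#'
#' @param cycles list from [run_serial_passages()].
#' @param path output CSV.
#' @export
write_cycles_csv <- function(cycles, path) {
  rows <- lapply(cycles, function(cy) {
    fr <- cy$edge_genotype_fractions
    df <- data.frame(cycle = cy$cycle, final_radius = cy$final_radius,
                     edge_spore_fraction = cy$edge_spore_fraction,
                     center_spore_fraction = cy$center_spore_fraction)
    for (g in names(fr)) df[[paste0("edge_frac_", g)]] <- fr[[g]]
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}
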