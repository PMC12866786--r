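#' Quality-control configuration
#'
#' Defaults follow the standard single-cell and spot-level filters: cells
#' with fewer than 200 or more than 2500 expressed genes, or more than 5%
#' mitochondrial transcripts, are removed, as are genes expressed in fewer
#' than 3 retained cells; spots with detected-gene counts below the 5th
#' percentile of their section are removed, as are genes detected in fewer
#' than 10 retained spots.
#'
#' @param min_genes_per_cell,max_genes_per_cell expressed-gene bounds per cell.
#' @param max_mito_fraction maximum mitochondrial transcript fraction.
#' @param min_cells_per_gene minimum retained cells expressing a gene.
#' @param spot_gene_count_percentile per-section percentile below which
#'   spots are dropped.
#' @param min_spots_per_gene minimum retained spots detecting a gene.
#' @return object of class `qc_config`.
#' @export
qc_config <- function(min_genes_per_cell = 200, max_genes_per_cell = 2500,
                      max_mito_fraction = 0.05, min_cells_per_gene = 3,
                      spot_gene_count_percentile = 5,
                      min_spots_per_gene = 10) {
  if (min_genes_per_cell >= max_genes_per_cell)
    stop_param("min_genes_per_cell must be < max_genes_per_cell")
  if (spot_gene_count_percentile < 0 || spot_gene_count_percentile > 100)
    stop_param("spot_gene_count_percentile must be in [0, 100]")
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_genes_per_cell = max_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene,
                 spot_gene_count_percentile = spot_gene_count_percentile,
                 min_spots_per_gene = min_spots_per_gene),
            class = "qc_config")
}

#' Filter cells and genes of a single-cell count matrix
#'
#' Cell filters run first: a cell is removed when its expressed-gene count
#' (genes with count > 0) falls outside `[min_genes, max_genes]` or its
#' mitochondrial transcript fraction exceeds `max_mito_fraction` (strict).
#' Genes expressed in fewer than `min_cells_per_gene` of the retained
#' cells are then removed. Because dropping genes lowers the remaining
#' cells' expressed-gene counts, the two passes repeat until nothing
#' changes, so the returned matrix is a fixed point of the filter.
#'
#' @param counts cell x gene nonnegative integer matrix.
#' @param mito_flags logical per-gene mitochondrial flag.
#' @param cfg a [qc_config()].
#' @return list with `counts` (filtered), `removed_cells` (data.frame:
#'   cell, reason), `removed_genes` (character), `empty` (TRUE when
#'   nothing survives).
#' @export
qc_filter_cells <- function(counts, mito_flags, cfg = qc_config()) {
  if (any(counts < 0)) stop_param("counts must be nonnegative")
  if (length(mito_flags) != ncol(counts))
    stop_param("mito_flags must have one entry per gene")
  cells <- rownames(counts) %||% sprintf("c%05d", seq_len(nrow(counts)))
  genes <- colnames(counts) %||% sprintf("g%05d", seq_len(ncol(counts)))

  keep_cell <- rep(TRUE, nrow(counts))
  keep_gene <- rep(TRUE, ncol(counts))
  reason <- rep(NA_character_, nrow(counts))
  repeat {
    sub <- counts[keep_cell, keep_gene, drop = FALSE]
    n_expr <- rowSums(sub > 0)
    total <- rowSums(sub)
    mito <- rowSums(sub[, mito_flags[keep_gene], drop = FALSE])
    mito_frac <- ifelse(total > 0, mito / total, 0)
    bad <- rep(NA_character_, nrow(sub))
    bad[n_expr > cfg$max_genes_per_cell] <- "too_many_genes"
    bad[n_expr < cfg$min_genes_per_cell] <- "too_few_genes"
    bad[is.na(bad) & mito_frac > cfg$max_mito_fraction] <- "high_mito"
    idx <- which(keep_cell)
    reason[idx[!is.na(bad)]] <- bad[!is.na(bad)]
    keep_cell[idx[!is.na(bad)]] <- FALSE

    kept <- counts[keep_cell, keep_gene, drop = FALSE]
    gene_cells <- colSums(kept > 0)
    drop_gene <- which(keep_gene)[gene_cells < cfg$min_cells_per_gene]
    keep_gene[drop_gene] <- FALSE
    if (!any(!is.na(bad)) && !length(drop_gene)) break
  }

  out <- counts[keep_cell, keep_gene, drop = FALSE]
  list(counts = out,
       removed_cells = data.frame(cell = cells[!keep_cell],
                                  reason = reason[!keep_cell],
                                  stringsAsFactors = FALSE),
       removed_genes = genes[!keep_gene],
       empty = nrow(out) == 0 || ncol(out) == 0)
}

#' Filter spots and genes of one spatial section
#'
#' Spots whose detected-gene count lies strictly below the section's
#' `spot_gene_count_percentile` (linear-interpolation percentile) are
#' removed; genes detected in fewer than `min_spots_per_gene` retained
#' spots are then removed. The percentile cutoff is a per-section
#' constant: pass the recorded `threshold` back in to re-apply the filter
#' without re-deriving the percentile from the already-filtered matrix
#' (re-deriving it would shave a further 5% tail on every run).
#'
#' @param counts spot x gene nonnegative integer matrix for one section.
#' @param cfg a [qc_config()].
#' @param threshold reuse a previously computed detected-gene cutoff
#'   instead of recomputing the percentile.
#' @return list with `counts`, `removed_spots` (character), `removed_genes`
#'   (character), `threshold` (the percentile value used).
#' @export
qc_filter_spots <- function(counts, cfg = qc_config(), threshold = NULL) {
  if (any(counts < 0)) stop_param("counts must be nonnegative")
  if (nrow(counts) < 20)
    warning("section has fewer than 20 spots; percentile filter is unstable")
  spots <- rownames(counts) %||% sprintf("s%06d", seq_len(nrow(counts)))

  n_genes <- rowSums(counts > 0)
  thr <- threshold %||%
    percentile(n_genes, cfg$spot_gene_count_percentile)
  keep_spot <- n_genes >= thr        # strictly-below spots are removed

  kept <- counts[keep_spot, , drop = FALSE]
  gene_spots <- colSums(kept > 0)
  keep_gene <- gene_spots >= cfg$min_spots_per_gene
  list(counts = kept[, keep_gene, drop = FALSE],
       removed_spots = spots[!keep_spot],
       removed_genes = colnames(counts)[!keep_gene] %||% which(!keep_gene),
       threshold = thr)
}
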