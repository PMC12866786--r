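#' Build a cell-type signature panel for simulation
#'
#' Constructs a gene panel emulating the single-cell reference used for
#' deconvolution: each cell type receives a disjoint block of marker genes
#' with elevated mean expression on top of a shared log-normal baseline,
#' genes are laid out on chromosomes in strictly increasing ordinal
#' position, and a fraction of genes is flagged as mitochondrial.
#'
#' @param n_genes total number of genes; must be at least `10 * n_types`
#'   so every type gets a 10-gene marker block.
#' @param n_types number of cell types.
#' @param n_chroms number of chromosomes genes are spread over.
#' @param mito_fraction fraction of genes flagged mitochondrial, in
#'   `[0, 0.5)`; `floor(mito_fraction * n_genes)` genes are flagged.
#' @param seed integer seed; identical calls are bit-identical.
#' @param type_names optional character vector of cell-type names; defaults
#'   to `AT2-like`, `AT2`, `fibroblast`, `macrophage`, then `type5`, ...
#' @param marker_boost multiplicative elevation of marker-gene means.
#'
#' @return An object of class `signature_panel`: a list with `genes`,
#'   `chrom`, `ord_pos`, `mito_flag`, `mu` (gene x type mean matrix),
#'   `dispersion` (per-gene negative-binomial dispersion, variance
#'   `mu + dispersion * mu^2`), and `markers` (list of marker genes per type).
#' @export
make_signature_panel <- function(n_genes, n_types, n_chroms = 4,
                                 mito_fraction = 0.02, seed = 1,
                                 type_names = NULL, marker_boost = 10) {
  if (n_genes < n_types * 10)
    stop_param("n_genes must be >= 10 * n_types (got ", n_genes, " for ",
               n_types, " types)")
  if (mito_fraction < 0 || mito_fraction >= 0.5)
    stop_param("mito_fraction must be in [0, 0.5)")
  if (n_chroms < 1 || n_chroms > n_genes)
    stop_param("n_chroms must be in [1, n_genes]")

  if (is.null(type_names)) {
    base_names <- c("AT2-like", "AT2", "fibroblast", "macrophage")
    type_names <- c(head(base_names, n_types),
                    if (n_types > 4) paste0("type", 5:n_types))
  }
  if (length(type_names) != n_types)
    stop_param("type_names must have length n_types")

  genes <- sprintf("g%05d", seq_len(n_genes))
  # contiguous, near-equal chromosome blocks; ordinal restarts per chromosome
  chrom_idx <- sort(rep_len(seq_len(n_chroms), n_genes))
  chrom <- paste0("chr", chrom_idx)
  ord_pos <- as.integer(unlist(lapply(split(seq_len(n_genes), chrom_idx),
                                      seq_along), use.names = FALSE))

  with_seed(seed, {
    baseline <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
    mu <- matrix(baseline, nrow = n_genes, ncol = n_types,
                 dimnames = list(genes, type_names))
    # disjoint 10-gene marker blocks, spread evenly along the panel
    block_starts <- floor(seq(1, n_genes - 9, length.out = n_types))
    markers <- vector("list", n_types)
    names(markers) <- type_names
    for (t in seq_len(n_types)) {
      idx <- block_starts[t]:(block_starts[t] + 9)
      mu[idx, t] <- baseline[idx] * marker_boost + median(baseline)
      markers[[t]] <- genes[idx]
    }
    n_mito <- floor(mito_fraction * n_genes)
    mito_flag <- rep(FALSE, n_genes)
    if (n_mito > 0) {
      non_marker <- setdiff(seq_len(n_genes), unlist(lapply(
        block_starts, function(s) s:(s + 9))))
      mito_flag[sample(non_marker, n_mito)] <- TRUE
    }
    dispersion <- runif(n_genes, 0.1, 0.6)
  })

  structure(list(genes = genes, chrom = chrom, ord_pos = ord_pos,
                 mito_flag = mito_flag, mu = mu, dispersion = dispersion,
                 markers = markers, seed = seed),
            class = "signature_panel")
}

#' @export
print.signature_panel <- function(x, ...) {
  cat("signature_panel:", length(x$genes), "genes x", ncol(x$mu),
      "cell types on", length(unique(x$chrom)), "chromosomes;",
      sum(x$mito_flag), "mitochondrial genes\n")
  invisible(x)
}

#' Gene annotation table of a signature panel
#'
#' @param panel a `signature_panel`.
#' @return data.frame with columns `gene`, `chrom`, `ord_pos` suitable for
#'   [order_genes()].
#' @export
panel_annotation <- function(panel) {
  data.frame(gene = panel$genes, chrom = panel$chrom,
             ord_pos = panel$ord_pos, stringsAsFactors = FALSE)
}
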