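#' Copy-number scoring configuration
#'
#' @param window_genes sliding-window width in genes (default 250; the
#'   window is centered with `floor(w/2)` genes to the left and
#'   `w - floor(w/2) - 1` to the right, truncated at chromosome ends).
#' @param reference_label cell-type label of the normal reference
#'   population (default `"AT2"`).
#' @param burden_stat `"signed_mean"` (net gain; higher = more gain) or
#'   `"mean_square"` (total aberration, sign-blind).
#' @return object of class `cnv_config`.
#' @export
cnv_config <- function(window_genes = 250, reference_label = "AT2",
                       burden_stat = c("signed_mean", "mean_square")) {
  if (window_genes < 3) stop_param("window_genes must be >= 3")
  structure(list(window_genes = window_genes,
                 reference_label = reference_label,
                 burden_stat = match.arg(burden_stat)),
            class = "cnv_config")
}

# natural chromosome order: chr1 < chr2 < chr10 < chrX (numeric before
# non-numeric, then alphabetical)
chrom_order <- function(chrom) {
  suffix <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(suffix))
  order(is.na(num), num, suffix)
}

#' Order genes along the genome
#'
#' Stable sort by (chromosome, ordinal position); chromosomes in natural
#' order (chr2 before chr10). Genes with missing annotation are excluded
#' and reported; duplicated (chromosome, ordinal) pairs are tie-broken by
#' gene id with a warning.
#'
#' @param annotation data.frame with columns `gene`, `chrom`, `ord_pos`.
#' @return data.frame ordered along the genome, with attribute `dropped`
#'   (gene ids lacking annotation).
#' @export
order_genes <- function(annotation) {
  need <- c("gene", "chrom", "ord_pos")
  if (!all(need %in% names(annotation)))
    stop_param("annotation needs columns gene, chrom, ord_pos")
  bad <- is.na(annotation$chrom) | is.na(annotation$ord_pos)
  dropped <- annotation$gene[bad]
  if (length(dropped))
    message(length(dropped), " gene(s) without annotation excluded")
  ann <- annotation[!bad, , drop = FALSE]
  dup <- duplicated(ann[, c("chrom", "ord_pos")])
  if (any(dup))
    warning(sum(dup), " duplicate (chromosome, ordinal) pair(s); ",
            "tie broken by gene id")
  co <- chrom_order(ann$chrom)
  ann <- ann[co, , drop = FALSE]
  ann <- ann[order(match(ann$chrom, unique(ann$chrom)), ann$ord_pos,
                   ann$gene), , drop = FALSE]
  rownames(ann) <- NULL
  attr(ann, "dropped") <- dropped
  ann
}

#' Mean expression profile of the reference population
#'
#' @param expr observation x gene normalized log-expression.
#' @param labels per-observation cell-type labels.
#' @param reference_label label of the normal reference population.
#' @return per-gene mean over reference observations.
#' @export
reference_profile <- function(expr, labels, reference_label = "AT2") {
  sel <- !is.na(labels) & labels == reference_label
  if (!any(sel)) stop_param("no observations with reference label '",
                            reference_label, "'")
  colMeans(expr[sel, , drop = FALSE])
}

# sparse moving-average operator: per chromosome, column j averages rows
# [j - left, j + right] clipped to the chromosome; chromosomes with < 3
# genes pass through unsmoothed.
smoothing_operator <- function(chrom, window_genes) {
  left <- floor(window_genes / 2)
  right <- window_genes - left - 1
  n <- length(chrom)
  ii <- vector("list", n); jj <- vector("list", n); vv <- vector("list", n)
  offset <- 0
  for (ch in unique(chrom)) {
    L <- sum(chrom == ch)
    if (L < 3) {
      warning("chromosome ", ch, " has fewer than 3 genes; left unsmoothed")
      for (j in seq_len(L)) {
        ii[[offset + j]] <- offset + j
        jj[[offset + j]] <- offset + j
        vv[[offset + j]] <- 1
      }
    } else {
      for (j in seq_len(L)) {
        lo <- max(1, j - left); hi <- min(L, j + right)
        ii[[offset + j]] <- offset + (lo:hi)
        jj[[offset + j]] <- rep(offset + j, hi - lo + 1)
        vv[[offset + j]] <- rep(1 / (hi - lo + 1), hi - lo + 1)
      }
    }
    offset <- offset + L
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(n, n))
}

#' Sliding-window CNV profile relative to a normal reference
#'
#' Subtracts the reference mean profile from each observation's normalized
#' log-expression and smooths the residual along genome order with a
#' centered moving average of `window_genes` genes, truncated at
#' chromosome boundaries (a window never spans two chromosomes; windows
#' shrink near chromosome ends).
#'
#' @param expr spot x gene normalized log-expression matrix (gene columns
#'   named).
#' @param reference per-gene reference mean (see [reference_profile()]),
#'   aligned to `expr` genes.
#' @param annotation gene annotation accepted by [order_genes()]; genes of
#'   `expr` missing from it are excluded.
#' @param cfg a [cnv_config()].
#' @return object of class `cnv_profile`: list with `profile` (spot x
#'   ordered-gene smoothed matrix), `genes`, `chrom`, `cfg`.
#' @export
smooth_cnv <- function(expr, reference, annotation, cfg = cnv_config()) {
  ann <- order_genes(annotation)
  ann <- ann[ann$gene %in% colnames(expr), , drop = FALSE]
  if (!nrow(ann)) stop_param("no annotated genes present in expr")
  if (is.null(names(reference))) names(reference) <- colnames(expr)
  rel <- sweep(expr[, ann$gene, drop = FALSE], 2, reference[ann$gene])
  W <- smoothing_operator(ann$chrom, cfg$window_genes)
  sm <- as.matrix(rel %*% W)
  dimnames(sm) <- list(rownames(expr), ann$gene)
  structure(list(profile = sm, genes = ann$gene, chrom = ann$chrom,
                 cfg = cfg),
            class = "cnv_profile")
}

#' Per-spot CNV burden
#'
#' Collapses a smoothed CNV profile to one scalar per spot:
#' `signed_mean` is the mean of the smoothed relative values (net gain;
#' higher values indicate more probable copy-number gain), `mean_square`
#' the mean squared deviation (total aberration, sign-blind).
#'
#' @param profile a [smooth_cnv()] result.
#' @param cfg a [cnv_config()]; its `burden_stat` selects the statistic.
#' @return named per-spot numeric vector.
#' @export
cnv_burden <- function(profile, cfg = profile$cfg) {
  stopifnot(inherits(profile, "cnv_profile"))
  switch(cfg$burden_stat,
         signed_mean = rowMeans(profile$profile),
         mean_square = rowMeans(profile$profile^2))
}

#' Compare CNV burden between groups
#'
#' Pairwise two-sided Mann-Whitney tests on per-spot burden with
#' Benjamini-Hochberg adjustment across pairs.
#'
#' @param groups named list of numeric burden vectors, one per group.
#' @return data.frame with `group_a`, `group_b`, `U`, `p`, `p_adj`; empty
#'   when fewer than two groups.
#' @export
compare_burden <- function(groups) {
  if (length(groups) < 2)
    return(data.frame(group_a = character(), group_b = character(),
                      U = numeric(), p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  pairs <- combn(length(groups), 2)
  res <- apply(pairs, 2, function(ij) {
    t <- rank_sum_test(groups[[ij[1]]], groups[[ij[2]]])
    c(U = t$statistic, p = t$p.value)
  })
  out <- data.frame(group_a = nm[pairs[1, ]], group_b = nm[pairs[2, ]],
                    U = res["U", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adj <- bh_adjust(out$p)
  out
}
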