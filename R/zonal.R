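#' Per-band cell-type composition
#'
#' Tabulates, for every zonal band, the proportion of assigned spots
#' carrying each cell-type call. Unassigned spots (`NA` type) are
#' excluded; bands without assigned spots are reported with `NA`
#' proportions rather than dropped.
#'
#' When an abundance matrix is supplied instead of type calls, the
#' proportion is the mean relative abundance of each cell type per band
#' (the quantity zone-wise abundance boxplots display), with `n_spots`
#' the number of spots in the band.
#'
#' @param band_labels per-spot band factor (see [assign_spots_to_bands()]).
#' @param type_labels per-spot cell-type call (`NA` = unassigned), or a
#'   spot x type abundance matrix for abundance-weighted composition.
#' @return data.frame with columns `band`, `cell_type`, `n_spots`,
#'   `proportion`; attribute `empty` is TRUE when no assigned spot falls
#'   in any band.
#' @export
band_composition <- function(band_labels, type_labels) {
  band_labels <- as.factor(band_labels)
  if (is.matrix(type_labels) || is.data.frame(type_labels)) {
    ab <- as.matrix(type_labels)
    if (length(band_labels) != nrow(ab))
      stop_param("band labels and abundance rows must align")
    ab <- ab / pmax(rowSums(ab), .Machine$double.eps)
    keep <- !is.na(band_labels)
    bands <- levels(band_labels)
    out <- do.call(rbind, lapply(bands, function(b) {
      sel <- keep & band_labels == b
      data.frame(band = b, cell_type = colnames(ab),
                 n_spots = sum(sel),
                 proportion = if (any(sel))
                   colMeans(ab[sel, , drop = FALSE]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    attr(out, "empty") <- !any(keep)
    return(out)
  }
  if (length(band_labels) != length(type_labels))
    stop_param("band and type labels must align")
  keep <- !is.na(band_labels) & !is.na(type_labels)
  tab <- table(band = band_labels[keep],
               cell_type = factor(type_labels[keep]))
  n_band <- rowSums(tab)
  df <- as.data.frame(tab, responseName = "n_spots",
                      stringsAsFactors = FALSE)
  df$proportion <- ifelse(n_band[df$band] > 0,
                          df$n_spots / n_band[df$band], NA_real_)
  df <- df[order(df$band, df$cell_type), ]
  rownames(df) <- NULL
  attr(df, "empty") <- sum(keep) == 0
  df
}

#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' U statistic with midranks for ties. For small samples
#' (`n + m <= exact_max`) the p-value is computed by exhaustive
#' enumeration of all group assignments of the observed values (exact,
#' tie-aware); otherwise by the normal approximation with continuity and
#' tie correction. When every value is tied across both samples, p = 1.
#'
#' @param x,y numeric samples, both nonempty.
#' @param exact_max largest combined size for exact enumeration.
#' @return list with `statistic` (U of `x`), `p.value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) stop_param("both samples must be nonempty")
  n <- length(x); m <- length(y)
  v <- c(x, y)
  r <- rank(v)                           # midranks
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (length(unique(v)) == 1)
    return(list(statistic = U, p.value = 1, method = "degenerate"))

  if (n + m <= exact_max) {
    idx <- combn(n + m, n)
    r_all <- rank(v)
    u_all <- colSums(matrix(r_all[idx], nrow = n)) - n * (n + 1) / 2
    dev <- abs(u_all - n * m / 2)
    p <- mean(dev >= abs(U - n * m / 2) - 1e-12)
    return(list(statistic = U, p.value = p, method = "exact"))
  }

  N <- n + m
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n * m / 12 * ((N + 1) - tie_term))
  z <- (abs(U - n * m / 2) - 0.5) / sigma
  p <- min(1, 2 * pnorm(-max(z, 0)))
  list(statistic = U, p.value = p, method = "normal")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone and clipped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_param("p-values must be in [0, 1] and non-missing")
  p.adjust(p, method = "BH")
}

# log1p library-size normalization to a fixed target depth per observation.
normalize_log1p <- function(counts, target = 1e4) {
  tot <- rowSums(counts)
  tot[tot == 0] <- 1
  log1p(counts / tot * target)
}

#' Differential expression between two groups of spots or cells
#'
#' Per-gene Welch t-test on log1p library-size-normalized expression with
#' Benjamini-Hochberg correction across genes. A gene is flagged when
#' `|log2FC| >= lfc_min` and adjusted p < `alpha`. The log2 fold change
#' is computed on the linear scale from the group means of
#' log-expression, `log2(expm1(mean_a) / expm1(mean_b))` (with a small
#' epsilon), so a k-fold expression change reports close to `log2(k)`
#' rather than the compressed difference of log1p means. Genes with zero
#' variance in both groups get p = 1.
#'
#' @param counts_a,counts_b observation x gene matrices over the same genes.
#' @param normalized set TRUE when the matrices are already normalized
#'   log-expression.
#' @param lfc_min,alpha flagging thresholds.
#' @return data.frame (class `deg_table`) with `gene`, `log2fc`, `t`,
#'   `p`, `p_adj`, `flagged`; thresholds kept as attributes.
#' @export
differential_expression <- function(counts_a, counts_b, normalized = FALSE,
                                    lfc_min = 1.5, alpha = 0.05) {
  if (ncol(counts_a) != ncol(counts_b))
    stop_param("groups must share the same genes")
  if (nrow(counts_a) < 2 || nrow(counts_b) < 2)
    stop_param("need >= 2 observations per group")
  a <- if (normalized) as.matrix(counts_a) else normalize_log1p(counts_a)
  b <- if (normalized) as.matrix(counts_b) else normalize_log1p(counts_b)
  na <- nrow(a); nb <- nrow(b)

  ma <- colMeans(a); mb <- colMeans(b)
  va <- (colSums(a^2) - na * ma^2) / (na - 1)
  vb <- (colSums(b^2) - nb * mb^2) / (nb - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               NA_real_)
  p <- ifelse(is.na(tstat), 1, 2 * pt(-abs(tstat), df))
  p_adj <- bh_adjust(p)
  log2fc <- log2((expm1(ma) + 1e-9) / (expm1(mb) + 1e-9))

  out <- data.frame(gene = colnames(a) %||% paste0("g", seq_along(ma)),
                    log2fc = log2fc, t = tstat, p = p, p_adj = p_adj,
                    flagged = abs(log2fc) >= lfc_min & p_adj < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lfc_min") <- lfc_min
  attr(out, "alpha") <- alpha
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Gene-set score per spot
#'
#' Scores each spot as the mean normalized expression of the gene set
#' minus the mean of a control set drawn from expression-matched bins:
#' genes are binned by average expression into `n_bins` rank bins and
#' `ctrl_size` control genes are sampled (without the set genes) from the
#' bin of each set gene. `method = "plain"` skips the control subtraction
#' and returns the raw average expression of the set.
#'
#' @param expr spot x gene normalized log-expression matrix.
#' @param gene_set character vector of gene ids; genes absent from `expr`
#'   are dropped with a warning.
#' @param n_bins number of expression bins.
#' @param ctrl_size control genes sampled per set gene.
#' @param seed RNG seed for control sampling.
#' @param method `"matched"` (control-subtracted) or `"plain"`.
#' @return object of class `gene_set_score`: list with `score` (per-spot),
#'   `gene_set` (genes used), `control_genes`, `n_bins`, `ctrl_size`.
#' @export
gene_set_score <- function(expr, gene_set, n_bins = 25, ctrl_size = 50,
                           seed = 0, method = c("matched", "plain")) {
  method <- match.arg(method)
  genes <- colnames(expr)
  if (is.null(genes)) stop_param("expr must have gene column names")
  missing <- setdiff(gene_set, genes)
  if (length(missing)) {
    warning(length(missing), " gene-set gene(s) not measured; dropped")
    gene_set <- intersect(gene_set, genes)
  }
  if (!length(gene_set)) stop_param("gene set empty after dropping unmeasured genes")

  set_mean <- rowMeans(expr[, gene_set, drop = FALSE])
  if (method == "plain")
    return(structure(list(score = set_mean, gene_set = gene_set,
                          control_genes = character(), n_bins = n_bins,
                          ctrl_size = ctrl_size),
                     class = "gene_set_score"))

  gmean <- colMeans(expr)
  bin <- ceiling(rank(gmean, ties.method = "first") / (length(gmean) / n_bins))
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(unique(bin[gene_set]), function(b) {
      pool <- setdiff(genes[bin == b], gene_set)
      n_in_set <- sum(bin[gene_set] == b)
      if (!length(pool)) return(character())
      sample(pool, min(length(pool), ctrl_size * n_in_set))
    })))
  })
  ctrl_mean <- if (length(ctrl)) rowMeans(expr[, ctrl, drop = FALSE]) else 0
  structure(list(score = set_mean - ctrl_mean, gene_set = gene_set,
                 control_genes = ctrl, n_bins = n_bins,
                 ctrl_size = ctrl_size),
            class = "gene_set_score")
}
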