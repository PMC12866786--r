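toy_annotation <- function(n = 30, chroms = c("chr1", "chr2")) {
  data.frame(gene = sprintf("g%03d", 1:n),
             chrom = rep(chroms, each = n / length(chroms)),
             ord_pos = rep(seq_len(n / length(chroms)), length(chroms)),
             stringsAsFactors = FALSE)
}

test_that("gene ordering is stable, natural-ordered and logs drops", {
  ann <- toy_annotation()
  expect_equal(order_genes(ann)$gene, ann$gene)   # already ordered
  set.seed(3)
  shuf <- ann[sample(nrow(ann)), ]
  expect_equal(order_genes(shuf)$gene, ann$gene)
  # chr10 sorts after chr2, not between chr1 and chr2
  ann2 <- data.frame(gene = c("a", "b", "c"),
                     chrom = c("chr10", "chr2", "chr1"),
                     ord_pos = c(1, 1, 1))
  expect_equal(order_genes(ann2)$gene, c("c", "b", "a"))
  # missing annotation dropped and reported
  ann3 <- ann; ann3$chrom[5] <- NA
  expect_message(out <- order_genes(ann3), "excluded")
  expect_false(ann$gene[5] %in% out$gene)
  expect_equal(attr(out, "dropped"), ann$gene[5])
  # duplicate loci warn and tie-break by gene id
  ann4 <- rbind(ann, data.frame(gene = "g000", chrom = "chr1", ord_pos = 1))
  expect_warning(out4 <- order_genes(ann4), "duplicate")
  expect_equal(out4$gene[1:2], c("g000", "g001"))
})

test_that("self-referenced expression smooths to an all-zero profile", {
  ann <- toy_annotation()
  set.seed(1)
  expr <- matrix(rnorm(10 * 30), 10, 30,
                 dimnames = list(NULL, ann$gene))
  ref <- colMeans(expr)
  prof <- smooth_cnv(rbind(ref, ref), ref, ann, cnv_config(window_genes = 5))
  expect_equal(max(abs(prof$profile)), 0)
})

test_that("smoothing equals the brute-force windowed mean at every gene", {
  ann <- toy_annotation(60, c("chr1", "chr2", "chr3"))
  set.seed(8)
  expr <- matrix(rnorm(5 * 60), 5, 60, dimnames = list(NULL, ann$gene))
  ref <- rnorm(60); names(ref) <- ann$gene
  w <- 7; left <- floor(w / 2); right <- w - left - 1
  prof <- smooth_cnv(expr, ref, ann, cnv_config(window_genes = w))
  rel <- sweep(expr, 2, ref)
  for (spot in 1:5) {
    for (g in 1:60) {
      ch <- ann$chrom[g]
      in_ch <- which(ann$chrom == ch)
      j <- match(g, in_ch)
      lo <- in_ch[max(1, j - left)]
      hi <- in_ch[min(length(in_ch), j + right)]
      expect_equal(unname(prof$profile[spot, g]), mean(rel[spot, lo:hi]),
                   info = sprintf("spot %d gene %d", spot, g))
    }
  }
})

test_that("windows never cross chromosome boundaries", {
  # sentinel: chr2 carries a large constant; if any chr1-edge window
  # leaked across the boundary its smoothed value would move off zero
  ann <- toy_annotation(40, c("chr1", "chr2"))
  expr <- matrix(0, 2, 40, dimnames = list(NULL, ann$gene))
  expr[, ann$chrom == "chr2"] <- 100
  ref <- rep(0, 40); names(ref) <- ann$gene
  prof <- smooth_cnv(expr, ref, ann, cnv_config(window_genes = 9))
  expect_lt(max(abs(prof$profile[, ann$chrom == "chr1"])), 1e-9)
  expect_lt(max(abs(prof$profile[, ann$chrom == "chr2"] - 100)), 1e-9)
})

test_that("tiny chromosomes pass through unsmoothed with a warning", {
  ann <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                    ord_pos = c(1, 2, 3, 4, 1))
  expr <- matrix(c(1, 2, 3, 4, 9), 1, 5, dimnames = list(NULL, ann$gene))
  ref <- setNames(rep(0, 5), ann$gene)
  expect_warning(prof <- smooth_cnv(expr, ref, ann,
                                    cnv_config(window_genes = 3)),
                 "fewer than 3")
  expect_equal(unname(prof$profile[1, "e"]), 9)  # untouched singleton chromosome
})

test_that("burden statistics behave under zero, gain and sign flips", {
  ann <- toy_annotation()
  expr <- matrix(0, 2, 30, dimnames = list(NULL, ann$gene))
  ref <- setNames(rep(0, 30), ann$gene)
  prof <- smooth_cnv(expr, ref, ann, cnv_config(window_genes = 5))
  expect_equal(unname(cnv_burden(prof)), c(0, 0))
  expect_equal(unname(cnv_burden(prof, cnv_config(burden_stat = "mean_square"))),
               c(0, 0))
  # gain spot outranks flat spot under signed mean
  expr2 <- expr; expr2[1, 1:15] <- 0.5
  prof2 <- smooth_cnv(expr2, ref, ann, cnv_config(window_genes = 5))
  b <- cnv_burden(prof2)
  expect_gt(b[1], b[2])
  # mean_square is sign-blind
  prof_neg <- prof2; prof_neg$profile <- -prof_neg$profile
  cfg_ms <- cnv_config(burden_stat = "mean_square")
  expect_equal(cnv_burden(prof_neg, cfg_ms), cnv_burden(prof2, cfg_ms))
})

test_that("burden comparisons run pairwise with BH across pairs", {
  expect_equal(nrow(compare_burden(list(a = 1:5))), 0)
  set.seed(2)
  g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 2))
  cmp <- compare_burden(g)
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$p_adj, bh_adjust(cmp$p))
  same <- compare_burden(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same$p, 1)
})

test_that("planted gain blocks rise 3 SD above the off-block profile", {
  panel <- fixture_panel(1200, seed = 5)
  scn <- scene(width_um = 5000, height_um = 5000, tumor_radius = 900,
               cnv_blocks = list(list(chrom = "chr2", start = 1, end = 300,
                                      factor = 2)),
               seed = 77)
  sec <- plant_cnv(simulate_section(scn, panel), panel, scn)
  expr <- spotzone:::normalize_log1p(sec$counts)
  labels <- ifelse(sec$spots$truth_tumor, "AT2-like", sec$spots$truth_type)
  ref <- reference_profile(expr, labels, "AT2")
  prof <- smooth_cnv(expr, ref, panel_annotation(panel), cnv_config())
  block <- attr(sec, "cnv_genes")[[1]]
  tumor <- sec$spots$truth_tumor
  mean_block <- mean(prof$profile[tumor, block])
  off <- setdiff(prof$genes, block)
  expect_gt(mean_block, 0)
  expect_gte(mean_block, 3 * sd(prof$profile[tumor, off]))
})

test_that("reference spots carry near-zero burden and gains rank above", {
  panel <- fixture_panel(800, seed = 6)
  scn <- scene(width_um = 4600, height_um = 4600, tumor_radius = 800,
               cnv_blocks = list(list(chrom = "chr3", start = 1, end = 150,
                                      factor = 1.5)),
               seed = 13)
  sec <- plant_cnv(simulate_section(scn, panel), panel, scn)
  expr <- spotzone:::normalize_log1p(sec$counts)
  labels <- ifelse(sec$spots$truth_tumor, "AT2-like", sec$spots$truth_type)
  ref <- reference_profile(expr, labels, "AT2")
  prof <- smooth_cnv(expr, ref, panel_annotation(panel), cnv_config())
  burden <- cnv_burden(prof)
  ref_burden <- burden[labels == "AT2"]
  expect_lt(abs(mean(ref_burden)), 3 * sd(ref_burden) / sqrt(length(ref_burden)) + 1e-3)
})

test_that("stronger planted gains increase the mean block profile", {
  panel <- fixture_panel(600, seed = 9)
  means <- sapply(c(1, 1.5, 2), function(f) {
    scn <- scene(width_um = 4600, height_um = 4600, tumor_radius = 800,
                 cnv_blocks = list(list(chrom = "chr2", start = 1, end = 100,
                                        factor = f)),
                 seed = 31)
    sec <- plant_cnv(simulate_section(scn, panel), panel, scn)
    expr <- spotzone:::normalize_log1p(sec$counts)
    labels <- ifelse(sec$spots$truth_tumor, "AT2-like", sec$spots$truth_type)
    ref <- reference_profile(expr, labels, "AT2")
    prof <- smooth_cnv(expr, ref, panel_annotation(panel), cnv_config())
    block <- panel$genes[panel$chrom == "chr2" & panel$ord_pos <= 100]
    mean(prof$profile[sec$spots$truth_tumor, block])
  })
  expect_true(all(diff(means) > 0))
})
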