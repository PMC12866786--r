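test_that("band composition computes per-band proportions over assigned spots", {
  lab <- factor(rep("TR1", 8), levels = c("NR1", "TR1"))
  types <- c(rep("tumor", 6), rep("fibro", 2))
  comp <- band_composition(lab, types)
  tr1 <- comp[comp$band == "TR1", ]
  expect_equal(tr1$proportion[tr1$cell_type == "tumor"], 0.75)
  expect_equal(tr1$proportion[tr1$cell_type == "fibro"], 0.25)
  # proportions sum to 1 per non-empty band; unassigned spots excluded
  lab2 <- factor(c(rep("TR1", 4), rep("NR1", 4)))
  types2 <- c("a", "a", "b", NA, "b", "b", "a", NA)
  comp2 <- band_composition(lab2, types2)
  sums <- tapply(comp2$proportion, comp2$band, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(sum(comp2$n_spots), 6)
})

test_that("abundance-weighted composition averages relative abundances", {
  lab <- factor(c("TR1", "TR1", "NR1"), levels = c("NR1", "TR1"))
  ab <- rbind(c(0.8, 0.2), c(0.6, 0.4), c(0.1, 0.9))
  colnames(ab) <- c("tumor", "fibro")
  comp <- band_composition(lab, ab)
  expect_equal(comp$proportion[comp$band == "TR1" &
                                 comp$cell_type == "tumor"], 0.7)
  expect_equal(comp$proportion[comp$band == "NR1" &
                                 comp$cell_type == "fibro"], 0.9)
})

test_that("rank-sum p-values equal exhaustive enumeration for n+m <= 12", {
  set.seed(17)
  for (n in 1:6) for (m in n:(12 - n)) {
    if (m < 1) next
    x <- round(rnorm(n), 1)           # rounding forces occasional ties
    y <- round(rnorm(m), 1)
    res <- rank_sum_test(x, y)
    expect_equal(res$p.value, enumerate_rank_sum_p(x, y),
                 info = sprintf("n=%d m=%d", n, m))
    expect_equal(res$method, if (length(unique(c(x, y))) == 1)
      "degenerate" else "exact")
  }
})

test_that("rank-sum matches the textbook small-sample example", {
  res <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1 / 3)
  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5))$p.value, 1)
})

test_that("normal approximation tracks the exact p-value", {
  set.seed(9)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    exact <- rank_sum_test(x, y)$p.value
    approx <- rank_sum_test(x, y, exact_max = 0)$p.value
    expect_lt(abs(exact - approx), 0.02)
  }
  # U statistic agrees with the standard implementation on tie-free data
  x <- rnorm(20); y <- rnorm(15)
  expect_equal(rank_sum_test(x, y)$statistic,
               unname(stats::wilcox.test(x, y)$statistic))
})

test_that("BH adjustment reproduces an independent step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(4)
  for (rep in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_adjust(p), stepup_bh(p))
    expect_true(all(bh_adjust(p) >= p))
  }
  # fixed point: equal p-values stay put
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "spotzone_param_error")
})

test_that("identical groups yield no flagged genes", {
  set.seed(6)
  counts <- matrix(rpois(40 * 100, 5), 40, 100)
  deg <- differential_expression(counts[1:20, ], counts[1:20, ])
  expect_equal(sum(deg$flagged), 0)
  expect_true(all(deg$p == 1 | abs(deg$log2fc) < 1e-12))
})

test_that("the fold-change gate blocks sub-threshold genes regardless of p", {
  # two tight groups separated by 1.4 in log2 units: significant p but
  # below the 1.5 fold-change cutoff
  set.seed(12)
  a <- matrix(rnorm(30 * 5, mean = 5, sd = 0.01), 30, 5)
  b <- matrix(rnorm(30 * 5, mean = 5 - 1.4 * log(2), sd = 0.01), 30, 5)
  deg <- differential_expression(a, b, normalized = TRUE)
  expect_true(all(deg$p_adj < 0.001))
  expect_true(all(abs(deg$log2fc) < 1.5))
  expect_equal(sum(deg$flagged), 0)
  # and a 2-unit separation passes
  b2 <- matrix(rnorm(30 * 5, mean = 3, sd = 0.01), 30, 5)
  deg2 <- differential_expression(a, b2, normalized = TRUE)
  expect_equal(sum(deg2$flagged), 5)
})

test_that("zero-variance genes report p = 1 with a defined fold change", {
  a <- matrix(3, 5, 2); b <- matrix(1, 5, 2)
  deg <- differential_expression(a, b, normalized = TRUE)
  expect_equal(deg$p, c(1, 1))
  expect_equal(deg$log2fc, rep(log2(expm1(3) / expm1(1)), 2),
               tolerance = 1e-6)
  expect_false(any(deg$flagged))
})

test_that("planted fold changes are recovered with few false flags", {
  set.seed(33)
  n_genes <- 400; n <- 30
  mu <- exp(rnorm(n_genes, log(8), 0.4))
  planted <- sample(n_genes, 20)
  mk <- function(mu) t(replicate(n, rnbinom(n_genes, mu = mu, size = 4)))
  a <- mk(mu)
  mu_b <- mu; mu_b[planted] <- mu_b[planted] * 4
  b <- mk(mu_b)
  deg <- differential_expression(b, a)
  expect_gte(sum(deg$flagged[planted]), 17)
  expect_lte(sum(deg$flagged[-planted]), 2)
  expect_true(all(deg$log2fc[deg$flagged & seq_len(n_genes) %in% planted] > 0))
})

test_that("gene-set scores are centered, deterministic and exchangeable", {
  set.seed(2)
  expr <- matrix(rnorm(200 * 300, 2, 0.5), 200, 300,
                 dimnames = list(NULL, sprintf("g%03d", 1:300)))
  gs <- sprintf("g%03d", sample(300, 12))
  s1 <- gene_set_score(expr, gs, seed = 5)
  s2 <- gene_set_score(expr, gs, seed = 5)
  expect_identical(s1$score, s2$score)
  # matched control keeps null sets near zero
  expect_lt(abs(mean(s1$score)), 0.1)
  # spot permutation permutes scores identically
  perm <- sample(200)
  s3 <- gene_set_score(expr[perm, ], gs, seed = 5)
  expect_equal(unname(s3$score), unname(s1$score[perm]))
  # unmeasured genes dropped with a warning; empty set errors
  expect_warning(gene_set_score(expr, c(gs, "nope"), seed = 5), "dropped")
  expect_error(suppressWarnings(gene_set_score(expr, "nope", seed = 1)),
               class = "spotzone_param_error")
})

test_that("a planted marker set scores higher at the tumor edge than far out", {
  panel <- fixture_panel(200, seed = 2)
  scn <- scene(width_um = 5000, height_um = 5000, tumor_radius = 900,
               seed = 44)
  sec <- simulate_section(scn, panel)
  expr <- spotzone:::normalize_log1p(sec$counts)
  score <- gene_set_score(expr, panel$markers[["AT2-like"]], seed = 1)$score
  band <- sec$spots$truth_band
  tr1 <- score[!is.na(band) & band == "TR1"]
  nr3 <- score[!is.na(band) & band == "NR3"]
  expect_gt(length(tr1), 100)
  expect_gt(length(nr3), 100)
  expect_gt(mean(tr1), mean(nr3))
  expect_lt(rank_sum_test(tr1, nr3)$p.value, 0.05)
})
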