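# Shared fixtures, built in code at test time.

# small reusable panel (5 types incl. AT2-like/AT2/fibroblast)
fixture_panel <- function(n_genes = 200, n_types = 5, seed = 2) {
  make_signature_panel(n_genes, n_types, n_chroms = 4,
                       mito_fraction = 0.02, seed = seed)
}

# clean disk scene: radius 1200 um in a 6 x 6 mm section
fixture_scene <- function(seed = 3, ...) {
  scene(width_um = 6000, height_um = 6000, tumor_radius = 1200,
        seed = seed, ...)
}

# large rectangle whose top edge is the straight border y = 0; the tumor
# side (interior) is y > 0. Far from the left/right/top edges the signed
# distance to this polygon equals y exactly.
straight_border <- function(half_width = 1e6) {
  rbind(c(-half_width, 0), c(half_width, 0),
        c(half_width, 2 * half_width), c(-half_width, 2 * half_width))
}

# fraction of spots whose band label matches the generator truth
# (NA agreeing with NA)
band_agreement <- function(labels, truth) {
  l <- as.character(labels); t <- as.character(truth)
  mean(ifelse(is.na(l) & is.na(t), TRUE, l == t), na.rm = TRUE)
}

# independent brute-force exact two-sided rank-sum p-value by enumeration
# of all group assignments of the pooled values
enumerate_rank_sum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  v <- c(x, y)
  r <- rank(v)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(n + m, n)
  u_all <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
  mean(abs(u_all - n * m / 2) >= abs(u_obs - n * m / 2) - 1e-12)
}

# independent Benjamini-Hochberg step-up implementation
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
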