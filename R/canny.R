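# Canny edge detector on a plain matrix image: Sobel gradients, non-maximum
# suppression, double threshold with hysteresis. Thresholds are fractions of
# the maximum gradient magnitude.
canny_edges <- function(img, low_frac = 0.1, high_frac = 0.3) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- as.matrix(EBImage::filter2(img, kx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(img, ky, boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(0, nrow(img), ncol(img)))

  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx)                       # in (-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4)     # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  nr <- nrow(mag); nc <- ncol(mag)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  nms <- matrix(FALSE, nr, nc)
  for (sct in 0:3) {
    o <- offs[[sct + 1]]
    n1 <- shift(mag, o[1], o[2])
    n2 <- shift(mag, -o[1], -o[2])
    nms <- nms | (sector == sct & mag >= n1 & mag >= n2)
  }

  hi <- mag >= high_frac * mmax & nms
  lo <- mag >= low_frac * mmax & nms
  if (!any(hi)) return(matrix(0, nr, nc))
  lab <- EBImage::bwlabel(lo * 1)
  keep <- unique(lab[hi])
  keep <- keep[keep > 0]
  matrix(as.numeric(as.matrix(lab) %in% keep), nr, nc)
}
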