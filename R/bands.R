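#' Build the six zonal bands around a tumor borderline
#'
#' Partitions the tissue around the borderline into 500-µm-wide bands by
#' signed distance: TR1-TR3 toward the tumor side (intervals
#' `[0,500)`, `[500,1000)`, `[1000,1500)` µm inward) and NR1-NR3 toward
#' the normal side (`(0,500]`, `(500,1000]`, `(1000,1500]` µm outward).
#' This is the signed-distance formulation of perpendicular parallel
#' offsets at 500/1000/1500 µm on both sides of the border. A point
#' exactly on the borderline falls in TR1.
#'
#' @param borderline closed polygon (n x 2 µm matrix, implicitly closed),
#'   e.g. from [extract_borderline()].
#' @param offsets strictly increasing positive offset distances in µm.
#' @param check_simple verify the borderline does not self-intersect.
#' @return object of class `band_set`: list with `borderline`, `offsets`,
#'   `labels` (ordered NR3, NR2, NR1, TR1, TR2, TR3), and `intervals`
#'   (signed-distance interval per band).
#' @export
build_bands <- function(borderline, offsets = c(500, 1000, 1500),
                        check_simple = TRUE) {
  borderline <- as.matrix(borderline)
  if (nrow(borderline) < 3) stop_geometry("borderline needs >= 3 vertices")
  if (any(offsets <= 0) || any(diff(offsets) <= 0))
    stop_param("offsets must be strictly increasing and positive")
  if (check_simple && !polygon_is_simple(borderline))
    stop_geometry("borderline is self-intersecting")
  k <- length(offsets)
  labels <- c(paste0("NR", k:1), paste0("TR", 1:k))
  lo <- c(0, offsets[-k])
  intervals <- c(
    lapply(k:1, function(i) c(-offsets[i], -lo[i])),   # NRk..NR1 (lo,hi]
    lapply(1:k, function(i) c(lo[i], offsets[i])))     # TR1..TRk [lo,hi)
  names(intervals) <- labels
  structure(list(borderline = orient_ccw(borderline), offsets = offsets,
                 labels = labels, intervals = intervals),
            class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  cat("band_set:", length(x$labels), "bands (",
      paste(x$labels, collapse = ", "), ") at offsets",
      paste(x$offsets, collapse = "/"), "um\n")
  invisible(x)
}

#' Assign spots to zonal bands
#'
#' Labels each spot with the band containing its center, by exact signed
#' distance to the borderline; spots farther than the outermost offset on
#' either side get `NA`. When several band sets are given (multifocal
#' sections), each spot is labeled relative to the nearest borderline.
#'
#' @param section a `spatial_section`, or a data.frame with `x_um`, `y_um`.
#' @param bands a [build_bands()] result, or a list of them.
#' @return factor of band labels (levels NR3..TR3), `NA` outside all bands,
#'   with the signed distances as attribute `signed_distance`.
#' @export
assign_spots_to_bands <- function(section, bands) {
  spots <- if (inherits(section, "spatial_section")) section$spots else section
  if (inherits(bands, "band_set")) bands <- list(bands)
  px <- spots$x_um; py <- spots$y_um
  s_best <- rep(NA_real_, length(px))
  for (bs in bands) {
    s <- signed_distance(px, py, bs$borderline)
    nearer <- is.na(s_best) | abs(s) < abs(s_best)
    s_best[nearer] <- s[nearer]
  }
  out <- band_from_signed_distance(s_best, offsets = bands[[1]]$offsets)
  attr(out, "signed_distance") <- s_best
  out
}
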