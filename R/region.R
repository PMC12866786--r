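# Otsu threshold on the positive-pixel histogram (256 bins).
otsu_threshold <- function(values) {
  v <- values[values > 0]
  if (!length(v)) return(NA_real_)
  if (length(unique(v)) == 1) return(v[1] / 2)
  h <- hist(v, breaks = seq(min(v), max(v), length.out = 257), plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Detect the tumor region from an abundance raster
#'
#' Runs the border-detection pipeline: threshold the image to a binary
#' mask (Otsu on the positive-pixel histogram, or a fixed cutoff),
#' Gaussian-blur it, detect Canny edges, morphologically close the edge
#' map, fill and label connected regions, trace each region's contour and
#' simplify it to a polygon. The candidate with the largest area is the
#' region of interest; all candidates are retained.
#'
#' @param grid a [rasterize_abundance()] raster.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_tau threshold value when `threshold_method = "fixed"`.
#' @param blur_sigma_um Gaussian blur sigma in µm (default one pixel).
#' @param canny_low,canny_high hysteresis thresholds as fractions of the
#'   maximum gradient magnitude.
#' @param simplify_eps_um contour simplification tolerance in µm; 0 keeps
#'   the raw traced contour.
#' @param close_kernel_px edge-map closing kernel size in pixels (odd);
#'   5 bridges the 2-3 pixel gaps non-maximum suppression leaves in a
#'   discretized edge chain.
#' @param min_area_um2 candidates below this area are discarded.
#' @param refine `"subpixel"` replaces each candidate's pixel-traced
#'   contour by the half-maximum iso-contour of the blurred mask (which
#'   crosses the underlying intensity step with sub-pixel accuracy);
#'   `"pixel"` keeps the raw traced contour.
#' @return object of class `tumor_region`: list with `polygon` (largest
#'   candidate, µm, counter-clockwise), `area_um2`, `all_candidates`
#'   (list of polygons), `areas_um2`, `threshold`.
#' @export
detect_tumor_region <- function(grid, threshold_method = c("otsu", "fixed"),
                                fixed_tau = NULL,
                                blur_sigma_um = grid$pixel_um,
                                canny_low = 0.1, canny_high = 0.3,
                                simplify_eps_um = 25,
                                close_kernel_px = 5,
                                min_area_um2 = 4 * grid$pixel_um^2,
                                refine = c("subpixel", "pixel")) {
  threshold_method <- match.arg(threshold_method)
  refine <- match.arg(refine)
  img <- grid$image
  if (!any(img > 0)) stop_no_region("no positive pixels in raster")

  tau <- if (threshold_method == "otsu") otsu_threshold(img)
         else fixed_tau %||% stop_param("fixed_tau required for fixed threshold")
  binary <- (img > tau) * 1
  if (!any(binary > 0)) stop_no_region("no pixels above threshold")

  blurred <- as.matrix(EBImage::gblur(binary, sigma = blur_sigma_um / grid$pixel_um))
  edges <- canny_edges(blurred, low_frac = canny_low, high_frac = canny_high)
  if (!any(edges > 0)) stop_no_region("no edges detected")

  # closing interleaved with hole filling: dilation bridges the (often
  # diagonal, 4-connectivity-fragmented) edge chain, filling turns the
  # closed ring into a region, erosion restores the boundary position
  brush <- EBImage::makeBrush(close_kernel_px, shape = "box")
  dil <- EBImage::dilate(edges, brush)
  filled <- EBImage::fillHull(EBImage::bwlabel(dil))
  mask <- as.matrix(EBImage::erode((as.matrix(filled) > 0) * 1, brush))
  lab <- EBImage::bwlabel(mask > 0)
  contours <- EBImage::ocontour(lab)
  if (!length(contours)) stop_no_region("no closed contour found")

  # sub-pixel iso-contours of the blurred mask at half maximum; the level
  # crossing of a blurred step sits on the step itself
  iso <- list()
  if (refine == "subpixel") {
    nx <- nrow(blurred); ny <- ncol(blurred)
    cl <- grDevices::contourLines(
      x = (seq_len(nx) - 0.5) * grid$pixel_um + grid$origin[1],
      y = (seq_len(ny) - 0.5) * grid$pixel_um + grid$origin[2],
      z = blurred, levels = max(blurred) / 2)
    iso <- Filter(function(cc) {
      length(cc$x) >= 4 && cc$x[1] == cc$x[length(cc$x)] &&
        cc$y[1] == cc$y[length(cc$y)]
    }, cl)
    iso <- lapply(iso, function(cc)
      cbind(cc$x[-length(cc$x)], cc$y[-length(cc$y)]))
  }

  polys <- list(); areas <- numeric()
  for (ct in contours) {
    if (nrow(ct) < 3) next
    # ocontour returns 0-based pixel indices; pixel centers in µm
    poly <- cbind((ct[, 1] + 0.5) * grid$pixel_um + grid$origin[1],
                  (ct[, 2] + 0.5) * grid$pixel_um + grid$origin[2])
    if (length(iso)) {
      centroid <- colMeans(poly)
      containing <- Filter(function(p)
        mgcv::in.out(rbind(p, p[1, ]), matrix(centroid, 1)), iso)
      if (length(containing)) {
        areas_iso <- vapply(containing, function(p) abs(polygon_area(p)), 0)
        poly <- containing[[which.min(areas_iso)]]
      }
    }
    poly <- orient_ccw(poly)
    if (simplify_eps_um > 0) poly <- simplify_polygon(poly, simplify_eps_um)
    if (nrow(poly) < 3) next
    a <- abs(polygon_area(poly))
    if (a < min_area_um2) next
    polys[[length(polys) + 1]] <- poly
    areas <- c(areas, a)
  }
  if (!length(polys)) stop_no_region("no candidate region above minimum area")

  ord <- order(areas, decreasing = TRUE)
  structure(list(polygon = polys[[ord[1]]], area_um2 = areas[ord[1]],
                 all_candidates = polys[ord], areas_um2 = areas[ord],
                 threshold = tau),
            class = "tumor_region")
}

#' @export
print.tumor_region <- function(x, ...) {
  cat("tumor_region: ROI area", format(x$area_um2, big.mark = ","),
      "um^2 (", length(x$all_candidates), "candidate(s))\n")
  invisible(x)
}

#' Extract the tumor borderline from a detected region
#'
#' Returns the region-of-interest polygon boundary as a closed polyline in
#' counter-clockwise orientation (tumor interior on the left).
#'
#' @param region a [detect_tumor_region()] result (or a bare polygon matrix).
#' @return n x 2 µm coordinate matrix, implicitly closed, class `borderline`.
#' @export
extract_borderline <- function(region) {
  poly <- if (inherits(region, "tumor_region")) region$polygon else as.matrix(region)
  if (is.null(dim(poly)) || nrow(poly) < 3)
    stop_geometry("degenerate region: fewer than 3 vertices")
  structure(orient_ccw(poly), class = c("borderline", "matrix"))
}
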