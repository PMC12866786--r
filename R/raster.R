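#' Rasterize one cell type's abundance onto a pixel grid
#'
#' Builds the image the border-detection step operates on: each pixel
#' holds the summed abundance of the spots falling in it (a single spot
#' per pixel when `pixel_um` equals the spot pitch, making the mapping
#' invertible), zero where no spot lies.
#'
#' @param section a `spatial_section` (or any list with `spots` and
#'   `abundance` in the same layout).
#' @param cell_type column of the abundance matrix to rasterize.
#' @param pixel_um µm per pixel; defaults to the section pitch.
#' @return object of class `raster_grid`: list with `image` (matrix,
#'   rows = x index, cols = y index), `pixel_um`, `origin` (µm).
#' @export
rasterize_abundance <- function(section, cell_type,
                                pixel_um = section$pitch_um) {
  if (!cell_type %in% colnames(section$abundance))
    stop_param("cell type '", cell_type, "' not in abundance matrix")
  if (pixel_um <= 0) stop_param("pixel_um must be positive")
  x <- section$spots$x_um
  y <- section$spots$y_um
  ix <- pmin(pmax(floor(x / pixel_um) + 1, 1), max(floor(max(x) / pixel_um) + 1, 1))
  iy <- pmin(pmax(floor(y / pixel_um) + 1, 1), max(floor(max(y) / pixel_um) + 1, 1))
  nx <- max(ix); ny <- max(iy)
  img <- matrix(0, nx, ny)
  vals <- section$abundance[, cell_type]
  acc <- rowsum(vals, group = (iy - 1L) * nx + ix)
  img[as.integer(rownames(acc))] <- acc[, 1]
  structure(list(image = img, pixel_um = pixel_um, origin = c(0, 0)),
            class = "raster_grid")
}
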