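# Readers and writers for the pipeline's on-disk formats: spot TSV,
# MatrixMarket counts with sidecar barcode/feature files, abundance TSV,
# panel TSV, band GeoJSON.

write_tsv_stable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated section to a directory
#'
#' Writes `spots.tsv` (spot_id, x_um, y_um, truth_type, truth_band),
#' counts as `counts.mtx` with `barcodes.tsv`/`features.tsv` sidecars
#' (genes as rows, spots as columns), `abundance.tsv` and `panel.tsv`.
#'
#' @param section a `spatial_section`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_section <- function(section, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- section$spots[, c("spot_id", "x_um", "y_um", "truth_type",
                          "truth_band")]
  write_tsv_stable(sp, file.path(dir, "spots.tsv"))
  ab <- data.frame(spot_id = section$spots$spot_id, section$abundance,
                   check.names = FALSE)
  write_tsv_stable(ab, file.path(dir, "abundance.tsv"))
  paths <- c(file.path(dir, c("spots.tsv", "abundance.tsv")))
  if (!is.null(section$counts)) {
    m <- Matrix::Matrix(t(section$counts), sparse = TRUE)  # gene x spot
    Matrix::writeMM(m, file.path(dir, "counts.mtx"))
    writeLines(colnames(section$counts), file.path(dir, "features.tsv"))
    writeLines(section$spots$spot_id, file.path(dir, "barcodes.tsv"))
    paths <- c(paths, file.path(dir, c("counts.mtx", "features.tsv",
                                       "barcodes.tsv")))
  }
  if (!is.null(section$panel)) {
    p <- section$panel
    pd <- data.frame(gene = p$genes, chrom = p$chrom, ord_pos = p$ord_pos,
                     mito_flag = p$mito_flag, dispersion = p$dispersion,
                     p$mu, check.names = FALSE)
    write_tsv_stable(pd, file.path(dir, "panel.tsv"))
    paths <- c(paths, file.path(dir, "panel.tsv"))
  }
  invisible(paths)
}

#' Read a section directory written by [write_section()]
#'
#' @param dir directory containing spots.tsv, abundance.tsv and optionally
#'   the counts MTX triplet.
#' @return a `spatial_section`-like list (no scene or panel attached).
#' @export
read_section <- function(dir) {
  spots <- read.table(file.path(dir, "spots.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  ab <- read.table(file.path(dir, "abundance.tsv"), header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE)
  abm <- as.matrix(ab[, -1, drop = FALSE])
  rownames(abm) <- ab$spot_id
  counts <- NULL
  if (file.exists(file.path(dir, "counts.mtx"))) {
    m <- Matrix::readMM(file.path(dir, "counts.mtx"))
    genes <- readLines(file.path(dir, "features.tsv"))
    barcodes <- readLines(file.path(dir, "barcodes.tsv"))
    counts <- t(as.matrix(m))
    dimnames(counts) <- list(barcodes, genes)
  }
  pitch <- if (nrow(spots) > 1) min(diff(sort(unique(spots$x_um)))) else NA
  structure(list(spots = spots, abundance = abm, counts = counts,
                 pitch_um = pitch, scene = NULL, panel = NULL),
            class = "spatial_section")
}

#' Write a borderline and its bands as GeoJSON
#'
#' Emits a FeatureCollection with the borderline as a closed LineString
#' (µm coordinates) and one feature per band carrying its label and
#' signed-distance interval.
#'
#' @param bands a [build_bands()] result.
#' @param path output file.
#' @export
write_bands_geojson <- function(bands, path) {
  ring <- rbind(bands$borderline, bands$borderline[1, , drop = FALSE])
  features <- c(
    list(list(
      type = "Feature",
      properties = list(role = "borderline"),
      geometry = list(type = "LineString",
                      coordinates = unname(lapply(seq_len(nrow(ring)),
                                                  function(i) ring[i, ]))))),
    lapply(bands$labels, function(lb) list(
      type = "Feature",
      properties = list(role = "band", label = lb,
                        signed_distance_um = bands$intervals[[lb]]),
      geometry = NULL)))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
}
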