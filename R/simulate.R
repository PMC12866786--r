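#' Describe a synthetic tissue section
#'
#' A scene fixes the geometry and composition of a simulated section: a
#' rectangular 50-µm spot grid, a circular tumor region where the
#' malignant (`AT2-like`) type dominates, optional peri-tumoral abundance
#' gradients, and optional copy-number blocks. The tumor must keep 1500 µm
#' of clearance to every section edge so that all six zonal bands fit.
#'
#' @param width_um,height_um section extent in µm.
#' @param pitch_um spot spacing in µm (spot centers at
#'   `(i - 0.5) * pitch_um`); 50 µm matches 50-µm binned spatial data.
#' @param tumor_center,tumor_radius circular tumor region, µm.
#' @param gradient_specs list of gradients, each a list with `cell_type`,
#'   `side` (`"tumor"` or `"normal"`), `decay_um` (exponential decay length
#'   of the abundance fraction with distance from the borderline) and
#'   `peak` (added abundance fraction at the borderline, in (0,1)).
#' @param cnv_blocks list of copy-number blocks, each a list with `chrom`,
#'   `start`, `end` (ordinal positions, inclusive) and `factor`
#'   (multiplicative change of expected expression, > 0).
#' @param base_dominant abundance fraction of the locally dominant type
#'   (AT2-like inside the tumor, AT2 outside) before normalization.
#' @param base_other abundance fraction of every other type.
#' @param library_size_median,library_size_sdlog per-spot library size is
#'   log-normal with this median (µ = log median) and sdlog; the default
#'   median of 3000 transcripts sits inside the per-spot range typical of
#'   50-µm binned sections.
#' @param abundance_noise_sd standard deviation of additive Gaussian noise
#'   applied to abundances before normalization (emulates deconvolution
#'   uncertainty); 0 = noise-free.
#' @param tumor_type,normal_type cell-type labels for the tumor-dominant
#'   and normal-dominant types.
#' @param seed integer seed driving every random draw of the section.
#'
#' @return object of class `scene`.
#' @export
scene <- function(width_um = 7000, height_um = 7000, pitch_um = 50,
                  tumor_center = c(width_um / 2, height_um / 2),
                  tumor_radius = 1700,
                  gradient_specs = list(), cnv_blocks = list(),
                  base_dominant = 0.65, base_other = 0.05,
                  library_size_median = 3000, library_size_sdlog = 0.35,
                  abundance_noise_sd = 0,
                  tumor_type = "AT2-like", normal_type = "AT2",
                  seed = 1) {
  if (pitch_um <= 0 || width_um < pitch_um || height_um < pitch_um)
    stop_param("section extent must cover at least one spot")
  clear <- 1500
  if (tumor_center[1] - tumor_radius < clear ||
      tumor_center[2] - tumor_radius < clear ||
      tumor_center[1] + tumor_radius > width_um - clear ||
      tumor_center[2] + tumor_radius > height_um - clear)
    stop_param("tumor region must keep >= 1500 um clearance to every edge")
  for (g in gradient_specs) {
    if (!g$side %in% c("tumor", "normal"))
      stop_param("gradient side must be 'tumor' or 'normal'")
    if (g$peak <= 0 || g$peak >= 1) stop_param("gradient peak must be in (0,1)")
    if (g$decay_um <= 0) stop_param("gradient decay_um must be positive")
  }
  for (b in cnv_blocks) {
    if (b$factor <= 0) stop_param("cnv block factor must be positive")
    if (b$start > b$end) stop_param("cnv block start must be <= end")
  }
  structure(list(width_um = width_um, height_um = height_um,
                 pitch_um = pitch_um, tumor_center = tumor_center,
                 tumor_radius = tumor_radius,
                 gradient_specs = gradient_specs, cnv_blocks = cnv_blocks,
                 base_dominant = base_dominant, base_other = base_other,
                 library_size_median = library_size_median,
                 library_size_sdlog = library_size_sdlog,
                 abundance_noise_sd = abundance_noise_sd,
                 tumor_type = tumor_type, normal_type = normal_type,
                 seed = seed),
            class = "scene")
}

#' Polygonal outline of a scene's tumor region
#'
#' @param scn a `scene`.
#' @param n_vertices number of polygon vertices approximating the circle.
#' @return n x 2 matrix of µm coordinates, counter-clockwise, not closed.
#' @export
scene_tumor_polygon <- function(scn, n_vertices = 256) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  cbind(scn$tumor_center[1] + scn$tumor_radius * cos(th),
        scn$tumor_center[2] + scn$tumor_radius * sin(th))
}

# Analytic signed distance to the circular tumor boundary (> 0 inside).
scene_signed_distance <- function(scn, x, y) {
  scn$tumor_radius - sqrt((x - scn$tumor_center[1])^2 +
                          (y - scn$tumor_center[2])^2)
}

# Band label from signed distance (µm, > 0 = tumor side). Tumor-side
# intervals are half-open [lo, hi); normal-side intervals are (lo, hi].
band_from_signed_distance <- function(s, offsets = c(500, 1000, 1500)) {
  k <- length(offsets)
  labels <- c(paste0("NR", k:1), paste0("TR", 1:k))
  brk <- c(0, offsets)
  out <- rep(NA_character_, length(s))
  pos <- !is.na(s) & s >= 0
  idx <- findInterval(s[pos], brk)            # [brk_i, brk_{i+1})
  ok <- idx >= 1 & idx <= k
  out[pos][ok] <- paste0("TR", idx[ok])
  neg <- !is.na(s) & s < 0
  d <- -s[neg]
  idx <- findInterval(d, brk, left.open = TRUE)  # (brk_i, brk_{i+1}]
  ok <- idx >= 1 & idx <= k
  out[neg][ok] <- paste0("NR", idx[ok])
  factor(out, levels = labels)
}

#' Simulate a spatial section from a scene and a signature panel
#'
#' Spots fill the grid `floor(width/pitch) x floor(height/pitch)`. Per-spot
#' cell-type abundances mix a dominant type (AT2-like inside the tumor
#' region, AT2 outside) with uniform background and any exponential
#' boundary gradients; counts are drawn negative-binomially with per-spot
#' mean `library_size * sum_t abundance_t * mu[, t]` (gene profile
#' row-normalized). Ground truth stored per spot: dominant type
#' (`truth_type`), tumor membership (`truth_tumor`) and zonal band from
#' the analytic signed distance to the tumor boundary (`truth_band`,
#' `NA` beyond 1500 µm).
#'
#' @param scn a [scene()].
#' @param panel a [make_signature_panel()] panel whose types include the
#'   scene's `tumor_type` and `normal_type`.
#' @param counts if `FALSE`, skip count sampling (geometry-only sections).
#' @return object of class `spatial_section`: list with `spots`
#'   (data.frame: spot_id, x_um, y_um, truth_type, truth_tumor,
#'   truth_band, library_size), `abundance` (spot x type), `counts`
#'   (spot x gene integer matrix or NULL), `pitch_um`, `scene`, `panel`.
#' @export
simulate_section <- function(scn, panel, counts = TRUE) {
  stopifnot(inherits(scn, "scene"), inherits(panel, "signature_panel"))
  types <- colnames(panel$mu)
  if (!all(c(scn$tumor_type, scn$normal_type) %in% types))
    stop_param("panel must contain the scene's tumor and normal types")

  nx <- floor(scn$width_um / scn$pitch_um)
  ny <- floor(scn$height_um / scn$pitch_um)
  gx <- (seq_len(nx) - 0.5) * scn$pitch_um
  gy <- (seq_len(ny) - 0.5) * scn$pitch_um
  x <- rep(gx, times = ny)
  y <- rep(gy, each = nx)
  n <- nx * ny
  spot_id <- sprintf("s%06d", seq_len(n))

  s <- scene_signed_distance(scn, x, y)
  inside <- s > 0

  ab <- matrix(scn$base_other, nrow = n, ncol = length(types),
               dimnames = list(spot_id, types))
  ab[inside, scn$tumor_type] <- ab[inside, scn$tumor_type] + scn$base_dominant
  ab[!inside, scn$normal_type] <- ab[!inside, scn$normal_type] + scn$base_dominant
  for (g in scn$gradient_specs) {
    if (!g$cell_type %in% types)
      stop_param("gradient cell type '", g$cell_type, "' not in panel")
    on_side <- if (g$side == "tumor") inside else !inside
    ab[on_side, g$cell_type] <- ab[on_side, g$cell_type] +
      g$peak * exp(-abs(s[on_side]) / g$decay_um)
  }

  ab <- ab / rowSums(ab)
  # truth reflects the planted (noise-free) composition
  truth_type <- types[max.col(ab, ties.method = "first")]
  truth_band <- band_from_signed_distance(s)

  if (scn$abundance_noise_sd > 0) {
    ab_noise <- with_seed(sub_seed(scn$seed, 11L), {
      matrix(rnorm(length(ab), sd = scn$abundance_noise_sd), nrow = n)
    })
    ab <- pmax(ab + ab_noise, 0)
    zero <- rowSums(ab) == 0
    ab[zero, ] <- 1 / length(types)
    ab <- ab / rowSums(ab)
  }

  lib <- with_seed(sub_seed(scn$seed, 12L), {
    rlnorm(n, meanlog = log(scn$library_size_median),
           sdlog = scn$library_size_sdlog)
  })

  cnt <- NULL
  if (counts) {
    prof <- ab %*% t(panel$mu)                   # spot x gene
    prof <- prof / rowSums(prof)
    mu_count <- prof * lib
    size <- rep(1 / panel$dispersion, each = n)  # column-major spot x gene
    cnt <- with_seed(sub_seed(scn$seed, 13L), {
      matrix(rnbinom(n * length(panel$genes), mu = as.vector(mu_count),
                     size = size),
             nrow = n, dimnames = list(spot_id, panel$genes))
    })
  }

  structure(list(
    spots = data.frame(spot_id = spot_id, x_um = x, y_um = y,
                       truth_type = truth_type, truth_tumor = inside,
                       truth_band = truth_band, library_size = lib,
                       stringsAsFactors = FALSE),
    abundance = ab, counts = cnt, pitch_um = scn$pitch_um,
    scene = scn, panel = panel),
    class = "spatial_section")
}

#' @export
print.spatial_section <- function(x, ...) {
  cat("spatial_section:", nrow(x$spots), "spots,",
      if (is.null(x$counts)) "no counts" else
        paste(ncol(x$counts), "genes"),
      "|", sum(x$spots$truth_tumor), "tumor-truth spots\n")
  invisible(x)
}

#' Plant copy-number blocks into a simulated section
#'
#' For tumor-truth spots only, the expected counts of the genes inside each
#' scene `cnv_block` are multiplied by the block factor and the counts for
#' those spot x gene cells re-drawn from the same negative-binomial model
#' under a deterministic sub-seed. Non-tumor spots are untouched, and a
#' factor of 1.0 leaves the section bit-identical.
#'
#' @param section a [simulate_section()] result with counts.
#' @param panel the panel used to simulate the section.
#' @param scn the scene carrying `cnv_blocks`.
#' @return the section with modified counts and a `cnv_genes` attribute
#'   (list of gene-id vectors, one per block).
#' @export
plant_cnv <- function(section, panel, scn) {
  stopifnot(inherits(section, "spatial_section"))
  if (is.null(section$counts)) stop_param("section has no counts")
  block_genes <- vector("list", length(scn$cnv_blocks))
  if (length(scn$cnv_blocks) == 0) {
    attr(section, "cnv_genes") <- block_genes
    return(section)
  }

  tumor <- section$spots$truth_tumor
  ab <- section$abundance
  prof <- ab %*% t(panel$mu)
  prof <- prof / rowSums(prof)
  mu_count <- prof * section$spots$library_size

  for (i in seq_along(scn$cnv_blocks)) {
    b <- scn$cnv_blocks[[i]]
    sel <- panel$chrom == b$chrom & panel$ord_pos >= b$start &
      panel$ord_pos <= b$end
    if (!any(sel))
      stop_param("cnv block ", i, " matches no genes (", b$chrom, ":",
                 b$start, "-", b$end, ")")
    block_genes[[i]] <- panel$genes[sel]
    if (b$factor == 1) next
    mu_blk <- mu_count[tumor, sel, drop = FALSE] * b$factor
    size_blk <- rep(1 / panel$dispersion[sel], each = sum(tumor))
    section$counts[tumor, sel] <- with_seed(sub_seed(scn$seed, 20L + i), {
      matrix(rnbinom(length(mu_blk), mu = as.vector(mu_blk), size = size_blk),
             nrow = sum(tumor))
    })
  }
  attr(section, "cnv_genes") <- block_genes
  section
}
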