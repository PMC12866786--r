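#' Pipeline run configuration
#'
#' Collects every stage parameter of the margin-zonation pipeline with the
#' standard defaults (QC 200/2500/5%/3 and 5th-percentile/10-spot spot
#' filters, assignment percentile q = 10, band offsets 500/1000/1500 µm,
#' 250-gene CNV window, DEG thresholds |log2FC| >= 1.5 and alpha = 0.05).
#'
#' @param out_dir artifact directory.
#' @param scene a [scene()] to simulate, or NULL to read `input_dir`.
#' @param input_dir directory with section files (see [read_section()]).
#' @param qc a [qc_config()].
#' @param q assignment ratio percentile.
#' @param tumor_cell_type abundance column used for border detection.
#' @param pixel_um,blur_sigma_um,canny_low,canny_high,simplify_eps_um
#'   geometry parameters (see [detect_tumor_region()]); `pixel_um = NULL`
#'   uses the section pitch.
#' @param offsets band offsets in µm.
#' @param cnv a [cnv_config()].
#' @param lfc_min,alpha DEG thresholds.
#' @param stages character subset of
#'   `c("simulate","qc","assign","margin","zones","cnv","report")`.
#' @param seed integer seed (overrides the scene's).
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, scene = NULL, input_dir = NULL,
                       qc = qc_config(), q = 10,
                       tumor_cell_type = "AT2-like",
                       pixel_um = NULL, blur_sigma_um = NULL,
                       canny_low = 0.1, canny_high = 0.3,
                       simplify_eps_um = 25,
                       offsets = c(500, 1000, 1500),
                       cnv = cnv_config(), lfc_min = 1.5, alpha = 0.05,
                       stages = c("simulate", "qc", "assign", "margin",
                                  "zones", "cnv", "report"),
                       seed = 1) {
  if (is.null(scene) && is.null(input_dir))
    stop_param("either a scene or an input_dir is required")
  structure(list(out_dir = out_dir, scene = scene, input_dir = input_dir,
                 qc = qc, q = q, tumor_cell_type = tumor_cell_type,
                 pixel_um = pixel_um, blur_sigma_um = blur_sigma_um,
                 canny_low = canny_low, canny_high = canny_high,
                 simplify_eps_um = simplify_eps_um, offsets = offsets,
                 cnv = cnv, lfc_min = lfc_min, alpha = alpha,
                 stages = stages, seed = seed),
            class = "run_config")
}

#' Validate pipeline input files
#'
#' Schema checks for the section file set: spot TSV columns and numeric
#' coordinates, unique spot ids, MTX header consistent with its sidecar
#' barcode/feature files, abundance spot ids matching the spot table.
#'
#' @param dir directory holding the input files.
#' @return list with `ok` (logical) and `errors` (character vector).
#' @export
validate_inputs <- function(dir) {
  errors <- character()
  spath <- file.path(dir, "spots.tsv")
  if (!file.exists(spath)) {
    return(list(ok = FALSE, errors = "spots.tsv missing"))
  }
  spots <- tryCatch(read.table(spath, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE),
                    error = function(e) NULL)
  if (is.null(spots)) {
    return(list(ok = FALSE, errors = "spots.tsv unreadable"))
  }
  for (col in c("spot_id", "x_um", "y_um"))
    if (!col %in% names(spots)) errors <- c(errors, paste0("spots.tsv lacks column ", col))
  if ("x_um" %in% names(spots) && !is.numeric(spots$x_um))
    errors <- c(errors, "non-numeric x_um coordinates")
  if ("y_um" %in% names(spots) && !is.numeric(spots$y_um))
    errors <- c(errors, "non-numeric y_um coordinates")
  if ("spot_id" %in% names(spots) && anyDuplicated(spots$spot_id))
    errors <- c(errors, paste0("duplicate spot ids: ",
                               paste(head(unique(spots$spot_id[duplicated(spots$spot_id)]), 5),
                                     collapse = ", ")))
  apath <- file.path(dir, "abundance.tsv")
  if (file.exists(apath)) {
    ab <- read.table(apath, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    miss <- setdiff(spots$spot_id, ab$spot_id)
    if (length(miss))
      errors <- c(errors, paste0("abundance.tsv missing spot id(s): ",
                                 paste(head(miss, 5), collapse = ", ")))
  }
  mpath <- file.path(dir, "counts.mtx")
  if (file.exists(mpath)) {
    hdr <- readLines(mpath, n = 3)
    if (!grepl("^%%MatrixMarket", hdr[1])) {
      errors <- c(errors, "malformed MTX header")
    } else {
      dims_line <- hdr[!grepl("^%", hdr)][1]
      dims <- as.integer(strsplit(trimws(dims_line), "\\s+")[[1]])
      nfeat <- length(readLines(file.path(dir, "features.tsv")))
      nbc <- length(readLines(file.path(dir, "barcodes.tsv")))
      if (dims[1] != nfeat || dims[2] != nbc)
        errors <- c(errors, sprintf(
          "MTX dimensions %dx%d inconsistent with %d features / %d barcodes",
          dims[1], dims[2], nfeat, nbc))
    }
  }
  list(ok = length(errors) == 0, errors = errors)
}

#' Run the margin-zonation pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load),
#' spot QC, cell-type assignment, border detection, zonal band
#' assignment and composition, CNV profiling — writing TSV/MTX/GeoJSON
#' artifacts plus a machine-readable `report.json` into `cfg$out_dir`.
#' Identical configuration and seed reproduce identical artifacts.
#'
#' @param cfg a [run_config()].
#' @return the run report (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(), warnings = character(),
                 version = as.character(packageVersion("spotzone")),
                 parameters = cfg[setdiff(names(cfg), c("scene"))])
  note <- function(w) report$warnings <<- c(report$warnings, w)

  # --- simulate / load -------------------------------------------------
  if ("simulate" %in% cfg$stages && !is.null(cfg$scene)) {
    scn <- cfg$scene
    scn$seed <- cfg$seed
    panel <- make_signature_panel(
      n_genes = 250, n_types = 5, n_chroms = 4, mito_fraction = 0.02,
      seed = sub_seed(cfg$seed, 1L))
    section <- simulate_section(scn, panel)
    section <- plant_cnv(section, panel, scn)
    write_section(section, file.path(cfg$out_dir, "section"))
    report$stages$simulate <- list(n_spots = nrow(section$spots),
                                   n_genes = ncol(section$counts))
  } else {
    section <- read_section(cfg$input_dir)
    v <- validate_inputs(cfg$input_dir)
    if (!v$ok) stop_param("invalid inputs: ", paste(v$errors, collapse = "; "))
    report$stages$load <- list(n_spots = nrow(section$spots))
  }

  # --- spot QC ---------------------------------------------------------
  if ("qc" %in% cfg$stages && !is.null(section$counts)) {
    qc <- qc_filter_spots(section$counts, cfg$qc)
    report$stages$qc <- list(spots_in = nrow(section$counts),
                             spots_removed = length(qc$removed_spots),
                             genes_removed = length(qc$removed_genes),
                             threshold = qc$threshold)
    keep <- !(section$spots$spot_id %in% qc$removed_spots)
    section$counts <- qc$counts
    section$spots <- section$spots[keep, , drop = FALSE]
    section$abundance <- section$abundance[keep, , drop = FALSE]
  }

  # --- assignment ------------------------------------------------------
  assignment <- NULL
  if ("assign" %in% cfg$stages) {
    assignment <- assign_spots(normalize_abundance(section$abundance),
                               q = cfg$q)
    for (w in assignment$warnings) note(w)
    write_tsv_stable(assignment$calls, file.path(cfg$out_dir, "assignment.tsv"))
    report$stages$assign <- list(
      n_assigned = sum(!is.na(assignment$calls$assigned_type)),
      ratio_threshold = assignment$ratio_threshold)
  }

  # --- margin geometry -------------------------------------------------
  bands <- NULL
  if ("margin" %in% cfg$stages) {
    grid <- rasterize_abundance(section, cfg$tumor_cell_type,
                                pixel_um = cfg$pixel_um %||% section$pitch_um)
    region <- detect_tumor_region(
      grid, blur_sigma_um = cfg$blur_sigma_um %||% grid$pixel_um,
      canny_low = cfg$canny_low, canny_high = cfg$canny_high,
      simplify_eps_um = cfg$simplify_eps_um)
    borderline <- extract_borderline(region)
    bands <- build_bands(borderline, offsets = cfg$offsets)
    write_bands_geojson(bands, file.path(cfg$out_dir, "bands.geojson"))
    report$stages$margin <- list(roi_area_um2 = region$area_um2,
                                 n_candidates = length(region$all_candidates),
                                 n_bands = length(bands$labels))
  }

  # --- zonal composition ----------------------------------------------
  if ("zones" %in% cfg$stages && !is.null(bands)) {
    band_labels <- assign_spots_to_bands(section, bands)
    df <- data.frame(spot_id = section$spots$spot_id,
                     band = as.character(band_labels),
                     stringsAsFactors = FALSE)
    write_tsv_stable(df, file.path(cfg$out_dir, "band_assignment.tsv"))
    if (!is.null(assignment)) {
      comp <- band_composition(band_labels, assignment$calls$assigned_type)
      write_tsv_stable(comp, file.path(cfg$out_dir, "composition.tsv"))
      report$stages$zones <- list(
        n_bands = length(levels(band_labels)),
        spots_in_bands = sum(!is.na(band_labels)),
        empty_bands = sum(!levels(band_labels) %in% band_labels))
      if (report$stages$zones$empty_bands > 0) note("empty zonal band(s)")
    }
  }

  # --- CNV -------------------------------------------------------------
  if ("cnv" %in% cfg$stages && !is.null(section$counts) &&
      !is.null(section$panel)) {
    expr <- normalize_log1p(section$counts)
    labels <- section$spots$truth_type
    ref <- reference_profile(expr, labels, cfg$cnv$reference_label)
    prof <- smooth_cnv(expr, ref, panel_annotation(section$panel), cfg$cnv)
    burden <- cnv_burden(prof)
    aberration <- cnv_burden(prof, cnv_config(
      window_genes = cfg$cnv$window_genes,
      reference_label = cfg$cnv$reference_label,
      burden_stat = "mean_square"))
    write_tsv_stable(data.frame(spot_id = section$spots$spot_id,
                                burden = burden,
                                aberration = aberration),
                     file.path(cfg$out_dir, "cnv_burden.tsv"))
    # group comparison on the sign-blind aberration load
    cmp <- compare_burden(split(aberration, labels))
    write_tsv_stable(cmp, file.path(cfg$out_dir, "cnv_comparison.tsv"))
    report$stages$cnv <- list(n_genes = length(prof$genes),
                              window_genes = cfg$cnv$window_genes,
                              n_comparisons = nrow(cmp))
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(report)
}
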