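#' Normalize a deconvolved abundance matrix to a 0-1 scale per spot
#'
#' Each spot's abundances are divided by the spot's maximum, so the
#' dominant type scores exactly 1. All-zero spots cannot be scaled; they
#' are left at zero and flagged via the `all_zero` attribute, and
#' [assign_spots()] leaves them unassigned.
#'
#' @param abundance spot x cell-type matrix of nonnegative reals.
#' @return the normalized matrix with logical attribute `all_zero`.
#' @export
normalize_abundance <- function(abundance) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop_param("abundance must be nonnegative")
  mx <- apply(abundance, 1, max)
  zero <- mx == 0
  out <- abundance / ifelse(zero, 1, mx)
  attr(out, "all_zero") <- zero
  out
}

#' Assign spots to cell types by the dominant-abundance ratio rule
#'
#' Each spot is a candidate for the cell type with the highest normalized
#' abundance. The call is accepted only when the ratio of the dominant to
#' the second-highest abundance strictly exceeds the `q`-th percentile
#' (linear interpolation) of the finite-ratio distribution across all
#' spots in the section. A second-highest abundance of zero gives an
#' infinite ratio: such spots are always assigned but excluded from the
#' threshold distribution.
#'
#' @param abundance normalized spot x type matrix (see
#'   [normalize_abundance()]; raw matrices are normalized on the fly).
#' @param q threshold percentile in `[0, 100)`; default 10.
#' @return object of class `assignment_result`: data.frame `calls` with
#'   spot_id, assigned_type (NA when unassigned), dominant_abundance,
#'   second_abundance, ratio; plus `ratio_threshold`, `q`, and `warnings`.
#' @export
assign_spots <- function(abundance, q = 10) {
  if (q < 0 || q >= 100) stop_param("q must be in [0, 100)")
  if (is.null(attr(abundance, "all_zero")))
    abundance <- normalize_abundance(abundance)
  zero <- attr(abundance, "all_zero")
  types <- colnames(abundance) %||% paste0("type", seq_len(ncol(abundance)))
  spot_id <- rownames(abundance) %||% sprintf("s%06d", seq_len(nrow(abundance)))

  top_idx <- max.col(abundance, ties.method = "first")
  dominant <- abundance[cbind(seq_len(nrow(abundance)), top_idx)]
  tmp <- abundance
  tmp[cbind(seq_len(nrow(abundance)), top_idx)] <- -Inf
  second <- if (ncol(abundance) >= 2) apply(tmp, 1, max) else rep(0, nrow(abundance))
  second <- pmax(second, 0)
  ratio <- ifelse(second == 0, Inf, dominant / second)

  warnings <- character()
  finite <- is.finite(ratio) & !zero
  if (!any(finite)) {
    threshold <- NA_real_
    assigned <- !zero
    warnings <- c(warnings,
                  "no finite abundance ratios; all non-empty spots assigned")
  } else {
    threshold <- percentile(ratio[finite], q)
    assigned <- ratio > threshold & !zero
    if (!any(assigned))
      warnings <- c(warnings, "no spot exceeds the ratio threshold")
  }

  calls <- data.frame(spot_id = spot_id,
                      assigned_type = ifelse(assigned, types[top_idx],
                                             NA_character_),
                      dominant_abundance = dominant,
                      second_abundance = second,
                      ratio = ratio, stringsAsFactors = FALSE)
  structure(list(calls = calls, ratio_threshold = threshold, q = q,
                 warnings = warnings),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  n <- nrow(x$calls); a <- sum(!is.na(x$calls$assigned_type))
  cat(sprintf("assignment_result: %d of %d spots assigned (%.1f%%), ratio threshold %s at q = %s\n",
              a, n, 100 * a / n, format(x$ratio_threshold, digits = 4),
              format(x$q)))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}
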