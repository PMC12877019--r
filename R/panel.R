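#' Marker panel definition
#'
#' An mIF marker panel: an ordered set of exactly eight protein markers plus
#' the image resolution used to convert pixel coordinates to microns. Two
#' stock panels are provided, [lymphoid_panel()] and [myeloid_panel()],
#' matching the two staining panels used in melanoma checkpoint-blockade
#' profiling.
#'
#' @param name Panel name, e.g. `"lymphoid"`.
#' @param markers Character vector of exactly 8 unique marker names. Order is
#'   canonical: positivity columns and state labels follow it.
#' @param resolution_um_per_px Image resolution in microns per pixel
#'   (default 0.4992, the PhenoImager HT export resolution).
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(name, markers, resolution_um_per_px = 0.4992) {
  markers <- as.character(markers)
  if (length(markers) != 8L) {
    stop("a marker panel must contain exactly 8 markers, got ", length(markers))
  }
  if (anyDuplicated(markers)) stop("marker names must be unique")
  if (!is.numeric(resolution_um_per_px) || length(resolution_um_per_px) != 1L ||
      !is.finite(resolution_um_per_px) || resolution_um_per_px <= 0) {
    stop("resolution_um_per_px must be a positive number")
  }
  structure(
    list(name = as.character(name)[1L], markers = markers,
         resolution_um_per_px = resolution_um_per_px),
    class = "marker_panel"
  )
}

#' @rdname marker_panel
#' @export
lymphoid_panel <- function(resolution_um_per_px = 0.4992) {
  marker_panel(
    "lymphoid",
    c("iNOS", "CD20", "PD-L1", "LAG-3", "CD8", "nNOS", "SOX10", "CD3"),
    resolution_um_per_px
  )
}

#' @rdname marker_panel
#' @export
myeloid_panel <- function(resolution_um_per_px = 0.4992) {
  marker_panel(
    "myeloid",
    c("iNOS", "eNOS", "NCad", "CD14", "CD34", "MHCII", "SOX10", "CD11c"),
    resolution_um_per_px
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", x$name, ": ", paste(x$markers, collapse = ", "),
      " (", x$resolution_um_per_px, " um/px)\n", sep = "")
  invisible(x)
}
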