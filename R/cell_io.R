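#' Compute cell centroids from bounding boxes
#'
#' The centroid is the bounding-box midpoint:
#' `x_c = (x_min + x_max) / 2`, `y_c = (y_min + y_max) / 2`. Cells are
#' assigned to tiles, neighborhoods and distances by this point.
#'
#' @param x_min,x_max,y_min,y_max Numeric vectors of bounding-box edges
#'   (any consistent length-recyclable shape).
#' @return A data.frame with columns `x_c`, `y_c`.
#' @export
compute_centroid <- function(x_min, x_max, y_min, y_max) {
  if (any(x_min > x_max, na.rm = TRUE) || any(y_min > y_max, na.rm = TRUE)) {
    stop("inverted bounding box: require x_min <= x_max and y_min <= y_max")
  }
  data.frame(x_c = (x_min + x_max) / 2, y_c = (y_min + y_max) / 2)
}

#' Construct a cell table from a per-cell data.frame
#'
#' Canonical container for one slide's segmentation export: micron
#' coordinates plus one logical positivity column per panel marker.
#'
#' @param df data.frame with columns `cell_id`, bounding box and/or centroid
#'   coordinates, and one column per panel marker (logical or 0/1).
#' @param panel A [marker_panel()].
#' @param slide_id Slide identifier shared by all cells.
#' @param response Response label: `"responder"`, `"non-responder"` or
#'   `"unknown"`.
#' @param sample_type `"resection"` or `"biopsy"`.
#' @return An object of class `cell_table`: list with `panel`, `slide_id`,
#'   `response`, `sample_type` and `cells` (data.frame, coordinates in
#'   microns, marker columns logical).
#' @export
cell_table <- function(df, panel, slide_id,
                       response = "unknown", sample_type = "resection") {
  stopifnot(inherits(panel, "marker_panel"))
  response <- match.arg(response, c("responder", "non-responder", "unknown"))
  sample_type <- match.arg(sample_type, c("resection", "biopsy"))
  need <- c("cell_id", "x_min", "x_max", "y_min", "y_max", "x_c", "y_c",
            panel$markers)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("cell table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  cells <- df[, need, drop = FALSE]
  for (m in panel$markers) cells[[m]] <- as.logical(cells[[m]])
  structure(
    list(panel = panel, slide_id = as.character(slide_id)[1L],
         response = response, sample_type = sample_type,
         cells = cells),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> slide ", x$slide_id, " (", x$response, ", ",
      x$sample_type, "): ", nrow(x$cells), " cells, panel ",
      x$panel$name, "\n", sep = "")
  invisible(x)
}

#' Read a per-cell segmentation export
#'
#' Reads one slide's per-cell table (CSV, or Parquet when the `arrow` package
#' is available), maps vendor column names to the canonical schema, converts
#' pixel coordinates to microns, and coerces marker positivity to logical.
#' Cells with a missing marker call are dropped with a warning: positivity is
#' the atomic datum and is never imputed.
#'
#' If the export carries only centroids, bounding boxes are degenerate
#' (`x_min = x_max = x_c`). If it carries only bounding boxes, centroids are
#' derived with [compute_centroid()].
#'
#' @param path File path (`.csv` or `.parquet`).
#' @param panel A [marker_panel()]; its `resolution_um_per_px` converts pixel
#'   input to microns.
#' @param coord_unit `"um"` or `"px"`: unit of the coordinate columns on file.
#' @param col_map Named character vector mapping canonical names
#'   (`cell_id`, `x_min`, `x_max`, `y_min`, `y_max`, `x_c`, `y_c`, and each
#'   marker) to the column names on file. Canonical names absent from
#'   `col_map` are looked up verbatim.
#' @param slide_id Slide identifier; defaults to the file name sans extension.
#' @param response,sample_type Slide metadata, see [cell_table()].
#' @return A [cell_table()] with coordinates in microns.
#' @export
read_cell_table <- function(path, panel, coord_unit = c("um", "px"),
                            col_map = character(),
                            slide_id = NULL,
                            response = "unknown", sample_type = "resection") {
  coord_unit <- match.arg(coord_unit)
  stopifnot(inherits(panel, "marker_panel"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(slide_id)) slide_id <- sub("\\.[^.]+$", "", basename(path))

  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading Parquet requires the 'arrow' package")
    }
    raw <- as.data.frame(arrow::read_parquet(path))
  } else {
    raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (nrow(raw) == 0L) stop("empty cell table: ", path)

  lookup <- function(canon) if (canon %in% names(col_map)) col_map[[canon]] else canon
  getcol <- function(canon, required = TRUE) {
    nm <- lookup(canon)
    if (!nm %in% names(raw)) {
      if (required) stop("missing column '", nm, "' (for '", canon, "') in ", path)
      return(NULL)
    }
    raw[[nm]]
  }

  # markers first: every panel marker must be present
  pos <- lapply(panel$markers, function(m) {
    v <- getcol(m)
    if (is.character(v)) v <- trimws(v)
    out <- if (is.logical(v)) v else {
      vn <- suppressWarnings(as.numeric(v))
      ifelse(is.na(vn), NA, vn != 0)
    }
    out
  })
  names(pos) <- panel$markers

  num <- function(canon, required = TRUE) {
    v <- getcol(canon, required)
    if (is.null(v)) return(NULL)
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vn) & !is.na(v))
    if (length(bad)) {
      stop("non-numeric coordinate in column '", lookup(canon),
           "' at row ", bad[1L], " of ", path)
    }
    vn
  }

  have_bbox <- all(vapply(c("x_min", "x_max", "y_min", "y_max"),
                          function(c) lookup(c) %in% names(raw), logical(1)))
  have_cent <- all(vapply(c("x_c", "y_c"),
                          function(c) lookup(c) %in% names(raw), logical(1)))
  if (!have_bbox && !have_cent) {
    stop("need bounding-box columns (x_min/x_max/y_min/y_max) or centroid ",
         "columns (x_c/y_c) in ", path)
  }
  if (have_bbox) {
    x_min <- num("x_min"); x_max <- num("x_max")
    y_min <- num("y_min"); y_max <- num("y_max")
  } else {
    x_min <- x_max <- num("x_c")
    y_min <- y_max <- num("y_c")
  }
  if (have_cent) {
    x_c <- num("x_c"); y_c <- num("y_c")
  } else {
    cen <- compute_centroid(x_min, x_max, y_min, y_max)
    x_c <- cen$x_c; y_c <- cen$y_c
  }

  scale <- if (coord_unit == "px") panel$resolution_um_per_px else 1
  df <- data.frame(
    cell_id = as.character(getcol("cell_id")),
    x_min = x_min * scale, x_max = x_max * scale,
    y_min = y_min * scale, y_max = y_max * scale,
    x_c = x_c * scale, y_c = y_c * scale,
    stringsAsFactors = FALSE
  )
  for (m in panel$markers) df[[m]] <- pos[[m]]

  incomplete <- Reduce(`|`, lapply(pos, is.na))
  if (any(incomplete)) {
    warning(sum(incomplete), " cell(s) with missing marker calls dropped from ",
            slide_id)
    df <- df[!incomplete, , drop = FALSE]
    if (nrow(df) == 0L) stop("no complete cells left in ", path)
  }
  cell_table(df, panel, slide_id, response, sample_type)
}

#' Write a cell table to CSV
#'
#' Inverse of [read_cell_table()] for the canonical schema (micron
#' coordinates, 0/1 positivity columns).
#'
#' @param table A [cell_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  stopifnot(inherits(table, "cell_table"))
  df <- table$cells
  for (m in table$panel$markers) df[[m]] <- as.integer(df[[m]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Validate a cell table against its invariants
#'
#' Checks every cell for: ordered bounding box, centroid inside the box,
#' finite non-negative coordinates, and complete marker calls. Violations are
#' returned as data, not raised.
#'
#' @param table A [cell_table()].
#' @return data.frame with columns `cell_id`, `rule`; zero rows when the
#'   table is valid.
#' @export
validate_cell_table <- function(table) {
  stopifnot(inherits(table, "cell_table"))
  d <- table$cells
  eps <- 1e-9
  viol <- function(idx, rule) {
    data.frame(cell_id = d$cell_id[idx], rule = rep(rule, length(idx)),
               stringsAsFactors = FALSE)
  }
  pos <- as.matrix(d[, table$panel$markers, drop = FALSE])
  out <- list(
    viol(which(d$x_min > d$x_max), "x_min > x_max"),
    viol(which(d$y_min > d$y_max), "y_min > y_max"),
    viol(which(d$x_c < d$x_min - eps | d$x_c > d$x_max + eps |
                 d$y_c < d$y_min - eps | d$y_c > d$y_max + eps),
         "centroid outside bounding box"),
    viol(which(!is.finite(d$x_c) | !is.finite(d$y_c) |
                 d$x_min < 0 | d$y_min < 0),
         "non-finite or negative coordinate"),
    viol(which(rowSums(is.na(pos)) > 0), "missing marker call")
  )
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
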