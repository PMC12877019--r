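#' Build the cell-state catalog from pooled marker combinations
#'
#' A cell state is a marker combination; the catalog comprises the `top_n`
#' most frequent exact positivity patterns pooled across all slides, plus a
#' singleton state for every panel marker not already present as a singleton,
#' plus the stromal state (no positive marker). State labels join marker
#' names in panel order with `"+"`; the stromal sentinel is `"Stromal"`.
#'
#' Counting uses exact patterns; membership (see [state_membership()]) uses
#' superset matching, so a CD3+CD8+ cell belongs to the CD3, CD8 and CD3+CD8
#' states alike.
#'
#' Ties in pattern counts are broken lexicographically by label, then by
#' smaller set size; this makes the catalog deterministic.
#'
#' @param tables List of [cell_table()] objects sharing one panel.
#' @param top_n Number of top exact patterns to admit (default 20).
#' @param min_prevalence Optional minimum pooled prevalence (fraction of all
#'   cells, exact-pattern basis) below which a top-`n` state is pruned;
#'   default `0` (no pruning).
#' @return An object of class `cell_state_catalog`: list with `panel`,
#'   `top_n` and `states` (data.frame: `label`, `markers` list-column,
#'   `rank`, `count`, `source` in `{"combination","singleton","stromal"}`).
#' @export
enumerate_states <- function(tables, top_n = 20, min_prevalence = 0) {
  if (inherits(tables, "cell_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L, inherits(tables[[1L]], "marker_panel") == FALSE)
  panel <- tables[[1L]]$panel
  mk <- panel$markers

  pos <- do.call(rbind, lapply(tables, function(t) {
    as.matrix(t$cells[, mk, drop = FALSE]) * 1L
  }))
  n_total <- nrow(pos)
  pat <- apply(pos, 1L, function(r) paste(r, collapse = ""))
  counts <- table(pat)
  stromal_code <- paste(rep("0", length(mk)), collapse = "")
  counts <- counts[names(counts) != stromal_code]

  label_of <- function(code) {
    on <- mk[strsplit(code, "")[[1L]] == "1"]
    paste(on, collapse = "+")
  }
  size_of <- function(code) sum(strsplit(code, "")[[1L]] == "1")

  if (length(counts) == 0L) {
    warning("all cells are marker-negative; catalog contains only Stromal")
    top <- data.frame(label = character(), count = integer(),
                      code = character(), stringsAsFactors = FALSE)
  } else {
    df <- data.frame(code = names(counts), count = as.integer(counts),
                     stringsAsFactors = FALSE)
    df$label <- vapply(df$code, label_of, character(1))
    df$size <- vapply(df$code, size_of, integer(1))
    # lexicographic tie-break on the sorted-marker label, then smaller set
    lex <- vapply(df$code, function(code) {
      on <- sort(mk[strsplit(code, "")[[1L]] == "1"])
      paste(on, collapse = "+")
    }, character(1))
    df <- df[order(-df$count, lex, df$size, method = "radix"), , drop = FALSE]
    top <- utils::head(df, top_n)
    if (min_prevalence > 0) {
      top <- top[top$count / n_total >= min_prevalence, , drop = FALSE]
    }
  }

  states <- data.frame(label = top$label, count = top$count,
                       source = rep("combination", nrow(top)),
                       stringsAsFactors = FALSE)
  states$markers <- lapply(top$code, function(code) mk[strsplit(code, "")[[1L]] == "1"])

  # singleton fill-in for markers not already represented as singletons
  have_singleton <- vapply(states$markers, function(s) length(s) == 1L, logical(1))
  singletons_present <- unlist(states$markers[have_singleton])
  todo <- setdiff(mk, singletons_present)
  if (length(todo)) {
    cnt <- vapply(todo, function(m) sum(pos[, m]), numeric(1))
    o <- order(-cnt, todo, method = "radix")
    add <- data.frame(label = todo[o], count = as.integer(cnt[o]),
                      source = "singleton", stringsAsFactors = FALSE)
    add$markers <- as.list(todo[o])
    states <- rbind(states, add)
  }
  stromal <- data.frame(label = "Stromal",
                        count = sum(pat == stromal_code),
                        source = "stromal", stringsAsFactors = FALSE)
  stromal$markers <- list(character(0))
  states <- rbind(states, stromal)
  states$rank <- seq_len(nrow(states))
  states <- states[, c("label", "markers", "rank", "count", "source")]

  structure(list(panel = panel, top_n = top_n, states = states),
            class = "cell_state_catalog")
}

#' @export
print.cell_state_catalog <- function(x, ...) {
  cat("<cell_state_catalog> ", nrow(x$states), " states (top_n = ", x$top_n,
      ", panel ", x$panel$name, ")\n", sep = "")
  invisible(x)
}

#' State membership under superset matching
#'
#' A cell belongs to state S iff it is positive for every marker of S
#' (regardless of further positives); it belongs to Stromal iff it is
#' negative for all panel markers.
#'
#' @param positivity Logical matrix (cells x panel markers) or a single
#'   cell's logical vector.
#' @param catalog A [enumerate_states()] catalog.
#' @return Logical matrix (cells x states), columns named by state label.
#' @export
state_membership <- function(positivity, catalog) {
  stopifnot(inherits(catalog, "cell_state_catalog"))
  mk <- catalog$panel$markers
  if (is.vector(positivity)) positivity <- matrix(positivity, nrow = 1,
                                                  dimnames = list(NULL, mk))
  pos <- positivity[, mk, drop = FALSE] * 1L
  memb <- vapply(seq_len(nrow(catalog$states)), function(i) {
    s <- catalog$states$markers[[i]]
    if (length(s) == 0L) rowSums(pos) == 0L
    else rowSums(pos[, s, drop = FALSE]) == length(s)
  }, logical(nrow(pos)))
  if (nrow(pos) == 1L) memb <- matrix(memb, nrow = 1)
  colnames(memb) <- catalog$states$label
  memb
}

#' Serialize / read a cell-state catalog as JSON
#'
#' @param catalog A `cell_state_catalog`.
#' @param path JSON file path.
#' @return `write_catalog`: `path` invisibly. `read_catalog`: the catalog.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "cell_state_catalog"))
  obj <- list(
    panel = list(name = catalog$panel$name, markers = catalog$panel$markers,
                 resolution_um_per_px = catalog$panel$resolution_um_per_px),
    top_n = catalog$top_n,
    states = lapply(seq_len(nrow(catalog$states)), function(i) {
      s <- catalog$states[i, ]
      list(label = s$label, markers = s$markers[[1L]], rank = s$rank,
           count = s$count, source = s$source)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  panel <- marker_panel(obj$panel$name, unlist(obj$panel$markers),
                        obj$panel$resolution_um_per_px)
  states <- data.frame(
    label = vapply(obj$states, `[[`, character(1), "label"),
    rank = vapply(obj$states, `[[`, integer(1), "rank"),
    count = vapply(obj$states, `[[`, integer(1), "count"),
    source = vapply(obj$states, `[[`, character(1), "source"),
    stringsAsFactors = FALSE
  )
  states$markers <- lapply(obj$states, function(s) as.character(unlist(s$markers)))
  states <- states[, c("label", "markers", "rank", "count", "source")]
  structure(list(panel = panel, top_n = obj$top_n, states = states),
            class = "cell_state_catalog")
}
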