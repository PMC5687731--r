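#' Per-vertex scalar map with a validity mask
#'
#' The carrier type for every per-vertex quantity in the package (mean tract
#' length, connectivity indices, statistics).  Vertices without data — e.g.
#' vertices that selected no streamline — are *invalid*: they carry `NA` and
#' are excluded from smoothing stencils and statistics rather than being
#' zero-filled, which would silently bias connectivity-index comparisons.
#'
#' @param values numeric vector, one entry per mesh vertex; `NA`/`NaN`
#'   entries are marked invalid.
#' @param valid optional logical vector; defaults to `!is.na(values)`.
#' @param name short label for the quantity.
#' @param units unit label (e.g. "mm", "percent").
#' @return an object of class `vertex_map`: list with `values` (invalid
#'   entries set to `NA`), `valid`, `name`, `units`.
#' @export
vertex_map <- function(values, valid = NULL, name = "", units = "") {
  values <- as.double(values)
  if (is.null(valid)) valid <- !is.na(values)
  valid <- as.logical(valid)
  if (length(valid) != length(values)) stop("values and valid must have equal length")
  valid[is.na(valid)] <- FALSE
  valid <- valid & !is.na(values)
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid, name = name, units = units),
            class = "vertex_map")
}

#' @export
print.vertex_map <- function(x, ...) {
  cat(sprintf("vertex_map '%s' [%s]: %d vertices, %d valid; range [%.4g, %.4g]\n",
              x$name, x$units, length(x$values), sum(x$valid),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

check_map_matches <- function(map, n_vertices) {
  if (length(map$values) != n_vertices) {
    stop(sprintf("vertex map has %d entries but the mesh has %d vertices",
                 length(map$values), n_vertices))
  }
  invisible(TRUE)
}

#' Write a per-vertex scalar map
#'
#' Supported formats: FreeSurfer curv (`freesurfer_curv`; invalid vertices
#' stored as NaN), GIFTI functional file (`gifti`, one FLOAT32 data array,
#' NaN sentinel), and CSV (`csv`: columns `vertex` — 0-based, documented in
#' a header comment — and `value`, with invalid vertices as empty fields).
#'
#' @param map a [vertex_map].
#' @param path output file path.
#' @param format one of `"csv"`, `"freesurfer_curv"`, `"gifti"`.
#' @param n_vertices optional declared mesh vertex count to check against.
#' @return `path`, invisibly.
#' @export
write_vertex_map <- function(map, path,
                             format = c("csv", "freesurfer_curv", "gifti"),
                             n_vertices = NULL) {
  format <- match.arg(format)
  if (!inherits(map, "vertex_map")) stop("map must be a vertex_map")
  if (!is.null(n_vertices)) check_map_matches(map, n_vertices)
  vals <- map$values
  vals[!map$valid] <- NaN
  switch(format,
    csv = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(c("# surfconn vertex map; vertex indices are 0-based; empty value = invalid vertex",
                   sprintf("# name=%s units=%s", map$name, map$units),
                   "vertex,value"), con)
      txt <- ifelse(map$valid, formatC(map$values, digits = 17, format = "g"), "")
      writeLines(paste(seq_along(vals) - 1L, txt, sep = ","), con)
    },
    freesurfer_curv = write_fs_curv(vals, path),
    gifti = write_gifti_func(vals, path, name = map$name)
  )
  invisible(path)
}

#' Read a per-vertex scalar map
#'
#' Inverse of [write_vertex_map()]; NaN values (curv/GIFTI) and empty CSV
#' fields are mapped back to invalid vertices.
#'
#' @param path input file path.
#' @param format one of `"csv"`, `"freesurfer_curv"`, `"gifti"`.
#' @param n_vertices optional declared vertex count to check against.
#' @return a [vertex_map].
#' @export
read_vertex_map <- function(path, format = c("csv", "freesurfer_curv", "gifti"),
                            n_vertices = NULL) {
  format <- match.arg(format)
  out <- switch(format,
    csv = {
      df <- utils::read.csv(path, comment.char = "#",
                            colClasses = c("integer", "numeric"))
      if (!all(c("vertex", "value") %in% names(df))) stop("CSV map needs vertex,value columns")
      nv <- max(df$vertex) + 1L
      vals <- rep(NA_real_, nv)
      vals[df$vertex + 1L] <- df$value
      vertex_map(vals)
    },
    freesurfer_curv = vertex_map(read_fs_curv(path)),
    gifti = vertex_map(read_gifti_func(path))
  )
  if (!is.null(n_vertices)) check_map_matches(out, n_vertices)
  out
}
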