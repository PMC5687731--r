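#' Read a triangulated cortical surface
#'
#' Supported formats: FreeSurfer binary triangle surface
#' (`freesurfer_binary`, the `lh.white`-style format), GIFTI surface
#' (`gifti`, `.surf.gii`) and OFF (`off`).  Coordinates are interpreted as
#' millimetres in the file's native space; all downstream computation stays
#' in that space.
#'
#' @param path input file.
#' @param format one of `"freesurfer_binary"`, `"gifti"`, `"off"`; by
#'   default guessed from the file extension (`.gii` -> gifti, `.off` ->
#'   off, anything else FreeSurfer binary).
#' @param validate passed to [surface_mesh()].
#' @return a [surface_mesh].
#' @export
read_surface <- function(path, format = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.gii$", path)) "gifti"
              else if (grepl("\\.off$", path, ignore.case = TRUE)) "off"
              else "freesurfer_binary"
  }
  format <- match.arg(format, c("freesurfer_binary", "gifti", "off"))
  raw <- switch(format,
    freesurfer_binary = read_fs_surface(path),
    gifti = read_gifti_surface(path),
    off = read_off_surface(path)
  )
  surface_mesh(raw$vertices, raw$triangles, validate = validate)
}

#' Write a triangulated surface
#'
#' @param mesh a [surface_mesh].
#' @param path output file.
#' @param format as in [read_surface()].
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gii$", path)) "gifti"
              else if (grepl("\\.off$", path, ignore.case = TRUE)) "off"
              else "freesurfer_binary"
  }
  format <- match.arg(format, c("freesurfer_binary", "gifti", "off"))
  switch(format,
    freesurfer_binary = write_fs_surface(mesh$vertices, mesh$triangles, path),
    gifti = write_gifti_surface(mesh$vertices, mesh$triangles, path),
    off = write_off_surface(mesh$vertices, mesh$triangles, path)
  )
  invisible(path)
}

# --- FreeSurfer binary triangle surface --------------------------------------
# Layout (big-endian): 3-byte magic 0xFFFFFE, a creator line terminated by
# "\n\n", int32 vertex count, int32 face count, float32 xyz per vertex,
# int32 triples of 0-based vertex indices per face.

FS_TRIANGLE_MAGIC <- as.raw(c(0xff, 0xff, 0xfe))
FS_CURV_MAGIC <- as.raw(c(0xff, 0xff, 0xff))

read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3)
  if (!identical(magic, FS_TRIANGLE_MAGIC)) {
    stop(sprintf("not a FreeSurfer binary triangle surface (bad magic at byte 0): %s", path))
  }
  # creator string ends at the first "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) stop("unexpected end of file in FreeSurfer surface header: ", path)
    if (b == as.raw(10) && prev == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (is.na(nv) || is.na(nf) || nv <= 0 || nf <= 0) {
    stop("invalid vertex/face counts in FreeSurfer surface: ", path)
  }
  verts <- readBin(con, "double", n = 3 * nv, size = 4, endian = "big")
  faces <- readBin(con, "integer", n = 3 * nf, size = 4, endian = "big")
  if (length(verts) < 3 * nv || length(faces) < 3 * nf) {
    stop("truncated FreeSurfer surface data section: ", path)
  }
  list(vertices = matrix(verts, ncol = 3, byrow = TRUE),
       triangles = matrix(faces, ncol = 3, byrow = TRUE) + 1L)
}

write_fs_surface <- function(vertices, triangles, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FS_TRIANGLE_MAGIC, con)
  writeBin(charToRaw("created by surfconn\n\n"), con)
  writeBin(as.integer(nrow(vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(nrow(triangles)), con, size = 4, endian = "big")
  writeBin(as.double(t(vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(triangles) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

# --- FreeSurfer curv (new format) --------------------------------------------
# 3-byte magic 0xFFFFFF, int32 vertex count, int32 face count, int32
# values-per-vertex (always 1 here), float32 values. Big-endian throughout.

read_fs_curv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3)
  if (!identical(magic, FS_CURV_MAGIC)) {
    stop("not a new-format FreeSurfer curv file (bad magic at byte 0): ", path)
  }
  nv <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  readBin(con, "integer", n = 1, size = 4, endian = "big")  # face count, unused
  vpv <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (vpv != 1L) stop("curv files with values_per_vertex != 1 are not supported: ", path)
  vals <- readBin(con, "double", n = nv, size = 4, endian = "big")
  if (length(vals) < nv) stop("truncated curv data section: ", path)
  vals
}

write_fs_curv <- function(values, path, n_faces = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FS_CURV_MAGIC, con)
  writeBin(as.integer(length(values)), con, size = 4, endian = "big")
  writeBin(as.integer(n_faces), con, size = 4, endian = "big")
  writeBin(1L, con, size = 4, endian = "big")
  writeBin(as.double(values), con, size = 4, endian = "big")
  invisible(path)
}

# --- OFF ---------------------------------------------------------------------

read_off_surface <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!grepl("^OFF", lines[1])) stop("not an OFF file (missing OFF keyword on line 1): ", path)
  counts <- scan(text = lines[2], what = double(), quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  verts <- matrix(scan(text = lines[3:(2 + nv)], what = double(), quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  fl <- scan(text = lines[(3 + nv):(2 + nv + nf)], what = double(), quiet = TRUE)
  fm <- matrix(fl, ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3)) stop("OFF reader supports triangle faces only: ", path)
  list(vertices = verts, triangles = fm[, 2:4, drop = FALSE] + 1L)
}

write_off_surface <- function(vertices, triangles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(vertices), nrow(triangles)), con)
  writeLines(apply(vertices, 1, function(r) paste(formatC(r, digits = 17, format = "g"), collapse = " ")), con)
  writeLines(apply(triangles - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' Read a 4x4 affine from a whitespace-separated text file
#'
#' Four lines of four numbers, as written by most registration tools'
#' text export.
#'
#' @param path input file.
#' @return 4x4 numeric matrix.
#' @export
read_affine <- function(path) {
  vals <- scan(path, what = double(), comment.char = "#", quiet = TRUE)
  if (length(vals) != 16) stop("affine file must contain exactly 16 numbers: ", path)
  matrix(vals, 4, 4, byrow = TRUE)
}
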