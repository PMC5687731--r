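#' Read a tractogram (TRK or TCK)
#'
#' Returned points are always in millimetre world (RAS) space: TCK files
#' store world coordinates natively; for TRK the header's voxel size and
#' voxel-to-RAS matrix are honored using the usual convention
#' `world = M %*% (p / voxel_size - 0.5)` (TRK stores corner-origin
#' voxel-mm coordinates).  Streamlines with fewer than 2 points are dropped
#' with a message, not an error.
#'
#' @param path input file.
#' @param format `"trk"` or `"tck"`; guessed from the extension by default.
#' @return a [tractogram].
#' @export
read_tractogram <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.trk$", path, ignore.case = TRUE)) "trk" else "tck"
  }
  format <- match.arg(format, c("trk", "tck"))
  pts <- switch(format, trk = read_trk(path), tck = read_tck(path))
  n_short <- sum(vapply(pts, nrow, integer(1)) < 2L)
  if (n_short > 0) {
    message(sprintf("dropped %d streamline(s) with < 2 points", n_short))
    pts <- pts[vapply(pts, nrow, integer(1)) >= 2L]
  }
  if (length(pts) == 0L) return(empty_tractogram())
  tractogram(pts)
}

#' Write a tractogram (TRK or TCK)
#'
#' @param tractogram a [tractogram] with points in mm world space.
#' @param path output file.
#' @param format `"trk"` or `"tck"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(tractogram, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.trk$", path, ignore.case = TRUE)) "trk" else "tck"
  }
  format <- match.arg(format, c("trk", "tck"))
  switch(format,
         trk = write_trk(tractogram$streamlines, path),
         tck = write_tck(tractogram$streamlines, path))
  invisible(path)
}

# --- TCK (MRtrix tracks) -----------------------------------------------------
# Text header terminated by "END\n"; float32 little-endian triplets, one
# (NaN,NaN,NaN) triplet between streamlines, one (Inf,Inf,Inf) at the end.

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (!grepl("^mrtrix tracks", first)) stop("not a TCK file (missing 'mrtrix tracks' signature): ", path)
  datatype <- "Float32LE"
  offset <- NA_integer_
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("TCK header missing END keyword: ", path)
    if (grepl("^END", line)) break
    kv <- sub("^([^:]+):\\s*(.*)$", "\\1\x01\\2", line)
    parts <- strsplit(kv, "\x01", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      key <- trimws(parts[1]); val <- trimws(parts[2])
      if (key == "datatype") datatype <- val
      if (key == "file") offset <- as.integer(sub("^\\.\\s*", "", val))
    }
  }
  if (!datatype %in% c("Float32LE", "Float32BE")) {
    stop("unsupported TCK datatype (only Float32LE/BE): ", datatype)
  }
  endian <- if (datatype == "Float32BE") "big" else "little"
  if (is.na(offset)) stop("TCK header missing 'file: . <offset>' entry: ", path)
  seek(con, where = offset, origin = "start")
  vals <- readBin(con, "double", n = (file.size(path) - offset) / 4, size = 4,
                  endian = endian)
  if (length(vals) %% 3 != 0) stop("TCK data section is not a whole number of triplets: ", path)
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  is_end <- is.infinite(m[, 1])
  if (any(is_end)) m <- m[seq_len(which(is_end)[1] - 1L), , drop = FALSE]
  is_sep <- is.nan(m[, 1])
  n_streams <- sum(is_sep) + as.integer(nrow(m) > 0 && !is_sep[nrow(m)])
  if (n_streams == 0L) return(list())
  grp <- cumsum(is_sep) - is_sep  # 0-based streamline id per row
  keep <- !is_sep
  groups <- split(which(keep), factor(grp[keep], levels = 0:(n_streams - 1L)))
  lapply(unname(groups), function(ix) m[ix, , drop = FALSE])
}

write_tck <- function(streamlines, path) {
  n <- length(streamlines)
  hdr_body <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                     sprintf("%010d", n), "\nfile: . ")
  # the offset field counts itself; fixed-width offset keeps this simple
  offset <- nchar(hdr_body, type = "bytes") + 10L + nchar("\nEND\n", type = "bytes")
  hdr <- paste0(hdr_body, sprintf("%10d", offset), "\nEND\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  for (s in streamlines) {
    writeBin(as.double(t(s)), con, size = 4, endian = "little")
    writeBin(as.double(c(NaN, NaN, NaN)), con, size = 4, endian = "little")
  }
  writeBin(as.double(c(Inf, Inf, Inf)), con, size = 4, endian = "little")
  invisible(path)
}

# --- TRK (TrackVis) ----------------------------------------------------------
# 1000-byte little-endian header (version 2). Points are stored in
# corner-origin voxel-mm coordinates; world = M %*% (p/voxel_size - 0.5).

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1000)
  if (length(hdr) < 1000) stop("TRK header shorter than 1000 bytes: ", path)
  if (rawToChar(hdr[1:5]) != "TRACK") stop("not a TRK file (bad id string at byte 0): ", path)
  rint <- function(off, n, size, endian = "little") {
    readBin(hdr[(off + 1):(off + n * size)], "integer", n = n, size = size, endian = endian)
  }
  rflt <- function(off, n, endian = "little") {
    readBin(hdr[(off + 1):(off + n * 4)], "double", n = n, size = 4, endian = endian)
  }
  endian <- "little"
  hdr_size <- rint(996, 1, 4, endian)
  if (hdr_size != 1000L) {
    endian <- "big"
    hdr_size <- rint(996, 1, 4, endian)
    if (hdr_size != 1000L) stop("TRK hdr_size field (byte 996) is not 1000; corrupt header: ", path)
  }
  voxel_size <- rflt(12, 3, endian)
  n_scalars <- rint(36, 1, 2, endian)
  n_properties <- rint(238, 1, 2, endian)
  M <- matrix(rflt(440, 16, endian), 4, 4, byrow = TRUE)
  if (all(M == 0)) {
    warning("TRK vox_to_ras matrix is all zeros; assuming identity")
    M <- diag(4)
  }
  if (all(voxel_size == 0)) voxel_size <- c(1, 1, 1)
  n_count <- rint(988, 1, 4, endian)

  A <- M[1:3, 1:3]
  b <- M[1:3, 4]
  out <- list()
  i <- 0L
  repeat {
    npts <- readBin(con, "integer", n = 1, size = 4, endian = endian)
    if (length(npts) == 0) break
    i <- i + 1L
    vals <- readBin(con, "double", n = npts * (3 + n_scalars), size = 4, endian = endian)
    if (length(vals) < npts * (3 + n_scalars)) stop("truncated TRK streamline record: ", path)
    if (n_properties > 0) readBin(con, "double", n = n_properties, size = 4, endian = endian)
    m <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2, voxel_size, "/") - 0.5
    out[[i]] <- sweep(vox %*% t(A), 2, b, "+")
    if (n_count > 0 && i >= n_count) break
  }
  out
}

write_trk <- function(streamlines, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- raw(1000)
  put <- function(h, off, raw) { h[(off + 1):(off + length(raw))] <- raw; h }
  hdr <- put(hdr, 0, charToRaw("TRACK"))
  hdr <- put(hdr, 6, writeBin(c(1L, 1L, 1L), raw(), size = 2, endian = "little"))      # dim
  hdr <- put(hdr, 12, writeBin(c(1, 1, 1), raw(), size = 4, endian = "little"))        # voxel_size
  hdr <- put(hdr, 36, writeBin(0L, raw(), size = 2, endian = "little"))                # n_scalars
  hdr <- put(hdr, 238, writeBin(0L, raw(), size = 2, endian = "little"))               # n_properties
  hdr <- put(hdr, 440, writeBin(as.double(t(diag(4))), raw(), size = 4, endian = "little"))
  hdr <- put(hdr, 948, charToRaw("RAS"))                                               # voxel_order
  hdr <- put(hdr, 988, writeBin(length(streamlines), raw(), size = 4, endian = "little"))
  hdr <- put(hdr, 992, writeBin(2L, raw(), size = 4, endian = "little"))               # version
  hdr <- put(hdr, 996, writeBin(1000L, raw(), size = 4, endian = "little"))            # hdr_size
  writeBin(hdr, con)
  # inverse of world = I %*% (p/1 - 0.5): p = world + 0.5
  for (s in streamlines) {
    writeBin(nrow(s), con, size = 4, endian = "little")
    writeBin(as.double(t(s + 0.5)), con, size = 4, endian = "little")
  }
  invisible(path)
}
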