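# Minimal GIFTI reader/writer (surface .surf.gii and functional .func.gii).
# Writes Base64Binary little-endian arrays; reads ASCII, Base64Binary and
# GZipBase64Binary encodings, which covers files produced by the common
# neuroimaging toolchains.

gifti_datatype_info <- function(dt) {
  switch(dt,
    NIFTI_TYPE_FLOAT32 = list(what = "double", size = 4L),
    NIFTI_TYPE_FLOAT64 = list(what = "double", size = 8L),
    NIFTI_TYPE_INT32 = list(what = "integer", size = 4L),
    NIFTI_TYPE_UINT8 = list(what = "integer", size = 1L),
    stop("unsupported GIFTI DataType: ", dt)
  )
}

read_gifti_array <- function(node) {
  dt <- xml2::xml_attr(node, "DataType")
  enc <- xml2::xml_attr(node, "Encoding")
  endian <- xml2::xml_attr(node, "Endian")
  ndim <- as.integer(xml2::xml_attr(node, "Dimensionality"))
  dims <- vapply(seq_len(ndim) - 1L, function(k)
    as.integer(xml2::xml_attr(node, paste0("Dim", k))), integer(1))
  order <- xml2::xml_attr(node, "ArrayIndexingOrder")
  data_node <- xml2::xml_find_first(node, ".//*[local-name()='Data']")
  txt <- xml2::xml_text(data_node)
  info <- gifti_datatype_info(dt)
  n <- prod(dims)
  vals <- switch(enc,
    ASCII = {
      v <- scan(text = txt, what = double(), quiet = TRUE)
      if (info$what == "integer") as.integer(v) else v
    },
    Base64Binary = {
      raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
      readBin(raw, info$what, n = n, size = info$size,
              endian = if (identical(endian, "BigEndian")) "big" else "little")
    },
    GZipBase64Binary = {
      raw <- memDecompress(jsonlite::base64_dec(gsub("[[:space:]]", "", txt)),
                           type = "gzip")
      readBin(raw, info$what, n = n, size = info$size,
              endian = if (identical(endian, "BigEndian")) "big" else "little")
    },
    stop("unsupported GIFTI Encoding: ", enc)
  )
  if (length(vals) != n) {
    stop(sprintf("GIFTI data array truncated: expected %d values, got %d", n, length(vals)))
  }
  if (ndim == 2L) {
    # RowMajorOrder is the GIFTI default and what we write
    if (identical(order, "ColumnMajorOrder")) {
      matrix(vals, nrow = dims[1], ncol = dims[2])
    } else {
      matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    }
  } else {
    vals
  }
}

gifti_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='DataArray']")
  if (length(nodes) == 0L) stop("no DataArray elements found in GIFTI file: ", path)
  intents <- vapply(nodes, function(n) xml2::xml_attr(n, "Intent"), character(1))
  list(nodes = nodes, intents = intents)
}

gifti_encode <- function(values, datatype) {
  info <- gifti_datatype_info(datatype)
  raw <- writeBin(if (info$what == "integer") as.integer(values) else as.double(values),
                  raw(), size = info$size, endian = "little")
  jsonlite::base64_enc(raw)
}

gifti_array_xml <- function(mat_or_vec, intent, datatype) {
  if (is.matrix(mat_or_vec)) {
    dims <- sprintf('Dimensionality="2" Dim0="%d" Dim1="%d"',
                    nrow(mat_or_vec), ncol(mat_or_vec))
    vals <- as.vector(t(mat_or_vec))  # row-major
  } else {
    dims <- sprintf('Dimensionality="1" Dim0="%d"', length(mat_or_vec))
    vals <- mat_or_vec
  }
  paste0('<DataArray Intent="', intent, '" DataType="', datatype,
         '" ArrayIndexingOrder="RowMajorOrder" ', dims,
         ' Encoding="Base64Binary" Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">\n',
         "<Data>", gifti_encode(vals, datatype), "</Data>\n</DataArray>")
}

write_gifti_doc <- function(arrays_xml, path) {
  txt <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<!DOCTYPE GIFTI SYSTEM "http://www.nitrc.org/frs/download.php/115/gifti.dtd">\n',
                '<GIFTI xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" Version="1.0" NumberOfDataArrays="',
                length(arrays_xml), '">\n',
                paste(arrays_xml, collapse = "\n"), "\n</GIFTI>\n")
  writeLines(txt, path, sep = "")
  invisible(path)
}

read_gifti_surface <- function(path) {
  ga <- gifti_arrays(path)
  ip <- which(ga$intents == "NIFTI_INTENT_POINTSET")
  it <- which(ga$intents == "NIFTI_INTENT_TRIANGLE")
  if (!length(ip) || !length(it)) {
    stop("GIFTI surface needs POINTSET and TRIANGLE data arrays: ", path)
  }
  verts <- read_gifti_array(ga$nodes[[ip[1]]])
  tris <- read_gifti_array(ga$nodes[[it[1]]])
  list(vertices = verts, triangles = matrix(as.integer(tris), ncol = 3) + 1L)
}

write_gifti_surface <- function(vertices, triangles, path) {
  write_gifti_doc(c(
    gifti_array_xml(vertices, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32"),
    gifti_array_xml(triangles - 1L, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32")
  ), path)
}

read_gifti_func <- function(path) {
  ga <- gifti_arrays(path)
  as.double(read_gifti_array(ga$nodes[[1]]))
}

write_gifti_func <- function(values, path, name = "") {
  write_gifti_doc(gifti_array_xml(as.double(values), "NIFTI_INTENT_NONE",
                                  "NIFTI_TYPE_FLOAT32"), path)
}
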