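#' Tractogram: a list of streamline polylines
#'
#' Streamlines are ordered 3-D polylines in millimetres.  Each streamline
#' carries a length (sum of segment norms) and a weight equal to the inverse
#' of its length — the standard correction for the bias that longer fibers
#' are reconstructed more often by streamline tractography.
#'
#' @param streamlines list of k x 3 numeric matrices (k >= 2).
#' @return an object of class `tractogram`: list with `streamlines`,
#'   `lengths` (mm) and `weights` (= 1/lengths).
#' @export
tractogram <- function(streamlines) {
  if (!is.list(streamlines)) stop("streamlines must be a list of k x 3 matrices")
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3L) stop("each streamline must have 3 columns (x, y, z)")
    if (nrow(s) < 2L) stop("each streamline must have >= 2 points")
    s
  })
  lengths <- streamline_lengths(streamlines)
  if (any(lengths <= 0)) stop("streamline with zero length (all points coincide)")
  structure(list(streamlines = streamlines, lengths = lengths,
                 weights = 1 / lengths),
            class = "tractogram")
}

streamline_lengths <- function(streamlines) {
  vapply(streamlines, function(s) {
    d <- diff(s)
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("tractogram: %d streamlines, length range [%.2f, %.2f] mm\n",
              n_streamlines(x),
              if (n_streamlines(x)) min(x$lengths) else NA,
              if (n_streamlines(x)) max(x$lengths) else NA))
  invisible(x)
}

#' Number of streamlines
#' @param tractogram a `tractogram`.
#' @return integer count.
#' @export
n_streamlines <- function(tractogram) length(tractogram$streamlines)

#' Extremities of every streamline
#'
#' @param tractogram a `tractogram`.
#' @return list with `first` and `last`, each an n x 3 matrix of the first
#'   and last polyline points.
#' @export
streamline_extremities <- function(tractogram) {
  n <- n_streamlines(tractogram)
  first <- matrix(0, n, 3)
  last <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    s <- tractogram$streamlines[[i]]
    first[i, ] <- s[1, ]
    last[i, ] <- s[nrow(s), ]
  }
  list(first = first, last = last)
}

#' Apply a 4x4 affine to every streamline point
#'
#' Brings streamlines into the surface's space (e.g. a diffusion-to-anatomy
#' registration).  Lengths and weights are recomputed from the transformed
#' points.
#'
#' @param tractogram a [tractogram].
#' @param affine invertible 4x4 matrix acting on homogeneous coordinates.
#' @return a transformed [tractogram].
#' @export
apply_affine <- function(tractogram, affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps * 100) stop("affine is singular")
  A <- affine[1:3, 1:3]
  b <- affine[1:3, 4]
  out <- lapply(tractogram$streamlines, function(s) {
    sweep(s %*% t(A), 2, b, "+")
  })
  tractogram(out)
}

#' Filter streamlines by minimum length
#'
#' Retains exactly the streamlines with length >= `min_length` (so a 3 mm
#' filter removes streamlines *shorter than* 3 mm, keeping the boundary),
#' preserving order.
#'
#' @param tractogram a [tractogram].
#' @param min_length minimum length in mm (>= 0).
#' @return a filtered [tractogram] with attribute `kept`, the indices (into
#'   the input) of the retained streamlines.
#' @export
filter_streamlines <- function(tractogram, min_length = 3) {
  if (min_length < 0) stop("min_length must be >= 0")
  keep <- which(tractogram$lengths >= min_length)
  out <- structure(list(streamlines = tractogram$streamlines[keep],
                        lengths = tractogram$lengths[keep],
                        weights = tractogram$weights[keep]),
                   class = "tractogram")
  attr(out, "kept") <- keep
  out
}

empty_tractogram <- function() {
  structure(list(streamlines = list(), lengths = numeric(0),
                 weights = numeric(0)),
            class = "tractogram")
}
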