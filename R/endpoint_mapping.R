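#' Assign streamline extremities to cortical vertices
#'
#' For every mesh vertex, selects all streamlines having one extremity
#' within `selection_radius` (closed ball, Euclidean distance in mm) of that
#' vertex; a streamline "starts from" each such vertex.  For every selected
#' (streamline, extremity) pair the *ending vertex* is the mesh vertex
#' globally closest to the streamline's *other* extremity (ties broken by
#' lowest vertex index).  Both extremities are eligible independently:
#' streamlines are undirected, so a streamline whose two extremities both
#' fall within the radius of the same vertex contributes two entries there.
#'
#' The search uses a uniform spatial grid (cell size = radius) with an exact
#' distance test on candidates, so results are identical to an exhaustive
#' all-pairs search.
#'
#' @param tractogram a [tractogram] already in the surface's mm space.
#' @param mesh a [surface_mesh].
#' @param selection_radius selection radius in mm (default 5, closed ball).
#' @param min_length minimum streamline length in mm (default 3); applied
#'   before assignment (a no-op if the tractogram is already filtered).
#'   Selected streamline indices always refer to the *input* tractogram.
#' @return an object of class `endpoint_assignment`: list with
#'   `pairs` — data.frame(`vertex`, `streamline`, `extremity` (1 = first,
#'   2 = last), `ending_vertex`), sorted by (vertex, streamline, extremity) —
#'   plus `n_vertices`, `n_streamlines`, `selection_radius`, `min_length`
#'   and `kept` (indices of streamlines passing the length filter).
#' @export
assign_endpoints <- function(tractogram, mesh, selection_radius = 5, min_length = 3) {
  if (!inherits(mesh, "surface_mesh")) stop("mesh must be a surface_mesh")
  if (n_vertices(mesh) == 0L) stop("empty mesh")
  if (selection_radius <= 0) stop("selection_radius must be > 0")
  nv <- n_vertices(mesh)

  kept <- which(tractogram$lengths >= min_length)
  empty <- data.frame(vertex = integer(0), streamline = integer(0),
                      extremity = integer(0), ending_vertex = integer(0))
  if (length(kept) == 0L) {
    return(structure(list(pairs = empty, n_vertices = nv,
                          n_streamlines = n_streamlines(tractogram),
                          selection_radius = selection_radius,
                          min_length = min_length, kept = kept),
                     class = "endpoint_assignment"))
  }

  sub <- structure(list(streamlines = tractogram$streamlines[kept],
                        lengths = tractogram$lengths[kept],
                        weights = tractogram$weights[kept]),
                   class = "tractogram")
  ex <- streamline_extremities(sub)
  # endpoint table: 2 rows per streamline
  pts <- rbind(ex$first, ex$last)
  ns <- length(kept)
  ep_stream <- rep(kept, 2L)
  ep_extremity <- rep(c(1L, 2L), each = ns)

  hits <- grid_radius_pairs(pts, mesh$vertices, selection_radius)
  if (nrow(hits) == 0L) {
    return(structure(list(pairs = empty, n_vertices = nv,
                          n_streamlines = n_streamlines(tractogram),
                          selection_radius = selection_radius,
                          min_length = min_length, kept = kept),
                     class = "endpoint_assignment"))
  }

  # ending vertex = nearest mesh vertex to the other extremity; compute only
  # for endpoints that are the "other end" of at least one selected pair
  other_ep <- ifelse(hits$point <= ns, hits$point + ns, hits$point - ns)
  need <- sort(unique(other_ep))
  nearest <- nearest_vertex(pts[need, , drop = FALSE], mesh$vertices)
  end_vtx <- nearest[match(other_ep, need)]

  pairs <- data.frame(vertex = hits$vertex,
                      streamline = ep_stream[hits$point],
                      extremity = ep_extremity[hits$point],
                      ending_vertex = end_vtx)
  pairs <- pairs[order(pairs$vertex, pairs$streamline, pairs$extremity), , drop = FALSE]
  rownames(pairs) <- NULL

  structure(list(pairs = pairs, n_vertices = nv,
                 n_streamlines = n_streamlines(tractogram),
                 selection_radius = selection_radius,
                 min_length = min_length, kept = kept),
            class = "endpoint_assignment")
}

#' @export
print.endpoint_assignment <- function(x, ...) {
  cat(sprintf(paste0("endpoint_assignment: %d selected (streamline, extremity) pairs, ",
                     "%d/%d vertices with >= 1 selection (radius %.3g mm, min length %.3g mm)\n"),
              nrow(x$pairs), length(unique(x$pairs$vertex)), x$n_vertices,
              x$selection_radius, x$min_length))
  invisible(x)
}

#' Vertices with at least one selected streamline
#' @param assignment an `endpoint_assignment`.
#' @return logical vector over mesh vertices.
#' @export
vertices_with_fibers <- function(assignment) {
  out <- logical(assignment$n_vertices)
  out[unique(assignment$pairs$vertex)] <- TRUE
  out
}

# All (point, vertex) pairs with Euclidean distance <= r, via uniform-grid
# binning (cell size r): candidates come from the 27 cells around each
# point's cell and are then distance-tested exactly.
grid_radius_pairs <- function(points, vertices, r) {
  np <- nrow(points); nv <- nrow(vertices)
  no_hits <- data.frame(point = integer(0), vertex = integer(0))
  if (np == 0L || nv == 0L) return(no_hits)
  origin <- pmin(apply(points, 2, min), apply(vertices, 2, min))
  upper <- pmax(apply(points, 2, max), apply(vertices, 2, max))
  # cell size >= r keeps the 27-cell neighborhood sufficient; the lower bound
  # caps the cell count so the integer keys stay exact in doubles
  cell <- max(r, max(upper - origin) / 256)
  cell_of <- function(m) {
    cbind(floor((m[, 1] - origin[1]) / cell),
          floor((m[, 2] - origin[2]) / cell),
          floor((m[, 3] - origin[3]) / cell))
  }
  vc <- cell_of(vertices)
  pc <- cell_of(points)
  K1 <- max(vc[, 1], pc[, 1]) + 2
  K2 <- max(vc[, 2], pc[, 2]) + 2
  # injective cell key given the coordinate bounds above
  vkey <- vc[, 1] + (K1 + 2) * (vc[, 2] + (K2 + 2) * vc[, 3])
  buckets <- split(seq_len(nv), vkey)
  bkeys <- as.numeric(names(buckets))

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  acc_p <- vector("list", 27)
  acc_v <- vector("list", 27)
  for (k in seq_len(27)) {
    nk <- (pc[, 1] + offs[k, 1]) +
      (K1 + 2) * ((pc[, 2] + offs[k, 2]) + (K2 + 2) * (pc[, 3] + offs[k, 3]))
    bi <- match(nk, bkeys)
    has <- which(!is.na(bi))
    if (!length(has)) next
    cand <- buckets[bi[has]]
    cl <- lengths(cand)
    acc_p[[k]] <- rep.int(has, cl)
    acc_v[[k]] <- unlist(cand, use.names = FALSE)
  }
  pid <- unlist(acc_p, use.names = FALSE)
  vid <- unlist(acc_v, use.names = FALSE)
  if (is.null(pid) || !length(pid)) return(no_hits)
  d2 <- rowSums((points[pid, , drop = FALSE] - vertices[vid, , drop = FALSE])^2)
  ok <- d2 <= r * r
  data.frame(point = pid[ok], vertex = vid[ok])
}

#' Nearest mesh vertex to each query point
#'
#' Exhaustive chunked search; ties broken by lowest vertex index.
#'
#' @param points n x 3 matrix of query points (mm).
#' @param vertices m x 3 matrix of mesh vertex coordinates (mm).
#' @return integer vector of nearest vertex indices.
#' @export
nearest_vertex <- function(points, vertices) {
  points <- as.matrix(points)
  np <- nrow(points)
  if (np == 0L) return(integer(0))
  v2 <- rowSums(vertices^2)
  out <- integer(np)
  chunk <- max(1L, floor(2e7 / nrow(vertices)))
  for (s in seq(1L, np, by = chunk)) {
    e <- min(np, s + chunk - 1L)
    P <- points[s:e, , drop = FALSE]
    # d^2 = |p|^2 - 2 p.v + |v|^2; |p|^2 constant per row, drop it
    D <- sweep(-2 * tcrossprod(P, vertices), 2, v2, "+")
    out[s:e] <- max.col(-D, ties.method = "first")
  }
  out
}
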