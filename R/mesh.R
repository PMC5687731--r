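#' Triangulated surface mesh
#'
#' Construct a `surface_mesh` from vertex coordinates (in millimetres) and a
#' triangle index matrix.  Derived geometry — vertex normals, vertex areas
#' (one third of the incident triangle areas, the standard barycentric
#' lumping), the one-ring adjacency list and the edge table — is computed on
#' construction, so every downstream metric can treat the mesh as immutable.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param triangles integer matrix, one row per triangle, three 1-based
#'   vertex indices per row.
#' @param validate if `TRUE` (default), check the mesh invariants: all
#'   indices in range, edge-manifoldness (no edge shared by more than two
#'   triangles), no degenerate (zero-area) triangles.
#' @return an object of class `surface_mesh`: a list with elements
#'   `vertices` (n x 3), `triangles` (m x 3, 1-based), `normals` (n x 3 unit
#'   vectors), `vertex_areas` (mm^2), `adjacency` (list of sorted neighbor
#'   index vectors), `edges` (e x 2, each undirected edge once, i < j) and
#'   `edge_lengths` (mm).
#' @export
surface_mesh <- function(vertices, triangles, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  nv <- nrow(vertices)
  if (nv < 3L || nrow(triangles) < 1L) stop("mesh needs >= 3 vertices and >= 1 triangle")

  if (validate) {
    bad <- which(triangles < 1L | triangles > nv)
    if (length(bad)) {
      stop(sprintf("triangle index out of range (vertex count %d): first offending triangle row %d",
                   nv, ((bad[1] - 1L) %% nrow(triangles)) + 1L))
    }
  }

  tri <- triangles
  p1 <- vertices[tri[, 1], , drop = FALSE]
  p2 <- vertices[tri[, 2], , drop = FALSE]
  p3 <- vertices[tri[, 3], , drop = FALSE]
  # triangle normal = (p2-p1) x (p3-p1); its norm is twice the area
  u <- p2 - p1
  v <- p3 - p1
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  tri_area2 <- sqrt(rowSums(cr^2))
  if (validate && any(tri_area2 <= 0)) {
    stop(sprintf("degenerate (zero-area) triangle at row %d", which(tri_area2 <= 0)[1]))
  }
  tri_area <- tri_area2 / 2

  # undirected edge table; manifold check counts triangles per edge
  ea <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  eo <- cbind(pmin.int(ea[, 1], ea[, 2]), pmax.int(ea[, 1], ea[, 2]))
  key <- (as.double(eo[, 1]) - 1) * nv + as.double(eo[, 2])
  if (validate) {
    cnt <- table(key)
    if (any(cnt > 2L)) {
      over <- as.double(names(cnt)[cnt > 2L][1])
      stop(sprintf("mesh is not edge-manifold: edge (%d, %d) belongs to more than two triangles",
                   floor((over - 1) / nv) + 1, ((over - 1) %% nv) + 1))
    }
  }
  keep <- !duplicated(key)
  edges <- eo[keep, , drop = FALSE]
  edge_lengths <- sqrt(rowSums((vertices[edges[, 1], , drop = FALSE] -
                                vertices[edges[, 2], , drop = FALSE])^2))

  # adjacency from undirected edges, symmetric by construction
  nb_from <- c(edges[, 1], edges[, 2])
  nb_to <- c(edges[, 2], edges[, 1])
  ord <- order(nb_from, nb_to)
  adjacency <- split(nb_to[ord], factor(nb_from[ord], levels = seq_len(nv)))
  names(adjacency) <- NULL

  # area-weighted vertex normals (cr already carries the area weight)
  normals <- matrix(0, nv, 3)
  for (k in 1:3) {
    acc <- rowsum(cr, group = tri[, k], reorder = FALSE)
    idx <- as.integer(rownames(acc))
    normals[idx, ] <- normals[idx, ] + acc
  }
  nn <- sqrt(rowSums(normals^2))
  pos <- nn > 0
  normals[pos, ] <- normals[pos, ] / nn[pos]

  vertex_areas <- numeric(nv)
  for (k in 1:3) {
    acc <- rowsum(tri_area / 3, group = tri[, k], reorder = FALSE)
    idx <- as.integer(rownames(acc))
    vertex_areas[idx] <- vertex_areas[idx] + acc
  }

  structure(list(vertices = vertices, triangles = triangles,
                 normals = normals, vertex_areas = vertex_areas,
                 adjacency = adjacency, edges = edges,
                 edge_lengths = edge_lengths,
                 triangle_areas = tri_area),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, total area %.2f mm^2\n",
              n_vertices(x), nrow(x$triangles), sum(x$triangle_areas)))
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer vertex count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Weighted edge graph of a mesh
#'
#' igraph representation with edge weights equal to Euclidean edge lengths,
#' used for graph-geodesic distances (smoothing calibration, synthetic
#' streamline targeting, patch definitions).
#'
#' @param mesh a `surface_mesh`.
#' @return an `igraph` undirected graph with a `weight` edge attribute.
#' @export
mesh_graph <- function(mesh) {
  g <- igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
  igraph::E(g)$weight <- mesh$edge_lengths
  g
}

#' Graph-geodesic distances from source vertices
#'
#' Shortest-path distance along mesh edges (edge weights = edge lengths in
#' mm).  An approximation of the exact geodesic adequate at the ~10 mm
#' scales the package works at.
#'
#' @param mesh a `surface_mesh`.
#' @param from integer vector of source vertex indices.
#' @return numeric matrix `length(from)` x `n_vertices(mesh)` of distances in mm.
#' @export
geodesic_distances <- function(mesh, from) {
  g <- mesh_graph(mesh)
  igraph::distances(g, v = from, algorithm = "dijkstra")
}

#' Vertices within a geodesic radius of a center vertex
#'
#' @param mesh a `surface_mesh`.
#' @param center vertex index.
#' @param radius geodesic radius in mm.
#' @return sorted integer vector of vertex indices (includes the center).
#' @export
geodesic_patch <- function(mesh, center, radius) {
  d <- geodesic_distances(mesh, center)
  which(d[1, ] <= radius)
}

is_connected_mesh <- function(mesh) {
  igraph::is_connected(mesh_graph(mesh))
}
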