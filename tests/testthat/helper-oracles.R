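# Independent oracles and small fixtures, kept free of the package's spatial
# search code paths.

# Exhaustive all-pairs endpoint assignment: for every streamline extremity,
# test every vertex against the selection radius directly.
brute_force_assignment <- function(tractogram, mesh, radius = 5, min_length = 3) {
  V <- mesh$vertices
  nv <- nrow(V)
  kept <- which(tractogram$lengths >= min_length)
  rows <- vector("list", 2L * length(kept))
  r2 <- radius^2
  ri <- 0L
  for (s in kept) {
    sl <- tractogram$streamlines[[s]]
    ends <- list(sl[1, ], sl[nrow(sl), ])
    for (e in 1:2) {
      p <- ends[[e]]
      d2 <- (V[, 1] - p[1])^2 + (V[, 2] - p[2])^2 + (V[, 3] - p[3])^2
      sel <- which(d2 <= r2)
      if (length(sel)) {
        o <- ends[[3L - e]]
        do2 <- (V[, 1] - o[1])^2 + (V[, 2] - o[2])^2 + (V[, 3] - o[3])^2
        ri <- ri + 1L
        rows[[ri]] <- data.frame(vertex = sel, streamline = s, extremity = e,
                                 ending_vertex = which.min(do2))
      }
    }
  }
  if (ri == 0L) {
    return(data.frame(vertex = integer(0), streamline = integer(0),
                      extremity = integer(0), ending_vertex = integer(0)))
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  out <- out[order(out$vertex, out$streamline, out$extremity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# A regular tetrahedron mesh (4 vertices, 4 faces; adjacency is K4).
make_tetrahedron <- function(scale = 10) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * scale
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  surface_mesh(v, f)
}

# Straight 2-point streamline between two points.
seg <- function(a, b) rbind(a, b)

# Streamline of exact total length L with its first extremity at `from`,
# running straight along `dir`.
ray <- function(from, dir, L, n_points = 5) {
  dir <- dir / sqrt(sum(dir^2))
  t <- seq(0, L, length.out = n_points)
  outer(t, dir) + matrix(from, n_points, 3, byrow = TRUE)
}

# Random polyline tractogram with extremities near the mesh surface.
random_tractogram <- function(mesh, n, jitter = 2, seed = 1) {
  set.seed(seed)
  nv <- n_vertices(mesh)
  sl <- lapply(seq_len(n), function(i) {
    a <- mesh$vertices[sample.int(nv, 1), ] + rnorm(3, 0, jitter)
    b <- mesh$vertices[sample.int(nv, 1), ] + rnorm(3, 0, jitter)
    k <- sample(2:8, 1)
    t <- seq(0, 1, length.out = k)
    outer(1 - t, a) + outer(t, b) + rbind(0, matrix(rnorm((k - 2) * 3, 0, 1), k - 2, 3), 0)
  })
  tractogram(sl)
}
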