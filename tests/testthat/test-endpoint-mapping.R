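test_that("affine application transforms points and recomputes lengths/weights", {
  tg <- tractogram(list(seg(c(0, 0, 0), c(0, 0, 10)), seg(c(1, 2, 3), c(4, 5, 6))))
  expect_equal(apply_affine(tg, diag(4)), tg)

  tr <- diag(4); tr[1, 4] <- 10
  shifted <- apply_affine(tg, tr)
  expect_equal(shifted$lengths, tg$lengths)
  expect_equal(shifted$streamlines[[1]][, 1], tg$streamlines[[1]][, 1] + 10)

  sc <- diag(c(2, 2, 2, 1))
  scaled <- apply_affine(tg, sc)
  expect_equal(scaled$lengths, 2 * tg$lengths)
  expect_equal(scaled$weights, tg$weights / 2)

  expect_error(apply_affine(tg, matrix(0, 4, 4)), "singular")
})

test_that("length filtering keeps the boundary and preserves order", {
  tg <- tractogram(list(seg(c(0, 0, 0), c(2.9, 0, 0)),
                        seg(c(0, 0, 0), c(3, 0, 0)),
                        seg(c(0, 0, 0), c(50, 0, 0))))
  f <- filter_streamlines(tg, 3)
  expect_equal(f$lengths, c(3, 50))
  expect_equal(attr(f, "kept"), c(2L, 3L))
  expect_equal(filter_streamlines(tg, 0)$lengths, tg$lengths)
  expect_equal(n_streamlines(filter_streamlines(tg, 100)), 0)
})

test_that("extremities exactly on vertices select with distance 0 and cross-reference", {
  mesh <- make_icosphere(2, 80)
  s <- seg(mesh$vertices[7, ], mesh$vertices[41, ])
  asn <- assign_endpoints(tractogram(list(s)), mesh, selection_radius = 1)
  p <- asn$pairs
  expect_equal(p[p$vertex == 7, c("streamline", "extremity", "ending_vertex")],
               data.frame(streamline = 1L, extremity = 1L, ending_vertex = 41L),
               ignore_attr = TRUE)
  expect_equal(p[p$vertex == 41, c("streamline", "extremity", "ending_vertex")],
               data.frame(streamline = 1L, extremity = 2L, ending_vertex = 7L),
               ignore_attr = TRUE)
})

test_that("the radius test is a closed ball: 5.0001 mm is out, 5 mm is in", {
  # exact integer coordinates make the boundary distance exactly 5
  mesh <- make_tetrahedron(scale = 10)  # vertex 1 at (10, 10, 10)
  far <- c(200, 200, 200)
  asn_in <- assign_endpoints(tractogram(list(seg(c(10, 10, 15), far))), mesh, 5,
                             min_length = 0)
  expect_true(1L %in% asn_in$pairs$vertex)
  asn_out <- assign_endpoints(tractogram(list(seg(c(10, 10, 15.0001), far))), mesh, 5,
                              min_length = 0)
  expect_false(1L %in% asn_out$pairs$vertex)
})

test_that("empty inputs behave per contract", {
  mesh <- make_tetrahedron()
  asn <- assign_endpoints(tractogram(list()), mesh)
  expect_equal(nrow(asn$pairs), 0)
  expect_equal(sum(vertices_with_fibers(asn)), 0)
})

test_that("accelerated assignment equals the exhaustive all-pairs oracle", {
  mesh <- make_icosphere(3, 80)
  tg <- random_tractogram(mesh, 200, jitter = 3, seed = 11)
  asn <- assign_endpoints(tg, mesh, selection_radius = 5, min_length = 3)
  oracle <- brute_force_assignment(tg, mesh, radius = 5, min_length = 3)
  expect_identical(asn$pairs, oracle)
})

test_that("selection is monotone in radius and invariant under rigid motion", {
  mesh <- make_icosphere(2, 80)
  tg <- random_tractogram(mesh, 150, jitter = 4, seed = 5)
  key <- function(p) paste(p$vertex, p$streamline, p$extremity)
  small <- assign_endpoints(tg, mesh, 4)
  big <- assign_endpoints(tg, mesh, 7)
  expect_true(all(key(small$pairs) %in% key(big$pairs)))

  # rigid rotation + translation applied to mesh and tractogram jointly
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  A <- rbind(cbind(R, c(5, -3, 12)), c(0, 0, 0, 1))
  mesh_r <- surface_mesh(sweep(mesh$vertices %*% t(R), 2, c(5, -3, 12), "+"),
                         mesh$triangles)
  tg_r <- apply_affine(tg, A)
  a0 <- assign_endpoints(tg, mesh, 5)
  a1 <- assign_endpoints(tg_r, mesh_r, 5)
  expect_equal(a1$pairs, a0$pairs, tolerance = 0)
})

test_that("nearest-vertex ties break to the lowest index", {
  # two vertices exactly equidistant from the query point by symmetry
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(nearest_vertex(rbind(c(0, 0, 0)), v), 1L)
  expect_equal(nearest_vertex(rbind(c(0, 0.6, 0.6)), v), 3L)
})
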