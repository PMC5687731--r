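# Fixture: streamlines with one extremity exactly on a chosen vertex and the
# other extremity far outside the selection radius of everything, so the
# selected lengths at that vertex are exactly the requested ones.  Axis-aligned
# rays with dyadic waypoints keep the polyline lengths exact in floating point.
vertex_fixture <- function(lengths, vertex = 1L, mesh = make_icosphere(2, 80)) {
  sl <- lapply(lengths, function(L)
    ray(mesh$vertices[vertex, ], c(1, 0, 0), L))
  tg <- tractogram(sl)
  list(mesh = mesh, tg = tg,
       asn = assign_endpoints(tg, mesh, selection_radius = 1, min_length = 0),
       vertex = vertex)
}

test_that("mean tract length: arithmetic mean, harmonic mean under 1/L weights", {
  fx <- vertex_fixture(c(10, 20, 30))
  unw <- mean_tract_length(fx$asn, fx$tg, weighted = FALSE)
  expect_equal(unw$values[fx$vertex], 20)
  w <- mean_tract_length(fx$asn, fx$tg, weighted = TRUE)
  expect_equal(w$values[fx$vertex], 3 / (1 / 10 + 1 / 20 + 1 / 30))  # 16.3636...
  # bounds: min <= mean <= max at the vertex
  expect_gte(w$values[fx$vertex], 10)
  expect_lte(w$values[fx$vertex], 30)
  # vertices with no selected streamline are invalid
  empty_vtx <- setdiff(seq_len(n_vertices(fx$mesh)), fx$asn$pairs$vertex)[1]
  expect_false(unw$valid[empty_vtx])
})

test_that("connectivity index matches hand-computed weighted and unweighted values", {
  fx <- vertex_fixture(c(10, 20, 40, 50))
  ci <- connectivity_index(fx$asn, fx$tg, 30, "short", weighted = FALSE)
  expect_equal(ci$values[fx$vertex], 50)

  fx2 <- vertex_fixture(c(10, 20))
  ciw <- connectivity_index(fx2$asn, fx2$tg, 15, "short", weighted = TRUE)
  expect_equal(ciw$values[fx2$vertex], 100 * (1 / 10) / (1 / 10 + 1 / 20))  # 66.666...

  # threshold below the length filter: no fiber can qualify as short
  asn3 <- assign_endpoints(fx2$tg, fx2$mesh, selection_radius = 1, min_length = 3)
  ci0 <- connectivity_index(asn3, fx2$tg, 2, "short")
  expect_equal(ci0$values[fx2$vertex], 0)
})

test_that("threshold sweeps are monotone step functions of the lengths", {
  fx <- vertex_fixture(c(10, 40))
  sw <- threshold_sweep(fx$asn, fx$tg, seq(5, 30, 5), "short", weighted = FALSE)
  expect_equal(vapply(sw, function(m) m$values[fx$vertex], numeric(1)),
               c(`5` = 0, `10` = 50, `15` = 50, `20` = 50, `25` = 50, `30` = 50))

  fx25 <- vertex_fixture(rep(25, 3))
  sw25 <- threshold_sweep(fx25$asn, fx25$tg, seq(5, 30, 5), "short")
  expect_equal(unname(vapply(sw25, function(m) m$values[fx25$vertex], numeric(1))),
               c(0, 0, 0, 0, 100, 100))

  expect_error(threshold_sweep(fx$asn, fx$tg, c(10, 5), "short"), "sorted")
})

test_that("partition, monotonicity, limits and weighted/unweighted agreement hold", {
  mesh <- make_icosphere(2, 80)
  tg <- simulate_tractogram(mesh, 800, seed = 21)
  asn <- assign_endpoints(tg, mesh)
  for (weighted in c(TRUE, FALSE)) {
    prev_s <- NULL
    for (Tt in seq(5, 60, 5)) {
      s <- connectivity_index(asn, tg, Tt, "short", weighted)$values
      l <- connectivity_index(asn, tg, Tt, "long", weighted)$values
      expect_equal(s + l, rep(100, length(s)), ignore_attr = TRUE,
                   tolerance = 1e-12)
      if (!is.null(prev_s)) expect_true(all(s - prev_s >= -1e-12, na.rm = TRUE))
      prev_s <- s
    }
    # T >= max length: everything is short
    smax <- connectivity_index(asn, tg, max(tg$lengths), "short", weighted)$values
    expect_equal(smax[!is.na(smax)], rep(100, sum(!is.na(smax))), ignore_attr = TRUE)
  }
  # equal lengths at a vertex: weighting is irrelevant
  fx <- vertex_fixture(rep(18, 4))
  expect_equal(connectivity_index(fx$asn, fx$tg, 20, "short", TRUE)$values[fx$vertex],
               connectivity_index(fx$asn, fx$tg, 20, "short", FALSE)$values[fx$vertex])
  expect_equal(mean_tract_length(fx$asn, fx$tg, TRUE)$values[fx$vertex],
               mean_tract_length(fx$asn, fx$tg, FALSE)$values[fx$vertex])
})

test_that("termination maps are weight fractions over ending vertices", {
  mesh <- make_icosphere(2, 80)
  seed_v <- 1L
  targets <- c(30L, 30L, 50L, 70L)
  sl <- lapply(targets, function(tv) seg(mesh$vertices[seed_v, ], mesh$vertices[tv, ]))
  tg <- tractogram(sl)
  asn <- assign_endpoints(tg, mesh, selection_radius = 1, min_length = 0)

  tm <- termination_map(asn, tg, seed_v, weighted = FALSE)
  expect_equal(tm$proportions$values[c(30, 50, 70)], c(0.5, 0.25, 0.25))
  expect_equal(sum(tm$proportions$values, na.rm = TRUE), 1)

  # weighted: proportions equal hand-summed weight fractions
  w <- tg$weights
  tmw <- termination_map(asn, tg, seed_v, weighted = TRUE)
  expect_equal(tmw$proportions$values[30], (w[1] + w[2]) / sum(w))
  expect_equal(tmw$proportions$values[50], w[3] / sum(w))
  expect_equal(sum(tmw$proportions$values, na.rm = TRUE), 1)

  # single streamline: proportion 1 at its ending vertex
  tg1 <- tractogram(sl[3])
  asn1 <- assign_endpoints(tg1, mesh, selection_radius = 1, min_length = 0)
  tm1 <- termination_map(asn1, tg1, seed_v)
  expect_equal(tm1$proportions$values[50], 1)

  # seed without streamlines: all-invalid with a warning
  lonely <- setdiff(seq_len(n_vertices(mesh)), asn$pairs$vertex)[1]
  expect_warning(tme <- termination_map(asn, tg, lonely), "no selected")
  expect_false(any(tme$proportions$valid))
})

test_that("sulcal/gyral classification follows the curvature sign rule", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  mesh <- surface_mesh(v, rbind(c(1, 2, 3)))
  lab <- classify_sulcal_gyral(mesh, vertex_map(c(0.2, -0.1, 0)))
  expect_equal(lab$values, c(1, 0, 0))  # sulcus, gyrus, gyrus
  expect_equal(classify_sulcal_gyral(mesh, vertex_map(c(1, 2, 3)))$values, rep(1, 3))
  expect_error(classify_sulcal_gyral(mesh, NULL), "required")
})

test_that("termination class proportions are weight-sum ratios", {
  mesh <- make_icosphere(2, 80)
  # one streamline ends exactly at vertex 30 (sulcus), one at vertex 50 (gyrus)
  sl <- list(seg(mesh$vertices[1, ], mesh$vertices[30, ]),
             seg(mesh$vertices[2, ], mesh$vertices[50, ]))
  curv <- rep(-1, n_vertices(mesh)); curv[30] <- 1
  labels <- classify_sulcal_gyral(mesh, vertex_map(curv))
  tg <- tractogram(sl)
  asn <- assign_endpoints(tg, mesh, selection_radius = 1, min_length = 0)
  asn$pairs <- asn$pairs[asn$pairs$vertex %in% c(1, 2), ]  # the selecting side only

  unw <- termination_class_proportions(asn, tg, labels, weighted = FALSE)
  expect_equal(unw, c(sulcus = 0.5, gyrus = 0.5))
  w <- termination_class_proportions(asn, tg, labels, weighted = TRUE)
  expect_equal(w[["sulcus"]], tg$weights[1] / sum(tg$weights))
  expect_equal(sum(w), 1)

  all_gyr <- classify_sulcal_gyral(mesh, vertex_map(rep(-1, n_vertices(mesh))))
  expect_equal(termination_class_proportions(asn, tg, all_gyr),
               c(sulcus = 0, gyrus = 1))
})

test_that("termination angles fold into [0, 90] degrees", {
  mesh <- make_icosphere(2, 80)
  v <- 25L
  n <- mesh$normals[v, ]
  start <- mesh$vertices[10, ]
  # terminal segment arriving along the normal at the ending vertex v
  along <- rbind(start, mesh$vertices[v, ] - 3 * n, mesh$vertices[v, ])
  anti <- rbind(start, mesh$vertices[v, ] + 3 * n, mesh$vertices[v, ])
  tang <- local({
    t1 <- c(-n[2], n[1], 0); t1 <- t1 / sqrt(sum(t1^2))
    rbind(start, mesh$vertices[v, ] - 3 * t1, mesh$vertices[v, ])
  })
  tg <- tractogram(list(along, anti, tang))
  asn <- assign_endpoints(tg, mesh, selection_radius = 1, min_length = 0)
  ang <- termination_angle(tg, mesh, asn)
  first_end <- ang[ang$extremity == 1 & ang$ending_vertex == v, ]
  first_end <- first_end[order(first_end$streamline), ]
  expect_equal(first_end$angle, c(0, 0, 90), tolerance = 1e-6)
})
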