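test_that("icosphere subdivision combinatorics are exact", {
  m1 <- make_icosphere(1, 1)
  expect_equal(n_vertices(m1), 42)
  expect_equal(nrow(m1$triangles), 80)
  for (k in 1:3) {
    expect_equal(nrow(make_icosphere(k, 1)$triangles),
                 4 * nrow(make_icosphere(k - 1, 1)$triangles))
  }
})

test_that("folded sheet curvature sign alternates with the ridges", {
  sheet <- make_folded_sheet(nx = 41, ny = 5, spacing = 1, amplitude = 3,
                             wavelength = 10)
  x <- sheet$mesh$vertices[, 1]
  s <- sin(2 * pi * x / 10)
  # valleys (sin < 0, z'' > 0) are sulci: positive curvature
  expect_true(all(sheet$curvature$values[s < -1e-9] > 0))
  expect_true(all(sheet$curvature$values[s > 1e-9] < 0))
  labs <- classify_sulcal_gyral(sheet$mesh, sheet$curvature)
  expect_setequal(unique(labs$values), c(0, 1))
})

test_that("fixed seeds give bit-identical tractograms", {
  mesh <- make_icosphere(2, 80)
  t1 <- simulate_tractogram(mesh, 100, seed = 5)
  t2 <- simulate_tractogram(mesh, 100, seed = 5)
  expect_identical(t1$streamlines, t2$streamlines)
  expect_identical(attr(t1, "ground_truth"), attr(t2, "ground_truth"))
  t3 <- simulate_tractogram(mesh, 100, seed = 6)
  expect_false(identical(t1$streamlines, t3$streamlines))
})

test_that("p_short = 1 makes every ground-truth class short", {
  mesh <- make_icosphere(2, 80)
  tg <- simulate_tractogram(mesh, 200, p_short = 1, seed = 2)
  expect_true(all(attr(tg, "ground_truth")$class == "short"))
})

test_that("zero endpoint jitter puts extremities exactly on their vertices", {
  mesh <- make_icosphere(3, 80)
  tg <- simulate_tractogram(mesh, 150, endpoint_jitter = 0, seed = 8)
  gt <- attr(tg, "ground_truth")
  # target lengths realised exactly by the bump construction
  expect_equal(tg$lengths, gt$target_length, tolerance = 1e-9)
  asn <- assign_endpoints(tg, mesh, selection_radius = 1e-6, min_length = 0)
  p <- asn$pairs
  first <- p[p$extremity == 1, ]
  expect_equal(first$vertex[order(first$streamline)], gt$start_vertex)
  expect_equal(first$ending_vertex[order(first$streamline)], gt$end_vertex)
})

test_that("generated lengths respect the minimum and the class mixture", {
  mesh <- make_icosphere(3, 80)
  tg <- simulate_tractogram(mesh, 10000, p_short = 0.6, seed = 17)
  gt <- attr(tg, "ground_truth")
  expect_true(all(tg$lengths >= 3))
  # law of large numbers: class proportion within 3 SE of p_short
  se <- sqrt(0.6 * 0.4 / 10000)
  expect_lt(abs(mean(gt$class == "short") - 0.6), 3 * se)
  # the realised length distribution matches the stated truncated-normal
  # mixture (KS distance; jitter perturbs lengths by well under a mm)
  mix_cdf <- function(q) {
    trunc_cdf <- function(q, mu, sd) {
      p0 <- pnorm(3, mu, sd)
      pmax(0, (pnorm(q, mu, sd) - p0)) / (1 - p0) * (q >= 3) +
        pnorm(3, mu, sd) * 0
    }
    0.6 * trunc_cdf(q, 15, 5) + 0.4 * trunc_cdf(q, 45, 10)
  }
  qs <- seq(3, 80, by = 0.5)
  emp <- ecdf(tg$lengths)
  expect_lt(max(abs(emp(qs) - mix_cdf(qs))), 0.05)
})

test_that("cohorts plant the effect only inside the patch", {
  mesh <- make_icosphere(2, 80)
  eff <- list(center = 40, radius = 30, delta = -20)
  coh <- simulate_cohort(mesh, n_per_group = 40, effect = eff, seed = 9)
  expect_true(all(coh$patch %in% seq_len(n_vertices(mesh))))
  gdiff <- colMeans(coh$maps[coh$design$group == "patient", ]) -
    colMeans(coh$maps[coh$design$group == "control", ])
  outside <- setdiff(seq_len(n_vertices(mesh)), coh$patch)
  # expected difference: -20 inside, 0 outside (up to noise, SE ~ 2.5)
  expect_lt(max(abs(gdiff[outside])), 10)
  expect_true(all(gdiff[coh$patch] < -10))

  null_coh <- simulate_cohort(mesh, n_per_group = 10, seed = 10)
  expect_length(null_coh$patch, 0)
  expect_equal(dim(null_coh$maps), c(20, n_vertices(mesh)))
})

test_that("cohort export writes design, manifest and readable maps", {
  mesh <- make_icosphere(1, 80)
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(mesh, n_per_group = 3, seed = 4, out_dir = dir)
  design <- read.csv(file.path(dir, "design.csv"))
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(design), 6)
  expect_equal(nrow(manifest), 6)
  m1 <- read_vertex_map(file.path(dir, manifest$map[1]), "csv")
  expect_equal(m1$values, coh$maps[1, ])
})
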