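# Synthetic meshes, tractograms and cohorts.  These state the world the
# test-suite runs in: a closed genus-0 mesh standing in for a hemisphere,
# streamlines whose extremities lie near the mesh with a two-component
# (short/long) length mixture, and cohorts with a spatially localized group
# difference in the short/long mixture.

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere.  Subdivision level 1 has
#' 42 vertices / 80 triangles; each level quadruples the triangle count.
#'
#' @param subdivisions number of subdivision passes (>= 0; 0 = icosahedron).
#' @param radius sphere radius in mm (default 80, the scale of a hemisphere).
#' @return a [surface_mesh] with outward-oriented normals.
#' @export
make_icosphere <- function(subdivisions = 3, radius = 80) {
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (lev in seq_len(subdivisions)) {
    ne <- nrow(f)
    ea <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    eo <- cbind(pmin.int(ea[, 1], ea[, 2]), pmax.int(ea[, 1], ea[, 2]))
    key <- (eo[, 1] - 1) * (nrow(v) + 1) + eo[, 2]
    uk <- unique(key)
    mid_id <- nrow(v) + match(key, uk)
    ue <- eo[!duplicated(key), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- mid_id[1:ne]
    m23 <- mid_id[(ne + 1):(2 * ne)]
    m31 <- mid_id[(2 * ne + 1):(3 * ne)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  surface_mesh(v * radius, f)
}

#' Folded-sheet mesh with analytic curvature sign
#'
#' A rectangular grid in the xy-plane with sinusoidal height
#' `z = amplitude * sin(2*pi*x / wavelength)`, emulating a gyral/sulcal
#' folding pattern.  The attached curvature field follows the FreeSurfer
#' sign convention — positive in the valleys (sulci, where z'' > 0),
#' negative on the ridges (gyri) — computed from the analytic second
#' derivative of the height profile.
#'
#' @param nx,ny grid points along x and y (>= 2 each).
#' @param spacing grid spacing in mm.
#' @param amplitude fold amplitude in mm.
#' @param wavelength fold wavelength in mm.
#' @return list with `mesh` (a [surface_mesh]) and `curvature`
#'   (a [vertex_map] of the signed analytic curvature of the height profile).
#' @export
make_folded_sheet <- function(nx = 40, ny = 20, spacing = 1,
                              amplitude = 3, wavelength = 10) {
  if (nx < 2 || ny < 2) stop("nx and ny must be >= 2")
  xs <- (seq_len(nx) - 1) * spacing
  ys <- (seq_len(ny) - 1) * spacing
  g <- expand.grid(x = xs, y = ys)
  z <- amplitude * sin(2 * pi * g$x / wavelength)
  v <- cbind(g$x, g$y, z)
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  f <- rbind(cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
             cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  mesh <- surface_mesh(v, f)
  # curvature of the profile z(x): kappa = z'' / (1 + z'^2)^(3/2); a valley
  # (z'' > 0) is a sulcus, matching the positive-in-sulci convention
  d1 <- amplitude * (2 * pi / wavelength) * cos(2 * pi * g$x / wavelength)
  d2 <- -amplitude * (2 * pi / wavelength)^2 * sin(2 * pi * g$x / wavelength)
  kappa <- d2 / (1 + d1^2)^(3 / 2)
  list(mesh = mesh,
       curvature = vertex_map(kappa, name = "curvature", units = "1/mm"))
}

# sub-seed derivation: keep everything below 2^31
sub_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}

#' Simulate a tractogram with a short/long length mixture
#'
#' For each streamline: a start vertex is drawn uniformly; a short/long
#' class is drawn with probability `p_short` of "short" (modified by
#' `effect$delta_p_short` inside the effect patch); a target length is drawn
#' from the class's truncated normal; the end vertex is the one whose
#' graph-geodesic distance from the start best matches the target (among
#' vertices whose chord distance does not exceed it); and the polyline is a
#' two-segment chord with a perpendicular bump sized so its arc length
#' equals the target exactly, subdivided into `n_points` points.
#' Extremities are then jittered off the surface by isotropic Gaussian
#' displacement with SD `endpoint_jitter` per axis (0 = extremities exactly
#' on their vertices).
#'
#' @param mesh a [surface_mesh].
#' @param n_streamlines streamline count.
#' @param p_short probability of the short class in [0, 1] (default 0.6).
#' @param short_mean,short_sd short-class length distribution (mm; default 15 +- 5).
#' @param long_mean,long_sd long-class length distribution (mm; default 45 +- 10).
#' @param endpoint_jitter extremity displacement SD in mm (default 0.5).
#' @param effect optional list(`center`, `radius`, `delta_p_short`): inside
#'   the geodesic patch, `p_short` is shifted by `delta_p_short` (clamped to
#'   [0, 1]).
#' @param min_length lower truncation of drawn lengths in mm (default 3, the
#'   standard pre-filter, so generated streamlines survive it).
#' @param n_points polyline points per streamline (default 12).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a [tractogram] with attribute `ground_truth`: data.frame
#'   (`start_vertex`, `end_vertex`, `class`, `target_length`, `length`).
#' @export
simulate_tractogram <- function(mesh, n_streamlines = 2000, p_short = 0.6,
                                short_mean = 15, short_sd = 5,
                                long_mean = 45, long_sd = 10,
                                endpoint_jitter = 0.5, effect = NULL,
                                min_length = 3, n_points = 12, seed = NULL) {
  if (p_short < 0 || p_short > 1) stop("p_short must be in [0, 1]")
  if (short_sd < 0 || long_sd < 0 || endpoint_jitter < 0) stop("SDs must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  nv <- n_vertices(mesh)

  p_vertex <- rep(p_short, nv)
  if (!is.null(effect)) {
    if (is.null(effect$center) || is.null(effect$radius)) {
      stop("effect needs center and radius")
    }
    patch <- geodesic_patch(mesh, effect$center, effect$radius)
    p_vertex[patch] <- pmin(1, pmax(0, p_short + effect$delta_p_short))
  }

  start <- sample.int(nv, n_streamlines, replace = TRUE)
  is_short <- stats::rbinom(n_streamlines, 1, p_vertex[start]) == 1
  target <- ifelse(is_short,
                   stats::rnorm(n_streamlines, short_mean, short_sd),
                   stats::rnorm(n_streamlines, long_mean, long_sd))
  target <- pmax(target, min_length)

  ustart <- sort(unique(start))
  G <- geodesic_distances(mesh, ustart)        # |ustart| x nv
  V <- mesh$vertices
  streamlines <- vector("list", n_streamlines)
  end <- integer(n_streamlines)
  for (i in seq_len(n_streamlines)) {
    srow <- match(start[i], ustart)
    geo <- G[srow, ]
    chord <- sqrt(colSums((t(V) - V[start[i], ])^2))
    cand <- which(chord <= target[i])
    end[i] <- cand[which.min(abs(geo[cand] - target[i]))]
    streamlines[[i]] <- bump_polyline(V[start[i], ], V[end[i], ],
                                      mesh$normals[start[i], ] + mesh$normals[end[i], ],
                                      target[i], n_points)
  }
  if (endpoint_jitter > 0) {
    n_resampled <- 0L
    for (i in seq_len(n_streamlines)) {
      k <- nrow(streamlines[[i]])
      base <- streamlines[[i]]
      # re-draw the jitter if it pushes the length below the minimum, so
      # generated streamlines always survive the standard length filter
      for (try in 1:100) {
        cand <- base
        cand[1, ] <- cand[1, ] + stats::rnorm(3, 0, endpoint_jitter)
        cand[k, ] <- cand[k, ] + stats::rnorm(3, 0, endpoint_jitter)
        if (streamline_lengths(list(cand)) >= min_length) break
        n_resampled <- n_resampled + 1L
      }
      streamlines[[i]] <- cand
    }
    if (n_resampled > 0) {
      message(sprintf("re-drew endpoint jitter %d time(s) to keep lengths >= %g mm",
                      n_resampled, min_length))
    }
  }
  out <- tractogram(streamlines)
  attr(out, "ground_truth") <- data.frame(
    start_vertex = start, end_vertex = end,
    class = ifelse(is_short, "short", "long"),
    target_length = target, length = out$lengths)
  out
}

# Two-segment polyline from a to b via a perpendicular bump, with total arc
# length equal to target (>= the chord length), subdivided into n points.
bump_polyline <- function(a, b, up_hint, target, n_points) {
  chord <- sqrt(sum((b - a)^2))
  h <- sqrt(max(target^2 / 4 - chord^2 / 4, 0))
  mid <- (a + b) / 2
  if (h > 0) {
    u <- up_hint
    if (chord > 0) {
      d <- (b - a) / chord
      u <- u - sum(u * d) * d
    }
    if (sum(u^2) < 1e-12) {
      # fallback: any direction perpendicular to the chord
      d <- if (chord > 0) (b - a) / chord else c(1, 0, 0)
      u <- c(-d[2], d[1], 0)
      if (sum(u^2) < 1e-12) u <- c(0, -d[3], d[2])
    }
    mid <- mid + u / sqrt(sum(u^2)) * h
  }
  half <- ceiling(n_points / 2)
  t1 <- seq(0, 1, length.out = half + 1)
  seg1 <- outer(1 - t1, a) + outer(t1, mid)
  t2 <- seq(0, 1, length.out = n_points - half + 1)
  seg2 <- outer(1 - t2, mid) + outer(t2, b)
  rbind(seg1, seg2[-1, , drop = FALSE])
}

#' Simulate a two-group cohort of per-vertex maps
#'
#' Generates per-subject connectivity maps in vertex correspondence with a
#' spatially localized group effect, either by *direct map simulation*
#' (`mode = "maps"`: baseline + subject random intercept + linear age trend
#' + iid vertex noise, with the patient group's values shifted by
#' `effect$delta` inside the patch) or by running the full per-subject
#' tractography-to-CI pipeline (`mode = "tractography"`: each subject gets an
#' independent [simulate_tractogram()] whose `p_short` is shifted by
#' `effect$delta_p_short` in the patch for patients, followed by
#' [assign_endpoints()] and [connectivity_index()]).
#'
#' Defaults state a CI_short-like world: baseline 50 percent, subject SD 5,
#' vertex noise SD 10, age trend -0.3 percent/year over ages 6-28.
#'
#' @param mesh a [surface_mesh].
#' @param n_per_group subjects per group (>= 2).
#' @param effect list(`center`, `radius` (mm, geodesic), and `delta` (map
#'   units, maps mode) or `delta_p_short` (tractography mode)); or `NULL`
#'   for a null cohort.
#' @param mode `"maps"` (default) or `"tractography"`.
#' @param baseline,subject_sd,vertex_sd,age_slope map-mode variance
#'   components (map units).
#' @param n_streamlines tractography-mode streamlines per subject.
#' @param cutoff tractography-mode CI cut-off in mm (default 30).
#' @param seed integer seed.
#' @param out_dir optional directory: writes `design.csv`, `manifest.csv`
#'   and one per-subject map CSV, in the layout the group-statistics CLI
#'   consumes.
#' @return list of class `cohort`: `maps` (subjects x vertices matrix),
#'   `design` (data.frame subject/group/age/sex), `patch` (vertex indices,
#'   empty if no effect), `mesh`.
#' @export
simulate_cohort <- function(mesh, n_per_group = 20, effect = NULL,
                            mode = c("maps", "tractography"),
                            baseline = 50, subject_sd = 5, vertex_sd = 10,
                            age_slope = -0.3, n_streamlines = 2000,
                            cutoff = 30, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (n_per_group < 2) stop("need >= 2 subjects per group")
  set.seed(as.integer(seed))
  nv <- n_vertices(mesh)
  n <- 2L * n_per_group
  group <- factor(rep(c("control", "patient"), each = n_per_group),
                  levels = c("control", "patient"))
  age <- stats::runif(n, 6, 28)
  sex <- factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M"))
  design <- data.frame(subject = sprintf("sub%03d", seq_len(n)),
                       group = group, age = age, sex = sex)

  patch <- integer(0)
  if (!is.null(effect)) patch <- geodesic_patch(mesh, effect$center, effect$radius)

  if (mode == "maps") {
    mu <- matrix(baseline, n, nv)
    mu <- mu + (age - mean(age)) * age_slope
    if (length(patch)) {
      delta <- effect[["delta"]]  # exact match: "delta_p_short" must not be picked up
      if (is.null(delta)) delta <- 100 * effect[["delta_p_short"]]
      mu[group == "patient", patch] <- mu[group == "patient", patch] + delta
    }
    maps <- mu + stats::rnorm(n) * subject_sd +
      matrix(stats::rnorm(n * nv, 0, vertex_sd), n, nv)
  } else {
    maps <- matrix(NA_real_, n, nv)
    for (i in seq_len(n)) {
      eff_i <- NULL
      if (length(patch) && group[i] == "patient") {
        eff_i <- list(center = effect$center, radius = effect$radius,
                      delta_p_short = effect$delta_p_short)
      }
      tg <- simulate_tractogram(mesh, n_streamlines = n_streamlines,
                                effect = eff_i, seed = sub_seed(seed, i))
      asn <- assign_endpoints(tg, mesh)
      ci <- connectivity_index(asn, tg, threshold = cutoff, mode = "short")
      maps[i, ] <- ci$values
    }
  }
  out <- structure(list(maps = maps, design = design, patch = patch, mesh = mesh),
                   class = "cohort")
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

#' Write a cohort to disk
#'
#' `design.csv` (subject, group, age, sex), one CSV vertex map per subject,
#' and `manifest.csv` pairing subjects with map files — the layout the
#' group-statistics CLI consumes.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$design, file.path(dir, "design.csv"), row.names = FALSE)
  files <- character(nrow(cohort$maps))
  for (i in seq_len(nrow(cohort$maps))) {
    files[i] <- paste0(cohort$design$subject[i], "_map.csv")
    write_vertex_map(vertex_map(cohort$maps[i, ]), file.path(dir, files[i]), "csv")
  }
  utils::write.csv(data.frame(subject = cohort$design$subject, map = files),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
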