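# Per-vertex connectivity metrics built on an endpoint assignment.
# Every metric aggregates the selected (streamline, extremity) pairs at each
# vertex; vertices with no selected streamline are invalid in every map.

pair_table <- function(assignment, tractogram) {
  p <- assignment$pairs
  data.frame(vertex = p$vertex,
             streamline = p$streamline,
             extremity = p$extremity,
             ending_vertex = p$ending_vertex,
             length = tractogram$lengths[p$streamline],
             weight = tractogram$weights[p$streamline])
}

vertex_aggregate <- function(values, vertex, n_vertices) {
  out <- rep(NA_real_, n_vertices)
  if (length(values)) {
    s <- rowsum(values, group = vertex, reorder = FALSE)
    out[as.integer(rownames(s))] <- s
  }
  out
}

#' Mean tract length at each vertex
#'
#' The mean length of all streamlines "starting from" a vertex (i.e.
#' selected there by the radius rule).  With `weighted = TRUE` the mean uses
#' the 1/length streamline weights, which makes it the harmonic mean of the
#' selected lengths; the unweighted arithmetic mean is the default.
#'
#' @param assignment an [assign_endpoints()] result built from `tractogram`.
#' @param tractogram the matching [tractogram].
#' @param weighted use 1/length weights (default `FALSE`).
#' @return a [vertex_map] in mm; vertices with no selected streamline are invalid.
#' @export
mean_tract_length <- function(assignment, tractogram, weighted = FALSE) {
  pt <- pair_table(assignment, tractogram)
  nv <- assignment$n_vertices
  w <- if (weighted) pt$weight else rep(1, nrow(pt))
  num <- vertex_aggregate(w * pt$length, pt$vertex, nv)
  den <- vertex_aggregate(w, pt$vertex, nv)
  vertex_map(num / den, name = "mean_tract_length", units = "mm")
}

#' Short- or long-range connectivity index
#'
#' At each vertex, the percentage of selected streamlines whose length is
#' `<= threshold` (mode `"short"`) or `> threshold` (mode `"long"`), so the
#' two modes partition and sum to 100 exactly at every threshold.  By
#' default counts are weighted by 1/length, correcting the
#' streamline-count bias toward long fibers.
#'
#' @param assignment an [assign_endpoints()] result built from `tractogram`.
#' @param tractogram the matching [tractogram].
#' @param threshold length threshold in mm (> 0); the group-average mean
#'   tract length (30 mm in the motivating application) is the usual cut-off.
#' @param mode `"short"` or `"long"`.
#' @param weighted use 1/length weights (default `TRUE`).
#' @return a [vertex_map] in percent (0-100).
#' @export
connectivity_index <- function(assignment, tractogram, threshold = 30,
                               mode = c("short", "long"), weighted = TRUE) {
  mode <- match.arg(mode)
  if (threshold <= 0) stop("threshold must be > 0")
  pt <- pair_table(assignment, tractogram)
  nv <- assignment$n_vertices
  w <- if (weighted) pt$weight else rep(1, nrow(pt))
  is_in <- if (mode == "short") pt$length <= threshold else pt$length > threshold
  num <- vertex_aggregate(w * is_in, pt$vertex, nv)
  den <- vertex_aggregate(w, pt$vertex, nv)
  vertex_map(100 * num / den,
             name = sprintf("CI_%s_%gmm", mode, threshold), units = "percent")
}

#' Connectivity index across a sweep of thresholds
#'
#' One connectivity-index map per threshold.  Per vertex, CI_short is
#' non-decreasing and CI_long non-increasing across an ascending sweep.
#'
#' @inheritParams connectivity_index
#' @param thresholds ascending thresholds in mm; defaults to the standard
#'   sweeps 5-30 mm (short) or 30-60 mm (long) in 5 mm steps.
#' @return named list of [vertex_map]s, one per threshold.
#' @export
threshold_sweep <- function(assignment, tractogram,
                            thresholds = NULL,
                            mode = c("short", "long"), weighted = TRUE) {
  mode <- match.arg(mode)
  if (is.null(thresholds)) {
    thresholds <- if (mode == "short") seq(5, 30, by = 5) else seq(30, 60, by = 5)
  }
  if (is.unsorted(thresholds, strictly = TRUE)) stop("thresholds must be sorted strictly ascending")
  out <- lapply(thresholds, function(t)
    connectivity_index(assignment, tractogram, t, mode, weighted))
  names(out) <- sprintf("%g", thresholds)
  out
}

#' Full per-vertex connectivity profile
#'
#' Convenience wrapper computing the mean tract length, the short/long
#' connectivity indices at the cut-off, and both threshold sweeps.
#'
#' @inheritParams connectivity_index
#' @param cutoff short/long cut-off in mm (default 30).
#' @param thresholds_short,thresholds_long sweep thresholds in mm.
#' @return list of class `connectivity_profile` with elements `mean_length`,
#'   `ci_short`, `ci_long`, `sweep_short`, `sweep_long`, `cutoff`, `weighted`.
#' @export
connectivity_profile <- function(assignment, tractogram, cutoff = 30,
                                 thresholds_short = seq(5, 30, by = 5),
                                 thresholds_long = seq(30, 60, by = 5),
                                 weighted = TRUE) {
  structure(list(
    mean_length = mean_tract_length(assignment, tractogram, weighted = FALSE),
    ci_short = connectivity_index(assignment, tractogram, cutoff, "short", weighted),
    ci_long = connectivity_index(assignment, tractogram, cutoff, "long", weighted),
    sweep_short = threshold_sweep(assignment, tractogram, thresholds_short, "short", weighted),
    sweep_long = threshold_sweep(assignment, tractogram, thresholds_long, "long", weighted),
    cutoff = cutoff, weighted = weighted
  ), class = "connectivity_profile")
}

#' Termination proportions of the streamlines starting at a seed vertex
#'
#' Where do the fibers selected at one vertex end?  For each mesh vertex v,
#' the (optionally 1/length-weighted) fraction of the seed's selected
#' streamlines whose ending vertex is v.  Proportions sum to 1 when the seed
#' has at least one selected streamline.
#'
#' @param assignment an [assign_endpoints()] result built from `tractogram`.
#' @param tractogram the matching [tractogram].
#' @param seed_vertex vertex index.
#' @param weighted use 1/length weights (default `TRUE`).
#' @return list of class `termination_map`: `seed_vertex` and `proportions`
#'   (a [vertex_map]; all-invalid with a warning if the seed selected nothing).
#' @export
termination_map <- function(assignment, tractogram, seed_vertex, weighted = TRUE) {
  if (seed_vertex < 1 || seed_vertex > assignment$n_vertices) stop("seed_vertex out of range")
  pt <- pair_table(assignment, tractogram)
  pt <- pt[pt$vertex == seed_vertex, , drop = FALSE]
  nv <- assignment$n_vertices
  if (nrow(pt) == 0L) {
    warning(sprintf("seed vertex %d has no selected streamlines", seed_vertex))
    prop <- vertex_map(rep(NA_real_, nv), name = "termination_proportion", units = "")
  } else {
    w <- if (weighted) pt$weight else rep(1, nrow(pt))
    acc <- vertex_aggregate(w, pt$ending_vertex, nv)
    acc[is.na(acc)] <- 0
    prop <- vertex_map(acc / sum(w), name = "termination_proportion", units = "")
  }
  structure(list(seed_vertex = seed_vertex, proportions = prop),
            class = "termination_map")
}

#' Classify vertices as sulcal or gyral from signed curvature
#'
#' Uses the FreeSurfer sign convention: positive mean curvature in sulci
#' (folds), non-positive in gyri (ridges).
#'
#' @param mesh a [surface_mesh] (used only to check the vertex count).
#' @param curvature a [vertex_map] of signed curvature values.
#' @return a [vertex_map] with values 1 (sulcus) / 0 (gyrus), units
#'   `"1=sulcus,0=gyrus"`; vertices with invalid curvature are invalid.
#' @export
classify_sulcal_gyral <- function(mesh, curvature) {
  if (missing(curvature) || is.null(curvature)) stop("curvature map is required")
  check_map_matches(curvature, n_vertices(mesh))
  vertex_map(ifelse(curvature$values > 0, 1, 0), valid = curvature$valid,
             name = "sulcal_gyral", units = "1=sulcus,0=gyrus")
}

#' Proportion of terminations landing in sulci vs gyri
#'
#' Weighted fractions of all selected streamlines' ending vertices falling
#' in each class; the weighting (1/length by default) normalizes the
#' termination counts by streamline length.
#'
#' @param assignment an [assign_endpoints()] result built from `tractogram`.
#' @param tractogram the matching [tractogram].
#' @param labels a [vertex_map] from [classify_sulcal_gyral()].
#' @param weighted use 1/length weights (default `TRUE`).
#' @return named numeric vector `c(sulcus = ..., gyrus = ...)` summing to 1.
#' @export
termination_class_proportions <- function(assignment, tractogram, labels,
                                          weighted = TRUE) {
  check_map_matches(labels, assignment$n_vertices)
  if (!all(labels$valid)) stop("labels must cover all vertices")
  pt <- pair_table(assignment, tractogram)
  if (nrow(pt) == 0L) return(c(sulcus = NA_real_, gyrus = NA_real_))
  w <- if (weighted) pt$weight else rep(1, nrow(pt))
  is_sulcus <- labels$values[pt$ending_vertex] == 1
  tot <- sum(w)
  c(sulcus = sum(w[is_sulcus]) / tot, gyrus = sum(w[!is_sulcus]) / tot)
}

#' Angle between terminal streamline segments and surface normals
#'
#' For every selected (streamline, extremity) pair, the angle between the
#' vertex normal at the pair's ending vertex and the streamline's terminal
#' segment at that end (its last two polyline points), folded into
#' [0, 90] degrees so antiparallel directions count as aligned.
#'
#' @param tractogram the matching [tractogram].
#' @param mesh a [surface_mesh].
#' @param assignment an [assign_endpoints()] result built from `tractogram`.
#' @return data.frame(`streamline`, `extremity`, `ending_vertex`, `angle`)
#'   with angles in degrees; degenerate (zero-length) terminal segments are
#'   skipped with a message.
#' @export
termination_angle <- function(tractogram, mesh, assignment) {
  p <- assignment$pairs
  if (nrow(p) == 0L) {
    return(data.frame(streamline = integer(0), extremity = integer(0),
                      ending_vertex = integer(0), angle = numeric(0)))
  }
  # terminal segment at the ending side = the extremity opposite the selecting one
  dirs <- matrix(0, nrow(p), 3)
  for (r in seq_len(nrow(p))) {
    s <- tractogram$streamlines[[p$streamline[r]]]
    k <- nrow(s)
    if (p$extremity[r] == 1L) {
      dirs[r, ] <- s[k, ] - s[k - 1, ]   # selecting end = first, ending side = last
    } else {
      dirs[r, ] <- s[1, ] - s[2, ]       # selecting end = last, ending side = first
    }
  }
  nrm <- sqrt(rowSums(dirs^2))
  ok <- nrm > 0
  n_skip <- sum(!ok)
  if (n_skip > 0) message(sprintf("skipped %d degenerate terminal segment(s)", n_skip))
  normals <- mesh$normals[p$ending_vertex, , drop = FALSE]
  cosang <- abs(rowSums(dirs * normals)) / nrm
  cosang <- pmin(1, cosang)
  out <- data.frame(streamline = p$streamline, extremity = p$extremity,
                    ending_vertex = p$ending_vertex,
                    angle = acos(cosang) * 180 / pi)
  out[ok, , drop = FALSE]
}
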