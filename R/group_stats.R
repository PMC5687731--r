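#' Build a group-comparison design matrix
#'
#' Intercept + binary group indicator + covariates, with the contrast
#' selecting the group effect.  The group factor's *second* level is coded 1
#' (so with levels `c("control", "patient")` the contrast tests patient
#' minus control; a positive Cohen's d from [cluster_effect_size()] then
#' means control > patient, the usual reporting convention).
#'
#' @param data data.frame with one row per subject.
#' @param group name of the two-level group column (factor or coercible).
#' @param covariates character vector of covariate column names (numeric or
#'   two-level factors, e.g. `c("age", "sex")`); may be empty.
#' @return list of class `design_matrix`: `X` (n x p), `contrast` (length p,
#'   selecting the group column), `group` (factor), `subjects`.
#' @export
design_matrix <- function(data, group = "group", covariates = c("age", "sex")) {
  if (!group %in% names(data)) stop("no column named '", group, "' in data")
  g <- factor(data[[group]])
  if (nlevels(g) != 2L) stop("group must have exactly 2 levels")
  if (min(table(g)) < 2L) stop("need >= 2 subjects per group")
  X <- cbind(intercept = 1, group = as.numeric(g == levels(g)[2]))
  for (cv in covariates) {
    if (!cv %in% names(data)) stop("no covariate column named '", cv, "'")
    v <- data[[cv]]
    if (is.factor(v) || is.character(v)) {
      f <- factor(v)
      if (nlevels(f) != 2L) stop("factor covariate '", cv, "' must have 2 levels")
      v <- as.numeric(f == levels(f)[2])
    }
    X <- cbind(X, as.numeric(v))
    colnames(X)[ncol(X)] <- cv
  }
  if (any(apply(X, 2, function(col) all(col == 0)))) stop("design has a constant-zero column")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  contrast <- as.numeric(colnames(X) == "group")
  structure(list(X = X, contrast = contrast, group = g,
                 subjects = if (!is.null(data$subject)) data$subject else seq_len(nrow(X))),
            class = "design_matrix")
}

map_stack <- function(maps) {
  if (is.matrix(maps)) return(maps)
  if (is.list(maps) && all(vapply(maps, inherits, logical(1), "vertex_map"))) {
    return(do.call(rbind, lapply(maps, function(m) m$values)))
  }
  stop("maps must be a subjects x vertices matrix or a list of vertex_map")
}

#' Vertex-wise general linear model
#'
#' Ordinary least squares at every vertex of a per-subject map stack, with a
#' t-test of the design's contrast (the group effect by default).  A vertex
#' is valid only if it is valid in every subject.
#'
#' @param maps subjects x vertices numeric matrix (`NA` = invalid) or list
#'   of per-subject [vertex_map]s in vertex correspondence.
#' @param design a [design_matrix()].
#' @return list of class `glm_fit`: `beta`, `t`, `p` ([vertex_map]s for the
#'   contrast effect, t statistic, two-sided p), `df` (residual degrees of
#'   freedom), `valid`.
#' @export
fit_glm <- function(maps, design) {
  Y <- map_stack(maps)
  X <- design$X
  if (nrow(Y) != nrow(X)) stop("map stack rows must match design rows")
  n <- nrow(X); p <- ncol(X)
  df <- n - p
  if (df < 1) stop("not enough subjects for the design (residual df < 1)")
  valid <- colSums(is.na(Y)) == 0L
  XtXinv <- solve(crossprod(X))
  XtXinvXt <- XtXinv %*% t(X)
  cXXc <- as.numeric(t(design$contrast) %*% XtXinv %*% design$contrast)

  nv <- ncol(Y)
  beta <- tvals <- pvals <- rep(NA_real_, nv)
  if (any(valid)) {
    Yv <- Y[, valid, drop = FALSE]
    B <- XtXinvXt %*% Yv
    res <- Yv - X %*% B
    sigma2 <- colSums(res^2) / df
    cb <- as.vector(design$contrast %*% B)
    tt <- cb / sqrt(sigma2 * cXXc)
    # numerically exact fits: residual negligible relative to the data scale
    scale2 <- pmax(colMeans(Yv^2), .Machine$double.xmin)
    exact <- sigma2 <= 1e-24 * scale2
    if (any(exact)) {
      tt[exact] <- sign(cb[exact]) * Inf
      tt[exact & cb^2 <= 1e-24 * scale2] <- 0
    }
    beta[valid] <- cb
    tvals[valid] <- tt
    pvals[valid] <- 2 * stats::pt(-abs(tt), df)
  }
  structure(list(beta = vertex_map(beta, name = "beta", units = ""),
                 t = vertex_map(tvals, name = "t", units = ""),
                 p = vertex_map(pvals, name = "p", units = ""),
                 df = df, valid = valid),
            class = "glm_fit")
}

# Connected components of a vertex subset under mesh adjacency (iterative BFS).
connected_components <- function(vertex_idx, adjacency) {
  if (length(vertex_idx) == 0L) return(list())
  in_set <- logical(length(adjacency))
  in_set[vertex_idx] <- TRUE
  visited <- logical(length(adjacency))
  comps <- list()
  for (v in vertex_idx) {
    if (visited[v]) next
    stack <- v
    visited[v] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, u)
      nb <- adjacency[[u]]
      nb <- nb[in_set[nb] & !visited[nb]]
      if (length(nb)) {
        visited[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

#' Find supra-threshold clusters of a statistic map
#'
#' Connected components (mesh adjacency) of vertices whose statistic exceeds
#' the cluster-forming threshold, separately for each requested sign, with
#' cluster area as the sum of member vertex areas.
#'
#' @param stat_map a [vertex_map] of t-values.
#' @param mesh the matching [surface_mesh].
#' @param forming_threshold positive t threshold.
#' @param sign `"both"` (default), `"positive"` or `"negative"`.
#' @return list of clusters, each a list with `vertices`, `area` (mm^2),
#'   `peak_vertex`, `peak_stat`, `sign` (+1/-1); ordered by decreasing area.
#' @export
find_clusters <- function(stat_map, mesh, forming_threshold,
                          sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  if (forming_threshold <= 0) stop("forming_threshold must be > 0")
  check_map_matches(stat_map, n_vertices(mesh))
  tvals <- stat_map$values
  out <- list()
  signs <- switch(sign, both = c(1, -1), positive = 1, negative = -1)
  for (sg in signs) {
    supra <- which(stat_map$valid & sg * tvals > forming_threshold)
    for (comp in connected_components(supra, mesh$adjacency)) {
      pk <- comp[which.max(abs(tvals[comp]))]
      out[[length(out) + 1L]] <- list(vertices = comp,
                                      area = sum(mesh$vertex_areas[comp]),
                                      peak_vertex = pk,
                                      peak_stat = tvals[pk],
                                      sign = sg)
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

#' Cluster-wise permutation correction of a vertex-wise group comparison
#'
#' Fits the GLM, forms supra-threshold clusters, and corrects cluster-wise
#' via Freedman-Lane residual permutation: the reduced model (covariates
#' only) is fitted, its residuals are permuted across subjects, the full
#' model is refitted to each permuted dataset, and the null distribution of
#' the maximum supra-threshold cluster area (over both signs) is recorded.
#' Each observed cluster gets
#' `corrected_p = (1 + #\{null max area >= observed area\}) / (1 + n_permutations)`.
#'
#' @param maps subjects x vertices matrix or list of [vertex_map]s.
#' @param design a [design_matrix()].
#' @param mesh the matching [surface_mesh].
#' @param forming_p two-sided vertex-wise p defining the cluster-forming t
#'   threshold (default 0.001; the threshold is `qt(1 - forming_p/2, df)`).
#' @param n_permutations number of permutations (default 1000, >= 100).
#' @param seed integer seed; same seed gives identical corrected p-values.
#' @return list of class `cluster_correction`: `clusters` (as in
#'   [find_clusters()], each with `corrected_p` and `effect_size` added),
#'   `fit` (the observed [fit_glm()] result), `forming_threshold`,
#'   `null_max_area`, `n_permutations`, `min_attainable_p`.
#' @export
permutation_cluster_correction <- function(maps, design, mesh,
                                           forming_p = 0.001,
                                           n_permutations = 1000,
                                           seed = 1L) {
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  Y <- map_stack(maps)
  X <- design$X
  n <- nrow(X)
  if (factorial(min(n, 12)) < 20 * n_permutations && n <= 12) {
    warning(sprintf("few exchangeable units (n = %d); minimum attainable corrected p is %.4g",
                    n, 1 / (1 + n_permutations)))
  }
  fit <- fit_glm(Y, design)
  df <- fit$df
  thr <- stats::qt(1 - forming_p / 2, df)
  obs_clusters <- find_clusters(fit$t, mesh, thr, "both")

  valid <- fit$valid
  Yv <- Y[, valid, drop = FALSE]
  vidx <- which(valid)
  XtXinv <- solve(crossprod(X))
  XtXinvXt <- XtXinv %*% t(X)
  cvec <- design$contrast
  cXXc <- as.numeric(t(cvec) %*% XtXinv %*% cvec)

  # reduced model: drop the contrast column(s)
  red_cols <- which(cvec == 0)
  Z <- X[, red_cols, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  fit_red <- Hz %*% Yv
  E <- Yv - fit_red

  adjacency <- mesh$adjacency
  areas <- mesh$vertex_areas
  null_max <- numeric(n_permutations)
  set.seed(as.integer(seed))
  tfull <- rep(NA_real_, length(valid))
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    Yp <- fit_red + E[perm, , drop = FALSE]
    B <- XtXinvXt %*% Yp
    res <- Yp - X %*% B
    sigma2 <- colSums(res^2) / df
    tt <- as.vector(cvec %*% B) / sqrt(sigma2 * cXXc)
    supra <- vidx[which(abs(tt) > thr)]
    tsup <- tt[abs(tt) > thr]
    mx <- 0
    if (length(supra)) {
      pos <- supra[tsup > 0]
      neg <- supra[tsup < 0]
      for (comp in c(connected_components(pos, adjacency),
                     connected_components(neg, adjacency))) {
        a <- sum(areas[comp])
        if (a > mx) mx <- a
      }
    }
    null_max[b] <- mx
  }

  clusters <- lapply(obs_clusters, function(cl) {
    cl$corrected_p <- (1 + sum(null_max >= cl$area)) / (1 + n_permutations)
    cl$effect_size <- cluster_effect_size(Y, design, cl)
    cl
  })
  structure(list(clusters = clusters, fit = fit, forming_threshold = thr,
                 null_max_area = null_max, n_permutations = n_permutations,
                 min_attainable_p = 1 / (1 + n_permutations)),
            class = "cluster_correction")
}

#' @export
print.cluster_correction <- function(x, ...) {
  cat(sprintf("cluster_correction: %d cluster(s), forming |t| > %.3f, %d permutations\n",
              length(x$clusters), x$forming_threshold, x$n_permutations))
  if (length(x$clusters)) print(cluster_table(x))
  invisible(x)
}

#' Tabulate corrected clusters
#'
#' One row per cluster: size in mm^2, peak vertex and statistic, direction,
#' corrected p and Cohen's d — the standard cluster-report columns.
#'
#' @param correction a [permutation_cluster_correction()] result.
#' @return data.frame with columns `cluster`, `n_vertices`, `area_mm2`,
#'   `peak_vertex`, `peak_t`, `direction`, `corrected_p`, `effect_size`.
#' @export
cluster_table <- function(correction) {
  cl <- correction$clusters
  data.frame(cluster = seq_along(cl),
             n_vertices = vapply(cl, function(c) length(c$vertices), integer(1)),
             area_mm2 = vapply(cl, `[[`, numeric(1), "area"),
             peak_vertex = vapply(cl, `[[`, integer(1), "peak_vertex"),
             peak_t = vapply(cl, `[[`, numeric(1), "peak_stat"),
             direction = ifelse(vapply(cl, `[[`, numeric(1), "sign") > 0,
                                "group2>group1", "group1>group2"),
             corrected_p = vapply(cl, `[[`, numeric(1), "corrected_p"),
             effect_size = vapply(cl, `[[`, numeric(1), "effect_size"))
}

#' Cohen's d of cluster-mean values between groups
#'
#' Each subject is reduced to the mean of its map over the cluster's
#' vertices; d = (mean of group level 1 - mean of group level 2) / pooled SD,
#' so with levels `c("control", "patient")` a positive d means
#' control > patient.
#'
#' @param maps subjects x vertices matrix or list of [vertex_map]s.
#' @param design a [design_matrix()].
#' @param cluster one cluster from [find_clusters()] (needs `$vertices`), or
#'   an integer vector of vertex indices.
#' @return Cohen's d (NA with a warning if the pooled SD is zero).
#' @export
cluster_effect_size <- function(maps, design, cluster) {
  Y <- map_stack(maps)
  vtx <- if (is.list(cluster)) cluster$vertices else as.integer(cluster)
  if (length(vtx) == 0L) stop("cluster is empty")
  subj_means <- rowMeans(Y[, vtx, drop = FALSE], na.rm = TRUE)
  g <- design$group
  x1 <- subj_means[g == levels(g)[1]]
  x2 <- subj_means[g == levels(g)[2]]
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    warning("zero pooled SD in cluster; effect size undefined")
    return(NA_real_)
  }
  (mean(x1) - mean(x2)) / sqrt(sp2)
}
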