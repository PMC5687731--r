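#' ICC and coefficient-of-variation reliability maps
#'
#' Per-vertex test-retest reliability across replicate acquisitions of the
#' same subjects: the two-way random-effects, single-measure,
#' absolute-agreement intraclass correlation ICC(2,1), and the
#' coefficient of variation, 100 x the within-subject SD over the
#' within-subject mean, averaged over subjects.
#'
#' @param replicate_maps list of >= 2 replicate stacks, each a subjects x
#'   vertices matrix (or list of [vertex_map]s), with identical subject
#'   order and vertex correspondence.
#' @return list of class `reliability_maps`: `icc` and `cv` ([vertex_map]s;
#'   a vertex is invalid if any replicate is invalid there, or — for ICC —
#'   if the total variance is zero, which is flagged with a warning).
#' @export
reliability <- function(replicate_maps) {
  if (!is.list(replicate_maps) || length(replicate_maps) < 2L) {
    stop("need >= 2 replicate map stacks")
  }
  stacks <- lapply(replicate_maps, map_stack)
  dims <- vapply(stacks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("replicate stacks must have identical subjects x vertices dimensions")
  }
  n <- dims[1, 1]
  k <- length(stacks)
  nv <- dims[2, 1]
  if (n < 2L) stop("need >= 2 subjects")

  valid <- Reduce(`&`, lapply(stacks, function(s) colSums(is.na(s)) == 0L))

  # per-vertex two-way ANOVA sums of squares, vectorized over vertices
  sum_all <- Reduce(`+`, stacks)                       # n x nv, sum over replicates
  grand <- colSums(sum_all) / (n * k)
  row_means <- sum_all / k                             # subject means, n x nv
  col_means <- do.call(rbind, lapply(stacks, colMeans))  # k x nv, replicate means

  ssr <- k * colSums((row_means - matrix(grand, n, nv, byrow = TRUE))^2)
  ssc <- n * colSums((col_means - matrix(grand, k, nv, byrow = TRUE))^2)
  sst <- Reduce(`+`, lapply(stacks, function(s)
    colSums((s - matrix(grand, n, nv, byrow = TRUE))^2)))
  sse <- pmax(sst - ssr - ssc, 0)

  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- (msr - mse) / denom
  degenerate <- valid & (denom <= 0)
  if (any(degenerate)) {
    warning(sprintf("%d vertex/vertices with zero total variance; ICC undefined there",
                    sum(degenerate)))
    icc[degenerate] <- NA_real_
  }
  icc[!valid] <- NA_real_

  # CV: per subject, SD over replicates / mean over replicates; average x 100
  within_mean <- row_means
  sq_dev <- Reduce(`+`, lapply(stacks, function(s) (s - within_mean)^2))
  within_sd <- sqrt(sq_dev / (k - 1))
  ratio <- within_sd / within_mean
  ratio[!is.finite(ratio)] <- NA_real_
  cv <- 100 * colMeans(ratio)
  cv[!valid] <- NA_real_

  structure(list(icc = vertex_map(icc, name = "ICC(2,1)", units = ""),
                 cv = vertex_map(cv, name = "CV", units = "percent")),
            class = "reliability_maps")
}
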