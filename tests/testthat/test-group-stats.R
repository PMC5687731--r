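make_design <- function(n_per_group = 10, seed = 1, covariates = c("age", "sex")) {
  set.seed(seed)
  df <- data.frame(group = rep(c("control", "patient"), each = n_per_group),
                   age = runif(2 * n_per_group, 6, 28),
                   sex = sample(c("F", "M"), 2 * n_per_group, replace = TRUE))
  design_matrix(df, covariates = covariates)
}

test_that("design matrix validates structure and codes the group contrast", {
  dm <- make_design()
  expect_equal(colnames(dm$X), c("intercept", "group", "age", "sex"))
  expect_equal(dm$contrast, c(0, 1, 0, 0))
  df <- data.frame(group = c("a", "a", "b", "b"), age = 1:4, age2 = 2 * (1:4))
  expect_error(design_matrix(df, covariates = c("age", "age2")), "collinear")
  expect_error(design_matrix(data.frame(group = c("a", "a", "a", "b"), age = 1:4)),
               ">= 2 subjects")
})

test_that("t is 0 for identical groups and explodes at separation", {
  dm <- make_design(5, covariates = character(0))
  Y <- matrix(3, 10, 4)
  fit <- fit_glm(Y, dm)
  expect_equal(fit$t$values, rep(0, 4))

  set.seed(2)
  for (eps in c(1e-2, 1e-4, 1e-6)) {
    Yv <- matrix(rep(c(0, 1), each = 5) + rnorm(10, 0, eps), 10, 1)
    t_eps <- fit_glm(Yv, dm)$t$values
    expect_gt(t_eps, 1 / (10 * eps))  # grows without bound, sign = patient coding
  }
})

test_that("per-vertex OLS matches an independent lm() solve", {
  dm <- make_design(8)
  set.seed(7)
  Y <- matrix(rnorm(16 * 3, mean = 50, sd = 5), 16, 3)
  fit <- fit_glm(Y, dm)
  for (v in 1:3) {
    ref <- lm(Y[, v] ~ 0 + dm$X)
    sm <- summary(ref)$coefficients
    expect_equal(fit$beta$values[v], unname(coef(ref)["dm$Xgroup"]))
    expect_equal(fit$t$values[v], unname(sm["dm$Xgroup", "t value"]))
    expect_equal(fit$p$values[v], unname(sm["dm$Xgroup", "Pr(>|t|)"]))
  }
  # invalid in one subject -> invalid vertex
  Y[3, 2] <- NA
  expect_equal(fit_glm(Y, dm)$valid, c(TRUE, FALSE, TRUE))
})

test_that("t statistics are invariant to affine covariate rescaling", {
  set.seed(8)
  df <- data.frame(group = rep(c("c", "p"), each = 8), age = runif(16, 6, 28),
                   sex = sample(c("F", "M"), 16, replace = TRUE))
  Y <- matrix(rnorm(16 * 5), 16, 5)
  t1 <- fit_glm(Y, design_matrix(df))$t$values
  df2 <- df; df2$age <- 12 * df$age - 100
  t2 <- fit_glm(Y, design_matrix(df2))$t$values
  expect_equal(t1, t2)
})

test_that("a covariate orthogonal to design and data shifts t only through df", {
  set.seed(10)
  n <- 16
  df <- data.frame(group = rep(c("c", "p"), each = n / 2), age = runif(n, 6, 28))
  dm1 <- design_matrix(df, covariates = "age")
  y <- rnorm(n)
  # Gram-Schmidt a column orthogonal to X and to y
  z <- rnorm(n)
  basis <- qr.Q(qr(cbind(dm1$X, y)))
  z <- z - basis %*% crossprod(basis, z)
  df2 <- df; df2$z <- as.vector(z)
  dm2 <- design_matrix(df2, covariates = c("age", "z"))
  f1 <- fit_glm(matrix(y, ncol = 1), dm1)
  f2 <- fit_glm(matrix(y, ncol = 1), dm2)
  expect_equal(f1$beta$values, f2$beta$values)
  expect_equal(f2$t$values, f1$t$values * sqrt(f2$df / f1$df))
})

test_that("cluster finding matches planted patches and handles edge cases", {
  mesh <- make_icosphere(3, 80)
  nv <- n_vertices(mesh)
  tvals <- rep(0.5, nv)
  expect_equal(find_clusters(vertex_map(tvals), mesh, 3), list())

  tvals[42] <- 4
  one <- find_clusters(vertex_map(tvals), mesh, 3)
  expect_length(one, 1)
  expect_equal(one[[1]]$vertices, 42L)
  expect_equal(one[[1]]$area, mesh$vertex_areas[42])

  # two planted disjoint patches, opposite signs
  p1 <- geodesic_patch(mesh, 1, 20)
  p2 <- geodesic_patch(mesh, 600, 20)
  expect_length(intersect(p1, p2), 0)
  tv <- rep(0, nv); tv[p1] <- 5; tv[p2] <- -6
  cl <- find_clusters(vertex_map(tv), mesh, 3, "both")
  expect_length(cl, 2)
  signs <- vapply(cl, `[[`, numeric(1), "sign")
  expect_setequal(cl[[which(signs == 1)]]$vertices, p1)
  expect_setequal(cl[[which(signs == -1)]]$vertices, p2)
  expect_length(find_clusters(vertex_map(tv), mesh, 3, "positive"), 1)
})

test_that("permutation correction is deterministic and orders p by area", {
  mesh <- make_icosphere(2, 80)
  coh <- simulate_cohort(mesh, n_per_group = 10,
                         effect = list(center = 5, radius = 30, delta = -40),
                         seed = 33)
  dm <- design_matrix(coh$design)
  cc1 <- permutation_cluster_correction(coh$maps, dm, mesh,
                                        n_permutations = 200, seed = 99)
  cc2 <- permutation_cluster_correction(coh$maps, dm, mesh,
                                        n_permutations = 200, seed = 99)
  expect_identical(vapply(cc1$clusters, `[[`, numeric(1), "corrected_p"),
                   vapply(cc2$clusters, `[[`, numeric(1), "corrected_p"))
  tab <- cluster_table(cc1)
  if (nrow(tab) > 1) {
    expect_true(all(diff(tab$corrected_p[order(-tab$area_mm2)]) >= 0))
  }
  # a dominant planted cluster reaches the minimum attainable p
  expect_equal(min(tab$corrected_p), 1 / (1 + 200))
})

test_that("cluster effect sizes follow the Cohen's d convention", {
  dm <- make_design(5, covariates = character(0))
  # equal group means by construction -> d = 0 exactly
  Y0 <- matrix(c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1), 10, 6)
  expect_equal(cluster_effect_size(Y0, dm, 1:6), 0)
  # controls 1 SD above patients -> positive d (control > patient)
  set.seed(12)
  Y <- matrix(rnorm(10 * 6), 10, 6) + rep(c(1, 0), each = 5)
  d <- cluster_effect_size(Y, dm, 1:6)
  expect_gt(d, 0)
  Yc <- matrix(rep(c(0, 1), each = 5), 10, 2)
  expect_warning(dd <- cluster_effect_size(Yc, dm, 1:2), "zero pooled SD")
  expect_true(is.na(dd))
})
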