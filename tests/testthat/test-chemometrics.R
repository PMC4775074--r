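test_that("Pareto scaling centers and divides by the root standard deviation", {
  X <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), k = c(5, 5, 5))
  sc <- pareto_scale(X)
  expect_equal(unname(sc$X[, "a"]), c(-1, 0, 1))
  expect_equal(unname(sc$X[, "b"]), c(-1.414, 0, 1.414), tolerance = 1e-3)
  expect_equal(unname(sc$X[, "k"]), c(0, 0, 0))
  expect_true(sc$model$constant[["k"]])
  expect_equal(apply_scaling(sc$model, X), sc$X)
  expect_error(pareto_scale(X[1, , drop = FALSE]), "2 samples")
})

test_that("NIPALS PCA matches the SVD oracle and captures low rank exactly", {
  set.seed(21)
  X1 <- outer(rnorm(10), rnorm(6))
  expect_equal(fit_pca(X1, 1, center = FALSE, scale = "none")$R2X, 1,
               tolerance = 1e-9)

  for (i in 1:5) {
    X <- matrix(rnorm(12 * 8), 12, 8)
    pc <- fit_pca(X, 3, center = TRUE, scale = "none")
    sv <- svd(scale(X, scale = FALSE))
    for (k in 1:3) {
      ref <- sv$u[, k] * sv$d[k]
      expect_lt(min(max(abs(pc$scores[, k] - ref)),
                    max(abs(pc$scores[, k] + ref))), 1e-8)
    }
    # rank-k reconstruction agrees with truncated SVD
    rec <- tcrossprod(pc$scores, pc$loadings)
    ref_rec <- sv$u[, 1:3] %*% diag(sv$d[1:3]) %*% t(sv$v[, 1:3])
    expect_equal(rec, ref_rec, tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(diff(pc$R2X) <= 1e-10))
    expect_equal(crossprod(pc$loadings), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # duplicated variables get equal loadings
  X <- matrix(rnorm(20 * 4), 20, 4)
  Xd <- cbind(X, X[, 2])
  pc <- fit_pca(Xd, 2, center = TRUE, scale = "none")
  expect_equal(pc$loadings[2, ], pc$loadings[5, ], tolerance = 1e-8)
})

test_that("OPLS-DA on the toy matrix separates the classes on the predictive score", {
  xy <- toy_xy()
  fit <- fit_opls_da(xy$X, xy$coding, n_ortho = 0)
  expect_identical(sign(fit$t), c(1, 1, -1, -1))
  expect_gte(fit$R2Y, 0.95)
  # the toy's predictive fit matches one-component NIPALS PLS1 exactly
  ref <- fit_pls_da(xy$X, xy$coding, n_components = 1)
  expect_equal(fit$fitted, ref$fitted, tolerance = 1e-10)
  # class-1 centroid predicts clearly as class 1
  centroid <- matrix(colMeans(xy$X[xy$coding$y == 1, ]), nrow = 1)
  expect_gt(predict(fit, centroid), 0.5)
  # training predictions reproduce R2Y's fitted values
  expect_equal(predict(fit, xy$X), fit$fitted, tolerance = 1e-10)
  expect_error(predict(fit, xy$X[, 1, drop = FALSE]), "mismatch")
})

test_that("a perfectly separating variable gives near-perfect R2Y", {
  set.seed(4)
  X <- cbind(sep = rep(c(5, -5), each = 10) + rnorm(20, 0, 0.05),
             matrix(rnorm(20 * 5, 0, 0.01), 20, 5))
  cod <- class_coding(rep(c("A", "B"), each = 10), "A", "B")
  fit <- fit_opls_da(X, cod, n_ortho = 0)
  expect_gte(fit$R2Y, 0.99)
  expect_error(class_coding(rep("A", 10), "A", "B"), "single class")
})

test_that("single-response OPLS reproduces (k+1)-component PLS1 fitted values", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(8:30, 1); p <- sample(5:50, 1)
    X <- matrix(rnorm(n * p), n, p)
    cod <- class_coding(rep(c("A", "B"), length.out = n), "A", "B")
    k <- sample(0:2, 1)
    opls <- fit_opls_da(X, cod, n_ortho = k)
    pls <- fit_pls_da(X, cod, n_components = k + 1)
    expect_equal(predict(opls, X), pls$fitted, tolerance = 1e-8)
  }
})

test_that("orthogonal scores are orthogonal to y and to the predictive score", {
  set.seed(32)
  for (i in 1:5) {
    X <- matrix(rnorm(24 * 30), 24, 30)
    cod <- class_coding(rep(c("A", "B"), each = 12), "A", "B")
    fit <- fit_opls_da(X, cod, n_ortho = 2)
    expect_lt(max(abs(cor(fit$t, fit$T_o))), 1e-8)
    expect_lt(max(abs(cor(fit$T_o, cod$y))), 1e-8)
  }
})

test_that("R2Y is invariant under variable and sample permutation", {
  set.seed(33)
  X <- matrix(rnorm(20 * 15), 20, 15)
  cod <- class_coding(rep(c("A", "B"), each = 10), "A", "B")
  base <- fit_opls_da(X, cod, n_ortho = 1)$R2Y
  vp <- sample(ncol(X))
  expect_equal(fit_opls_da(X[, vp], cod, n_ortho = 1)$R2Y, base,
               tolerance = 1e-10)
  sp <- sample(nrow(X))
  cod2 <- class_coding(cod$labels[sp], "A", "B")
  expect_equal(fit_opls_da(X[sp, ], cod2, n_ortho = 1)$R2Y, base,
               tolerance = 1e-10)
})

test_that("cross-validation is stratified, deterministic and bounded by R2Y", {
  m <- binned_choline(seed = 51, fold = 2, n_a = 14, n_b = 14)
  xy <- np_vs_c_xy(m)
  cv1 <- cross_validate(xy$X, xy$coding, n_ortho = 1, seed = 9)
  cv2 <- cross_validate(xy$X, xy$coding, n_ortho = 1, seed = 9)
  expect_identical(cv1, cv2)
  for (k in unique(cv1$fold_assignments)) {
    expect_setequal(unique(xy$coding$y[cv1$fold_assignments == k]), c(0, 1))
  }
  fit <- fit_opls_da(xy$X, xy$coding, n_ortho = 1)
  expect_lte(cv1$Q2Y, fit$R2Y)
  expect_gte(cv1$Q2Y, 0.5)

  # fold count shrinks so both classes stay present in every fold
  small <- binned_choline(seed = 52, fold = 2, n_a = 4, n_b = 10)
  xys <- np_vs_c_xy(small)
  expect_warning(cvs <- cross_validate(xys$X, xys$coding, n_ortho = 0,
                                       n_folds = 7, seed = 1), "reduced")
  expect_equal(cvs$n_folds, 4)
})

test_that("strongly separable data gives high Q2Y, null data does not", {
  m <- binned_choline(seed = 61, fold = 2, n_a = 25, n_b = 25)
  xy <- np_vs_c_xy(m)
  expect_gte(cross_validate(xy$X, xy$coding, n_ortho = 1, seed = 2)$Q2Y, 0.8)

  q2_null <- vapply(1:15, function(s) {
    mm <- binned_null(seed = 400 + s, n_a = 12, n_b = 12)
    xy <- np_vs_c_xy(mm)
    suppressWarnings(
      cross_validate(xy$X, xy$coding, n_ortho = 0, seed = s)$Q2Y)
  }, numeric(1))
  expect_gte(mean(q2_null <= 0.2), 0.9)
  expect_lte(mean(q2_null), 0)
})

test_that("permutation p-values behave at the edges and flag real signal", {
  m <- binned_choline(seed = 71, fold = 2, n_a = 20, n_b = 20)
  xy <- np_vs_c_xy(m)
  pt <- permutation_test(xy$X, xy$coding, n_ortho = 0, n_perm = 99, seed = 5)
  expect_identical(nrow(pt$permutations), 99L)
  expect_lte(pt$p_value_Q2, 0.01)
  expect_true(all(abs(pt$permutations$label_correlation) < 1))

  p1 <- permutation_test(xy$X, xy$coding, n_ortho = 0, n_perm = 1, seed = 6)
  expect_true(p1$p_value_Q2 %in% c(0.5, 1.0))
})

test_that("select_n_ortho prefers small models on noise and finds a confounder", {
  picks <- vapply(1:10, function(s) {
    set.seed(900 + s)
    X <- matrix(rnorm(20 * 30), 20, 30)
    cod <- class_coding(rep(c("A", "B"), each = 10), "A", "B")
    select_n_ortho(X, cod, max_ortho = 2, seed = s)
  }, integer(1))
  expect_gte(mean(picks == 0), 0.6)

  # one strong y-orthogonal direction: stripping it must help
  set.seed(77)
  n <- 30
  y <- rep(c(1, 0), each = n / 2)
  conf <- rnorm(n, 0, 4) # orthogonal nuisance direction
  signal <- y - 0.5 + rnorm(n, 0, 0.4)
  load_c <- rnorm(40); load_s <- rnorm(40)
  X <- outer(conf, load_c) + outer(signal, load_s) +
    matrix(rnorm(n * 40, 0, 0.3), n, 40)
  cod <- class_coding(ifelse(y == 1, "A", "B"), "A", "B")
  k <- select_n_ortho(X, cod, max_ortho = 3, seed = 3)
  expect_gte(k, 1)
  q0 <- cross_validate(X, cod, n_ortho = 0, seed = 3)$Q2Y
  qk <- cross_validate(X, cod, n_ortho = k, seed = 3)$Q2Y
  expect_gt(qk, q0)
  expect_identical(select_n_ortho(X, cod, max_ortho = 0, seed = 1), 0L)
})

test_that("loadings report ranks the separating variable first, bounded reliabilities", {
  xy <- toy_xy()
  fit <- fit_opls_da(xy$X, xy$coding, n_ortho = 0)
  ld <- loadings_report(fit)
  expect_identical(which.max(abs(ld$magnitude)), 1L)
  expect_identical(which.max(abs(ld$reliability)), 1L)
  expect_true(all(ld$reliability >= -1 & ld$reliability <= 1))

  # zero-variance variable flagged with reliability 0
  X2 <- cbind(xy$X, 1)
  fit2 <- fit_opls_da(X2, xy$coding, n_ortho = 0)
  ld2 <- loadings_report(fit2)
  expect_true(ld2$zero_variance[3])
  expect_identical(ld2$reliability[3], 0)
})
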