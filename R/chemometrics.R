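# Latent-variable engine: Pareto scaling, NIPALS PCA, NIPALS PLS1,
# OPLS-DA, stratified cross-validation (Q2Y), permutation testing and
# covariance/correlation loadings diagnostics.
#
# All algorithms are written out explicitly (NIPALS iterations, Trygg-Wold
# orthogonal filtering) rather than delegated, because the latent-variable
# machinery is the point of the package; SVD serves only as a test oracle.

# ---- scaling -------------------------------------------------------------

# Column standard deviations without apply(); called in every CV refit.
col_sds <- function(X, means = colMeans(X)) {
  n <- nrow(X)
  v <- (colSums(X^2) - n * means^2) / (n - 1)
  sqrt(pmax(v, 0))
}

#' Mean-center and scale a data matrix
#'
#' Pareto scaling divides each mean-centered column by the square root of
#' its sample standard deviation — the conventional compromise for NMR
#' metabolomics between no scaling (large peaks dominate) and unit variance
#' (noise inflated).  Constant columns are centered only and flagged.
#'
#' @param X Samples x variables numeric matrix, at least 2 rows.
#' @param method `"pareto"` (default), `"uv"` (unit variance) or
#'   `"center"` (mean centering only).
#' @return List with `X` (the scaled matrix) and `model` (a
#'   `scaling_model`: `means`, `divisors`, `constant` flags, `method`).
#' @export
pareto_scale <- function(X, method = c("pareto", "uv", "center")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("scaling needs at least 2 samples")
  means <- colMeans(X)
  sds <- col_sds(X, means)
  constant <- sds <= .Machine$double.eps * 100
  div <- switch(method,
                pareto = sqrt(sds),
                uv = sds,
                center = rep(1, length(sds)))
  div[constant] <- 1
  model <- structure(list(means = means, divisors = div, constant = constant,
                          method = method),
                     class = "scaling_model")
  list(X = apply_scaling(model, X), model = model)
}

#' @rdname pareto_scale
#' @param model A `scaling_model`.
#' @export
apply_scaling <- function(model, X) {
  stopifnot(inherits(model, "scaling_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$means)) {
    stop("variable count mismatch: model has ", length(model$means),
         ", data has ", ncol(X))
  }
  sweep(sweep(X, 2, model$means, `-`), 2, model$divisors, `/`)
}

# ---- class coding --------------------------------------------------------

#' Dummy-code two classes for discriminant analysis
#'
#' Pairwise discriminant models regress a 0/1 dummy: samples of `class_a`
#' (the "affected"/positive class) are coded 1, `class_b` 0.
#'
#' @param labels Character or factor vector of per-sample class labels.
#' @param class_a,class_b The two class names; every label must be one of
#'   them and both must be present.
#' @return A `class_coding`: `y` (0/1), `class_a`, `class_b`, `labels`.
#' @export
class_coding <- function(labels, class_a, class_b) {
  labels <- as.character(labels)
  if (!all(labels %in% c(class_a, class_b))) {
    stop("labels outside {", class_a, ", ", class_b, "}")
  }
  y <- as.numeric(labels == class_a)
  if (length(unique(y)) < 2) {
    stop("both classes must be present (got a single class)")
  }
  structure(list(y = y, class_a = class_a, class_b = class_b,
                 labels = labels),
            class = "class_coding")
}

# ---- PCA -----------------------------------------------------------------

#' Principal component analysis by NIPALS
#'
#' Sequentially extracts components by the NIPALS power iteration with
#' deflation.  Per-component explained variation R2X_k is the fraction of
#' the (preprocessed) matrix sum of squares captured by component k.
#'
#' @param X Samples x variables matrix.
#' @param n_components Number of components to extract.
#' @param center,scale Preprocessing (see [pareto_scale()]); `scale =
#'   "none"` skips scaling.
#' @param tol,max_iter NIPALS convergence controls.
#' @return A `pca_model` with `scores`, `loadings`, `R2X`.
#' @export
fit_pca <- function(X, n_components = 2, center = TRUE,
                    scale = c("none", "pareto", "uv"),
                    tol = 1e-13, max_iter = 2000) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  means <- if (center) colMeans(X) else rep(0, ncol(X))
  div <- rep(1, ncol(X))
  if (scale != "none") {
    sds <- apply(X, 2, stats::sd)
    div <- if (scale == "pareto") sqrt(sds) else sds
    div[sds <= .Machine$double.eps * 100] <- 1
  }
  sc_model <- structure(list(means = means, divisors = div,
                             constant = div == 1 & scale != "none",
                             method = scale),
                        class = "scaling_model")
  Xw <- apply_scaling(sc_model, X)
  max_rank <- min(nrow(Xw) - if (center) 1 else 0, ncol(Xw))
  if (n_components > max_rank) {
    warning("n_components truncated to matrix rank bound (", max_rank, ")")
    n_components <- max_rank
  }
  ss_total <- sum(Xw^2)
  scores <- matrix(0, nrow(Xw), n_components)
  loadings <- matrix(0, ncol(Xw), n_components)
  r2x <- numeric(n_components)
  E <- Xw
  for (k in seq_len(n_components)) {
    t_vec <- E[, which.max(colSums(E^2))]
    if (sum(t_vec^2) < tol) { # residual exhausted
      scores <- scores[, seq_len(k - 1), drop = FALSE]
      loadings <- loadings[, seq_len(k - 1), drop = FALSE]
      r2x <- r2x[seq_len(k - 1)]
      break
    }
    for (it in seq_len(max_iter)) {
      p <- crossprod(E, t_vec) / sum(t_vec^2)
      p <- p / sqrt(sum(p^2))
      t_new <- E %*% p
      if (sum((t_new - t_vec)^2) / max(sum(t_new^2), tol) < tol^2) {
        t_vec <- as.vector(t_new)
        break
      }
      t_vec <- as.vector(t_new)
    }
    scores[, k] <- t_vec
    loadings[, k] <- p
    r2x[k] <- sum(t_vec^2) / ss_total
    E <- E - tcrossprod(t_vec, p)
  }
  structure(list(scores = scores, loadings = loadings, R2X = r2x,
                 scaling = sc_model, center = center),
            class = "pca_model")
}

# ---- PLS1 (NIPALS) -------------------------------------------------------

# Core NIPALS PLS1 on preprocessed X and centered y.  For a single
# response NIPALS needs no inner iteration: w is proportional to X'y.
# Returns weights W, scores T, x-loadings P, y-loadings c per component.
pls1_nipals_core <- function(Xs, yc, ncomp) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); cvec <- numeric(ncomp)
  E <- Xs; f <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("X carries no covariance with y at component ", a)
    w <- w / nw
    t_vec <- as.vector(E %*% w)
    tt <- sum(t_vec^2)
    if (tt < 1e-12) stop("degenerate score vector at component ", a)
    p_vec <- as.vector(crossprod(E, t_vec)) / tt
    c_a <- sum(f * t_vec) / tt
    E <- E - tcrossprod(t_vec, p_vec)
    f <- f - c_a * t_vec
    W[, a] <- w; P[, a] <- p_vec; Tm[, a] <- t_vec; cvec[a] <- c_a
  }
  list(W = W, P = P, T = Tm, c = cvec)
}

#' One-block PLS1 discriminant model (NIPALS)
#'
#' Plain multi-component PLS regression of the 0/1 class dummy on X.
#' Mostly used as the reference against which the OPLS-DA single-response
#' equivalence is asserted, but usable as a classifier in its own right.
#'
#' @param X Samples x variables matrix.
#' @param coding A [class_coding()].
#' @param n_components Number of PLS components.
#' @param scale Column scaling method.
#' @return A `pls_model` with weights, scores, loadings, `R2Y`, `fitted`.
#' @export
fit_pls_da <- function(X, coding, n_components = 1,
                       scale = c("pareto", "uv", "center")) {
  scale <- match.arg(scale)
  stopifnot(inherits(coding, "class_coding"))
  X <- as.matrix(X)
  sc <- pareto_scale(X, method = scale)
  ybar <- mean(coding$y)
  yc <- coding$y - ybar
  fit <- pls1_nipals_core(sc$X, yc, n_components)
  fitted <- as.vector(fit$T %*% fit$c) + ybar
  r2y <- 1 - sum((coding$y - fitted)^2) / sum(yc^2)
  structure(list(weights = fit$W, scores = fit$T, loadings = fit$P,
                 y_loadings = fit$c, y_mean = ybar, fitted = fitted,
                 R2Y = r2y, scaling = sc$model, coding = coding),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  Xs <- apply_scaling(object$scaling, newdata)
  ncomp <- ncol(object$weights)
  t_all <- matrix(0, nrow(Xs), ncomp)
  E <- Xs
  for (a in seq_len(ncomp)) {
    t_all[, a] <- E %*% object$weights[, a]
    E <- E - tcrossprod(t_all[, a], object$loadings[, a])
  }
  as.vector(t_all %*% object$y_loadings) + object$y_mean
}

# ---- OPLS-DA -------------------------------------------------------------

#' Orthogonal PLS discriminant analysis
#'
#' Implements the single-response orthogonal projection to latent
#' structures: `n_ortho` components orthogonal to the class dummy are
#' stripped from X (Trygg-Wold orthogonal filtering), then exactly one
#' predictive PLS component is fitted on the filtered matrix, so all
#' between-class separation is forced into the first (predictive)
#' component and the orthogonal components express intra-class variability
#' only.  With `n_ortho = 0` the model coincides with one-component PLS-DA.
#'
#' @param X Samples x variables matrix (both classes need >= 2 samples).
#' @param coding A [class_coding()].
#' @param n_ortho Number of orthogonal components (>= 0).
#' @param scale Column scaling method (Pareto by default).
#' @return An `opls_model`: predictive weights/scores/loadings
#'   (`w`, `t`, `p`) and y-loading `c`; orthogonal `W_o`, `T_o`, `P_o`;
#'   `R2Y`, `R2X`, `fitted`, the scaling model and the class coding.
#' @export
fit_opls_da <- function(X, coding, n_ortho = 1,
                        scale = c("pareto", "uv", "center")) {
  scale <- match.arg(scale)
  stopifnot(inherits(coding, "class_coding"))
  if (n_ortho < 0) stop("`n_ortho` must be >= 0")
  X <- as.matrix(X)
  if (min(table(coding$y)) < 2) stop("both classes need at least 2 samples")
  sc <- pareto_scale(X, method = scale)
  Xs <- sc$X
  ybar <- mean(coding$y)
  yc <- coding$y - ybar
  n <- nrow(Xs); p <- ncol(Xs)
  if (n_ortho > min(n - 1, p) - 1) {
    stop("`n_ortho` too large for the data rank")
  }
  W_o <- matrix(0, p, n_ortho); P_o <- matrix(0, p, n_ortho)
  T_o <- matrix(0, n, n_ortho)
  E <- Xs
  for (j in seq_len(n_ortho)) {
    w <- crossprod(E, yc)
    w <- w / sqrt(sum(w^2))
    t_vec <- as.vector(E %*% w)
    p_vec <- as.vector(crossprod(E, t_vec)) / sum(t_vec^2)
    w_o <- p_vec - as.vector(crossprod(w, p_vec)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-10) {
      stop("no orthogonal variation left at component ", j,
           "; reduce `n_ortho`")
    }
    w_o <- w_o / nw
    t_o <- as.vector(E %*% w_o)
    p_o <- as.vector(crossprod(E, t_o)) / sum(t_o^2)
    W_o[, j] <- w_o; P_o[, j] <- p_o; T_o[, j] <- t_o
    E <- E - tcrossprod(t_o, p_o)
  }
  # single predictive component on the orthogonal-filtered matrix
  w <- crossprod(E, yc)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("X carries no covariance with y")
  w <- as.vector(w / nw)
  t_vec <- as.vector(E %*% w)
  tt <- sum(t_vec^2)
  p_vec <- as.vector(crossprod(E, t_vec)) / tt
  c_load <- sum(yc * t_vec) / tt
  fitted <- t_vec * c_load + ybar
  r2y <- 1 - sum((coding$y - fitted)^2) / sum(yc^2)
  ssx <- sum(Xs^2)
  r2x <- (tt + if (n_ortho) sum(T_o^2) else 0) / ssx
  structure(
    list(w = w, t = t_vec, p = p_vec, c = c_load,
         W_o = W_o, T_o = T_o, P_o = P_o, n_ortho = n_ortho,
         y_mean = ybar, fitted = fitted, R2Y = r2y, R2X = r2x,
         R2X_pred = tt / ssx,
         scaling = sc$model, coding = coding, X_scaled = Xs),
    class = "opls_model"
  )
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA model %s (1) vs %s (0): 1 predictive + %d orthogonal\n",
    x$coding$class_a, x$coding$class_b, x$n_ortho))
  cat(sprintf("  R2Y = %.3f, R2X = %.3f\n", x$R2Y, x$R2X))
  invisible(x)
}

#' Predict class-membership values from an OPLS-DA model
#'
#' New samples are scaled with the stored scaling model, their orthogonal
#' variation removed with the stored orthogonal weights/loadings, and the
#' predictive score projected back to the 0/1 dummy scale.  Values are not
#' clipped: membership thresholding is the evaluation layer's job.
#'
#' @param object An `opls_model`.
#' @param newdata Matrix with the model's variable count.
#' @param ... Unused.
#' @return Numeric vector of continuous membership predictions
#'   (1 = `class_a`, 0 = `class_b`).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xs <- apply_scaling(object$scaling, newdata)
  if (object$n_ortho > 0) {
    for (j in seq_len(object$n_ortho)) {
      t_o <- Xs %*% object$W_o[, j]
      Xs <- Xs - tcrossprod(t_o, object$P_o[, j])
    }
  }
  t_vec <- as.vector(Xs %*% object$w)
  t_vec * object$c + object$y_mean
}

# ---- cross-validation ----------------------------------------------------

# Deterministic stratified fold assignment: within each class the samples
# are shuffled by the seed, then dealt round-robin so every fold contains
# both classes whenever n_folds <= min class size.
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validated classification power Q2Y
#'
#' Stratified k-fold cross-validation of an OPLS-DA model: folds are built
#' so that samples of both classes are present in every fold, the full
#' model (scaling included) is refitted on each training split, and
#' out-of-fold membership predictions give
#' `Q2Y = 1 - PRESS / TSS`, the cross-validated analogue of R2Y.
#'
#' @param X Samples x variables matrix.
#' @param coding A [class_coding()].
#' @param n_ortho Orthogonal component count for each refit.
#' @param n_folds Number of folds (default 7); reduced with a warning when
#'   a class has fewer samples than folds.
#' @param seed Integer seed for fold assignment.
#' @param scale Column scaling method.
#' @return A `validation_report`: `Q2Y`, `fold_assignments`, `predictions`
#'   (out-of-fold, in input order), `n_folds`.
#' @export
cross_validate <- function(X, coding, n_ortho = 1, n_folds = 7, seed = 1,
                           scale = "pareto") {
  stopifnot(inherits(coding, "class_coding"))
  X <- as.matrix(X)
  if (n_folds < 2) stop("`n_folds` must be >= 2")
  min_class <- min(table(coding$y))
  if (min_class < 2) stop("both classes need at least 2 samples")
  if (n_folds > min_class) {
    n_folds <- min_class
    warning("n_folds reduced to ", n_folds,
            " so every fold contains both classes")
  }
  fold <- stratified_folds(coding$y, n_folds, seed)
  pred <- numeric(length(coding$y))
  for (k in seq_len(n_folds)) {
    test <- fold == k
    cod_tr <- class_coding(coding$labels[!test],
                           coding$class_a, coding$class_b)
    fit <- fit_opls_da(X[!test, , drop = FALSE], cod_tr,
                       n_ortho = n_ortho, scale = scale)
    pred[test] <- predict(fit, X[test, , drop = FALSE])
  }
  tss <- sum((coding$y - mean(coding$y))^2)
  q2 <- 1 - sum((coding$y - pred)^2) / tss
  structure(list(Q2Y = q2, fold_assignments = fold, predictions = pred,
                 n_folds = n_folds, seed = seed),
            class = "validation_report")
}

# ---- permutation test ----------------------------------------------------

#' Label-permutation test for an OPLS-DA model
#'
#' Refits the model under randomly permuted class labels `n_perm` times
#' (the identity permutation is excluded) and records, per permutation, the
#' correlation of the permuted dummy with the original, R2Y and
#' cross-validated Q2Y.  The Q2 p-value uses the add-one estimator
#' `p = (1 + #{Q2_perm >= Q2_obs}) / (n_perm + 1)`, which can never be 0.
#'
#' @inheritParams cross_validate
#' @param n_perm Number of permutations (the study checked n = 400).
#' @param n_folds Folds for the per-permutation Q2Y.
#' @return A `permutation_report`: data frame `permutations`
#'   (`label_correlation`, `R2Y`, `Q2Y`), observed `R2Y_obs`/`Q2Y_obs`,
#'   `p_value_Q2`, `p_value_R2`.
#' @export
permutation_test <- function(X, coding, n_ortho = 1, n_perm = 400,
                             n_folds = 7, seed = 1, scale = "pareto") {
  stopifnot(inherits(coding, "class_coding"))
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  X <- as.matrix(X)
  obs_fit <- fit_opls_da(X, coding, n_ortho = n_ortho, scale = scale)
  obs_cv <- cross_validate(X, coding, n_ortho = n_ortho, n_folds = n_folds,
                           seed = child_seed(seed, 0), scale = scale)
  y <- coding$y
  res <- matrix(NA_real_, n_perm, 3,
                dimnames = list(NULL, c("label_correlation", "R2Y", "Q2Y")))
  with_seed(child_seed(seed, 1), {
    for (b in seq_len(n_perm)) {
      repeat {
        yp <- sample(y)
        if (!all(yp == y)) break # identity permutation excluded
      }
      labp <- ifelse(yp == 1, coding$class_a, coding$class_b)
      codp <- class_coding(labp, coding$class_a, coding$class_b)
      fitp <- fit_opls_da(X, codp, n_ortho = n_ortho, scale = scale)
      cvp <- cross_validate(X, codp, n_ortho = n_ortho, n_folds = n_folds,
                            seed = child_seed(seed, b + 1), scale = scale)
      res[b, ] <- c(stats::cor(yp, y), fitp$R2Y, cvp$Q2Y)
    }
  })
  structure(
    list(permutations = as.data.frame(res),
         R2Y_obs = obs_fit$R2Y, Q2Y_obs = obs_cv$Q2Y,
         p_value_Q2 = (1 + sum(res[, "Q2Y"] >= obs_cv$Q2Y)) / (n_perm + 1),
         p_value_R2 = (1 + sum(res[, "R2Y"] >= obs_fit$R2Y)) / (n_perm + 1),
         n_perm = n_perm, seed = seed),
    class = "permutation_report"
  )
}

# ---- model-size selection ------------------------------------------------

#' Choose the orthogonal component count by cross-validation
#'
#' Q2Y does not automatically increase with additional components — past
#' the useful rank, extra components only add noise.  This scans
#' `0..max_ortho` and returns the smallest count whose Q2Y is within `tol`
#' of the maximum.
#'
#' @inheritParams cross_validate
#' @param max_ortho Largest orthogonal count to consider.
#' @param tol Q2Y tolerance for preferring a smaller model (default 0.01).
#' @return Integer count.
#' @export
select_n_ortho <- function(X, coding, max_ortho = 3, n_folds = 7, seed = 1,
                           tol = 0.01, scale = "pareto") {
  if (max_ortho < 0) stop("`max_ortho` must be >= 0")
  q2 <- rep(-Inf, max_ortho + 1)
  for (k in 0:max_ortho) {
    cv <- tryCatch(
      suppressWarnings(cross_validate(X, coding, n_ortho = k,
                                      n_folds = n_folds, seed = seed,
                                      scale = scale)),
      error = function(e) NULL)
    if (is.null(cv)) break # rank exhausted
    q2[k + 1] <- cv$Q2Y
  }
  which(q2 >= max(q2) - tol)[1] - 1L
}

# ---- loadings diagnostics ------------------------------------------------

#' Covariance/correlation loadings for biomarker ranking
#'
#' For each variable, `magnitude` is the covariance of its (scaled) values
#' with the predictive score and `reliability` the corresponding
#' correlation — high reliability flags a variable whose association with
#' the predictive component is strong relative to its own spread, which can
#' surface small but consistent signals that covariance alone (under Pareto
#' scaling) would not highlight.  Positive values point toward the class
#' coded 1 (`class_a`).
#'
#' @param model A fitted `opls_model`.
#' @return A `loadings_report` data frame: `variable`, `magnitude`,
#'   `reliability`, `zero_variance` flag.
#' @export
loadings_report <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  Xs <- model$X_scaled
  t_vec <- model$t
  n <- nrow(Xs)
  magnitude <- as.vector(crossprod(Xs, t_vec - mean(t_vec))) / (n - 1)
  sx <- apply(Xs, 2, stats::sd)
  st <- stats::sd(t_vec)
  zero_var <- sx <= .Machine$double.eps * 100
  reliability <- ifelse(zero_var, 0, magnitude / (sx * st))
  reliability <- pmin(1, pmax(-1, reliability))
  out <- data.frame(
    variable = colnames(Xs) %||% paste0("V", seq_len(ncol(Xs))),
    magnitude = magnitude, reliability = reliability,
    zero_variance = zero_var, row.names = NULL)
  class(out) <- c("loadings_report", class(out))
  out
}
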