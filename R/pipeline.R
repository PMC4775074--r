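# Orchestration of the four pairwise discriminant models:
# Pain vs C, NP vs C, NC vs C and NP vs NC.  Each model optionally excludes
# the mannitol excipient window, re-normalizes, fits OPLS-DA with a
# cross-validation-chosen orthogonal count, validates by permutation,
# thresholds the cross-validated membership predictions and reports the
# contingency-table diagnostics.

#' Specify one pairwise discriminant model
#'
#' The four canonical models are: `pain_vs_c` (NP and NC merged into a
#' "pain" class vs all controls), `np_vs_c` (NP vs its matched controls),
#' `nc_vs_c` (NC vs its matched controls) and `np_vs_nc`.  Matched-control
#' subsets are taken from the `C-NP`/`C-NC` tags carried by the data; when
#' a tagged subset is absent, all controls are used (with a message), since
#' matching covariates are not part of the spectral matrix.
#'
#' @param name One of `"pain_vs_c"`, `"np_vs_c"`, `"nc_vs_c"`, `"np_vs_nc"`.
#' @param exclude_mannitol Drop the 3.62-3.90 ppm excipient window (and
#'   re-normalize) before fitting.  Default `TRUE`: the excipient tracks
#'   drug treatment, not biology.
#' @param renormalize Re-normalize rows after the exclusion.
#' @param n_ortho `"auto"` (cross-validation choice via [select_n_ortho()])
#'   or a fixed count.
#' @param max_ortho Search bound for the automatic choice.
#' @param n_folds,n_perm,seed Validation settings.
#' @return A `model_spec`.
#' @export
model_spec <- function(name = c("pain_vs_c", "np_vs_c", "nc_vs_c",
                                "np_vs_nc"),
                       exclude_mannitol = TRUE, renormalize = TRUE,
                       n_ortho = "auto", max_ortho = 2, n_folds = 7,
                       n_perm = 400, seed = 1) {
  name <- match.arg(name)
  structure(list(name = name, exclude_mannitol = exclude_mannitol,
                 renormalize = renormalize, n_ortho = n_ortho,
                 max_ortho = max_ortho, n_folds = n_folds, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "model_spec")
}

mannitol_window <- function() c(3.62, 3.90)

#' Select the samples and class coding for a pairwise model
#'
#' @param matrix A `binned_matrix`.
#' @param spec A [model_spec()].
#' @return List with `X` (the selected value rows), `coding`
#'   (a [class_coding()]) and `sample_ids`.
#' @export
select_samples <- function(matrix, spec) {
  stopifnot(inherits(matrix, "binned_matrix"), inherits(spec, "model_spec"))
  lab <- as.character(matrix$labels)
  tag <- matrix$control_tag
  need <- function(cls) {
    if (!any(lab == cls)) stop("no samples with label ", cls)
  }
  matched_controls <- function(which_tag) {
    idx <- which(lab == "C" & !is.na(tag) & tag == which_tag)
    if (!length(idx)) {
      need("C")
      message("no ", which_tag, "-tagged controls; using all C samples")
      idx <- which(lab == "C")
    }
    idx
  }
  sel <- switch(spec$name,
    pain_vs_c = {
      need("NP"); need("NC"); need("C")
      idx <- which(lab %in% c("NP", "NC", "C"))
      list(idx = idx, cls = ifelse(lab[idx] == "C", "C", "pain"),
           a = "pain", b = "C")
    },
    np_vs_c = {
      need("NP")
      idx <- c(which(lab == "NP"), matched_controls("C-NP"))
      list(idx = idx, cls = lab[idx], a = "NP", b = "C")
    },
    nc_vs_c = {
      need("NC")
      idx <- c(which(lab == "NC"), matched_controls("C-NC"))
      list(idx = idx, cls = lab[idx], a = "NC", b = "C")
    },
    np_vs_nc = {
      need("NP"); need("NC")
      idx <- which(lab %in% c("NP", "NC"))
      list(idx = idx, cls = lab[idx], a = "NP", b = "NC")
    })
  list(X = matrix$values[sel$idx, , drop = FALSE],
       coding = class_coding(sel$cls, sel$a, sel$b),
       sample_ids = matrix$sample_ids[sel$idx])
}

#' Run one pairwise discriminant model end to end
#'
#' Applies the configured exclusion and re-normalization, selects samples,
#' chooses the orthogonal component count (when `n_ortho = "auto"`), fits
#' the OPLS-DA model, cross-validates, runs the permutation test, and
#' evaluates the model's membership predictions of the samples through the
#' borderline-aware contingency table (out-of-fold predictions are kept in
#' `cv_predictions` for a stricter reading).  Fully deterministic given the
#' seed.
#'
#' @param matrix A `binned_matrix` (normalized).
#' @param spec A [model_spec()].
#' @param thresholds A [threshold_config()].
#' @return A `model_report`: the fitted `model`, `cv`, `permutation`,
#'   `contingency`, `metrics`, `loadings`, per-class sample counts.
#' @export
run_model <- function(matrix, spec, thresholds = threshold_config()) {
  m <- matrix
  if (spec$exclude_mannitol) {
    w <- mannitol_window()
    covered <- any(m$bin_edges[, 1] < w[2] & m$bin_edges[, 2] > w[1])
    if (covered) {
      m <- drop_region(m, w)
      if (spec$renormalize) m <- normalize_total_area(m)
    }
  }
  sel <- select_samples(m, spec)
  n_ortho <- spec$n_ortho
  if (identical(n_ortho, "auto")) {
    n_ortho <- select_n_ortho(sel$X, sel$coding, max_ortho = spec$max_ortho,
                              n_folds = spec$n_folds,
                              seed = child_seed(spec$seed, 11))
  }
  fit <- fit_opls_da(sel$X, sel$coding, n_ortho = n_ortho)
  cv <- suppressWarnings(
    cross_validate(sel$X, sel$coding, n_ortho = n_ortho,
                   n_folds = spec$n_folds, seed = child_seed(spec$seed, 12)))
  perm <- permutation_test(sel$X, sel$coding, n_ortho = n_ortho,
                           n_perm = spec$n_perm, n_folds = cv$n_folds,
                           seed = child_seed(spec$seed, 13))
  yhat <- predict(fit, sel$X)
  calls <- call_membership(yhat, thresholds)
  tab <- build_contingency(calls, sel$coding$y == 1, thresholds,
                           gold_standard = "clinical evaluation")
  metrics <- compute_metrics(tab)
  counts <- table(factor(sel$coding$labels,
                         levels = unique(sel$coding$labels)))
  structure(list(name = spec$name, spec = spec,
                 n_class_a = sum(sel$coding$y == 1),
                 n_class_b = sum(sel$coding$y == 0),
                 class_a = sel$coding$class_a, class_b = sel$coding$class_b,
                 n_ortho = n_ortho, model = fit, cv = cv, permutation = perm,
                 predictions = yhat, cv_predictions = cv$predictions,
                 calls = calls,
                 contingency = tab, metrics = metrics,
                 loadings = loadings_report(fit),
                 sample_ids = sel$sample_ids, counts = counts),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("%s: %s (n=%d) vs %s (n=%d), %d orthogonal component(s)\n",
              x$name, x$class_a, x$n_class_a, x$class_b, x$n_class_b,
              x$n_ortho))
  cat(sprintf("  R2Y %.2f  Q2Y %.2f  perm p(Q2) %.4g\n",
              x$model$R2Y, x$cv$Q2Y, x$permutation$p_value_Q2))
  cat(sprintf("  sens %.2f  spec %.2f  acc %.2f  Fisher p %.3g\n",
              x$metrics$sensitivity, x$metrics$specificity,
              x$metrics$accuracy, x$metrics$fisher_p))
  invisible(x)
}

#' Run all four pairwise models
#'
#' @param matrix A normalized `binned_matrix` carrying NP, NC and C labels.
#' @param exclude_mannitol,n_ortho,n_perm,n_folds,seed Settings applied to
#'   every model (per-model seeds are derived from `seed`).
#' @param thresholds A [threshold_config()].
#' @return A `run_report`: list of `model_report`s plus a summary
#'   data frame `table` (Model, n_NP, n_NC, n_C, R2Y, Q2Y, Sensitivity,
#'   Specificity, Accuracy, p).
#' @export
run_all <- function(matrix, exclude_mannitol = TRUE, n_ortho = "auto",
                    n_perm = 400, n_folds = 7, seed = 1,
                    thresholds = threshold_config()) {
  stopifnot(inherits(matrix, "binned_matrix"))
  if (nrow(matrix$values) == 0) stop("empty matrix")
  names4 <- c("pain_vs_c", "np_vs_c", "nc_vs_c", "np_vs_nc")
  reports <- list()
  failures <- character()
  for (i in seq_along(names4)) {
    spec <- model_spec(names4[i], exclude_mannitol = exclude_mannitol,
                       n_ortho = n_ortho, n_perm = n_perm,
                       n_folds = n_folds, seed = child_seed(seed, i))
    rep_i <- tryCatch(run_model(matrix, spec, thresholds),
                      error = function(e) {
                        failures <<- c(failures,
                                       paste0(names4[i], ": ",
                                              conditionMessage(e)))
                        NULL
                      })
    if (!is.null(rep_i)) reports[[names4[i]]] <- rep_i
  }
  lab <- as.character(matrix$labels)
  count_of <- function(r, cls) {
    switch(paste(r$name, cls),
      "pain_vs_c NP" = sum(lab == "NP"),
      "pain_vs_c NC" = sum(lab == "NC"),
      "pain_vs_c C" = r$n_class_b,
      "np_vs_c NP" = r$n_class_a,
      "np_vs_c C" = r$n_class_b,
      "nc_vs_c NC" = r$n_class_a,
      "nc_vs_c C" = r$n_class_b,
      "np_vs_nc NP" = r$n_class_a,
      "np_vs_nc NC" = r$n_class_b,
      NA_integer_)
  }
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(Model = r$name,
               n_NP = count_of(r, "NP"), n_NC = count_of(r, "NC"),
               n_C = count_of(r, "C"),
               R2Y = r$model$R2Y, Q2Y = r$cv$Q2Y,
               Sensitivity = r$metrics$sensitivity,
               Specificity = r$metrics$specificity,
               Accuracy = r$metrics$accuracy,
               p = r$metrics$fisher_p, row.names = NULL)
  }))
  structure(list(models = reports, table = tab, failures = failures,
                 seed = seed),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  df <- x$table
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 3))
  print(df, row.names = FALSE)
  if (length(x$failures)) cat("failed:", x$failures, sep = "\n  ")
  invisible(x)
}

#' Rank discriminant variables of a fitted model
#'
#' Sorts the model's buckets by absolute loading magnitude (covariance
#' with the predictive score) and annotates each with its reliability
#' (correlation), its direction (toward the class coded 1 or the class
#' coded 0) and, when an annotation map is given, the metabolites whose
#' peaks fall in the bucket.
#'
#' @param report A `model_report` (or `opls_model`).
#' @param annotation Optional named list mapping metabolite name to a
#'   vector of peak positions (ppm), e.g. from
#'   [library_annotation()].
#' @param top Number of rows to return (default all).
#' @return Data frame: `variable`, `low`, `high`, `magnitude`,
#'   `reliability`, `direction`, `metabolites`.
#' @export
rank_discriminants <- function(report, annotation = NULL, top = Inf) {
  if (inherits(report, "model_report")) {
    ld <- report$loadings
    class_a <- report$class_a; class_b <- report$class_b
  } else {
    ld <- loadings_report(report)
    class_a <- report$coding$class_a; class_b <- report$coding$class_b
  }
  parts <- do.call(rbind, strsplit(sub("^ppm_", "", ld$variable), "_"))
  lo <- suppressWarnings(as.numeric(parts[, 1]))
  hi <- suppressWarnings(as.numeric(parts[, 2]))
  met <- rep("", nrow(ld))
  if (!is.null(annotation) && !anyNA(lo)) {
    met <- vapply(seq_len(nrow(ld)), function(i) {
      hits <- names(annotation)[vapply(annotation, function(pos) {
        any(pos >= lo[i] & pos < hi[i])
      }, logical(1))]
      paste(hits, collapse = ";")
    }, character(1))
  }
  out <- data.frame(variable = ld$variable, low = lo, high = hi,
                    magnitude = ld$magnitude, reliability = ld$reliability,
                    direction = ifelse(ld$magnitude >= 0, class_a, class_b),
                    metabolites = met, row.names = NULL)
  out <- out[order(-abs(out$magnitude)), ]
  utils::head(out, top)
}

#' Peak-position annotation from a metabolite library
#'
#' @param library A metabolite library, as from
#'   [default_metabolite_library()].
#' @return Named list of peak-center vectors (ppm), for
#'   [rank_discriminants()].
#' @export
library_annotation <- function(library = default_metabolite_library()) {
  lapply(library, function(sp) sp$peaks$center)
}
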