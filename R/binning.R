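# Spectral bucketing and the analysis-ready binned matrix.
#
# Spectra are reduced to consecutive fixed-width buckets (0.04 ppm over
# 0.5-9.5 ppm by default), the water/urea window 4.50-6.50 ppm is excluded,
# and each sample's bucket areas are normalized to a constant total (100) to
# remove dilution differences between urine samples.

#' Construct a spectrum
#'
#' @param ppm Strictly monotone chemical-shift axis (ppm).
#' @param intensity Intensities, same length as `ppm`, finite.
#' @return An object of class `spectrum`.
#' @export
new_spectrum <- function(ppm, intensity) {
  if (length(ppm) != length(intensity)) {
    stop("`ppm` and `intensity` must have equal length")
  }
  d <- diff(ppm)
  if (length(ppm) < 2 || !(all(d > 0) || all(d < 0))) {
    stop("`ppm` must be strictly monotone")
  }
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  if (d[1] < 0) { # store ascending
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity)),
            class = "spectrum")
}

#' Binning configuration
#'
#' @param width Bucket width in ppm (default 0.04).
#' @param range Two-element numeric, low and high limits in ppm
#'   (default 0.5-9.5); must span an integer number of buckets.
#' @param exclusions List of `c(low, high)` ppm windows whose buckets are
#'   dropped whole; defaults to the water/urea region 4.50-6.50 ppm.
#' @param normalization_target Row total after normalization (default 100).
#' @return An object of class `binning_config`.
#' @export
binning_config <- function(width = 0.04, range = c(0.5, 9.5),
                           exclusions = list(c(4.50, 6.50)),
                           normalization_target = 100) {
  if (width <= 0) stop("`width` must be > 0")
  if (range[1] >= range[2]) stop("range low must be < high")
  for (w in exclusions) {
    if (w[1] >= w[2]) stop("exclusion window low must be < high")
    if (w[1] < range[1] || w[2] > range[2]) {
      stop("exclusion windows must lie within the binning range")
    }
  }
  structure(list(width = width, range = as.numeric(range),
                 exclusions = exclusions,
                 normalization_target = normalization_target),
            class = "binning_config")
}

#' Compute bucket edges
#'
#' Buckets are left-closed/right-open `[low + k w, low + (k+1) w)` (the last
#' bucket right-closed); any bucket overlapping an exclusion window is
#' removed whole.  With the defaults this yields 225 buckets for 0.5-9.5 ppm
#' at 0.04 ppm, 175 after excluding 4.50-6.50 ppm, and 168 after further
#' excluding the mannitol window 3.62-3.90 ppm.
#'
#' @param config A [binning_config()].
#' @return Two-column matrix of bucket edges (`low`, `high`).
#' @export
make_bin_edges <- function(config = binning_config()) {
  stopifnot(inherits(config, "binning_config"))
  span <- config$range[2] - config$range[1]
  n <- span / config$width
  if (abs(n - round(n)) > 1e-9) {
    stop("binning range is not an integer multiple of the bucket width")
  }
  n <- round(n)
  lo <- config$range[1] + (seq_len(n) - 1) * config$width
  hi <- lo + config$width
  keep <- rep(TRUE, n)
  for (w in config$exclusions) {
    keep <- keep & !(lo < w[2] & hi > w[1]) # open-interval overlap
  }
  cbind(low = lo[keep], high = hi[keep])
}

#' Integrate a spectrum over buckets
#'
#' Each bucket value is the trapezoidal integral of intensity over the
#' bucket's ppm window (edge values interpolated linearly); negative totals
#' are floored at 0.  Integration is implemented as a precomputable linear
#' map from axis intensities to bucket areas, so binning a whole cohort is a
#' single matrix product.
#'
#' @param s A `spectrum`.
#' @param edges Edge matrix from [make_bin_edges()].
#' @param weights Optional weight matrix from [bin_weights()] for `s$ppm`
#'   and `edges` (computed if omitted).
#' @return Numeric vector of bucket areas, named by bucket window.
#' @export
bin_spectrum <- function(s, edges, weights = NULL) {
  stopifnot(inherits(s, "spectrum"))
  if (is.null(weights)) weights <- bin_weights(s$ppm, edges)
  areas <- as.vector(crossprod(weights, s$intensity))
  areas[areas < 0] <- 0
  names(areas) <- format_bin_names(edges)
  areas
}

format_bin_names <- function(edges) {
  sprintf("ppm_%.2f_%.2f", edges[, 1], edges[, 2])
}

#' Trapezoidal integration weights for a set of buckets
#'
#' Returns the matrix `W` (axis points x buckets) such that `t(W) %*% y`
#' is the trapezoidal integral of the linear interpolant of `(ppm, y)` over
#' each bucket window.
#'
#' @param ppm Strictly increasing axis.
#' @param edges Two-column edge matrix.
#' @return Numeric matrix, `length(ppm)` rows by `nrow(edges)` columns.
#' @export
bin_weights <- function(ppm, edges) {
  if (min(edges) < min(ppm) - 1e-12 || max(edges) > max(ppm) + 1e-12) {
    stop("spectrum axis does not cover the binning range")
  }
  n <- length(ppm)
  W <- matrix(0, nrow = n, ncol = nrow(edges))
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    i0 <- max(1L, findInterval(a, ppm))
    i1 <- min(n - 1L, findInterval(b, ppm, left.open = TRUE))
    for (i in i0:i1) {
      xl <- ppm[i]; xr <- ppm[i + 1]; h <- xr - xl
      l <- max(a, xl); r <- min(b, xr)
      if (r <= l) next
      # integral of the linear interpolant over [l, r], split into the
      # coefficients of y_i and y_{i+1}
      W[i, k] <- W[i, k] + ((xr - l)^2 - (xr - r)^2) / (2 * h)
      W[i + 1, k] <- W[i + 1, k] + ((r - xl)^2 - (l - xl)^2) / (2 * h)
    }
  }
  W
}

#' Construct a binned data matrix
#'
#' @param values Samples x buckets numeric matrix of areas (>= 0).
#' @param sample_ids Unique sample identifiers.
#' @param labels Class labels, each one of `NP`, `NC`, `C`.
#' @param bin_edges Two-column edge matrix matching the columns of `values`.
#' @param control_tag Optional matched-control tags (`C-NP`, `C-NC` or NA).
#' @return An object of class `binned_matrix`.
#' @export
binned_matrix <- function(values, sample_ids, labels, bin_edges,
                          control_tag = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(sample_ids) || nrow(values) != length(labels)) {
    stop("row count, sample_ids and labels must agree")
  }
  if (ncol(values) != nrow(bin_edges)) {
    stop("column count must equal the number of bucket edges")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1])
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("NP", "NC", "C"))
  if (length(bad)) stop("unknown label token: ", paste(bad, collapse = ", "))
  if (is.null(control_tag)) control_tag <- rep(NA_character_, length(labels))
  rownames(values) <- sample_ids
  colnames(values) <- format_bin_names(bin_edges)
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         labels = factor(labels, levels = c("NP", "NC", "C")),
         bin_edges = bin_edges, control_tag = as.character(control_tag)),
    class = "binned_matrix"
  )
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat("Binned NMR matrix:", nrow(x$values), "samples x", ncol(x$values),
      "buckets [", min(x$bin_edges), "-", max(x$bin_edges), "ppm ]\n")
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.binned_matrix <- function(x) dim(x$values)

#' Bin a whole cohort of spectra
#'
#' Applies [bin_spectrum()] to every spectrum of a labeled set and, by
#' default, normalizes each sample's bucket areas to the configured total.
#'
#' @param set A `labeled_spectrum_set`.
#' @param config A [binning_config()].
#' @param normalize Normalize rows to `config$normalization_target`?
#' @return A `binned_matrix`.
#' @export
bin_cohort <- function(set, config = binning_config(), normalize = TRUE) {
  stopifnot(inherits(set, "labeled_spectrum_set"))
  edges <- make_bin_edges(config)
  W <- bin_weights(set$spectra[[1]]$ppm, edges)
  vals <- t(vapply(set$spectra, bin_spectrum, numeric(nrow(edges)),
                   edges = edges, weights = W))
  m <- binned_matrix(vals, set$sample_ids, set$labels, edges,
                     control_tag = set$control_tag)
  if (normalize) m <- normalize_total_area(m, config$normalization_target)
  m
}

#' Total-area normalization
#'
#' Rescales each sample (row) so its bucket areas sum to `target`,
#' removing between-sample dilution differences.  Idempotent.
#'
#' @param matrix A `binned_matrix`.
#' @param target Row total after scaling (default 100).
#' @return The normalized `binned_matrix`.
#' @export
normalize_total_area <- function(matrix, target = 100) {
  stopifnot(inherits(matrix, "binned_matrix"))
  rs <- rowSums(matrix$values)
  if (any(rs <= 0)) {
    stop("zero total area for sample: ",
         paste(matrix$sample_ids[rs <= 0], collapse = ", "))
  }
  matrix$values <- matrix$values * (target / rs)
  matrix
}

#' Drop a spectral region from a binned matrix
#'
#' Removes every bucket whose `[low, high)` interval intersects `window`
#' (used for the mannitol excipient region 3.62-3.90 ppm).  Values of the
#' remaining buckets are untouched; re-normalization is a separate call.
#'
#' @param matrix A `binned_matrix`.
#' @param window `c(low, high)` in ppm.
#' @return A `binned_matrix` with the overlapping buckets removed.
#' @export
drop_region <- function(matrix, window) {
  stopifnot(inherits(matrix, "binned_matrix"))
  lo <- matrix$bin_edges[, 1]; hi <- matrix$bin_edges[, 2]
  hit <- lo < window[2] & hi > window[1]
  if (!any(hit)) {
    warning(sprintf("window [%g, %g] overlaps no bucket; matrix unchanged",
                    window[1], window[2]))
    return(matrix)
  }
  if (all(hit)) stop("window removes every bucket")
  matrix$values <- matrix$values[, !hit, drop = FALSE]
  matrix$bin_edges <- matrix$bin_edges[!hit, , drop = FALSE]
  matrix
}

#' Read / write binned matrices as delimited text or spreadsheet
#'
#' The on-disk layout is one row per sample: an id column, a class column
#' (tokens `NP`, `NC`, `C`, `C-NP`, `C-NC`; the matched-control tags map to
#' class `C` with the tag preserved) and one numeric column per bucket named
#' `ppm_<low>_<high>`.  `read_matrix` accepts `.csv`, `.tsv`/`.txt` and —
#' when the readxl package is installed — `.xlsx`.
#'
#' @param path File path.
#' @param id_col,label_col Names of the id and class columns.
#' @param sep Field separator for `write_matrix` (comma or tab).
#' @param matrix A `binned_matrix` (for `write_matrix`).
#' @return `read_matrix` returns a `binned_matrix`; `write_matrix` returns
#'   `path` invisibly.
#' @export
read_matrix <- function(path, id_col = "sample_id", label_col = "class") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, check.names = FALSE),
    tsv = ,
    txt = utils::read.delim(path, check.names = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading .xlsx requires the readxl package")
      }
      as.data.frame(readxl::read_excel(path), check.names = FALSE)
    },
    stop("unsupported file extension: ", ext)
  )
  if (!all(c(id_col, label_col) %in% names(df))) {
    stop("missing id or label column (", id_col, ", ", label_col, ")")
  }
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample id: ", ids[duplicated(ids)][1])
  }
  raw_lab <- as.character(df[[label_col]])
  bad <- setdiff(unique(raw_lab), c("NP", "NC", "C", "C-NP", "C-NC"))
  if (length(bad)) stop("unknown label token: ", paste(bad, collapse = ", "))
  tag <- ifelse(raw_lab %in% c("C-NP", "C-NC"), raw_lab, NA_character_)
  lab <- ifelse(raw_lab %in% c("C-NP", "C-NC"), "C", raw_lab)
  bin_cols <- grep("^ppm_", names(df), value = TRUE)
  if (!length(bin_cols)) stop("no bucket columns (ppm_<low>_<high>) found")
  vals <- as.matrix(df[bin_cols])
  if (!is.numeric(vals) || anyNA(vals)) {
    stop("non-numeric bucket value in file: ", path)
  }
  parts <- do.call(rbind, strsplit(sub("^ppm_", "", bin_cols), "_"))
  edges <- cbind(low = as.numeric(parts[, 1]), high = as.numeric(parts[, 2]))
  binned_matrix(vals, ids, lab, edges, control_tag = tag)
}

#' @rdname read_matrix
#' @export
write_matrix <- function(matrix, path, sep = ",") {
  stopifnot(inherits(matrix, "binned_matrix"))
  lab <- as.character(matrix$labels)
  lab <- ifelse(!is.na(matrix$control_tag), matrix$control_tag, lab)
  # %.17g keeps the text round-trip exact for doubles
  chr <- apply(matrix$values, 2, function(v) sprintf("%.17g", v))
  chr <- matrix(chr, nrow = nrow(matrix$values),
                dimnames = dimnames(matrix$values))
  df <- data.frame(sample_id = matrix$sample_ids, class = lab,
                   chr, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
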