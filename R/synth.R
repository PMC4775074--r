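# Synthetic urinary 1H-NMR spectra and cohorts.
#
# The simulator renders Lorentzian lineshapes on a dense ppm axis for a small
# library of urinary metabolites, applies per-sample log-normal dilution and
# additive Gaussian noise, and labels samples NP (neuropathic pain),
# NC (nociceptive pain) or C (control).  It exists so that every downstream
# stage (binning, OPLS-DA, validation, evaluation) can be exercised on data
# with known ground truth.

#' Describe a metabolite by its NMR peaks
#'
#' A metabolite spec holds the chemical shifts and relative heights of the
#' resonances a compound contributes to a urine spectrum, together with a
#' population mean level (`base_level`, arbitrary concentration scale) and a
#' between-subject coefficient of variation (`cv`).
#'
#' @param name Metabolite name.
#' @param peaks Data frame (or matrix coercible to one) with columns
#'   `center` (ppm), `relative_height` (>= 0) and `half_width`
#'   (half width at half maximum, ppm, > 0).
#' @param base_level Mean population intensity scale, >= 0.
#' @param cv Between-subject coefficient of variation, >= 0.
#' @return An object of class `metabolite_spec`.
#' @examples
#' ala <- metabolite_spec("alanine",
#'   data.frame(center = c(1.46, 1.49), relative_height = 1, half_width = 0.006),
#'   base_level = 1, cv = 0.2)
#' @export
metabolite_spec <- function(name, peaks, base_level = 1, cv = 0.2) {
  peaks <- as.data.frame(peaks)
  req <- c("center", "relative_height", "half_width")
  if (!all(req %in% names(peaks))) {
    stop("`peaks` needs columns center, relative_height, half_width")
  }
  if (any(peaks$center < 0 | peaks$center > 10)) {
    stop(sprintf("%s: peak centers must lie in [0, 10] ppm", name))
  }
  if (any(peaks$half_width <= 0)) stop(sprintf("%s: half_width must be > 0", name))
  if (any(peaks$relative_height < 0)) {
    stop(sprintf("%s: relative_height must be >= 0", name))
  }
  if (base_level < 0) stop(sprintf("%s: base_level must be >= 0", name))
  if (cv < 0) stop(sprintf("%s: cv must be >= 0", name))
  structure(
    list(name = name, peaks = peaks[req], base_level = base_level, cv = cv),
    class = "metabolite_spec"
  )
}

#' Default urinary metabolite library
#'
#' Chemical shifts follow standard urine assignment tables: choline
#' (N-trimethyl singlet at 3.20 ppm), phosphocholine (3.22 ppm), taurine
#' (triplets at 3.25 and 3.42 ppm), alanine (doublet at 1.48 ppm), citrate
#' (AB system at 2.54/2.66 ppm), creatinine (3.05 and 4.05 ppm), plus common
#' background signals (creatine, hippurate, glycine, lactate, dimethylamine,
#' trimethylamine N-oxide) and the drug excipient mannitol, whose multiplet
#' lies wholly inside the 3.62-3.90 ppm window.  No default peak falls inside
#' the water/urea exclusion window (4.50-6.50 ppm).
#'
#' @param half_width Default Lorentzian half width at half maximum (ppm).
#' @return Named list of [metabolite_spec()] objects.
#' @export
default_metabolite_library <- function(half_width = 0.006) {
  pk <- function(centers, heights = rep(1, length(centers)), hw = half_width) {
    data.frame(center = centers, relative_height = heights, half_width = hw)
  }
  specs <- list(
    metabolite_spec("creatinine", pk(c(3.05, 4.05), c(3, 2)),
                    base_level = 10, cv = 0.12),
    metabolite_spec("creatine", pk(c(3.03, 3.93), c(1, 0.7)),
                    base_level = 2, cv = 0.15),
    metabolite_spec("citrate", pk(c(2.55, 2.67), c(1, 1)),
                    base_level = 4, cv = 0.12),
    metabolite_spec("choline", pk(3.20, 9), base_level = 1, cv = 0.10),
    metabolite_spec("phosphocholine", pk(3.23, 9), base_level = 0.8,
                    cv = 0.10),
    metabolite_spec("taurine", pk(c(3.25, 3.43), c(1, 1)),
                    base_level = 3, cv = 0.12),
    metabolite_spec("alanine", pk(c(1.47, 1.49), c(1, 1)),
                    base_level = 1.5, cv = 0.10),
    metabolite_spec("lactate", pk(c(1.32, 1.34, 4.11), c(1, 1, 0.3)),
                    base_level = 2, cv = 0.15),
    metabolite_spec("glycine", pk(3.56, 2), base_level = 2, cv = 0.12),
    metabolite_spec("hippurate", pk(c(3.97, 7.55, 7.64, 7.83),
                                    c(1.5, 1.4, 0.8, 1.5)),
                    base_level = 5, cv = 0.20),
    metabolite_spec("dimethylamine", pk(2.72, 3), base_level = 1.5,
                    cv = 0.15),
    metabolite_spec("trimethylamine N-oxide", pk(3.27, 6),
                    base_level = 1, cv = 0.20),
    metabolite_spec("mannitol", pk(c(3.67, 3.71, 3.75, 3.80, 3.87),
                                   c(1, 1.2, 1.5, 1.2, 1)),
                    base_level = 0, cv = 0.15)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Default ppm axis for simulated spectra
#'
#' 0.5-9.5 ppm at 0.002 ppm steps: at least 20 axis points per 0.04 ppm
#' bucket, dense enough for stable trapezoidal bin integrals.
#'
#' @param from,to,by Axis limits and step (ppm).
#' @return Numeric vector of chemical shifts.
#' @export
default_ppm_axis <- function(from = 0.5, to = 9.5, by = 0.002) {
  seq(from, to, by = by)
}

# Lorentzian profile matrix: one column per metabolite, evaluated on `axis`
# at unit amount.  Rendering a spectrum is then a matrix-vector product.
metabolite_profiles <- function(library, axis) {
  out <- matrix(0, nrow = length(axis), ncol = length(library),
                dimnames = list(NULL, names(library)))
  for (j in seq_along(library)) {
    pk <- library[[j]]$peaks
    v <- numeric(length(axis))
    for (i in seq_len(nrow(pk))) {
      hw <- pk$half_width[i]
      v <- v + pk$relative_height[i] * hw^2 / ((axis - pk$center[i])^2 + hw^2)
    }
    out[, j] <- v
  }
  out
}

#' Render one synthetic spectrum
#'
#' Intensity is `dilution_factor` times the sum of Lorentzian peaks over all
#' metabolites (each scaled by its amount), plus i.i.d. Gaussian noise.
#'
#' @param amounts Named numeric vector of metabolite amounts (>= 0); names
#'   must match entries of `library`.
#' @param axis Strictly monotone ppm grid.
#' @param library Metabolite library, as from [default_metabolite_library()].
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param dilution_factor Global multiplicative scale for the sample.
#' @return A `spectrum` object: list with `ppm` and `intensity`.
#' @export
render_spectrum <- function(amounts, axis, library = default_metabolite_library(),
                            noise_sd = 0, dilution_factor = 1) {
  d <- diff(axis)
  if (length(axis) < 2 || !(all(d > 0) || all(d < 0))) {
    stop("`axis` must be strictly monotone")
  }
  if (any(amounts < 0)) stop("`amounts` must be >= 0")
  unknown <- setdiff(names(amounts), names(library))
  if (length(unknown)) stop("unknown metabolites: ", paste(unknown, collapse = ", "))
  prof <- metabolite_profiles(library[names(amounts)], axis)
  intensity <- dilution_factor * as.vector(prof %*% amounts)
  if (noise_sd > 0) intensity <- intensity + stats::rnorm(length(axis), 0, noise_sd)
  new_spectrum(axis, intensity)
}

#' Design a synthetic cohort
#'
#' Defaults mirror the study cohort: 25 neuropathic (NP), 12 nociceptive
#' (NC) and 37 control (C) urine samples, with the five discriminant
#' metabolites elevated in NP and a mannitol excipient signal present in the
#' pain classes only.
#'
#' @param n_np,n_nc,n_c Class sizes.
#' @param effect_sizes Named multiplicative fold-changes applied to the NP
#'   class mean (>= 0).
#' @param mannitol_in_pain If `TRUE`, pain samples (NP and NC) receive a
#'   mannitol signal of level `mannitol_level` (controls never do).
#' @param mannitol_level Mean mannitol amount in pain samples.
#' @param dilution_cv Coefficient of variation of the per-sample log-normal
#'   dilution factor.
#' @param noise_sd Additive spectral noise standard deviation.
#' @param seed Integer seed; identical designs yield identical cohorts.
#' @param library Metabolite library.
#' @param axis ppm axis.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_np = 25, n_nc = 12, n_c = 37,
                          effect_sizes = c(choline = 2, phosphocholine = 1.8,
                                           citrate = 1.5, alanine = 1.5,
                                           taurine = 1.5),
                          mannitol_in_pain = TRUE, mannitol_level = 4,
                          dilution_cv = 0.2, noise_sd = 0.02, seed = 1,
                          library = default_metabolite_library(),
                          axis = default_ppm_axis()) {
  if (any(c(n_np, n_nc, n_c) < 0)) stop("class sizes must be >= 0")
  if (any(effect_sizes < 0)) stop("fold-changes must be >= 0")
  if (dilution_cv < 0 || noise_sd < 0) stop("cv and noise_sd must be >= 0")
  unknown <- setdiff(names(effect_sizes), names(library))
  if (length(unknown)) stop("unknown effect metabolites: ",
                            paste(unknown, collapse = ", "))
  structure(
    list(n_np = n_np, n_nc = n_nc, n_c = n_c, effect_sizes = effect_sizes,
         mannitol_in_pain = isTRUE(mannitol_in_pain),
         mannitol_level = mannitol_level, dilution_cv = dilution_cv,
         noise_sd = noise_sd, seed = as.integer(seed),
         library = library, axis = axis),
    class = "cohort_design"
  )
}

#' Generate a labeled synthetic cohort
#'
#' Per-sample metabolite amounts are drawn log-normally around each
#' metabolite's `base_level` with its `cv`; NP samples get the design's
#' fold-changes applied to the mean; dilution is a global log-normal factor
#' per sample.  Controls are tagged as matched to NP (`C-NP`) or NC (`C-NC`)
#' in design order, emulating the age/gender-matched control subsets of the
#' study (matching covariates themselves are not simulated).
#'
#' @param design A [cohort_design()].
#' @return A `labeled_spectrum_set`: list with `spectra` (list of
#'   `spectrum`), `labels` (factor NP/NC/C), `control_tag` (`C-NP`/`C-NC`/NA)
#'   and `sample_ids`.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  lib <- design$library
  axis <- design$axis
  n_tot <- design$n_np + design$n_nc + design$n_c
  labels <- factor(rep(c("NP", "NC", "C"),
                       c(design$n_np, design$n_nc, design$n_c)),
                   levels = c("NP", "NC", "C"))
  ids <- sprintf("S%03d_%s", seq_len(n_tot), as.character(labels))

  base <- vapply(lib, `[[`, numeric(1), "base_level")
  cv <- vapply(lib, `[[`, numeric(1), "cv")
  prof <- metabolite_profiles(lib, axis)

  with_seed(design$seed, {
    amounts <- matrix(0, nrow = length(lib), ncol = n_tot,
                      dimnames = list(names(lib), ids))
    for (i in seq_len(n_tot)) {
      mu <- base
      if (labels[i] == "NP" && length(design$effect_sizes)) {
        mu[names(design$effect_sizes)] <-
          mu[names(design$effect_sizes)] * design$effect_sizes
      }
      if (design$mannitol_in_pain && labels[i] %in% c("NP", "NC")) {
        mu["mannitol"] <- design$mannitol_level
      }
      # log-normal draw with mean mu and cv per metabolite
      sdl <- sqrt(log1p(cv^2))
      amt <- ifelse(mu > 0,
                    stats::rlnorm(length(mu), log(mu) - sdl^2 / 2, sdl), 0)
      amounts[, i] <- amt
    }
    sdl_d <- sqrt(log1p(design$dilution_cv^2))
    dilution <- stats::rlnorm(n_tot, -sdl_d^2 / 2, sdl_d)
    intens <- prof %*% amounts
    intens <- sweep(intens, 2, dilution, `*`)
    if (design$noise_sd > 0) {
      intens <- intens + matrix(stats::rnorm(length(intens), 0, design$noise_sd),
                                nrow = nrow(intens))
    }
    spectra <- lapply(seq_len(n_tot), function(i) new_spectrum(axis, intens[, i]))
  })

  tag <- rep(NA_character_, n_tot)
  cidx <- which(labels == "C")
  k_np <- min(design$n_np, length(cidx))
  if (k_np > 0) tag[cidx[seq_len(k_np)]] <- "C-NP"
  k_nc <- min(design$n_nc, length(cidx) - k_np)
  if (k_nc > 0) tag[cidx[k_np + seq_len(k_nc)]] <- "C-NC"

  structure(
    list(spectra = spectra, labels = labels, control_tag = tag,
         sample_ids = ids, design = design),
    class = "labeled_spectrum_set"
  )
}

#' @export
print.labeled_spectrum_set <- function(x, ...) {
  cat("Labeled spectrum set:", length(x$spectra), "spectra,",
      length(x$spectra[[1]]$ppm), "points each\n")
  print(table(x$labels))
  invisible(x)
}

#' Write / read a cohort as plain text
#'
#' Two-file layout: `<stem>_spectra.tsv` holds the intensity matrix (rows =
#' ppm values, one column per sample) and `<stem>_samples.tsv` the sample
#' sheet (sample_id, class, control_tag).
#'
#' @param set A `labeled_spectrum_set`.
#' @param stem Output path stem.
#' @return `write_cohort` returns the two paths invisibly; `read_cohort`
#'   returns a `labeled_spectrum_set` (without the generating design).
#' @export
write_cohort <- function(set, stem) {
  stopifnot(inherits(set, "labeled_spectrum_set"))
  mat <- vapply(set$spectra, `[[`, numeric(length(set$spectra[[1]]$ppm)),
                "intensity")
  colnames(mat) <- set$sample_ids
  spath <- paste0(stem, "_spectra.tsv")
  mpath <- paste0(stem, "_samples.tsv")
  utils::write.table(
    data.frame(ppm = set$spectra[[1]]$ppm, mat, check.names = FALSE),
    spath, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(sample_id = set$sample_ids, class = as.character(set$labels),
               control_tag = ifelse(is.na(set$control_tag), "",
                                    set$control_tag)),
    mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(spectra = spath, samples = mpath))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(stem) {
  sp <- utils::read.delim(paste0(stem, "_spectra.tsv"), check.names = FALSE)
  sheet <- utils::read.delim(paste0(stem, "_samples.tsv"),
                             colClasses = "character")
  axis <- sp$ppm
  ids <- sheet$sample_id
  if (anyDuplicated(ids)) {
    stop("duplicate sample id: ", ids[duplicated(ids)][1])
  }
  spectra <- lapply(ids, function(id) new_spectrum(axis, sp[[id]]))
  structure(
    list(spectra = spectra,
         labels = factor(sheet$class, levels = c("NP", "NC", "C")),
         control_tag = ifelse(sheet$control_tag == "", NA_character_,
                              sheet$control_tag),
         sample_ids = ids),
    class = "labeled_spectrum_set"
  )
}
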