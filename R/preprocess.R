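#' A quality-control rule for background spectra
#'
#' @param metric One of `"rms_noise_2200_2000"` (root-mean-square of the
#'   signal in the quiet 2200-2000 cm^-1 window), `"integrated_absorbance"`
#'   (trapezoidal integral over the whole trace) or `"max_absorbance"`.
#' @param min,max Acceptance interval; a spectrum fails the rule if the
#'   metric falls outside `[min, max]`.
#' @return An object of class `qc_rule`.
#' @export
qc_rule <- function(metric = c("rms_noise_2200_2000",
                               "integrated_absorbance", "max_absorbance"),
                    min = -Inf, max = Inf) {
  metric <- match.arg(metric)
  if (min > max) stop("qc_rule: min > max", call. = FALSE)
  structure(list(metric = metric, min = min, max = max), class = "qc_rule")
}

qc_metric_value <- function(spectrum, metric) {
  wn <- spectrum$wavenumbers
  y <- spectrum$absorbance
  switch(metric,
    rms_noise_2200_2000 = {
      sel <- wn <= 2200 & wn >= 2000
      if (!any(sel)) {
        stop("qc: spectrum does not cover the 2200-2000 cm-1 window",
             call. = FALSE)
      }
      sqrt(mean(y[sel]^2))
    },
    integrated_absorbance = abs(sum(diff(sort(wn)) *
                                      (utils::head(y, -1) + utils::tail(y, -1)) / 2)),
    max_absorbance = max(y)
  )
}

#' Check a background spectrum against acceptance rules
#'
#' The published protocol accepts an internal-reflection-element well only
#' if its background spectrum falls within a defined acceptance range;
#' this operation encodes that gate as an explicit rule set. A verdict
#' records every metric value, so a failed slide is auditable.
#'
#' @param spectrum An [ftir_spectrum()] with role `"background"`.
#' @param rules A list of [qc_rule()] objects.
#' @return List of class `qc_verdict`: `pass` (logical), `values` (named
#'   numeric of metric values), `failed` (character of failed metrics).
#' @export
qc_background <- function(spectrum, rules) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  if (spectrum$role != "background") {
    stop("qc_background: spectrum role is '", spectrum$role,
         "'; background QC applies to background spectra only",
         call. = FALSE)
  }
  if (inherits(rules, "qc_rule")) rules <- list(rules)
  values <- numeric(0)
  failed <- character(0)
  for (r in rules) {
    v <- qc_metric_value(spectrum, r$metric)
    values[r$metric] <- v
    if (v < r$min || v > r$max) failed <- c(failed, r$metric)
  }
  structure(list(pass = !length(failed), values = values, failed = failed),
            class = "qc_verdict")
}

#' Rubber-band baseline correction
#'
#' Subtracts the lower convex hull of the (wavenumber, absorbance) trace,
#' linearly interpolated between hull vertices. The corrected spectrum is
#' non-negative everywhere and touches zero at every hull vertex (at
#' least the two endpoints); applying the correction twice is the same as
#' applying it once. The method is parameter-free, which is why it is the
#' package default for serum ATR-FTIR work.
#'
#' @param spectrum An [ftir_spectrum()] with at least 3 points.
#' @return The corrected [ftir_spectrum()].
#' @export
rubber_band_baseline <- function(spectrum) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  n <- length(spectrum$wavenumbers)
  if (n < 3) {
    stop("rubber_band_baseline: need at least 3 points", call. = FALSE)
  }
  # work in ascending order; restore orientation afterwards
  ord <- order(spectrum$wavenumbers)
  x <- spectrum$wavenumbers[ord]
  y <- spectrum$absorbance[ord]
  hull <- lower_hull_indices(x, y)
  baseline <- stats::approx(x[hull], y[hull], xout = x)$y
  corrected <- y - baseline
  corrected[corrected < 0] <- 0 # clip numerical dust from interpolation
  out <- spectrum
  out$absorbance[ord] <- corrected
  out
}

# Andrew's monotone-chain lower hull on points already sorted by x.
lower_hull_indices <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      # pop while o -> a -> i fails to turn counter-clockwise (keeps the
      # chain lower-convex)
      o <- hull[k - 1L]; a <- hull[k]
      cross <- (x[a] - x[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (x[i] - x[o])
      if (cross <= 0) k <- k - 1L else break
    }
    k <- k + 1L
    hull[k] <- i
  }
  hull[seq_len(k)]
}

#' Normalise a spectrum
#'
#' `"vector_l2"` scales the trace to unit Euclidean norm (making spectra
#' comparable regardless of absolute absorbance, and cancelling any
#' overall multiplicative factor such as deposited serum mass).
#' `"amide_i_peak"` scales so the maximum within 1680-1620 cm^-1 (the
#' amide I band) equals 1. `"none"` returns the input.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param method `"vector_l2"`, `"amide_i_peak"` or `"none"`.
#' @return The normalised [ftir_spectrum()].
#' @export
normalize_spectrum <- function(spectrum,
                               method = c("vector_l2", "amide_i_peak",
                                          "none")) {
  method <- match.arg(method)
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  if (method == "none") return(spectrum)
  y <- spectrum$absorbance
  scale <- switch(method,
    vector_l2 = sqrt(sum(y^2)),
    amide_i_peak = {
      sel <- spectrum$wavenumbers <= 1680 & spectrum$wavenumbers >= 1620
      if (!any(sel)) {
        stop("normalize_spectrum: spectrum does not cover 1680-1620 cm-1",
             call. = FALSE)
      }
      max(y[sel])
    }
  )
  if (scale == 0) {
    stop("normalize_spectrum: degenerate all-zero spectrum cannot be ",
         "normalised", call. = FALSE)
  }
  spectrum$absorbance <- y / scale
  spectrum
}

#' Crop a spectrum to a wavenumber range
#'
#' @param spectrum An [ftir_spectrum()].
#' @param range Two-element numeric; points with wavenumber inside
#'   `[min(range), max(range)]` are kept.
#' @return The cropped [ftir_spectrum()].
#' @export
crop_spectrum <- function(spectrum, range = c(1800, 1000)) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  lo <- min(range); hi <- max(range)
  sel <- spectrum$wavenumbers >= lo & spectrum$wavenumbers <= hi
  if (sum(sel) < 2) {
    stop("crop_spectrum: range [", lo, ", ", hi,
         "] leaves fewer than 2 points", call. = FALSE)
  }
  spectrum$wavenumbers <- spectrum$wavenumbers[sel]
  spectrum$absorbance <- spectrum$absorbance[sel]
  spectrum
}

#' Reduce a spectrum by mean binning
#'
#' Consecutive blocks of `bin_factor` points are averaged; the output
#' grid point is the mean wavenumber of each block. If `bin_factor` does
#' not divide the length, the trailing remainder points are dropped
#' (output length is `floor(n / bin_factor)`).
#'
#' @param spectrum An [ftir_spectrum()].
#' @param bin_factor Integer >= 1; 1 is the identity.
#' @return The binned [ftir_spectrum()].
#' @export
bin_spectrum <- function(spectrum, bin_factor = 4) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  if (bin_factor < 1 || bin_factor != round(bin_factor)) {
    stop("bin_spectrum: 'bin_factor' must be an integer >= 1",
         call. = FALSE)
  }
  if (bin_factor == 1) return(spectrum)
  n_out <- length(spectrum$wavenumbers) %/% bin_factor
  if (n_out < 1) {
    stop("bin_spectrum: spectrum shorter than one bin", call. = FALSE)
  }
  keep <- seq_len(n_out * bin_factor)
  grp <- rep(seq_len(n_out), each = bin_factor)
  spectrum$wavenumbers <-
    as.numeric(tapply(spectrum$wavenumbers[keep], grp, mean))
  spectrum$absorbance <-
    as.numeric(tapply(spectrum$absorbance[keep], grp, mean))
  spectrum
}

#' Preprocessing configuration
#'
#' Fixes the preprocessing chain, applied per spectrum in the fixed order
#' crop -> baseline -> normalise -> reduce. Normalisation after baseline
#' correction means offsets never dominate the norm; the chain is applied
#' to each spectrum in isolation, so no statistic pools across patients
#' (train/test leakage is impossible by construction).
#'
#' @param crop_range Wavenumber window kept (default the 1800-1000 cm^-1
#'   fingerprint region).
#' @param baseline_method `"rubber_band"` or `"none"`.
#' @param normalization `"vector_l2"`, `"amide_i_peak"` or `"none"`.
#' @param bin_factor Mean-binning factor (default 4, matching a 4 cm^-1
#'   optical resolution on a 1 cm^-1 grid); 1 disables reduction.
#' @param qc List of [qc_rule()] objects applied to background spectra
#'   (empty by default).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(crop_range = c(1800, 1000),
                              baseline_method = c("rubber_band", "none"),
                              normalization = c("vector_l2",
                                                "amide_i_peak", "none"),
                              bin_factor = 4,
                              qc = list()) {
  structure(
    list(crop_range = crop_range,
         baseline_method = match.arg(baseline_method),
         normalization = match.arg(normalization),
         bin_factor = bin_factor,
         qc = qc),
    class = "preprocess_config"
  )
}

preprocess_one <- function(spectrum, config) {
  s <- crop_spectrum(spectrum, config$crop_range)
  if (config$baseline_method == "rubber_band") s <- rubber_band_baseline(s)
  s <- normalize_spectrum(s, config$normalization)
  bin_spectrum(s, config$bin_factor)
}

#' Preprocess a collection into a per-spectrum feature table
#'
#' Runs background QC (when rules are configured), then applies the
#' preprocessing chain to every sample spectrum. The result is a feature
#' table: one row per spectrum, identity columns (patient_id, well,
#' replicate) followed by one feature column per retained bin, labelled
#' by its centre wavenumber. Patients whose spectra all fail are listed
#' in the `patients_without_spectra` attribute rather than silently
#' vanishing.
#'
#' @param collection A [spectra_collection()].
#' @param config A [preprocess_config()].
#' @return A data.frame of class `feature_table`. Attributes:
#'   `feature_cols` (names of the feature columns), `qc_verdicts` (named
#'   list of background [qc_background()] verdicts),
#'   `patients_without_spectra` (character).
#' @export
preprocess_collection <- function(collection,
                                  config = preprocess_config()) {
  stopifnot(inherits(collection, "spectra_collection"),
            inherits(config, "preprocess_config"))
  qc_verdicts <- list()
  if (length(config$qc)) {
    bg_idx <- which(collection$meta$role == "background")
    for (i in bg_idx) {
      v <- qc_background(get_spectrum(collection, i), config$qc)
      qc_verdicts[[collection$meta$key[i]]] <- v
    }
  }
  idx <- which(collection$meta$role == "sample")
  if (!length(idx)) {
    stop("preprocess_collection: no sample spectra", call. = FALSE)
  }
  first <- preprocess_one(get_spectrum(collection, idx[1]), config)
  feat_names <- sprintf("wn%.1f", first$wavenumbers)
  mat <- matrix(NA_real_, nrow = length(idx), ncol = length(feat_names))
  mat[1, ] <- first$absorbance
  for (j in seq_along(idx)[-1]) {
    s <- preprocess_one(get_spectrum(collection, idx[j]), config)
    mat[j, ] <- s$absorbance
  }
  colnames(mat) <- feat_names
  meta <- collection$meta[idx, c("patient_id", "well", "replicate")]
  out <- cbind(meta, as.data.frame(mat), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  attr(out, "feature_cols") <- feat_names
  attr(out, "qc_verdicts") <- qc_verdicts
  all_patients <- unique(collection$meta$patient_id[collection$meta$role ==
                                                      "sample"])
  attr(out, "patients_without_spectra") <-
    setdiff(all_patients, unique(out$patient_id))
  out
}

#' Feature matrix of a feature table
#'
#' @param features A `feature_table` from [preprocess_collection()].
#' @return Numeric matrix (spectra x features).
#' @export
feature_matrix <- function(features) {
  stopifnot(inherits(features, "feature_table"))
  as.matrix(features[, attr(features, "feature_cols"), drop = FALSE])
}

#' Read a feature table written as CSV
#'
#' Restores the `feature_table` structure from a CSV produced by
#' `write.csv` of a [preprocess_collection()] result: the first three
#' columns are the identity columns, everything after is a feature.
#'
#' @param path CSV file path.
#' @return A `feature_table` data.frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  id_cols <- c("patient_id", "well", "replicate")
  if (!identical(names(df)[1:3], id_cols)) {
    stop("read_feature_table: first columns must be ",
         paste(id_cols, collapse = ", "), call. = FALSE)
  }
  df$patient_id <- as.character(df$patient_id)
  df$well <- as.character(df$well)
  class(df) <- c("feature_table", "data.frame")
  attr(df, "feature_cols") <- names(df)[-(1:3)]
  df
}
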