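#' Acquisition settings for an ATR-FTIR measurement
#'
#' Describes the wavenumber grid and instrument parameters under which
#' spectra are (or are simulated to be) acquired: a descending grid from
#' `wavenumber_start` to `wavenumber_end` at `spacing` cm^-1 data spacing,
#' with an optical `resolution` that may be coarser than the data spacing.
#' The defaults correspond to 4 cm^-1 resolution with 1 cm^-1 data spacing
#' and 16 co-added scans over 4000-950 cm^-1.
#'
#' @param wavenumber_start Start of the grid in cm^-1 (high end; default 4000).
#' @param wavenumber_end End of the grid in cm^-1 (low end; default 950).
#' @param spacing Data spacing in cm^-1 (default 1).
#' @param resolution Optical resolution in cm^-1 (default 4); must be at
#'   least `spacing`.
#' @param coadded_scans Number of co-added scans (metadata only; default 16).
#' @return An object of class `acquisition_settings`.
#' @examples
#' acq <- acquisition_settings()
#' length(wavenumber_grid(acq)) # 3051 points
#' @export
acquisition_settings <- function(wavenumber_start = 4000,
                                 wavenumber_end = 950,
                                 spacing = 1,
                                 resolution = 4,
                                 coadded_scans = 16) {
  if (!(wavenumber_start > wavenumber_end)) {
    stop("acquisition_settings: 'wavenumber_start' must exceed 'wavenumber_end'",
         call. = FALSE)
  }
  if (spacing <= 0) {
    stop("acquisition_settings: 'spacing' must be positive", call. = FALSE)
  }
  if (resolution < spacing) {
    stop("acquisition_settings: 'resolution' must be >= 'spacing'",
         call. = FALSE)
  }
  structure(
    list(
      wavenumber_start = wavenumber_start,
      wavenumber_end = wavenumber_end,
      spacing = spacing,
      resolution = resolution,
      coadded_scans = coadded_scans
    ),
    class = "acquisition_settings"
  )
}

#' Wavenumber grid implied by acquisition settings
#'
#' @param acquisition An [acquisition_settings()] object.
#' @return Numeric vector of wavenumbers, descending, with
#'   `floor((start - end)/spacing) + 1` points.
#' @export
wavenumber_grid <- function(acquisition) {
  stopifnot(inherits(acquisition, "acquisition_settings"))
  n <- floor((acquisition$wavenumber_start - acquisition$wavenumber_end) /
               acquisition$spacing) + 1
  acquisition$wavenumber_start - (seq_len(n) - 1) * acquisition$spacing
}

#' A single spectrum with patient/well/replicate identity
#'
#' The atomic record of the package: one absorbance trace on a strictly
#' monotone (by convention descending) wavenumber grid, tagged with the
#' patient it came from, the sample well (1-3, or `"background"`), the
#' replicate acquisition index, and its role (`"sample"` or `"background"`).
#'
#' @param wavenumbers Numeric, strictly monotone wavenumber grid in cm^-1.
#' @param absorbance Numeric of the same length; must be finite.
#' @param patient_id Patient identifier; must not contain underscores
#'   (they delimit column keys in the wide CSV format).
#' @param well Well identifier: `"1"`, `"2"`, `"3"` or `"background"`.
#' @param replicate Replicate acquisition index (1-based).
#' @param role `"sample"` or `"background"`.
#' @param acquisition Optional [acquisition_settings()] metadata.
#' @return An object of class `ftir_spectrum`.
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, patient_id = "unknown",
                          well = "1", replicate = 1L,
                          role = c("sample", "background"),
                          acquisition = NULL) {
  role <- match.arg(role)
  if (length(wavenumbers) != length(absorbance)) {
    stop("ftir_spectrum: 'wavenumbers' and 'absorbance' lengths differ",
         call. = FALSE)
  }
  if (anyNA(wavenumbers) || anyNA(absorbance) ||
      any(!is.finite(absorbance))) {
    stop("ftir_spectrum: non-finite values are not permitted", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("ftir_spectrum: wavenumber grid must be strictly monotone",
         call. = FALSE)
  }
  if (grepl("_", patient_id, fixed = TRUE)) {
    stop("ftir_spectrum: 'patient_id' must not contain underscores",
         call. = FALSE)
  }
  structure(
    list(
      wavenumbers = as.numeric(wavenumbers),
      absorbance = as.numeric(absorbance),
      patient_id = as.character(patient_id),
      well = as.character(well),
      replicate = as.integer(replicate),
      role = role,
      acquisition = acquisition
    ),
    class = "ftir_spectrum"
  )
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ftir_spectrum> patient %s, well %s, replicate %d (%s)\n  %d points, %g to %g cm-1\n",
    x$patient_id, x$well, x$replicate, x$role,
    length(x$wavenumbers), x$wavenumbers[1],
    x$wavenumbers[length(x$wavenumbers)]
  ))
  invisible(x)
}

#' A collection of spectra on a shared grid
#'
#' Stores many spectra column-wise against one common wavenumber grid,
#' with a metadata table (one row per spectrum) carrying patient, well,
#' replicate and role. All spectra in a collection must share the grid
#' exactly; this is the invariant every downstream stage relies on.
#'
#' @param spectra A list of [ftir_spectrum()] objects on identical grids.
#' @return An object of class `spectra_collection` with elements
#'   `wavenumbers` (numeric), `absorbance` (points x spectra matrix) and
#'   `meta` (data.frame with columns key, patient_id, well, replicate, role).
#' @export
spectra_collection <- function(spectra) {
  if (!length(spectra)) {
    stop("spectra_collection: empty spectrum list", call. = FALSE)
  }
  wn <- spectra[[1]]$wavenumbers
  for (s in spectra) {
    if (!identical(length(s$wavenumbers), length(wn)) ||
        any(s$wavenumbers != wn)) {
      stop("spectra_collection: all spectra must share one wavenumber grid",
           call. = FALSE)
    }
  }
  meta <- data.frame(
    key = vapply(spectra, function(s)
      paste(s$patient_id, s$well, s$replicate, sep = "_"), character(1)),
    patient_id = vapply(spectra, function(s) s$patient_id, character(1)),
    well = vapply(spectra, function(s) s$well, character(1)),
    replicate = vapply(spectra, function(s) s$replicate, integer(1)),
    role = vapply(spectra, function(s) s$role, character(1)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(meta$key)) {
    stop("spectra_collection: duplicate patient/well/replicate keys: ",
         paste(unique(meta$key[duplicated(meta$key)]), collapse = ", "),
         call. = FALSE)
  }
  ab <- vapply(spectra, function(s) s$absorbance, numeric(length(wn)))
  dim(ab) <- c(length(wn), length(spectra))
  colnames(ab) <- meta$key
  structure(
    list(wavenumbers = wn, absorbance = ab, meta = meta),
    class = "spectra_collection"
  )
}

#' @export
print.spectra_collection <- function(x, ...) {
  cat(sprintf(
    "<spectra_collection> %d spectra (%d sample, %d background), %d patients\n  grid: %d points, %g to %g cm-1\n",
    nrow(x$meta), sum(x$meta$role == "sample"),
    sum(x$meta$role == "background"),
    length(unique(x$meta$patient_id[x$meta$role == "sample"])),
    length(x$wavenumbers), x$wavenumbers[1],
    x$wavenumbers[length(x$wavenumbers)]
  ))
  invisible(x)
}

#' Number of spectra held for each patient
#'
#' @param collection A [spectra_collection()].
#' @param role Count only spectra with this role (default `"sample"`).
#' @return Named integer vector, one entry per patient.
#' @export
spectra_per_patient <- function(collection, role = "sample") {
  stopifnot(inherits(collection, "spectra_collection"))
  m <- collection$meta[collection$meta$role == role, , drop = FALSE]
  tab <- table(m$patient_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Extract one spectrum from a collection
#'
#' @param collection A [spectra_collection()].
#' @param key Column key `"patientid_well_replicate"`, or a column index.
#' @return An [ftir_spectrum()].
#' @export
get_spectrum <- function(collection, key) {
  stopifnot(inherits(collection, "spectra_collection"))
  idx <- if (is.numeric(key)) key else match(key, collection$meta$key)
  if (is.na(idx) || idx < 1 || idx > nrow(collection$meta)) {
    stop("get_spectrum: no spectrum with key ", key, call. = FALSE)
  }
  m <- collection$meta[idx, ]
  ftir_spectrum(collection$wavenumbers, collection$absorbance[, idx],
                patient_id = m$patient_id, well = m$well,
                replicate = m$replicate, role = m$role)
}
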