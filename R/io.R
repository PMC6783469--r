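#' Write a spectra collection as a wide CSV
#'
#' First column `wavenumber`, then one column per spectrum keyed
#' `patientid_well_replicate` (underscores are therefore forbidden inside
#' patient ids). This is the package's interchange format for whole
#' cohorts.
#'
#' @param collection A [spectra_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wide_csv <- function(collection, path) {
  stopifnot(inherits(collection, "spectra_collection"))
  df <- data.frame(wavenumber = collection$wavenumbers,
                   collection$absorbance, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

parse_spectrum_key <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3
  if (any(bad)) {
    stop("read_wide_csv: malformed column key(s) (need patientid_well_replicate): ",
         paste(key[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(
    key = key,
    patient_id = vapply(parts, `[`, character(1), 1),
    well = vapply(parts, `[`, character(1), 2),
    replicate = as.integer(vapply(parts, `[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
}

#' Read a wide-CSV spectra file
#'
#' Strict reader for the format written by [write_wide_csv()]: rejects
#' duplicate column keys, malformed keys, ragged rows, missing cells and
#' non-monotone grids rather than repairing them, naming the offending
#' row or column. Ascending grids are accepted and flipped to the
#' descending convention (the flip is recorded in the collection's
#' `normalized_ascending` attribute).
#'
#' @param path CSV file path.
#' @return A [spectra_collection()].
#' @export
read_wide_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "numeric")
  if (names(df)[1] != "wavenumber") {
    stop("read_wide_csv: first column must be 'wavenumber', found '",
         names(df)[1], "'", call. = FALSE)
  }
  keys <- names(df)[-1]
  if (!length(keys)) stop("read_wide_csv: no spectrum columns", call. = FALSE)
  dup <- unique(keys[duplicated(keys)])
  if (length(dup)) {
    stop("read_wide_csv: duplicate column key(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyNA(df)) {
    bad <- which(rowSums(is.na(df)) > 0)[1]
    stop("read_wide_csv: missing value at data row ", bad,
         " (missing absorbance cells are an error, not interpolated)",
         call. = FALSE)
  }
  wn <- df$wavenumber
  d <- diff(wn)
  if (!(all(d > 0) || all(d < 0))) {
    stop("read_wide_csv: wavenumber column is not strictly monotone",
         call. = FALSE)
  }
  flipped <- FALSE
  ab <- as.matrix(df[-1])
  if (all(d > 0)) { # normalise to descending convention
    wn <- rev(wn)
    ab <- ab[rev(seq_len(nrow(ab))), , drop = FALSE]
    flipped <- TRUE
  }
  meta <- parse_spectrum_key(keys)
  meta$role <- ifelse(meta$well == "background", "background", "sample")
  out <- structure(
    list(wavenumbers = as.numeric(wn), absorbance = unname(ab), meta = meta),
    class = "spectra_collection"
  )
  colnames(out$absorbance) <- meta$key
  attr(out, "normalized_ascending") <- flipped
  out
}

#' Write a spectrum as a JCAMP-DX file
#'
#' Fixed-form JCAMP-DX 4.24 subset: `XYDATA=(X++(Y..Y))` with
#' FIRSTX/LASTX/DELTAX/NPOINTS/YFACTOR labelled records and unpacked
#' integer ordinates. Ordinates are quantised to multiples of `yfactor`,
#' so a round trip is exact to `yfactor / 2`.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param path Output file path.
#' @param yfactor Ordinate quantisation step (default 1e-6 absorbance).
#' @param title TITLE record content.
#' @return `path`, invisibly.
#' @export
write_jcampdx <- function(spectrum, path, yfactor = 1e-6,
                          title = NULL) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  wn <- spectrum$wavenumbers
  n <- length(wn)
  deltax <- (wn[n] - wn[1]) / (n - 1)
  if (is.null(title)) {
    title <- sprintf("spectrum %s well %s replicate %d",
                     spectrum$patient_id, spectrum$well, spectrum$replicate)
  }
  yint <- round(spectrum$absorbance / yfactor)
  head <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    paste0("##FIRSTX=", format(wn[1], digits = 12)),
    paste0("##LASTX=", format(wn[n], digits = 12)),
    paste0("##DELTAX=", format(deltax, digits = 12)),
    paste0("##NPOINTS=", n),
    paste0("##YFACTOR=", format(yfactor, digits = 12)),
    paste0("##FIRSTY=", format(spectrum$absorbance[1], digits = 12)),
    "##XYDATA=(X++(Y..Y))"
  )
  # 6 ordinates per line, each line led by its abscissa
  idx <- seq(1, n, by = 6)
  body <- vapply(idx, function(i) {
    j <- min(i + 5, n)
    paste(c(format(wn[i], digits = 12), yint[i:j]), collapse = " ")
  }, character(1))
  writeLines(c(head, body, "##END="), path)
  invisible(path)
}

jcamp_record <- function(lines, label, required = TRUE) {
  pat <- paste0("^##", label, "=")
  hit <- grep(pat, lines, value = TRUE)
  if (!length(hit)) {
    if (required) {
      stop("read_jcampdx: missing required record ##", label, "=",
           call. = FALSE)
    }
    return(NA_character_)
  }
  sub(pat, "", hit[1])
}

#' Read a JCAMP-DX spectrum
#'
#' Counterpart of [write_jcampdx()]; supports the fixed-form
#' `(X++(Y..Y))` layout only (no SQZ/DIF/DUP compression). The grid is
#' reconstructed from FIRSTX/DELTAX/NPOINTS; a DELTAX whose sign
#' contradicts FIRSTX/LASTX, or a point count that does not match
#' NPOINTS, is a format error.
#'
#' @param path JCAMP-DX file path.
#' @param patient_id,well,replicate,role Identity metadata to attach
#'   (JCAMP carries none).
#' @return An [ftir_spectrum()].
#' @export
read_jcampdx <- function(path, patient_id = "unknown", well = "1",
                         replicate = 1L, role = "sample") {
  lines <- readLines(path, warn = FALSE)
  firstx <- as.numeric(jcamp_record(lines, "FIRSTX"))
  lastx <- as.numeric(jcamp_record(lines, "LASTX"))
  deltax <- as.numeric(jcamp_record(lines, "DELTAX"))
  npoints <- as.integer(jcamp_record(lines, "NPOINTS"))
  yfactor <- as.numeric(jcamp_record(lines, "YFACTOR"))
  jcamp_record(lines, "XYDATA") # required presence
  if (sign(deltax) != sign(lastx - firstx)) {
    stop("read_jcampdx: DELTAX sign contradicts FIRSTX/LASTX",
         call. = FALSE)
  }
  start <- grep("^##XYDATA=", lines)[1]
  end <- grep("^##END=", lines)
  end <- if (length(end)) end[1] else length(lines) + 1
  body <- lines[(start + 1):(end - 1)]
  y <- numeric(0)
  for (ln in body) {
    tok <- strsplit(trimws(ln), "[ \t]+")[[1]]
    y <- c(y, as.numeric(tok[-1]))
  }
  if (length(y) != npoints) {
    stop("read_jcampdx: found ", length(y), " ordinates but NPOINTS=",
         npoints, " (truncated file?)", call. = FALSE)
  }
  wn <- firstx + (seq_len(npoints) - 1) * deltax
  ftir_spectrum(wn, y * yfactor, patient_id = patient_id, well = well,
                replicate = replicate, role = role)
}

manifest_columns <- c("patient_id", "cohort", "label", "tumour_type",
                      "who_grade", "age", "sex")

validate_manifest <- function(manifest) {
  missing <- setdiff(manifest_columns, names(manifest))
  if (length(missing)) {
    stop("manifest: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(manifest$patient_id)) {
    stop("manifest: duplicate patient_id(s): ",
         paste(unique(manifest$patient_id[duplicated(manifest$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- manifest$label == "non-cancer" & manifest$tumour_type != ""
  if (any(bad)) {
    stop("manifest: non-cancer patients must have empty tumour_type (",
         paste(manifest$patient_id[bad], collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(manifest)
}

#' Load a cohort manifest CSV
#'
#' Expects the exact columns patient_id, cohort, label, tumour_type,
#' who_grade, age, sex; validates uniqueness of patient ids and that
#' tumour types are empty exactly for non-cancer patients.
#'
#' @param path Manifest CSV path.
#' @return A validated manifest data.frame.
#' @export
load_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  missing <- setdiff(manifest_columns, names(m))
  if (length(missing)) {
    stop("load_manifest: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m$age <- as.numeric(m$age)
  m$tumour_type[is.na(m$tumour_type)] <- ""
  m$who_grade[is.na(m$who_grade)] <- ""
  validate_manifest(m[manifest_columns])
}

#' Write a cohort manifest CSV
#'
#' @param manifest A manifest data.frame (see [load_manifest()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest[manifest_columns], path, row.names = FALSE)
  invisible(path)
}
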