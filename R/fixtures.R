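#' Built-in cohort manifests
#'
#' Expands the packaged cohort count tables into per-patient manifests.
#'
#' `"retrospective_table1"` reproduces the published 724-patient
#' retrospective brain-cancer cohort breakdown: 487 cancer patients across
#' 20 tumour-type rows (260 glioblastoma multiforme down to single-case
#' types) and 237 controls, with sex counts matching the published
#' demographics (cancer 280 M / 207 F; control 149 M / 84 F).
#'
#' `"prospective_interim"` reproduces the first interim analysis of the
#' prospective validation cohort: 104 patients, of whom 12 had cancer
#' (4 glioblastoma multiforme, 3 anaplastic astrocytoma,
#' 2 oligoastrocytoma, 1 medulloblastoma, 1 ependymoma, 1 gliosarcoma)
#' and 92 did not.
#'
#' Class, tumour-type and sex counts come from the published tables;
#' per-patient ages (evenly spaced over the published ranges) and the
#' assignment of sex to individual ids are synthetic, deterministic
#' placeholders — the patient-level data were never deposited.
#'
#' @param name `"retrospective_table1"` or `"prospective_interim"`.
#' @return A manifest data.frame (see [load_manifest()] for columns).
#' @examples
#' m <- builtin_fixture("retrospective_table1")
#' table(m$label) # 487 cancer, 237 non-cancer
#' @export
builtin_fixture <- function(name = c("retrospective_table1",
                                     "prospective_interim")) {
  name <- match.arg(name)
  file <- switch(name,
    retrospective_table1 = "retrospective_cohort_counts.csv",
    prospective_interim = "prospective_interim_counts.csv"
  )
  path <- system.file("extdata", file, package = "spectriage",
                      mustWork = TRUE)
  counts <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(count = "integer"))
  counts$tumour_type[is.na(counts$tumour_type)] <- ""
  counts$who_grade[is.na(counts$who_grade)] <- ""

  label <- rep(counts$label, counts$count)
  tumour <- rep(counts$tumour_type, counts$count)
  grade <- rep(counts$who_grade, counts$count)
  n <- length(label)
  prefix <- if (name == "retrospective_table1") "R" else "P"
  ids <- sprintf("%s%04d", prefix, seq_len(n))

  if (name == "retrospective_table1") {
    cohort <- "retrospective"
    # published demographics: sex counts per class, age ranges per class
    sex <- character(n)
    sex[label == "cancer"] <- rep(c("M", "F"), c(280, 207))
    # the published control sex counts (149 M / 84 F) sum to 233, not
    # 237; the four unaccounted controls are assigned F deterministically
    sex[label == "non-cancer"] <-
      rep(c("M", "F"), c(149, sum(label == "non-cancer") - 149))
    age <- numeric(n)
    age[label == "cancer"] <-
      round(seq(21, 96, length.out = sum(label == "cancer")))
    age[label == "non-cancer"] <-
      round(seq(19, 69, length.out = sum(label == "non-cancer")))
  } else {
    cohort <- "prospective"
    sex <- rep(c("M", "F"), length.out = n)
    age <- round(seq(18, 85, length.out = n))
  }

  validate_manifest(data.frame(
    patient_id = ids, cohort = cohort, label = label,
    tumour_type = tumour, who_grade = grade, age = age, sex = sex,
    stringsAsFactors = FALSE
  ))
}

#' Cohort count table backing a built-in fixture
#'
#' Returns the packaged per-tumour-type count table itself (rather than
#' the expanded manifest), useful for checking fixture integrity or for
#' driving [cohort_design()] with the published tumour mix.
#'
#' @inheritParams builtin_fixture
#' @return data.frame with columns who_classification, tumour_type,
#'   who_grade, label, count.
#' @export
fixture_counts <- function(name = c("retrospective_table1",
                                    "prospective_interim")) {
  name <- match.arg(name)
  file <- switch(name,
    retrospective_table1 = "retrospective_cohort_counts.csv",
    prospective_interim = "prospective_interim_counts.csv"
  )
  path <- system.file("extdata", file, package = "spectriage",
                      mustWork = TRUE)
  counts <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(count = "integer"))
  counts$tumour_type[is.na(counts$tumour_type)] <- ""
  counts$who_grade[is.na(counts$who_grade)] <- ""
  counts
}
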