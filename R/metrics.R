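#' Per-patient confusion matrix
#'
#' Cancer is the positive class throughout the package.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion_matrix: counts must be non-negative integers",
         call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(truth = c("cancer", "non-cancer"),
                              predicted = c("cancer", "non-cancer")))
  print(m)
  invisible(x)
}

#' Build a confusion matrix from label vectors
#'
#' @param truth,predicted Character vectors of `"cancer"` /
#'   `"non-cancer"` labels, equal length.
#' @param positive The positive-class label (default `"cancer"`).
#' @return A [confusion_matrix()].
#' @export
confusion_from_labels <- function(truth, predicted, positive = "cancer") {
  if (length(truth) != length(predicted)) {
    stop("confusion_from_labels: length mismatch", call. = FALSE)
  }
  confusion_matrix(
    tp = sum(truth == positive & predicted == positive),
    fp = sum(truth != positive & predicted == positive),
    tn = sum(truth != positive & predicted != positive),
    fn = sum(truth == positive & predicted != positive)
  )
}

cm_total <- function(cm) cm$tp + cm$fp + cm$tn + cm$fn

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = (TP + TN) / N` and chance agreement
#' `p_e = [(TP+FN)(TP+FP) + (TN+FP)(TN+FN)] / N^2`. When `p_e = 1`
#' (both margins degenerate) the matrix is perfectly concordant and the
#' limit value 1 is returned. This statistic is the model-selection
#' criterion of the classification protocol, computed per spectrum.
#'
#' @param cm A [confusion_matrix()].
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohens_kappa(confusion_matrix(tp = 40, fp = 5, tn = 45, fn = 10)) # 0.70
#' @export
cohens_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm_total(cm)
  if (n == 0) stop("cohens_kappa: empty confusion matrix", call. = FALSE)
  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fn) * (cm$tp + cm$fp) +
           (cm$tn + cm$fp) * (cm$tn + cm$fn)) / n^2
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Sensitivity and specificity
#'
#' Exact ratios TP/(TP+FN) and TN/(TN+FP). A member whose denominator is
#' zero (no patients of that class) is reported as `NA`, never imputed
#' as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Named list with `sensitivity` and `specificity` proportions.
#' @export
sens_spec <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm_total(cm) == 0) {
    stop("sens_spec: empty confusion matrix", call. = FALSE)
  }
  list(
    sensitivity = if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_,
    specificity = if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else NA_real_
  )
}

#' Round half-up to a fixed number of decimals
#'
#' Plain decimal rounding with ties going up (0.05 -> 0.1), the
#' convention used for reporting percentages; base `round()` rounds
#' half-to-even and would print 92.25 as 92.2.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Format a proportion as a one-decimal percentage
#'
#' @param x Proportion in `[0, 1]`.
#' @return Character, e.g. `"83.3%"`.
#' @export
format_percent <- function(x) {
  ifelse(is.na(x), "NA",
         sprintf("%.1f%%", round_half_up(100 * x, 1)))
}

#' Integer counts consistent with a printed percentage
#'
#' Given a percentage printed to one decimal and the class size `n`,
#' enumerates every count `k` in `0..n` for which `k/n` rounds (half-up,
#' one decimal) to that percentage. With small class sizes the printed
#' value often pins the underlying count uniquely, letting a confusion
#' matrix be reconstructed exactly from reported summary statistics.
#'
#' @param percent Printed percentage (e.g. 83.3).
#' @param n Class size (denominator).
#' @return Integer vector of consistent counts (possibly empty).
#' @examples
#' counts_matching_percent(83.3, 12) # 10 is the only consistent count
#' @export
counts_matching_percent <- function(percent, n) {
  k <- 0:n
  k[round_half_up(100 * k / n, 1) == round_half_up(percent, 1)]
}

#' Rank-based ROC curve and AUC
#'
#' The AUC is computed as the Mann-Whitney concordance probability (ties
#' counted 1/2) via midranks, which equals the trapezoidal area under
#' the empirical ROC curve and is invariant under strictly monotone
#' score transforms. Higher scores must indicate the positive class.
#'
#' @param scores Numeric per-patient scores.
#' @param labels Character labels, `"cancer"` / `"non-cancer"`.
#' @param positive Positive-class label (default `"cancer"`).
#' @return List of class `roc_result`: `auc`, and `curve` (data.frame
#'   with columns threshold, fpr, tpr, stepping through unique scores).
#' @export
roc_auc <- function(scores, labels, positive = "cancer") {
  if (length(scores) != length(labels)) {
    stop("roc_auc: length mismatch", call. = FALSE)
  }
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("roc_auc: both classes must be present", call. = FALSE)
  }
  r <- rank(scores) # midranks handle ties as 1/2
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thresholds,
    fpr = vapply(thresholds, function(t) sum(scores[!pos] >= t) / n0,
                 numeric(1)),
    tpr = vapply(thresholds, function(t) sum(scores[pos] >= t) / n1,
                 numeric(1))
  )
  structure(list(auc = auc, curve = curve), class = "roc_result")
}

#' Average per-iteration diagnostic metrics
#'
#' @param metrics data.frame with one row per resampling iteration and
#'   numeric metric columns (e.g. sensitivity, specificity, auc, kappa).
#' @return List of class `diagnostic_summary`: `per_iteration` (the
#'   input), `mean` and `sd` (named numerics over the metric columns),
#'   `n_iterations`.
#' @export
summarize_iterations <- function(metrics) {
  if (!nrow(metrics)) {
    stop("summarize_iterations: no iterations", call. = FALSE)
  }
  num <- vapply(metrics, is.numeric, logical(1))
  cols <- names(metrics)[num & !(names(metrics) %in% "iteration")]
  m <- vapply(cols, function(cl) mean(metrics[[cl]], na.rm = TRUE),
              numeric(1))
  s <- vapply(cols, function(cl) stats::sd(metrics[[cl]], na.rm = TRUE),
              numeric(1))
  structure(
    list(per_iteration = metrics, mean = m, sd = s,
         n_iterations = nrow(metrics)),
    class = "diagnostic_summary"
  )
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("<diagnostic_summary> %d iteration(s)\n", x$n_iterations))
  for (nm in names(x$mean)) {
    cat(sprintf("  %-12s mean %.4f  sd %.4f\n", nm, x$mean[nm],
                if (is.na(x$sd[nm])) 0 else x$sd[nm]))
  }
  invisible(x)
}

#' Write a diagnostic report to disk
#'
#' Emits a deterministic file set into `out_dir`: `metrics.csv`
#' (per-iteration values), `metrics.json` (cohort sizes, per-iteration
#' values, means and standard deviations at full precision),
#' `confusion.pdf` (pooled per-patient confusion matrix) and, when
#' patient scores are available, `roc.pdf`.
#'
#' @param summary A `resampling_summary` from [run_resampling()].
#' @param out_dir Output directory (created if needed).
#' @param cohort Cohort tag written into the JSON.
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(summary, out_dir, cohort = "retrospective") {
  stopifnot(inherits(summary, "resampling_summary"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("render_report: cannot create ", out_dir, call. = FALSE)
    }
  }
  files <- character(0)
  metrics <- summary$metrics
  ds <- summarize_iterations(metrics)

  f <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, f, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(
    list(cohort = cohort,
         n_patients = summary$n_patients,
         n_cancer = summary$n_cancer,
         n_iterations = ds$n_iterations,
         per_iteration = metrics,
         mean = as.list(ds$mean),
         sd = as.list(ds$sd)),
    f, auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, f)

  pooled <- Reduce(function(a, b) confusion_matrix(
    a$tp + b$tp, a$fp + b$fp, a$tn + b$tn, a$fn + b$fn),
    lapply(summary$iterations, `[[`, "confusion"))
  f <- file.path(out_dir, "confusion.pdf")
  grDevices::pdf(f, width = 4.5, height = 4.5)
  plot_confusion(pooled, main = sprintf("%s cohort (pooled over %d iterations)",
                                        cohort, ds$n_iterations))
  grDevices::dev.off()
  files <- c(files, f)

  scores <- do.call(rbind, lapply(summary$iterations, `[[`, "patients"))
  if (!is.null(scores) && nrow(scores)) {
    roc <- roc_auc(scores$mean_margin, scores$truth)
    f <- file.path(out_dir, "roc.pdf")
    grDevices::pdf(f, width = 4.5, height = 4.5)
    plot(roc$curve$fpr, roc$curve$tpr, type = "s",
         xlab = "1 - specificity", ylab = "sensitivity",
         main = sprintf("Pooled ROC, AUC = %.3f", roc$auc))
    graphics::abline(0, 1, lty = 3)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}

plot_confusion <- function(cm, main = "") {
  m <- matrix(c(cm$tp, cm$fp, cm$fn, cm$tn), 2, 2)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 2), ylim = c(0, 2), asp = 1)
  cols <- matrix(grDevices::grey(1 - 0.7 * m / max(m, 1)), 2, 2)
  for (i in 1:2) for (j in 1:2) {
    graphics::rect(j - 1, 2 - i, j, 3 - i, col = cols[i, j])
    graphics::text(j - 0.5, 2.5 - i, m[i, j],
                   col = if (1 - 0.7 * m[i, j] / max(m, 1) < 0.5) "white"
                         else "black")
  }
  graphics::axis(1, at = c(0.5, 1.5), labels = c("cancer", "non-cancer"),
                 tick = FALSE)
  graphics::axis(2, at = c(1.5, 0.5), labels = c("cancer", "non-cancer"),
                 tick = FALSE, las = 1)
  graphics::title(main = main, xlab = "predicted", ylab = "truth")
}
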