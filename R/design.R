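#' Design parameters for a precision-based diagnostic accuracy study
#'
#' Parameters for sizing a prospective cohort so that sensitivity or
#' specificity is estimated to within a stated absolute precision. Only
#' patients of the relevant class contribute to each metric — cancer
#' patients to sensitivity, non-cancer to specificity — so at low
#' disease prevalence the total recruitment for sensitivity is inflated
#' dramatically relative to the effective sample size.
#'
#' @param metric_kind `"sensitivity"` or `"specificity"`.
#' @param assumed_metric Working value of the metric being estimated
#'   (proportion in (0, 1)).
#' @param precision Half-width `d` of the desired estimate interval
#'   (absolute proportion).
#' @param prevalence Disease prevalence in the recruited population.
#' @param power Nominal power; carried as documentation for the plain
#'   precision bound (default 0.80).
#' @param alpha Significance level of the interval (default 0.05).
#' @return An object of class `design_params`.
#' @export
design_params <- function(metric_kind = c("specificity", "sensitivity"),
                          assumed_metric, precision, prevalence,
                          power = 0.80, alpha = 0.05) {
  metric_kind <- match.arg(metric_kind)
  for (fld in c("assumed_metric", "precision", "prevalence", "power",
                "alpha")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v >= 1) {
      stop("design_params: '", fld, "' must lie in (0, 1)", call. = FALSE)
    }
  }
  if (precision >= assumed_metric - 1e-12 ||
      precision >= 1 - assumed_metric - 1e-12) {
    warning("design_params: precision reaches the [0, 1] boundary of the ",
            "assumed metric; the normal-approximation estimate is ",
            "unstable there")
  }
  structure(
    list(metric_kind = metric_kind, assumed_metric = assumed_metric,
         precision = precision, prevalence = prevalence,
         power = power, alpha = alpha),
    class = "design_params"
  )
}

#' Sample size to estimate a proportion to a given precision
#'
#' Normal-approximation (Wald) bound: the effective number of patients of
#' the relevant class is `n_eff = ceil(z^2 m (1 - m) / d^2)` with
#' `z = z_{1-alpha/2}`, `m` the assumed metric and `d` the precision.
#' The total recruitment inflates `n_eff` by the fraction of recruits in
#' the relevant class: `f = prevalence` for sensitivity,
#' `1 - prevalence` for specificity; `total = ceil(n_eff / f)`.
#'
#' @param p A [design_params()] object.
#' @return List of class `sample_size`: `n_effective`, `total`, and the
#'   class fraction `f`.
#' @examples
#' # estimate an assumed 95% specificity to +-5% at 2% prevalence
#' n_for_precision(design_params("specificity", 0.95, 0.05, 0.02))
#' @export
n_for_precision <- function(p) {
  stopifnot(inherits(p, "design_params"))
  z <- stats::qnorm(1 - p$alpha / 2)
  m <- p$assumed_metric
  n_eff <- ceiling(z^2 * m * (1 - m) / p$precision^2)
  f <- if (p$metric_kind == "sensitivity") p$prevalence else
    1 - p$prevalence
  structure(
    list(n_effective = as.integer(n_eff),
         total = as.integer(ceiling(n_eff / f)),
         class_fraction = f),
    class = "sample_size"
  )
}

#' @export
print.sample_size <- function(x, ...) {
  cat(sprintf(
    "<sample_size> %d patients of the relevant class (%.1f%% of recruits) -> %d total recruits\n",
    x$n_effective, 100 * x$class_fraction, x$total))
  invisible(x)
}

#' Interim recalibration of the remaining recruitment
#'
#' The adaptive element of a prospective design: at an interim analysis,
#' replace the assumed metric with the one actually observed, re-solve
#' the precision bound, and subtract the recruits already enrolled. The
#' result is floored at zero (a study can be ahead of its requirement).
#'
#' @param observed A [confusion_matrix()] from the interim data.
#' @param p A [design_params()]; its `assumed_metric` is ignored in
#'   favour of the observed value.
#' @return List of class `interim_update`: `observed_metric`,
#'   `required_total`, `recruited`, `remaining`.
#' @export
interim_update <- function(observed, p) {
  stopifnot(inherits(observed, "confusion_matrix"),
            inherits(p, "design_params"))
  n_obs <- cm_total(observed)
  if (n_obs == 0) {
    stop("interim_update: empty interim confusion matrix", call. = FALSE)
  }
  ss <- sens_spec(observed)
  m <- if (p$metric_kind == "sensitivity") ss$sensitivity else
    ss$specificity
  if (is.na(m)) {
    stop("interim_update: ", p$metric_kind,
         " is undefined on the observed matrix", call. = FALSE)
  }
  m <- min(max(m, 1e-6), 1 - 1e-6) # keep the variance term defined
  p2 <- design_params(p$metric_kind, m, p$precision, p$prevalence,
                      p$power, p$alpha)
  req <- n_for_precision(p2)
  structure(
    list(observed_metric = m, required_total = req$total,
         n_effective = req$n_effective, recruited = n_obs,
         remaining = max(0L, req$total - n_obs)),
    class = "interim_update"
  )
}

#' @export
print.interim_update <- function(x, ...) {
  cat(sprintf(
    "<interim_update> observed %.3f -> %d total required, %d recruited, %d remaining\n",
    x$observed_metric, x$required_total, x$recruited, x$remaining))
  invisible(x)
}
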