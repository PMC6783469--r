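#' Resampling evaluation plan
#'
#' The evaluation protocol as data: patients are split 70/30 into
#' training and test portions (stratified by class), hyperparameters are
#' tuned by patient-disjoint 5-fold cross-validation on the training
#' portion, and the whole procedure is repeated 51 times with different
#' random splits for summative statistics.
#'
#' @param train_fraction Proportion of patients in the training portion
#'   (default 0.70).
#' @param n_iterations Number of independent split/tune/test repetitions
#'   (default 51).
#' @param cv_folds Cross-validation folds used during tuning (default 5).
#' @param stratified Stratify splits by class label (default TRUE).
#' @param base_seed Base seed; iteration `i` uses `base_seed + i`.
#' @return An object of class `resampling_plan`.
#' @export
resampling_plan <- function(train_fraction = 0.70, n_iterations = 51,
                            cv_folds = 5, stratified = TRUE,
                            base_seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("resampling_plan: 'train_fraction' must be in (0, 1)",
         call. = FALSE)
  }
  if (n_iterations < 1) {
    stop("resampling_plan: 'n_iterations' must be >= 1", call. = FALSE)
  }
  if (cv_folds < 2) {
    stop("resampling_plan: 'cv_folds' must be >= 2", call. = FALSE)
  }
  structure(
    list(train_fraction = train_fraction,
         n_iterations = as.integer(n_iterations),
         cv_folds = as.integer(cv_folds),
         stratified = isTRUE(stratified),
         base_seed = as.integer(base_seed)),
    class = "resampling_plan"
  )
}

#' Patient-level train/test split for one iteration
#'
#' Splitting is always at the patient level — a patient's nine replicate
#' spectra travel together, so no patient can appear in both portions.
#' With stratification, each class contributes
#' `round(train_fraction * class size)` patients to the training portion.
#'
#' @param manifest Cohort manifest data.frame with `patient_id` and
#'   `label` columns.
#' @param plan A [resampling_plan()].
#' @param iteration Iteration index (1-based); fixes the split seed as
#'   `base_seed + iteration`.
#' @return List of class `split_plan`: `train_ids`, `test_ids`, `seed`,
#'   `iteration`.
#' @export
split_patients <- function(manifest, plan, iteration = 1L) {
  stopifnot(inherits(plan, "resampling_plan"))
  classes <- unique(manifest$label)
  if (length(classes) < 2) {
    stop("split_patients: manifest must contain both classes",
         call. = FALSE)
  }
  tab <- table(manifest$label)
  if (any(tab < 2)) {
    stop("split_patients: class(es) with fewer than 2 patients: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  seed <- plan$base_seed + as.integer(iteration)
  set.seed(seed)
  train_ids <- character(0)
  if (plan$stratified) {
    for (cls in sort(classes)) {
      ids <- manifest$patient_id[manifest$label == cls]
      n_train <- round(plan$train_fraction * length(ids))
      train_ids <- c(train_ids, sample(ids, n_train))
    }
  } else {
    train_ids <- sample(manifest$patient_id,
                        round(plan$train_fraction * nrow(manifest)))
  }
  structure(
    list(train_ids = sort(train_ids),
         test_ids = sort(setdiff(manifest$patient_id, train_ids)),
         seed = seed, iteration = as.integer(iteration)),
    class = "split_plan"
  )
}

#' Patient-disjoint cross-validation folds
#'
#' Assigns whole patients to folds (stratified by label), so replicate
#' spectra of one patient never straddle a fold boundary — spectrum-level
#' folds would leak the replicate structure into validation scores.
#'
#' @param patient_ids Patients to fold.
#' @param labels Class label per patient (parallel to `patient_ids`).
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Named integer vector: fold index (1..k) per patient id.
#' @export
make_cv_folds <- function(patient_ids, labels, k, seed = 1L) {
  stopifnot(length(patient_ids) == length(labels))
  if (k < 2 || k > length(patient_ids)) {
    stop("make_cv_folds: need 2 <= k <= number of patients", call. = FALSE)
  }
  set.seed(seed)
  fold <- stats::setNames(integer(length(patient_ids)), patient_ids)
  for (cls in sort(unique(labels))) {
    ids <- patient_ids[labels == cls]
    fold[sample(ids)] <- rep_len(seq_len(k), length(ids))
  }
  fold
}

#' Hyperparameter grid for the RBF support-vector classifier
#'
#' @param cost Cost values (default 0.1, 1, 10, 100).
#' @param gamma Kernel width values (default five log steps 1e-3..10).
#' @return data.frame over the full grid, ordered by cost then gamma so
#'   ties in tuning resolve toward the simplest model.
#' @export
svm_grid <- function(cost = c(0.1, 1, 10, 100),
                     gamma = 10^seq(-3, 1)) {
  g <- expand.grid(gamma = sort(gamma), cost = sort(cost))[, 2:1]
  g[order(g$cost, g$gamma), , drop = FALSE]
}

patient_labels <- function(manifest, ids) {
  lab <- manifest$label[match(ids, manifest$patient_id)]
  if (anyNA(lab)) {
    stop("patient(s) missing from manifest: ",
         paste(ids[is.na(lab)], collapse = ", "), call. = FALSE)
  }
  lab
}

spectrum_labels <- function(features, manifest) {
  patient_labels(manifest, features$patient_id)
}

fit_svm <- function(x, y, cost, gamma) {
  e1071::svm(x, factor(y, levels = c("cancer", "non-cancer")),
             kernel = "radial", cost = cost, gamma = gamma, scale = FALSE)
}

svm_predict_margin <- function(model, x) {
  p <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  margin <- as.numeric(dv[, 1])
  # libsvm orients the decision value toward the first class of the
  # column label; flip so that positive margin always means cancer
  if (!startsWith(colnames(dv)[1], "cancer")) margin <- -margin
  list(label = as.character(p), margin = margin)
}

#' Tune and train the spectrum classifier on a training split
#'
#' Grid search over an RBF support-vector machine, selecting the grid
#' point with the highest mean per-spectrum Cohen's kappa across
#' patient-disjoint cross-validation folds, then refitting on the full
#' training portion. Ties resolve to the smallest cost, then the
#' smallest gamma (the simplest model). Only spectra of training-split
#' patients are reachable during tuning; the function fails hard if the
#' supplied fold assignment mentions any patient outside the split.
#'
#' @param features A `feature_table` (see [preprocess_collection()])
#'   covering at least the training patients.
#' @param manifest Cohort manifest supplying the class labels.
#' @param split A `split_plan` from [split_patients()].
#' @param grid Hyperparameter grid, as from [svm_grid()].
#' @param cv_folds Number of folds (default 5); ignored when `folds` is
#'   supplied.
#' @param folds Optional named fold vector from [make_cv_folds()];
#'   derived from the split seed when omitted.
#' @return List of class `tuned_classifier`: the fitted model, chosen
#'   `cost` and `gamma`, the per-grid-point CV table (`cv_results`),
#'   training kappa, feature column names, training patient ids and fold
#'   assignment.
#' @export
tune_and_train <- function(features, manifest, split, grid = svm_grid(),
                           cv_folds = 5, folds = NULL) {
  stopifnot(inherits(features, "feature_table"),
            inherits(split, "split_plan"))
  if (!all(c("cost", "gamma") %in% names(grid))) {
    stop("tune_and_train: grid needs 'cost' and 'gamma' columns",
         call. = FALSE)
  }
  train_rows <- features$patient_id %in% split$train_ids
  if (!any(train_rows)) {
    stop("tune_and_train: no spectra for training patients", call. = FALSE)
  }
  tf <- features[train_rows, , drop = FALSE]
  class(tf) <- class(features)
  attr(tf, "feature_cols") <- attr(features, "feature_cols")
  x <- feature_matrix(tf)
  y <- spectrum_labels(tf, manifest)

  if (is.null(folds)) {
    folds <- make_cv_folds(split$train_ids,
                           patient_labels(manifest, split$train_ids),
                           cv_folds, seed = derive_seed(split$seed, 1))
  }
  if (length(setdiff(names(folds), split$train_ids)) ||
      length(intersect(names(folds), split$test_ids))) {
    stop("tune_and_train: leakage - fold assignment reaches beyond the ",
         "training split", call. = FALSE)
  }
  k <- max(folds)
  fold_of_row <- folds[tf$patient_id]

  cv_kappa <- matrix(NA_real_, nrow = nrow(grid), ncol = k)
  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(k)) {
      hold <- fold_of_row == f
      if (!any(hold) || !any(!hold)) next
      fit <- fit_svm(x[!hold, , drop = FALSE], y[!hold],
                     grid$cost[g], grid$gamma[g])
      pred <- svm_predict_margin(fit, x[hold, , drop = FALSE])$label
      cv_kappa[g, f] <- cohens_kappa(confusion_from_labels(y[hold], pred))
    }
  }
  mean_kappa <- rowMeans(cv_kappa, na.rm = TRUE)
  best <- which.max(mean_kappa) # grid pre-ordered: ties -> simplest model
  model <- fit_svm(x, y, grid$cost[best], grid$gamma[best])
  train_pred <- svm_predict_margin(model, x)$label
  structure(
    list(model = model,
         cost = grid$cost[best], gamma = grid$gamma[best],
         cv_results = cbind(grid, mean_cv_kappa = mean_kappa),
         train_kappa = cohens_kappa(confusion_from_labels(y, train_pred)),
         feature_cols = attr(features, "feature_cols"),
         train_patient_ids = split$train_ids,
         folds = folds),
    class = "tuned_classifier"
  )
}

#' Per-spectrum predictions from a tuned classifier
#'
#' @param classifier A `tuned_classifier` (or stub classifier).
#' @param features A `feature_table`; its feature columns must match the
#'   training dimension exactly.
#' @param manifest Required for stub classifiers only (they corrupt the
#'   true label at a fixed rate); ignored by real models, which never see
#'   labels at prediction time.
#' @return data.frame: patient_id, well, replicate, label, margin.
#' @export
predict_spectra <- function(classifier, features, manifest = NULL) {
  UseMethod("predict_spectra")
}

#' @export
predict_spectra.tuned_classifier <- function(classifier, features,
                                             manifest = NULL) {
  stopifnot(inherits(features, "feature_table"))
  if (!identical(attr(features, "feature_cols"), classifier$feature_cols)) {
    stop("predict_spectra: feature dimension/grid mismatch with the ",
         "training data", call. = FALSE)
  }
  pm <- svm_predict_margin(classifier$model, feature_matrix(features))
  data.frame(patient_id = features$patient_id, well = features$well,
             replicate = features$replicate,
             label = pm$label, margin = pm$margin,
             stringsAsFactors = FALSE)
}

#' Stub per-spectrum classifier with known accuracy
#'
#' A test harness device: predicts each spectrum's true class
#' independently with probability `accuracy`, using the current RNG
#' state. It lets the resampling and consensus machinery be exercised
#' (and its amplification behaviour checked against the binomial closed
#' form) without any model fitting.
#'
#' @param accuracy Per-spectrum probability of a correct label.
#' @return An object of class `stub_classifier`.
#' @export
stub_classifier <- function(accuracy = 0.7) {
  if (!(accuracy >= 0 && accuracy <= 1)) {
    stop("stub_classifier: 'accuracy' must be in [0, 1]", call. = FALSE)
  }
  structure(list(accuracy = accuracy), class = "stub_classifier")
}

#' @export
predict_spectra.stub_classifier <- function(classifier, features,
                                            manifest = NULL) {
  if (is.null(manifest)) {
    stop("predict_spectra: stub classifier needs the manifest for truth",
         call. = FALSE)
  }
  truth <- spectrum_labels(features, manifest)
  correct <- stats::runif(length(truth)) < classifier$accuracy
  other <- ifelse(truth == "cancer", "non-cancer", "cancer")
  label <- ifelse(correct, truth, other)
  data.frame(patient_id = features$patient_id, well = features$well,
             replicate = features$replicate, label = label,
             margin = ifelse(label == "cancer", 1, -1),
             stringsAsFactors = FALSE)
}

#' Consensus (majority) vote over per-spectrum labels
#'
#' The patient-level diagnosis is the majority label among the patient's
#' replicate-spectrum predictions. With the standard nine spectra a tie
#' is impossible; after quality-control drops an even count can tie, and
#' ties resolve to cancer — a triage tool prefers a false referral over
#' a missed tumour.
#'
#' @param labels Character vector of `"cancer"` / `"non-cancer"`.
#' @return `"cancer"` or `"non-cancer"`.
#' @export
consensus_vote <- function(labels) {
  if (!length(labels)) {
    stop("consensus_vote: no labels", call. = FALSE)
  }
  n_cancer <- sum(labels == "cancer")
  if (2 * n_cancer >= length(labels)) "cancer" else "non-cancer"
}

consensus_by_patient <- function(preds, truth_lookup = NULL) {
  ids <- unique(preds$patient_id)
  out <- data.frame(
    patient_id = ids,
    consensus_label = vapply(ids, function(id)
      consensus_vote(preds$label[preds$patient_id == id]), character(1)),
    consensus_score = vapply(ids, function(id)
      mean(preds$label[preds$patient_id == id] == "cancer"), numeric(1)),
    mean_margin = vapply(ids, function(id)
      mean(preds$margin[preds$patient_id == id]), numeric(1)),
    n_spectra_used = vapply(ids, function(id)
      sum(preds$patient_id == id), integer(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (!is.null(truth_lookup)) {
    out$truth <- truth_lookup[out$patient_id]
  }
  out
}

#' Run the full resampled evaluation protocol
#'
#' For each of `plan$n_iterations` iterations: split patients 70/30,
#' build patient-disjoint CV folds, tune and train the classifier on the
#' training portion (or apply a stub), predict every test-patient
#' spectrum, take per-patient consensus votes, and record the per-patient
#' confusion matrix and metrics. Iteration failures propagate; nothing is
#' silently skipped.
#'
#' @param features A `feature_table` covering every manifest patient.
#' @param manifest Cohort manifest.
#' @param plan A [resampling_plan()].
#' @param trainer `"svm"` (default) or a [stub_classifier()].
#' @param grid Hyperparameter grid for the SVM trainer.
#' @param keep_models Retain each iteration's fitted model (needed for
#'   ensemble external prediction; default TRUE).
#' @return List of class `resampling_summary`: `plan`, `iterations`
#'   (per-iteration records with split, folds, confusion, per-patient
#'   table, model), `metrics` (data.frame: iteration, sensitivity,
#'   specificity, auc, kappa, patient_accuracy, spectrum_accuracy),
#'   `n_patients`, `n_cancer`, `train_ids_used`.
#' @export
run_resampling <- function(features, manifest, plan = resampling_plan(),
                           trainer = "svm", grid = svm_grid(),
                           keep_models = TRUE) {
  stopifnot(inherits(features, "feature_table"),
            inherits(plan, "resampling_plan"))
  missing_pat <- setdiff(manifest$patient_id, features$patient_id)
  if (length(missing_pat)) {
    stop("run_resampling: manifest patients without spectra: ",
         paste(utils::head(missing_pat, 5), collapse = ", "),
         if (length(missing_pat) > 5) ", ...", call. = FALSE)
  }
  truth_lookup <- stats::setNames(manifest$label, manifest$patient_id)
  iterations <- vector("list", plan$n_iterations)
  metrics <- vector("list", plan$n_iterations)

  for (it in seq_len(plan$n_iterations)) {
    split <- split_patients(manifest, plan, it)
    folds <- make_cv_folds(split$train_ids,
                           patient_labels(manifest, split$train_ids),
                           plan$cv_folds, seed = derive_seed(split$seed, 1))
    set.seed(derive_seed(split$seed, 2)) # stream for stochastic trainers
    if (inherits(trainer, "stub_classifier")) {
      model <- trainer
    } else if (identical(trainer, "svm")) {
      model <- tune_and_train(features, manifest, split, grid = grid,
                              cv_folds = plan$cv_folds, folds = folds)
    } else {
      stop("run_resampling: unknown trainer", call. = FALSE)
    }
    test_rows <- features$patient_id %in% split$test_ids
    tf <- features[test_rows, , drop = FALSE]
    class(tf) <- class(features)
    attr(tf, "feature_cols") <- attr(features, "feature_cols")
    preds <- predict_spectra(model, tf, manifest)
    patients <- consensus_by_patient(preds, truth_lookup)
    cm <- confusion_from_labels(patients$truth, patients$consensus_label)
    ss <- sens_spec(cm)
    auc <- roc_auc(patients$mean_margin, patients$truth)$auc
    spectrum_acc <- mean(preds$label == truth_lookup[preds$patient_id])

    iterations[[it]] <- list(
      iteration = it, split = split, folds = folds,
      model = if (keep_models) model else NULL,
      confusion = cm, patients = patients
    )
    metrics[[it]] <- data.frame(
      iteration = it,
      sensitivity = ss$sensitivity, specificity = ss$specificity,
      auc = auc, kappa = cohens_kappa(cm),
      patient_accuracy = mean(patients$consensus_label == patients$truth),
      spectrum_accuracy = spectrum_acc
    )
  }
  summary <- structure(
    list(plan = plan, iterations = iterations,
         metrics = do.call(rbind, metrics),
         n_patients = nrow(manifest),
         n_cancer = sum(manifest$label == "cancer"),
         train_ids_used = sort(unique(unlist(
           lapply(iterations, function(z) z$split$train_ids))))),
    class = "resampling_summary"
  )
  assert_no_leakage(summary)
  summary
}

#' @export
print.resampling_summary <- function(x, ...) {
  ds <- summarize_iterations(x$metrics)
  cat(sprintf(
    "<resampling_summary> %d iteration(s), %d patients (%d cancer)\n",
    ds$n_iterations, x$n_patients, x$n_cancer))
  cat(sprintf(
    "  mean sensitivity %.3f, specificity %.3f, AUC %.3f\n",
    ds$mean["sensitivity"], ds$mean["specificity"], ds$mean["auc"]))
  invisible(x)
}

#' Prove that no training/test or external leakage occurred
#'
#' Walks every iteration of a resampling summary and asserts: the train
#' and test id sets are disjoint and cover the cohort; the CV fold
#' assignment mentions exactly the training patients; and, when external
#' ids are supplied, none of them ever appeared in any training fold.
#' Violations raise an error naming the iteration.
#'
#' @param summary A `resampling_summary`.
#' @param external_ids Optional patient ids of an external cohort.
#' @return TRUE, invisibly.
#' @export
assert_no_leakage <- function(summary, external_ids = NULL) {
  stopifnot(inherits(summary, "resampling_summary"))
  cohort <- summary$n_patients
  for (rec in summary$iterations) {
    sp <- rec$split
    if (length(intersect(sp$train_ids, sp$test_ids))) {
      stop("leakage: train/test overlap at iteration ", rec$iteration,
           call. = FALSE)
    }
    if (length(sp$train_ids) + length(sp$test_ids) != cohort) {
      stop("leakage: split does not cover the cohort at iteration ",
           rec$iteration, call. = FALSE)
    }
    if (!setequal(names(rec$folds), sp$train_ids)) {
      stop("leakage: CV folds are not exactly the training patients at ",
           "iteration ", rec$iteration, call. = FALSE)
    }
    if (!is.null(external_ids) &&
        length(intersect(external_ids, sp$train_ids))) {
      stop("leakage: external patient id(s) found in training fold at ",
           "iteration ", rec$iteration, ": ",
           paste(utils::head(intersect(external_ids, sp$train_ids), 5),
                 collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Blind prediction of an external cohort
#'
#' Applies every retained iteration model (the ensemble; or one supplied
#' `tuned_classifier`) to the spectra of an external cohort, pooling all
#' per-spectrum predictions per patient into a single consensus vote.
#' Blinding is enforced by the interface: class labels are never read —
#' the caller compares the returned predictions with truth afterwards,
#' via the metrics functions. Any external patient id that appeared in a
#' training fold is an error.
#'
#' @param fit A `resampling_summary` with retained models, or a single
#'   `tuned_classifier`.
#' @param external_features A `feature_table` for the external cohort.
#' @return data.frame of class `prediction_record`: patient_id,
#'   consensus_label, consensus_score (fraction of predictions voting
#'   cancer), mean_margin, n_spectra_used (pooled over models).
#' @export
predict_external <- function(fit, external_features) {
  stopifnot(inherits(external_features, "feature_table"))
  models <- if (inherits(fit, "resampling_summary")) {
    got <- lapply(fit$iterations, `[[`, "model")
    if (any(vapply(got, is.null, logical(1)))) {
      stop("predict_external: summary was run with keep_models = FALSE",
           call. = FALSE)
    }
    got
  } else if (inherits(fit, "tuned_classifier")) {
    list(fit)
  } else {
    stop("predict_external: 'fit' must be a resampling_summary or ",
         "tuned_classifier", call. = FALSE)
  }
  train_ids <- sort(unique(unlist(lapply(models, `[[`,
                                         "train_patient_ids"))))
  overlap <- intersect(unique(external_features$patient_id), train_ids)
  if (length(overlap)) {
    stop("predict_external: blinding violation - external patient id(s) ",
         "appear in the training cohort: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  preds <- do.call(rbind, lapply(models, function(m)
    predict_spectra(m, external_features)))
  out <- consensus_by_patient(preds)
  class(out) <- c("prediction_record", "data.frame")
  out
}
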