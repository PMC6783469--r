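test_that("patient splits are stratified, disjoint and reproducible", {
  m <- builtin_fixture("retrospective_table1")
  plan <- resampling_plan()
  sp <- split_patients(m, plan, 1)
  # round(0.7 * 487) = 341 cancer + round(0.7 * 237) = 166 control
  expect_length(sp$train_ids, 507)
  expect_length(sp$test_ids, 217)
  lab <- m$label[match(sp$train_ids, m$patient_id)]
  expect_equal(sum(lab == "cancer"), 341)
  expect_equal(sum(lab == "non-cancer"), 166)
  # same iteration twice -> identical plan; disjoint across all iterations
  expect_identical(split_patients(m, plan, 1), sp)
  for (it in 1:51) {
    s <- split_patients(m, plan, it)
    expect_length(intersect(s$train_ids, s$test_ids), 0)
    expect_setequal(c(s$train_ids, s$test_ids), m$patient_id)
  }
  # different iterations give different splits
  expect_false(identical(split_patients(m, plan, 2)$train_ids,
                         sp$train_ids))
  one_class <- m[m$label == "cancer", ]
  expect_error(split_patients(one_class, plan, 1), "both classes")
})

test_that("CV folds are a patient-disjoint stratified partition", {
  m <- toy_manifest(20, 15)
  folds <- make_cv_folds(m$patient_id, m$label, 5, seed = 3)
  expect_setequal(names(folds), m$patient_id)
  expect_equal(sort(unique(folds)), 1:5)
  # stratification: each fold holds 4 cancer and 3 control patients
  for (f in 1:5) {
    ids <- names(folds)[folds == f]
    expect_equal(sum(m$label[match(ids, m$patient_id)] == "cancer"), 4)
    expect_equal(sum(m$label[match(ids, m$patient_id)] == "non-cancer"), 3)
  }
  expect_identical(folds, make_cv_folds(m$patient_id, m$label, 5, seed = 3))
  expect_error(make_cv_folds(m$patient_id, m$label, 1), "2 <= k")
})

test_that("consensus voting is the majority with a cancer tie-break", {
  expect_identical(consensus_vote(rep(c("cancer", "non-cancer"),
                                      c(6, 3))), "cancer")
  expect_identical(consensus_vote(rep("non-cancer", 9)), "non-cancer")
  # a 4/4 tie (after one QC drop) resolves to cancer
  expect_identical(consensus_vote(rep(c("cancer", "non-cancer"),
                                      c(4, 4))), "cancer")
  expect_identical(consensus_vote("non-cancer"), "non-cancer")
  expect_error(consensus_vote(character(0)), "no labels")
})

test_that("grid tuning selects by mean CV kappa with simplest-model ties", {
  sim <- small_cohort()
  ft <- preprocess_collection(sim$spectra)
  plan <- resampling_plan(base_seed = 17)
  split <- split_patients(sim$manifest, plan, 1)

  # a one-point grid must return exactly that point
  g1 <- data.frame(cost = 10, gamma = 0.1)
  fit1 <- tune_and_train(ft, sim$manifest, split, grid = g1)
  expect_equal(fit1$cost, 10)
  expect_equal(fit1$gamma, 0.1)

  # large class effects make the cohort separable: CV kappa above 0.8
  fit <- tune_and_train(ft, sim$manifest, split,
                        grid = svm_grid(cost = c(1, 10),
                                        gamma = c(0.01, 0.1)))
  expect_gt(max(fit$cv_results$mean_cv_kappa), 0.8)
  expect_true(fit$cost %in% c(1, 10))
  # chosen point is the first (simplest) maximiser of the ordered grid
  best <- which.max(fit$cv_results$mean_cv_kappa)
  expect_equal(fit$cost, fit$cv_results$cost[best])
  expect_equal(fit$gamma, fit$cv_results$gamma[best])

  # fold assignments reaching outside the training split fail hard
  bad_folds <- make_cv_folds(sim$manifest$patient_id,
                             sim$manifest$label, 5, seed = 1)
  expect_error(tune_and_train(ft, sim$manifest, split, grid = g1,
                              folds = bad_folds), "leakage")
})

test_that("permuted labels drive CV kappa to its null near zero", {
  sim <- small_cohort()
  ft <- preprocess_collection(sim$spectra)
  plan <- resampling_plan(base_seed = 29)
  g1 <- data.frame(cost = 1, gamma = 0.01)
  kappas <- vapply(1:9, function(rep) {
    perm <- sim$manifest
    set.seed(rep * 13)
    perm$label <- sample(perm$label)
    split <- split_patients(perm, plan, rep)
    fit <- tune_and_train(ft, perm, split, grid = g1)
    fit$cv_results$mean_cv_kappa[1]
  }, numeric(1))
  expect_lt(abs(stats::median(kappas)), 0.15)
})

test_that("spectrum predictions refuse a mismatched feature dimension", {
  sim <- small_cohort()
  ft <- preprocess_collection(sim$spectra)
  split <- split_patients(sim$manifest, resampling_plan(), 1)
  fit <- tune_and_train(ft, sim$manifest, split,
                        grid = data.frame(cost = 1, gamma = 0.01))
  ft8 <- preprocess_collection(sim$spectra,
                               preprocess_config(bin_factor = 8))
  expect_error(predict_spectra(fit, ft8), "dimension")
  preds <- predict_spectra(fit, ft)
  expect_named(preds, c("patient_id", "well", "replicate", "label",
                        "margin"))
  # positive margin always means the cancer side of the hyperplane
  expect_true(all((preds$margin > 0) == (preds$label == "cancer")))
})

test_that("the resampling harness executes the plan it is given", {
  manifest <- toy_manifest(12, 8)
  features <- make_stub_features(manifest)
  plan <- resampling_plan(n_iterations = 7, base_seed = 3)
  res <- run_resampling(features, manifest, plan,
                        trainer = stub_classifier(0.75))
  expect_length(res$iterations, 7)
  expect_equal(nrow(res$metrics), 7)
  expect_s3_class(res$iterations[[1]]$confusion, "confusion_matrix")
  # deterministic: bit-identical on re-run with the same base seed
  res2 <- run_resampling(features, manifest, plan,
                         trainer = stub_classifier(0.75))
  expect_identical(res$metrics, res2$metrics)
  # a patient without spectra is an error, not a silent drop
  expect_error(run_resampling(features[features$patient_id != "T0003", ],
                              manifest, plan,
                              trainer = stub_classifier(0.75)),
               "T0003")
})

test_that("stub classifiers at the extremes pin sensitivity/specificity", {
  manifest <- toy_manifest(15, 15)
  features <- make_stub_features(manifest)
  plan <- resampling_plan(n_iterations = 3, base_seed = 5)
  res <- run_resampling(features, manifest, plan,
                        trainer = stub_classifier(1))
  expect_true(all(res$metrics$sensitivity == 1))
  expect_true(all(res$metrics$specificity == 1))
  # accuracy 0 flips every spectrum: all-cancer patients predicted control
  res0 <- run_resampling(features, manifest, plan,
                         trainer = stub_classifier(0))
  expect_true(all(res0$metrics$sensitivity == 0))
  expect_true(all(res0$metrics$specificity == 0))
})

test_that("consensus amplifies independent per-spectrum accuracy", {
  # binomial majority: patient accuracy sum_{k>=5} C(9,k) p^k (1-p)^(9-k)
  manifest <- toy_manifest(150, 150)
  features <- make_stub_features(manifest)
  plan <- resampling_plan(n_iterations = 8, base_seed = 9)
  for (p in c(0.6, 0.7, 0.8)) {
    res <- run_resampling(features, manifest, plan,
                          trainer = stub_classifier(p))
    votes <- unlist(lapply(res$iterations, function(z)
      z$patients$consensus_label == z$patients$truth))
    acc <- mean(votes)
    closed_form <- sum(dbinom(5:9, 9, p))
    expect_gt(acc, p) # amplification above the per-spectrum rate
    # binomial sampling band: 3.3 sigma around the closed form
    se <- sqrt(closed_form * (1 - closed_form) / length(votes))
    expect_lt(abs(acc - closed_form), 3.3 * se)
  }
})

test_that("external prediction is blind, ensemble-voted and guarded", {
  sim <- small_cohort()
  ft <- preprocess_collection(sim$spectra)
  res <- run_resampling(ft, sim$manifest,
                        resampling_plan(n_iterations = 2, base_seed = 1),
                        grid = data.frame(cost = 1, gamma = 0.01))
  ext <- simulate_cohort(simulation_config(seed = 777),
                         cohort_design(5, 5))
  # external ids collide with the training cohort -> blinding error
  expect_error(predict_external(res, preprocess_collection(ext$spectra)),
               "blinding")
  # rename and predict: ensemble pools 2 models x 9 spectra per patient
  ext$manifest$patient_id <- sub("^C", "XC", ext$manifest$patient_id)
  ext$manifest$patient_id <- sub("^N", "XN", ext$manifest$patient_id)
  extft <- preprocess_collection(ext$spectra)
  extft$patient_id <- paste0("X", extft$patient_id)
  preds <- predict_external(res, extft)
  expect_s3_class(preds, "prediction_record")
  expect_equal(nrow(preds), 10)
  expect_true(all(preds$n_spectra_used == 18))
  # generator exchangeability: external accuracy matches internal range
  truth <- ifelse(grepl("^XC", preds$patient_id), "cancer", "non-cancer")
  expect_gt(mean(preds$consensus_label == truth), 0.8)
  # single-model mode: consensus equals the majority of 9 spectra
  one <- predict_external(res$iterations[[1]]$model, extft)
  expect_true(all(one$n_spectra_used == 9))
  spec_preds <- predict_spectra(res$iterations[[1]]$model, extft)
  for (id in one$patient_id) {
    expect_identical(one$consensus_label[one$patient_id == id],
                     consensus_vote(spec_preds$label[
                       spec_preds$patient_id == id]))
  }
})

test_that("the leakage assertion layer catches fabricated overlap", {
  manifest <- toy_manifest(10, 10)
  features <- make_stub_features(manifest)
  res <- run_resampling(features, manifest,
                        resampling_plan(n_iterations = 5, base_seed = 2),
                        trainer = stub_classifier(0.9))
  expect_true(assert_no_leakage(res))
  expect_true(assert_no_leakage(res, external_ids = c("Z1", "Z2")))
  # an external id that sits in a training fold is flagged
  leaky_id <- res$iterations[[1]]$split$train_ids[1]
  expect_error(assert_no_leakage(res, external_ids = leaky_id),
               "external")
  # corrupt a split and watch the layer object
  broken <- res
  broken$iterations[[2]]$split$test_ids[1] <-
    broken$iterations[[2]]$split$train_ids[1]
  expect_error(assert_no_leakage(broken), "iteration 2")
})
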