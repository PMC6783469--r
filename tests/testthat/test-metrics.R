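test_that("Cohen's kappa matches its defining arithmetic", {
  expect_equal(cohens_kappa(confusion_matrix(50, 0, 50, 0)), 1.0)
  # p_o = 0.85, p_e = 0.5 by hand
  expect_equal(cohens_kappa(confusion_matrix(40, 5, 45, 10)), 0.70)
  # independent margins give exactly zero
  expect_equal(cohens_kappa(confusion_matrix(25, 25, 25, 25)), 0.0)
  expect_error(cohens_kappa(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("kappa equals an independent computation on random matrices", {
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    truth <- sample(c("cancer", "non-cancer"), n, replace = TRUE)
    pred <- sample(c("cancer", "non-cancer"), n, replace = TRUE)
    cm <- confusion_from_labels(truth, pred)
    ours <- cohens_kappa(cm)
    oracle <- e1071::classAgreement(table(
      factor(truth, c("cancer", "non-cancer")),
      factor(pred, c("cancer", "non-cancer"))))$kappa
    if (is.nan(oracle)) next # degenerate margins; ours defines the limit
    expect_equal(ours, oracle, tolerance = 1e-12)
  }
})

test_that("sensitivity and specificity are exact ratios with NA edges", {
  # the unique matrix consistent with the 104-patient interim cohort
  ss <- sens_spec(confusion_matrix(tp = 10, fp = 12, tn = 80, fn = 2))
  expect_equal(ss$sensitivity, 10 / 12)
  expect_equal(ss$specificity, 80 / 92)
  expect_identical(format_percent(ss$sensitivity), "83.3%")
  expect_identical(format_percent(ss$specificity), "87.0%")

  ss <- sens_spec(confusion_matrix(0, 0, 5, 5))
  expect_equal(ss$sensitivity, 0)
  expect_equal(ss$specificity, 1)
  for (k in c(1, 7)) for (m in c(1, 3)) {
    ss <- sens_spec(confusion_matrix(k, m, 0, 0))
    expect_equal(ss$sensitivity, 1)
    expect_equal(ss$specificity, 0)
  }
  # an absent class yields NA, never an imputed zero
  ss <- sens_spec(confusion_matrix(3, 0, 0, 1))
  expect_true(is.na(ss$specificity))
  expect_error(sens_spec(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("the printed confusion matrix is truth x predicted", {
  out <- capture.output(print(confusion_matrix(tp = 10, fp = 12,
                                               tn = 80, fn = 2)))
  # truth = cancer row: 10 predicted cancer, 2 predicted non-cancer
  expect_match(out[grep("^  cancer", out)], "10\\s+2")
  expect_match(out[grep("non-cancer", out)[2]], "12\\s+80")
})

test_that("percentage rounding is half-up and counts reconstruct", {
  expect_equal(round_half_up(92.25, 1), 92.3)
  expect_equal(round_half_up(83.3333, 1), 83.3)
  # printed percentages pin the underlying counts for these class sizes
  expect_identical(counts_matching_percent(83.3, 12), 10L)
  expect_identical(counts_matching_percent(87.0, 92), 80L)
  # reconstruction is consistent for every count at a given n
  for (n in c(12, 92, 217)) {
    for (k in 0:n) {
      pct <- round_half_up(100 * k / n, 1)
      expect_true(k %in% counts_matching_percent(pct, n))
    }
  }
})

test_that("rank-based AUC agrees with pairwise counting and pROC", {
  # perfectly separated
  expect_equal(roc_auc(c(3, 4, 1, 2), c("cancer", "cancer", "non-cancer",
                                        "non-cancer"))$auc, 1.0)
  # 3 of 4 concordant pairs
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.3),
                       c("cancer", "cancer", "non-cancer",
                         "non-cancer"))$auc, 0.75)
  set.seed(21)
  for (i in 1:1000) {
    n1 <- sample(2:12, 1); n0 <- sample(2:12, 1)
    scores <- round(c(rnorm(n1, 0.5), rnorm(n0)), 1) # rounding forces ties
    labels <- rep(c("cancer", "non-cancer"), c(n1, n0))
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  # independent library cross-check on a larger instance
  set.seed(22)
  scores <- c(rnorm(80, 1), rnorm(120))
  labels <- rep(c("cancer", "non-cancer"), c(80, 120))
  ours <- roc_auc(scores, labels)
  expect_equal(ours$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              levels = c("non-cancer", "cancer"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
  # trapezoidal area under our own empirical curve equals the rank AUC
  cv <- ours$curve
  trap <- sum(diff(cv$fpr) * (utils::head(cv$tpr, -1) +
                                utils::tail(cv$tpr, -1)) / 2)
  expect_equal(trap, ours$auc, tolerance = 1e-12)
})

test_that("AUC is invariant under monotone transforms and null near 0.5", {
  set.seed(31)
  scores <- rnorm(100)
  labels <- sample(c("cancer", "non-cancer"), 100, replace = TRUE,
                   prob = c(0.4, 0.6))
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a)
  expect_equal(roc_auc(2 * scores - 7, labels)$auc, a)
  # labels shuffled: null AUC within 3/sqrt(n) of one half
  shuffled <- sample(labels)
  expect_lt(abs(roc_auc(scores, shuffled)$auc - 0.5), 3 / sqrt(100))
  expect_error(roc_auc(scores, rep("cancer", 100)), "both classes")
})

test_that("iteration averaging is the plain arithmetic mean and sd", {
  m <- data.frame(iteration = 1:2, sensitivity = c(0.9, 1.0),
                  specificity = c(0.8, 0.8))
  ds <- summarize_iterations(m)
  expect_equal(unname(ds$mean["sensitivity"]), 0.95)
  expect_equal(unname(ds$mean["specificity"]), 0.8)
  expect_equal(unname(ds$sd["specificity"]), 0)

  set.seed(41)
  m51 <- data.frame(iteration = 1:51, sensitivity = runif(51),
                    specificity = runif(51), auc = runif(51))
  ds <- summarize_iterations(m51)
  for (cl in c("sensitivity", "specificity", "auc")) {
    expect_equal(unname(ds$mean[cl]), sum(m51[[cl]]) / 51,
                 tolerance = 1e-12)
    expect_equal(unname(ds$sd[cl]),
                 sqrt(sum((m51[[cl]] - mean(m51[[cl]]))^2) / 50),
                 tolerance = 1e-12)
  }
  # identical iterations: mean is the value, sd is zero
  ds1 <- summarize_iterations(data.frame(iteration = 1:3,
                                         sensitivity = rep(0.7, 3)))
  expect_equal(unname(ds1$mean["sensitivity"]), 0.7)
  expect_equal(unname(ds1$sd["sensitivity"]), 0)
  expect_error(summarize_iterations(data.frame()), "no iterations")
})

test_that("reports round-trip their numbers at full precision", {
  manifest <- toy_manifest(20, 20)
  features <- make_stub_features(manifest)
  set.seed(5)
  res <- run_resampling(features, manifest,
                        resampling_plan(n_iterations = 3, base_seed = 11),
                        trainer = stub_classifier(0.8))
  out <- withr::local_tempdir()
  files <- render_report(res, out, cohort = "synthetic")
  expect_true(all(file.exists(file.path(out, c("metrics.csv",
                                               "metrics.json",
                                               "confusion.pdf")))))
  back <- utils::read.csv(file.path(out, "metrics.csv"))
  expect_equal(back$sensitivity, res$metrics$sensitivity)
  js <- jsonlite::read_json(file.path(out, "metrics.json"),
                            simplifyVector = TRUE)
  ds <- summarize_iterations(res$metrics)
  expect_equal(js$mean$sensitivity, unname(ds$mean["sensitivity"]))
  expect_equal(js$n_patients, 40)
  expect_equal(js$n_cancer, 20)
})
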