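test_that("accuracy implements (TP+TN)/total on the percent scale", {
  expect_equal(accuracy(tp = 50, tn = 50, fp = 0, fn = 0), 100)
  expect_equal(accuracy(tp = 0, tn = 0, fp = 50, fn = 50), 0)
  expect_equal(accuracy(tp = 30, tn = 20, fp = 10, fn = 40), 50)
  expect_error(accuracy(0, 0, 0, 0), "positive")
  expect_error(accuracy(-1, 2, 3, 4), "non-negative")
})

test_that("a perfectly separating feature reaches 100% accuracy", {
  labels <- rep(c(0, 1), each = 20)
  feature <- matrix(labels + withr::with_seed(1, rnorm(40, sd = 0.01)))
  cv <- run_cv(feature, labels, "svm_linear", seed = 3)
  expect_equal(cv$mean_accuracy, 100)
  expect_equal(cv$fold_accuracies, rep(100, 5))
})

test_that("cross-validation is reproducible from its seed", {
  ds <- simulate_table4(k = 1, n = 100, seed = 4)
  a <- run_cv(true_pair_features(ds), ds$labels, "random_forest", seed = 11)
  b <- run_cv(true_pair_features(ds), ds$labels, "random_forest", seed = 11)
  expect_identical(a$fold_accuracies, b$fold_accuracies)
  d <- run_cv(true_pair_features(ds), ds$labels, "random_forest", seed = 12)
  expect_false(identical(a$fold_accuracies, d$fold_accuracies))
})

test_that("every registered classifier runs and scores the easy dataset", {
  ds <- simulate_table4(k = 1, n = 100, seed = 9)
  z <- true_pair_features(ds)
  for (clf in classifiers()) {
    cv <- run_cv(z, ds$labels, clf, seed = 2)
    expect_true(all(cv$fold_accuracies >= 0 & cv$fold_accuracies <= 100),
                info = clf)
    expect_gt(cv$mean_accuracy, 75)
  }
  expect_error(run_cv(z, ds$labels, "nearest_centroid"), "Unknown classifier")
})

test_that("pure-noise features score near chance", {
  means <- vapply(1:20, function(s) {
    draw <- withr::with_seed(s, {
      list(x = matrix(runif(120 * 4), 120), y = rep(c(0, 1), each = 60))
    })
    run_cv(draw$x, draw$y, "svm_rbf", seed = s)$mean_accuracy
  }, numeric(1))
  expect_gt(mean(means), 40)
  expect_lt(mean(means), 60)
})

test_that("label randomization collapses a perfect predictor to chance", {
  labels <- rep(c(0, 1), each = 30)
  feature <- matrix(labels + withr::with_seed(2, rnorm(60, sd = 0.01)))
  rnd <- label_randomization(feature, labels, "svm_linear", n_reps = 50,
                             seed = 5)
  expect_gte(rnd$mean, 45)
  expect_lte(rnd$mean, 55)
  # real-label accuracy clearly exceeds the randomized mean
  real <- run_cv(feature, labels, "svm_linear", seed = 5)
  expect_gt(real$mean_accuracy, rnd$mean + 3 * rnd$sd)
})

test_that("an identity permutation reproduces the unpermuted analysis", {
  ds <- simulate_table4(k = 1, n = 60, seed = 21)
  z <- true_pair_features(ds)
  rnd <- label_randomization(z, ds$labels, "svm_rbf", seed = 7,
                             permutations = list(seq_along(ds$labels)))
  real <- run_cv(z, ds$labels, "svm_rbf", seed = 7)
  expect_equal(rnd$accuracies, real$mean_accuracy)
})

test_that("randomized accuracy sits below real accuracy on converted features", {
  ds <- simulate_table4(k = 1, n = 100, seed = 13)
  z <- true_pair_features(ds)
  real <- run_cv(z, ds$labels, "svm_rbf", seed = 1)
  rnd <- label_randomization(z, ds$labels, "svm_rbf", n_reps = 10, seed = 1)
  expect_gt(real$mean_accuracy, rnd$mean)
})

test_that("accuracy is invariant to sample order", {
  ds <- simulate_table4(k = 1, n = 80, seed = 17)
  z <- true_pair_features(ds)
  perm <- withr::with_seed(3, sample(nrow(z)))
  a <- run_cv(z, ds$labels, "svm_linear", seed = 6)
  b <- run_cv(z[perm, , drop = FALSE], ds$labels[perm], "svm_linear",
              seed = 6)
  # same data, same folds modulo relabeling: means agree closely
  expect_lt(abs(a$mean_accuracy - b$mean_accuracy), 5)
})

test_that("scheme comparison builds converted features and honours degenerate cases", {
  ds <- simulate_mixed(n_ind = 2, n_syn_pairs = 2, n_noise = 16, n = 200,
                       seed = 31)
  res <- run_scheme_comparison(ds, top_ind = 4, top_syn = 2,
                               conversions = "abs", seed = 1)
  schemes <- unique(res$scheme)
  expect_setequal(schemes,
                  c("Top4_Ind", "Top2_Syn_abs", "Top4_Ind+Top2_Syn_abs"))
  nf <- res |> dplyr::distinct(scheme, n_features)
  expect_equal(nf$n_features[nf$scheme == "Top4_Ind"], 4L)
  expect_equal(nf$n_features[nf$scheme == "Top2_Syn_abs"], 2L)
  expect_equal(nf$n_features[nf$scheme == "Top4_Ind+Top2_Syn_abs"], 6L)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))

  # top_syn = 0 degenerates to the Ind-only scheme
  ind_only <- run_scheme_comparison(ds, top_ind = 4, top_syn = 0, seed = 1)
  expect_equal(unique(ind_only$scheme), "Top4_Ind")
})

test_that("combining individual and synergic features does not hurt", {
  deltas <- vapply(1:8, function(s) {
    ds <- simulate_mixed(n_ind = 2, n_syn_pairs = 2, n_noise = 46, n = 400,
                         seed = 400 + s)
    res <- run_scheme_comparison(ds, top_ind = 2, top_syn = 2,
                                 conversions = "abs", seed = s)
    means <- res |>
      dplyr::group_by(scheme) |>
      dplyr::summarise(acc = mean(accuracy))
    means$acc[means$scheme == "Top2_Ind+Top2_Syn_abs"] -
      means$acc[means$scheme == "Top2_Ind"]
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("nested screening mode runs per-fold selection end to end", {
  ds <- simulate_mixed(n_ind = 2, n_syn_pairs = 1, n_noise = 10, n = 100,
                       seed = 51)
  res <- run_scheme_comparison(ds, top_ind = 2, top_syn = 1,
                               conversions = "abs", seed = 2, nested = TRUE)
  expect_equal(attr(res, "mode"), "nested")
  expect_equal(sort(unique(res$fold)), 1:5)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
  # strong planted signal still detected under nested selection
  comb <- res |>
    dplyr::filter(scheme == "Top2_Ind+Top1_Syn_abs") |>
    dplyr::summarise(acc = mean(accuracy))
  expect_gt(comb$acc, 60)
})

test_that("tidiers return the documented shapes", {
  ds <- simulate_table4(k = 1, n = 60, seed = 61)
  cv <- run_cv(true_pair_features(ds), ds$labels, "svm_rbf", seed = 1)
  td <- tidy(cv)
  expect_equal(names(td), c("fold", "accuracy"))
  expect_equal(nrow(td), 5)
  gl <- glance(cv)
  expect_equal(gl$mean_accuracy, cv$mean_accuracy)

  res <- scan_pairs(ds, "abs", top_n = 1)
  expect_equal(names(glance(res)),
               c("method", "top_n", "n_scored", "n_genes_union", "max_abs_t",
                 "t_variant"))
  s <- interaction_information(runif(100), runif(100),
                               rep(c(0, 1), 50), n_bins = 2)
  expect_equal(nrow(tidy(s)), 4)
})
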