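test_that("train/validation splitting reproduces the cohort sizes", {
  sp <- split_train_validation(445L, 0.75, seed = 1L)
  expect_length(sp$train, 333L)
  expect_length(sp$validation, 112L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_setequal(c(sp$train, sp$validation), 1:445)

  sp4 <- split_train_validation(4L, 0.5, seed = 2L)
  expect_length(sp4$train, 2L)
  expect_length(sp4$validation, 2L)

  expect_identical(split_train_validation(100L, 0.75, seed = 9L),
                   split_train_validation(100L, 0.75, seed = 9L))
  expect_error(split_train_validation(1L, 0.5), "at least 2")
  expect_error(split_train_validation(10L, 1.0), "train_fraction")
})

test_that("sampled configurations stay inside their declared ranges", {
  set.seed(601)
  fams <- c("logistic_regression", "knn", "random_forest",
            "least_angle_regression", "naive_bayes", "gaussian_process",
            "decision_tree", "neural_network")
  for (rep in 1:2000) {
    fam <- sample(fams, 1)
    cfg <- sample_config(fam)
    expect_identical(cfg$family, fam)
    expect_true(cfg$fpr_alpha >= 1e-4 && cfg$fpr_alpha <= 0.5)
    expect_true(cfg$fwer_alpha >= 1e-4 && cfg$fwer_alpha <= 0.5)
    expect_true(cfg$pca_var_fraction >= 0.80 && cfg$pca_var_fraction <= 0.999)
    p <- cfg$family_params
    switch(fam,
      knn = expect_true(p$k >= 1 && p$k <= 50),
      random_forest = expect_true(p$n_trees >= 50 && p$n_trees <= 500 &&
                                    p$max_depth >= 2 && p$max_depth <= 20),
      least_angle_regression = expect_true(p$n_nonzero >= 1 &&
                                             p$n_nonzero <= 50),
      naive_bayes = expect_true(p$var_smoothing >= 1e-12 &&
                                  p$var_smoothing <= 1e-6),
      logistic_regression = expect_true(p$C >= 1e-3 && p$C <= 1e3),
      gaussian_process = expect_true(p$length_scale >= 0.1 &&
                                       p$length_scale <= 100),
      decision_tree = expect_true(p$max_depth >= 1 && p$max_depth <= 20 &&
                                    p$min_leaf >= 1 && p$min_leaf <= 20),
      neural_network = expect_true(p$units %in% c(8, 16, 32, 64) &&
                                     p$l2 >= 1e-6 && p$l2 <= 1e-1))
  }
  set.seed(77); a <- replicate(3, sample_config("knn"), simplify = FALSE)
  set.seed(77); b <- replicate(3, sample_config("knn"), simplify = FALSE)
  expect_identical(a, b)
})

test_that("the preprocessing chain follows its contract", {
  toy <- toy_classification(n = 40, p = 8)
  X <- cbind(toy$X, constant = 5)
  cfg <- structure(list(fpr_alpha = 1, fwer_alpha = 1,
                        pca_var_fraction = 0.999,
                        family = "logistic_regression",
                        family_params = list(C = 1)),
                   class = "pipeline_config")
  tf <- preprocess_fit(X, toy$y, cfg)
  expect_false(tf$failed)
  expect_false("constant" %in% tf$keep_names)  # zero variance dropped

  # robust scaling: median 2.5, IQR 2 -> value 4.5 scales to exactly 1.0
  Xr <- cbind(v = rep(c(1.5, 1.5, 2.5, 3.5, 3.5), 4),
              w = rnorm(20))
  yr <- as.integer(Xr[, "v"] > 2)  # associated with v so selection keeps it
  tfr <- preprocess_fit(Xr, yr, cfg)
  med <- tfr$med["v"]; iqr <- tfr$iqr["v"]
  expect_equal(unname(med), 2.5)
  expect_equal(unname(iqr), 2)
  expect_equal(unname((4.5 - med) / iqr), 1.0)

  # strict selection keeps only genuinely associated features
  cfg_sel <- cfg
  cfg_sel$fpr_alpha <- 1e-4
  cfg_sel$fwer_alpha <- 1e-4
  toy_big <- toy_classification(n = 200, p = 30, informative = 2, delta = 3)
  tfs <- preprocess_fit(toy_big$X, toy_big$y, cfg_sel)
  expect_true(all(c("f1", "f2") %in% tfs$keep_names))
  expect_lte(length(tfs$keep_names), 6L)

  # impossible selection level flags a config failure
  cfg_fail <- cfg
  cfg_fail$fpr_alpha <- 1e-300
  expect_true(preprocess_fit(toy$X, toy$y, cfg_fail)$failed)
})

test_that("PCA keeps the smallest component count reaching the target", {
  set.seed(604)
  n <- 100
  base <- matrix(rnorm(n * 2), n, 2)
  X <- cbind(base %*% matrix(rnorm(8), 2, 4) * 5,
             matrix(rnorm(n * 4, sd = 0.05), n, 4))
  colnames(X) <- paste0("c", 1:8)
  y <- rbinom(n, 1, plogis(base[, 1]))
  cfg <- structure(list(fpr_alpha = 1, fwer_alpha = 1,
                        pca_var_fraction = 0.95, family = "knn",
                        family_params = list(k = 3)),
                   class = "pipeline_config")
  tf <- preprocess_fit(X, y, cfg)
  expect_lte(tf$n_pc, 4L)  # two real factors dominate after scaling
  Z <- preprocess_apply(tf, X)
  expect_equal(ncol(Z), tf$n_pc)
})

test_that("cross-validation scores a perfect separator at AUC 1", {
  set.seed(605)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(sep = y * 10 + rnorm(n, sd = 0.01),
             noise1 = rnorm(n), noise2 = rnorm(n))
  cfg <- structure(list(fpr_alpha = 0.5, fwer_alpha = 0.5,
                        pca_var_fraction = 0.99,
                        family = "logistic_regression",
                        family_params = list(C = 10)),
                   class = "pipeline_config")
  cv <- cross_validate(cfg, X, y, k = 5L, seed = 3L)
  expect_equal(cv$mean_auc, 1.0, tolerance = 1e-8)
  expect_length(cv$fold_aucs, 5L)

  # fold partition covers each sample exactly once as held-out
  fold <- plaqueomics:::.with_seed(3L, plaqueomics:::.stratified_folds(y, 5L))
  expect_equal(sort(unique(fold)), 1:5)
  expect_true(all(tabulate(fold[y == 1], 5) == 6))
})

test_that("no training information leaks into held-out scoring", {
  toy <- toy_classification(n = 80, p = 10, informative = 3)
  sp <- split_train_validation(80L, 0.75, seed = 4L)
  cfg <- structure(list(fpr_alpha = 0.5, fwer_alpha = 0.5,
                        pca_var_fraction = 0.95,
                        family = "logistic_regression",
                        family_params = list(C = 1)),
                   class = "pipeline_config")
  tf <- preprocess_fit(toy$X[sp$train, ], toy$y[sp$train], cfg)
  model <- plaqueomics:::.fit_family("logistic_regression", list(C = 1),
                                     preprocess_apply(tf, toy$X[sp$train, ]),
                                     toy$y[sp$train])
  Zv <- preprocess_apply(tf, toy$X[sp$validation, ])
  s1 <- plaqueomics:::.predict_family(model, Zv)
  s2 <- plaqueomics:::.predict_family(model, Zv)  # labels played no role
  expect_identical(s1, s2)
  # validation scores are a pure function of the training fit and features:
  # recomputing the transform with permuted *validation* labels is impossible
  # by construction (labels never enter preprocess_apply/predict)
  expect_true(!any(c("y", "labels") %in% names(formals(preprocess_apply))))
})

test_that("each model family fits and produces usable scores", {
  toy <- toy_classification(n = 70, p = 6, informative = 2, delta = 2.5)
  Z <- scale(toy$X)
  fams <- list(
    logistic_regression = list(C = 1),
    knn = list(k = 7L),
    random_forest = list(n_trees = 60L, max_depth = 6L),
    least_angle_regression = list(n_nonzero = 3L),
    naive_bayes = list(var_smoothing = 1e-9),
    gaussian_process = list(length_scale = 3),
    decision_tree = list(max_depth = 4L, min_leaf = 3L),
    neural_network = list(units = 8L, l2 = 1e-3))
  set.seed(606)
  for (fam in names(fams)) {
    model <- plaqueomics:::.fit_family(fam, fams[[fam]], Z, toy$y)
    s <- plaqueomics:::.predict_family(model, Z)
    expect_length(s, 70L)
    expect_true(all(is.finite(s)), info = fam)
    expect_gt(plaqueomics:::.fast_auc(s, toy$y), 0.7)
  }
})

test_that("randomized search logs every configuration and is deterministic", {
  toy <- toy_classification(n = 60, p = 8, informative = 3, delta = 2)
  res <- run_search(toy$X, toy$y, iterations = 2L, seed = 11L)
  expect_equal(nrow(res$log), 16L)  # 8 families x 2 iterations
  expect_equal(res$best$mean_cv_auc, max(res$log$mean_cv_auc))
  expect_equal(nrow(res$per_family), 8L)

  res2 <- run_search(toy$X, toy$y, iterations = 2L, seed = 11L)
  expect_identical(res$log, res2$log)
  expect_identical(res$best$family, res2$best$family)

  # validation evaluation returns a proper ROC result
  val <- toy_classification(n = 40, p = 8, informative = 3, delta = 2,
                            seed = 123)
  roc <- evaluate_validation(res, val$X, val$y)
  expect_s3_class(roc, "roc_result")
  expect_true(roc$auc >= 0 && roc$auc <= 1)
  expect_equal(unname(roc$auc), oracle_auc(roc$scores, val$y))
})
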