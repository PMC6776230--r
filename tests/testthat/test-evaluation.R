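test_that("low-attenuation area counts strictly below threshold", {
  les <- voxel_lesion(c(rep(20L, 10), rep(90L, 10)),
                      cbind(0:19, 0L, 0L), c(0.4, 0.4, 0.6))
  expect_equal(low_attenuation_area(les), 10 * 0.16)

  high <- voxel_lesion(rep(35L, 8), cbind(0:7, 0L, 0L), c(0.4, 0.4, 0.6))
  expect_equal(low_attenuation_area(high), 0)

  # a voxel at exactly 30 HU is excluded (strict inequality)
  edge <- voxel_lesion(c(29L, 30L, 31L), cbind(0:2, 0L, 0L), c(1, 1, 1))
  expect_equal(low_attenuation_area(edge), 1)

  # multi-layer slab: mean per-layer area
  slab <- voxel_lesion(rep(10L, 12),
                       as.matrix(expand.grid(0:1, 0:1, 0:2)),
                       c(0.5, 0.5, 1))
  expect_equal(low_attenuation_area(slab), 12 * 0.25 / 3)
})

test_that("mean HU equals the first-order mean", {
  les <- voxel_lesion(c(0L, 10L, 20L), cbind(0:2, 0L, 0L), c(1, 1, 1))
  expect_equal(mean_hu(les), 10)
  expect_equal(mean_hu(voxel_lesion(rep(50L, 7), cbind(0:6, 0L, 0L),
                                    c(1, 1, 1))), 50)
  set.seed(701)
  rl <- random_lesion()
  expect_equal(mean_hu(rl), unname(compute_firstorder(rl)["fo_mean"]))
})

test_that("AUC matches brute-force pair counting with tie handling", {
  r <- auc_delong(c(0.2, 0.8, 0.6, 0.4), c(0, 1, 0, 1))
  expect_equal(r$auc, 0.75)

  perfect <- auc_delong(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$var, 0)

  set.seed(702)
  for (rep in 1:100) {
    n <- sample(8:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq_len(8), n, replace = TRUE)  # many ties
    r <- auc_delong(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  }
  expect_error(auc_delong(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(703)
  scores <- rnorm(50)
  labels <- rbinom(50, 1, 0.4)
  labels[1:2] <- c(0, 1)
  a <- auc_delong(scores, labels)
  b <- auc_delong(exp(2 * scores) + 5, labels)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_equal(a$var, b$var, tolerance = 1e-12)
})

test_that("DeLong variance and CI agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(704)
  for (rep in 1:20) {
    n <- 80
    labels <- c(0, 1, rbinom(n - 2, 1, 0.35))
    scores <- rnorm(n) + labels
    mine <- auc_delong(scores, labels)
    ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    expect_equal(mine$var, as.numeric(pROC::var(ref, method = "delong")),
                 tolerance = 1e-10)
  }
})

test_that("paired DeLong comparison behaves correctly", {
  set.seed(705)
  labels <- c(rep(0, 30), rep(1, 20))
  s1 <- rnorm(50) + labels
  s2 <- rnorm(50) + 0.5 * labels
  a <- auc_delong(s1, labels)
  b <- auc_delong(s2, labels)
  cmp <- compare_delong(a, b)
  expect_false(cmp$degenerate)
  expect_equal(sign(cmp$z), sign(a$auc - b$auc))
  cmp_rev <- compare_delong(b, a)
  expect_equal(cmp_rev$z, -cmp$z, tolerance = 1e-12)
  expect_equal(cmp_rev$p, cmp$p, tolerance = 1e-12)

  # identical ranking (shifted scores): degenerate, no p value
  shifted <- auc_delong(s1 + 100, labels)
  dg <- compare_delong(a, shifted)
  expect_true(dg$degenerate)
  expect_equal(dg$diff, 0)
  expect_true(is.na(dg$p))

  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(labels, s1, quiet = TRUE, direction = "<"),
                        pROC::roc(labels, s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(cmp$p, ref$p.value, tolerance = 1e-10)
})

test_that("the univariate logistic baseline scores validation rows", {
  set.seed(706)
  y_tr <- rep(c(0L, 1L), each = 25)
  y_va <- rep(c(0L, 1L), each = 10)
  # monotone predictor identical to labels: perfect validation AUC
  r <- univariate_logistic_baseline(as.numeric(y_tr), y_tr,
                                    as.numeric(y_va), y_va)
  expect_equal(r$auc, 1)

  # single numeric predictor: AUC equals the raw predictor's AUC
  x_tr <- rnorm(50) + y_tr
  x_va <- rnorm(20) + y_va
  r2 <- univariate_logistic_baseline(x_tr, y_tr, x_va, y_va)
  expect_equal(r2$auc, unname(auc_delong(x_va, y_va)$auc), tolerance = 1e-12)

  # categorical pattern predictor with no class association: AUC near 0.5
  aucs <- replicate(40, {
    pat_tr <- sample(c("homogeneous", "heterogeneous", "napkin-ring"),
                     60, replace = TRUE)
    pat_va <- sample(c("homogeneous", "heterogeneous", "napkin-ring"),
                     40, replace = TRUE)
    yt <- rbinom(60, 1, 0.4); yt[1:2] <- 0:1
    yv <- rbinom(40, 1, 0.4); yv[1:2] <- 0:1
    univariate_logistic_baseline(pat_tr, yt, pat_va, yv)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("chi-square balance test matches the Pearson formula", {
  flat <- chi_square_balance(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  diag <- chi_square_balance(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag$statistic, 40)

  set.seed(707)
  for (rep in 1:25) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    got <- chi_square_balance(tab)
    expect_equal(got$statistic, oracle_chisq(tab), tolerance = 1e-10)
  }
  expect_warning(chi_square_balance(matrix(c(5, 0, 7, 0), 2)), "zero-margin")
})
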