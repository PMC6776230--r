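#' Random train/validation split
#'
#' Draws a uniform random permutation under the given seed; the first
#' `floor(n * train_fraction)` permuted indices form the training set
#' (445 cross sections at 75% give the 333/112 split).
#'
#' @param n number of cases (>= 2).
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with integer vectors `train`, `validation`, plus
#'   `train_fraction` and `seed`.
#' @export
split_train_validation <- function(n, train_fraction = 0.75, seed = 1L) {
  if (n < 2L) stop("need at least 2 cases to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  perm <- .with_seed(seed, sample.int(n))
  n_train <- floor(n * train_fraction)
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[(n_train + 1L):n]),
       train_fraction = train_fraction, seed = as.integer(seed))
}

.model_families <- c("logistic_regression", "knn", "random_forest",
                     "least_angle_regression", "naive_bayes",
                     "gaussian_process", "decision_tree", "neural_network")

.runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Sample one pipeline configuration for a model family
#'
#' Shared preprocessing hyperparameters: the false-positive-rate and
#' family-wise-error selection levels are log-uniform on `[1e-4, 0.5]`, the
#' retained PCA variance fraction uniform on `[0.80, 0.999]`. Family
#' hyperparameters follow the documented per-family grids (see the methods
#' vignette).
#'
#' @param family one of the eight model family names.
#' @return a `pipeline_config` list with `fpr_alpha`, `fwer_alpha`,
#'   `pca_var_fraction`, `family`, `family_params`.
#' @export
sample_config <- function(family = .model_families) {
  family <- match.arg(family)
  params <- switch(family,
    logistic_regression = list(C = .runif_log(1, 1e-3, 1e3)),
    knn = list(k = sample.int(50L, 1L)),
    random_forest = list(n_trees = sample(50:500, 1L),
                         max_depth = sample(2:20, 1L)),
    least_angle_regression = list(n_nonzero = sample.int(50L, 1L)),
    naive_bayes = list(var_smoothing = .runif_log(1, 1e-12, 1e-6)),
    gaussian_process = list(length_scale = .runif_log(1, 0.1, 100)),
    decision_tree = list(max_depth = sample.int(20L, 1L),
                         min_leaf = sample.int(20L, 1L)),
    neural_network = list(units = sample(c(8L, 16L, 32L, 64L), 1L),
                          l2 = .runif_log(1, 1e-6, 1e-1))
  )
  structure(list(fpr_alpha = .runif_log(1, 1e-4, 0.5),
                 fwer_alpha = .runif_log(1, 1e-4, 0.5),
                 pca_var_fraction = stats::runif(1, 0.80, 0.999),
                 family = family, family_params = params),
            class = "pipeline_config")
}

# vectorized one-way ANOVA F-test p-values (two classes) per column
.anova_f_pvalues <- function(X, y) {
  y <- as.integer(y)
  n <- nrow(X)
  n1 <- sum(y == 1L); n0 <- n - n1
  m1 <- colMeans(X[y == 1L, , drop = FALSE])
  m0 <- colMeans(X[y == 0L, , drop = FALSE])
  gm <- (n1 * m1 + n0 * m0) / n
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  sst <- colSums(X^2) - n * gm^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / 1) / (ssw / (n - 2L))
  p <- stats::pf(f, 1, n - 2L, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1      # constant column: no evidence
  p[ssw == 0 & ssb > 0] <- 0       # perfectly separated means
  p
}

#' Fit the preprocessing chain on training data
#'
#' Sequentially: (a) drop zero-variance columns; (b) robust scaling
#' `x -> (x - median) / IQR` per column (zero-IQR columns are dropped);
#' (c) univariate two-sample ANOVA F-tests, keeping features with
#' `p < fpr_alpha` (false-positive-rate test) and then
#' `p < fwer_alpha / m` (Bonferroni family-wise test, `m` the number of
#' features entering that step); (d) PCA retaining the smallest number of
#' components whose cumulative explained variance reaches
#' `pca_var_fraction`. All statistics are estimated on the training rows
#' only; the fitted transform is applied unchanged to held-out data.
#'
#' @param X numeric matrix (training rows x features), with column names.
#' @param y 0/1 training labels.
#' @param config a [sample_config()] result.
#' @return a `fitted_transform` (or a config-failure flag with `failed =
#'   TRUE` when no feature survives selection).
#' @export
preprocess_fit <- function(X, y, config) {
  sc <- .robust_scale_fit(as.matrix(X))
  if (is.null(sc))
    return(structure(list(failed = TRUE), class = "fitted_transform"))
  p <- .anova_f_pvalues(sc$Xs, y)
  sp <- .select_pca_fit(sc$Xs, p, config)
  if (is.null(sp))
    return(structure(list(failed = TRUE), class = "fitted_transform"))
  structure(list(failed = FALSE,
                 keep_names = colnames(sc$Xs)[sp$sel],
                 med = sc$med[sp$sel], iqr = sc$iqr[sp$sel],
                 center = sp$center, rotation = sp$rotation,
                 n_pc = sp$n_pc),
            class = "fitted_transform")
}

# steps (a)-(b): zero-variance exclusion and median/IQR scaling; quantiles
# are type 7 (linear interpolation). Returns NULL when nothing survives.
.robust_scale_fit <- function(X) {
  keep_var <- which(matrixStats_colVars(X) > 0)
  if (length(keep_var) == 0L) return(NULL)
  X <- X[, keep_var, drop = FALSE]
  qs <- .col_quantiles(X, c(0.25, 0.5, 0.75))
  med <- qs[2L, ]
  iqr <- qs[3L, ] - qs[1L, ]
  keep_iqr <- which(iqr > 0)
  if (length(keep_iqr) == 0L) return(NULL)
  X <- X[, keep_iqr, drop = FALSE]
  med <- med[keep_iqr]; iqr <- iqr[keep_iqr]
  names(med) <- names(iqr) <- colnames(X)
  Xs <- sweep(sweep(X, 2L, med), 2L, iqr, "/")
  list(Xs = Xs, med = med, iqr = iqr)
}

# type-7 column quantiles via one radix sort of the whole matrix
.col_quantiles <- function(X, probs) {
  n <- nrow(X); p <- ncol(X)
  ord <- order(rep.int(seq_len(p), rep.int(n, p)), X)
  S <- matrix(X[ord], n, p)
  h <- (n - 1) * probs + 1
  lo <- floor(h); g <- h - lo
  out <- S[lo, , drop = FALSE] * (1 - g) +
    S[pmin(lo + 1, n), , drop = FALSE] * g
  colnames(out) <- colnames(X)
  out
}

# steps (c)-(d): FPR-then-FWER univariate selection and PCA retaining the
# smallest component count reaching the variance target. NULL = no feature
# survives (config failure).
.select_pca_fit <- function(Xs, p, config) {
  sel_fpr <- which(p < config$fpr_alpha)
  if (length(sel_fpr) == 0L) return(NULL)
  m <- length(sel_fpr)
  sel <- sel_fpr[p[sel_fpr] < config$fwer_alpha / m]
  if (length(sel) == 0L) return(NULL)
  Xsel <- Xs[, sel, drop = FALSE]
  ctr <- colMeans(Xsel)
  Xc <- sweep(Xsel, 2L, ctr)
  n <- nrow(Xc)
  if (ncol(Xc) > 1.5 * n) {
    # wide data: eigendecompose the n x n Gram matrix instead of a full SVD
    eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    n_pc <- .n_components(ev, config$pca_var_fraction)
    keep <- seq_len(n_pc)
    d <- sqrt(ev[keep])
    d[d == 0] <- 1
    rot <- crossprod(Xc, eg$vectors[, keep, drop = FALSE]) %*% diag(1 / d, n_pc)
  } else {
    sv <- svd(Xc, nu = 0)
    ev <- sv$d^2
    n_pc <- .n_components(ev, config$pca_var_fraction)
    rot <- sv$v[, seq_len(n_pc), drop = FALSE]
  }
  list(sel = sel, center = ctr, rotation = rot, n_pc = n_pc)
}

.n_components <- function(ev, target) {
  if (sum(ev) == 0) return(1L)
  cum <- cumsum(ev) / sum(ev)
  n_pc <- which(cum >= target)[1]
  if (is.na(n_pc)) length(ev) else n_pc
}

# colVars without a dependency
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(rep(0, ncol(X)))
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1L)
}

#' Apply a fitted preprocessing transform to new data
#'
#' @param transform a `fitted_transform` from [preprocess_fit()].
#' @param X numeric matrix with the same column names as the training data.
#' @return matrix of principal-component scores.
#' @export
preprocess_apply <- function(transform, X) {
  if (isTRUE(transform$failed)) stop("cannot apply a failed transform")
  X <- as.matrix(X)[, transform$keep_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, transform$med), 2L, transform$iqr, "/")
  sweep(Xs, 2L, transform$center) %*% transform$rotation
}

# --- model family fitting ---------------------------------------------------

# glmnet needs >= 2 columns; pad with an inert zero column when necessary
.pad2 <- function(X) {
  if (ncol(X) >= 2L) return(X)
  cbind(X, `.pad` = 0)
}

.fit_family <- function(family, params, X, y) {
  y <- as.integer(y)
  switch(family,
    logistic_regression = {
      lam <- 1 / (params$C * nrow(X))
      list(kind = family,
           fit = glmnet::glmnet(.pad2(X), y, family = "binomial", alpha = 0,
                                lambda = lam))
    },
    knn = list(kind = family, X = X, y = y, k = min(params$k, nrow(X))),
    random_forest = {
      list(kind = family,
           fit = randomForest::randomForest(
             x = X, y = factor(y, levels = c(0L, 1L)),
             ntree = params$n_trees,
             maxnodes = min(2L^params$max_depth, nrow(X))))
    },
    least_angle_regression = {
      fit <- glmnet::glmnet(.pad2(X), as.numeric(y), family = "gaussian",
                            alpha = 1, nlambda = 100)
      df <- fit$df
      ok <- which(df >= min(params$n_nonzero, max(df)))
      s <- fit$lambda[if (length(ok)) ok[1] else length(fit$lambda)]
      list(kind = family, fit = fit, s = s)
    },
    naive_bayes = {
      eps <- params$var_smoothing * max(matrixStats_colVars(X), 1e-12)
      stats_by <- lapply(c(0L, 1L), function(cl) {
        Xi <- X[y == cl, , drop = FALSE]
        list(mean = colMeans(Xi),
             var = matrixStats_colVars(Xi) + eps,
             prior = nrow(Xi) / nrow(X))
      })
      list(kind = family, classes = stats_by)
    },
    gaussian_process = {
      sigma <- 1 / (2 * params$length_scale^2)
      fit <- suppressWarnings(kernlab::gausspr(
        x = X, y = factor(y, levels = c(0L, 1L)), kernel = "rbfdot",
        kpar = list(sigma = sigma), type = "classification"))
      list(kind = family, fit = fit)
    },
    decision_tree = {
      df <- data.frame(.y = factor(y, levels = c(0L, 1L)), X,
                       check.names = FALSE)
      list(kind = family,
           fit = rpart::rpart(.y ~ ., data = df, method = "class",
                              control = rpart::rpart.control(
                                maxdepth = params$max_depth,
                                minbucket = params$min_leaf,
                                minsplit = 2L * params$min_leaf,
                                cp = 0, xval = 0)))
    },
    neural_network = {
      list(kind = family,
           fit = nnet::nnet(x = X, y = y, size = params$units,
                            decay = params$l2, maxit = 200L,
                            entropy = TRUE, trace = FALSE,
                            MaxNWts = 50000L))
    },
    stop("unknown family: ", family)
  )
}

.predict_family <- function(model, X) {
  switch(model$kind,
    logistic_regression = as.numeric(
      stats::predict(model$fit, newx = .pad2(X), type = "response")),
    knn = {
      pr <- class::knn(train = model$X, test = X,
                       cl = factor(model$y, levels = c(0L, 1L)),
                       k = model$k, prob = TRUE)
      w <- attr(pr, "prob")
      ifelse(pr == "1", w, 1 - w)
    },
    random_forest = as.numeric(
      stats::predict(model$fit, newdata = X, type = "prob")[, "1"]),
    least_angle_regression = as.numeric(
      stats::predict(model$fit, newx = .pad2(X), s = model$s)),
    naive_bayes = {
      ll <- vapply(model$classes, function(cl) {
        log(cl$prior) + rowSums(
          -0.5 * log(2 * pi * rep(cl$var, each = nrow(X))) -
            0.5 * sweep(X, 2L, cl$mean)^2 /
              rep(cl$var, each = nrow(X)))
      }, numeric(nrow(X)))
      1 / (1 + exp(ll[, 1] - ll[, 2]))
    },
    gaussian_process = as.numeric(
      kernlab::predict(model$fit, X, type = "probabilities")[, "1"]),
    decision_tree = as.numeric(
      stats::predict(model$fit, newdata = data.frame(X, check.names = FALSE),
                     type = "prob")[, "1"]),
    neural_network = as.numeric(stats::predict(model$fit, X)),
    stop("unknown model kind")
  )
}

# fast tie-aware AUC (Mann-Whitney) for CV scoring
.fast_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  m <- sum(labels == 1L); n <- length(labels) - m
  if (m == 0L || n == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
}

# stratified k-fold assignment
.stratified_folds <- function(y, k) {
  y <- as.integer(y)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validate one pipeline configuration
#'
#' Stratified five-fold cross-validation on the training table: per fold the
#' preprocessing chain and the model are fitted on the other folds and the
#' held-out fold is scored by the AUC of the continuous model output. Each
#' case is held out exactly once. A configuration whose selection step
#' retains no feature (or whose model fit fails) scores AUC 0.5 for that
#' fold and is flagged.
#'
#' @param config a [sample_config()] result.
#' @param X training feature matrix.
#' @param y 0/1 training labels.
#' @param k number of folds.
#' @param seed seed for the fold assignment.
#' @return list with `fold_aucs` (length `k`), `mean_auc`, `failed`.
#' @export
cross_validate <- function(config, X, y, k = 5L, seed = 1L) {
  y <- as.integer(y)
  if (min(table(y)) < k)
    stop("not enough cases of the rarer class for stratified ", k, "-fold CV")
  fold <- .with_seed(seed, .stratified_folds(y, k))
  failed <- FALSE
  fold_aucs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    tf <- preprocess_fit(X[tr, , drop = FALSE], y[tr], config)
    if (isTRUE(tf$failed)) {
      failed <<- TRUE
      return(0.5)
    }
    Ztr <- preprocess_apply(tf, X[tr, , drop = FALSE])
    Zte <- preprocess_apply(tf, X[!tr, , drop = FALSE])
    scores <- tryCatch({
      model <- .fit_family(config$family, config$family_params, Ztr, y[tr])
      .predict_family(model, Zte)
    }, error = function(e) NULL)
    if (is.null(scores)) {
      failed <<- TRUE
      return(0.5)
    }
    .fast_auc(scores, y[!tr])
  }, numeric(1))
  list(fold_aucs = fold_aucs, mean_auc = mean(fold_aucs), failed = failed)
}

# cross-validation over precomputed fold caches; numerically identical to
# cross_validate() with the same seed (shared scaling/selection/PCA code)
.cv_cached <- function(config, cache) {
  failed <- FALSE
  fold_aucs <- vapply(cache, function(fd) {
    if (is.null(fd)) {
      failed <<- TRUE
      return(0.5)
    }
    sp <- .select_pca_fit(fd$Xs_tr, fd$p, config)
    if (is.null(sp)) {
      failed <<- TRUE
      return(0.5)
    }
    Ztr <- sweep(fd$Xs_tr[, sp$sel, drop = FALSE], 2L, sp$center) %*%
      sp$rotation
    Zte <- sweep(fd$Xs_te[, sp$sel, drop = FALSE], 2L, sp$center) %*%
      sp$rotation
    scores <- tryCatch({
      model <- .fit_family(config$family, config$family_params, Ztr, fd$ytr)
      .predict_family(model, Zte)
    }, error = function(e) NULL)
    if (is.null(scores)) {
      failed <<- TRUE
      return(0.5)
    }
    .fast_auc(scores, fd$yte)
  }, numeric(1))
  list(fold_aucs = fold_aucs, mean_auc = mean(fold_aucs), failed = failed)
}

#' Randomized hyperparameter search over the eight model families
#'
#' For each family, `iterations` random configurations are drawn and scored
#' by mean five-fold cross-validated AUC on the training table; the same
#' fold assignment (derived from `seed`) is used for every configuration so
#' scores are comparable. The best configuration per family and overall
#' (ties broken by evaluation order) is recorded, and the overall winner is
#' refitted on the full training set.
#'
#' @param X training feature matrix (rows x named feature columns).
#' @param y 0/1 training labels.
#' @param iterations configurations per family (>= 1).
#' @param seed integer seed driving both the configuration draws and the CV
#'   folds.
#' @param families character vector of families to search (default all 8).
#' @param k CV folds.
#' @return a `search_result`: list with `log` (one row per evaluated
#'   configuration), `per_family` (best config + mean CV AUC per family),
#'   `best` (family, config, mean CV AUC), and `fitted` (transform + model
#'   refitted on the full training set).
#' @export
run_search <- function(X, y, iterations = 100L, seed = 1L,
                       families = .model_families, k = 5L) {
  stopifnot(iterations >= 1L)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (min(table(y)) < k)
    stop("not enough cases of the rarer class for stratified ", k, "-fold CV")
  # scaling statistics and univariate p values depend on the fold split
  # only, never on the sampled configuration, so they are computed once
  fold <- .with_seed(seed, .stratified_folds(y, k))
  cache <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    sc <- .robust_scale_fit(X[tr, , drop = FALSE])
    if (is.null(sc)) return(NULL)
    Xte <- X[!tr, names(sc$med), drop = FALSE]
    Xte <- sweep(sweep(Xte, 2L, sc$med), 2L, sc$iqr, "/")
    list(Xs_tr = sc$Xs, Xs_te = Xte,
         p = .anova_f_pvalues(sc$Xs, y[tr]), ytr = y[tr], yte = y[!tr])
  })
  configs <- list()
  log_rows <- list()
  row <- 0L
  .with_seed(seed, {
    for (fam in families) {
      for (it in seq_len(iterations)) {
        row <- row + 1L
        cfg <- sample_config(fam)
        cv <- .cv_cached(cfg, cache)
        configs[[row]] <- cfg
        log_rows[[row]] <- data.frame(
          family = fam, iteration = it,
          fpr_alpha = cfg$fpr_alpha, fwer_alpha = cfg$fwer_alpha,
          pca_var_fraction = cfg$pca_var_fraction,
          params = paste(names(cfg$family_params),
                         vapply(cfg$family_params, format, character(1)),
                         sep = "=", collapse = ";"),
          mean_cv_auc = cv$mean_auc,
          failed = cv$failed,
          t(stats::setNames(cv$fold_aucs,
                            paste0("fold", seq_along(cv$fold_aucs)))),
          stringsAsFactors = FALSE)
      }
    }
  })
  log <- do.call(rbind, log_rows)
  per_family <- do.call(rbind, lapply(families, function(fam) {
    rows <- which(log$family == fam)
    best <- rows[which.max(log$mean_cv_auc[rows])]
    data.frame(family = fam, best_row = best,
               mean_cv_auc = log$mean_cv_auc[best],
               stringsAsFactors = FALSE)
  }))
  best_row <- which.max(log$mean_cv_auc)   # first maximum = earliest
  best_cfg <- configs[[best_row]]
  transform <- preprocess_fit(X, y, best_cfg)
  model <- if (!isTRUE(transform$failed)) {
    Z <- preprocess_apply(transform, X)
    .with_seed(seed, .fit_family(best_cfg$family, best_cfg$family_params, Z, y))
  }
  structure(list(log = log, per_family = per_family,
                 best = list(family = best_cfg$family, config = best_cfg,
                             mean_cv_auc = log$mean_cv_auc[best_row],
                             row = best_row),
                 fitted = list(transform = transform, model = model)),
            class = "search_result")
}

#' Score a fitted pipeline on the validation set
#'
#' Applies the training-fitted preprocessing transform and model unchanged
#' to the validation rows and returns the validation ROC with DeLong
#' variance and 95% CI.
#'
#' @param search a `search_result` from [run_search()] (or any list with
#'   `fitted$transform` and `fitted$model`).
#' @param X_val validation feature matrix.
#' @param y_val 0/1 validation labels.
#' @return a `roc_result`.
#' @export
evaluate_validation <- function(search, X_val, y_val) {
  Z <- preprocess_apply(search$fitted$transform, as.matrix(X_val))
  scores <- .predict_family(search$fitted$model, Z)
  auc_delong(scores, y_val)
}
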