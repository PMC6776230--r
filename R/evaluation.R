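#' Low-attenuation plaque area
#'
#' Area of plaque voxels strictly below the threshold (default 30 HU), the
#' classic histogram-based high-risk marker. For a slab several voxels
#' thick, the per-cross-section area is the voxel count below threshold
#' times the in-plane pixel area, divided by the number of z layers the mask
#' occupies (mean per-layer area).
#'
#' @param lesion a [voxel_lesion()].
#' @param threshold HU threshold; voxels with `HU < threshold` count.
#' @return area in mm^2.
#' @export
low_attenuation_area <- function(lesion, threshold = 30) {
  n_layers <- length(unique(lesion$coords[, 3]))
  sum(lesion$values < threshold) * lesion$spacing[1] * lesion$spacing[2] /
    n_layers
}

#' Mean attenuation of a lesion
#'
#' @param lesion a [voxel_lesion()].
#' @return arithmetic mean of the masked HU values.
#' @export
mean_hu <- function(lesion) mean(as.numeric(lesion$values))

# DeLong placement values: V10 (per positive) and V01 (per negative).
.delong_placements <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L) stop("both classes must be present")
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with DeLong variance and confidence interval
#'
#' The AUC is the Mann-Whitney statistic (ties contribute 0.5); its variance
#' comes from DeLong's structural components — the empirical variance of the
#' per-positive and per-negative placement values. The 95% CI is
#' `AUC +/- 1.96 * SE`, clipped to `[0, 1]`.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return an object of class `roc_result`: list with `auc`, `var`, `ci`
#'   (length 2), `scores`, `labels`, and the placement values.
#' @export
auc_delong <- function(scores, labels) {
  pl <- .delong_placements(scores, labels)
  auc <- mean(pl$v10)
  v <- if (pl$m > 1L) stats::var(pl$v10) / pl$m else 0
  v <- v + if (pl$n > 1L) stats::var(pl$v01) / pl$n else 0
  se <- sqrt(v)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * se))
  structure(list(auc = auc, var = v, ci = ci, scores = scores,
                 labels = as.integer(labels), placements = pl),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI: %.3f, %.3f)\n", x$auc, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Paired DeLong comparison of two correlated ROC curves
#'
#' Both results must score the same cases (identical labels, paired scores).
#' The test statistic is
#' `z = (AUC_a - AUC_b) / sqrt(var_a + var_b - 2 cov)` with the DeLong
#' covariance of the placement values, and a two-sided normal p value. A
#' zero variance of the difference (e.g. scores of one model are a monotone
#' transform of the other's) is flagged degenerate with `p = NA`.
#'
#' @param result_a,result_b `roc_result` objects from [auc_delong()] on the
#'   same labels.
#' @return list with `diff`, `var`, `z`, `p`, `degenerate`.
#' @export
compare_delong <- function(result_a, result_b) {
  if (!identical(result_a$labels, result_b$labels))
    stop("paired comparison requires identical labels")
  pa <- result_a$placements; pb <- result_b$placements
  cov10 <- if (pa$m > 1L) stats::cov(pa$v10, pb$v10) / pa$m else 0
  cov01 <- if (pa$n > 1L) stats::cov(pa$v01, pb$v01) / pa$n else 0
  v <- result_a$var + result_b$var - 2 * (cov10 + cov01)
  d <- result_a$auc - result_b$auc
  if (v <= .Machine$double.eps^0.5 * max(1, abs(d))) {
    return(list(diff = d, var = max(v, 0), z = NA_real_, p = NA_real_,
                degenerate = TRUE))
  }
  z <- d / sqrt(v)
  list(diff = d, var = v, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Univariate logistic baseline
#'
#' Fits a logistic regression of the outcome on a single numeric predictor
#' (or a 3-level pattern category encoded as two indicators) on the training
#' rows, scores the validation rows by fitted probability, and returns the
#' validation ROC. Under complete separation the fitted probabilities are a
#' monotone transform of the predictor anyway, so the score falls back to
#' the predictor's rank (the AUC is unchanged).
#'
#' @param train_x,val_x numeric vector or factor/character predictor for the
#'   training and validation rows.
#' @param train_y,val_y 0/1 outcomes.
#' @return a `roc_result` on the validation rows.
#' @export
univariate_logistic_baseline <- function(train_x, train_y, val_x, val_y) {
  if (is.character(train_x)) train_x <- factor(train_x)
  if (is.character(val_x))
    val_x <- factor(val_x, levels = levels(train_x))
  df_tr <- data.frame(y = as.integer(train_y), x = train_x)
  df_va <- data.frame(x = val_x)
  fit <- tryCatch(
    stats::glm(y ~ x, family = stats::binomial(), data = df_tr),
    warning = function(w) NULL, error = function(e) NULL)
  if (is.null(fit)) {
    if (is.factor(train_x)) {
      rate <- tapply(df_tr$y, df_tr$x, mean)
      scores <- as.numeric(rate[as.character(val_x)])
      scores[is.na(scores)] <- mean(df_tr$y)
    } else {
      slope_sign <- sign(stats::cor(as.numeric(train_x), df_tr$y))
      if (is.na(slope_sign) || slope_sign == 0) slope_sign <- 1
      scores <- slope_sign * rank(as.numeric(val_x))
    }
  } else {
    scores <- stats::predict(fit, newdata = df_va, type = "response")
  }
  auc_delong(scores, val_y)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction, as used to check the
#' balance of categorical variables across data splits. Zero-margin rows and
#' columns are dropped with a warning.
#'
#' @param table 2D matrix of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_balance <- function(table) {
  table <- as.matrix(table)
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin rows/columns")
    table <- table[keep_r, keep_c, drop = FALSE]
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
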