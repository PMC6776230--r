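#' Names of the 44 first-order statistics
#'
#' @return character vector of length 44, in output order.
#' @export
firstorder_names <- function() {
  c(
    # core distribution statistics (16)
    "fo_mean", "fo_median", "fo_mode", "fo_sd", "fo_variance",
    "fo_skewness", "fo_kurtosis", "fo_min", "fo_max", "fo_range",
    "fo_iqr", "fo_mad_mean", "fo_mad_median", "fo_rms", "fo_energy",
    "fo_cv",
    # percentiles (14)
    paste0("fo_p", c(1, 5, 10, 20, 25, 30, 40, 60, 70, 75, 80, 90, 95, 99)),
    # robust location (4)
    "fo_trimmed5", "fo_trimmed10", "fo_winsorized5", "fo_midhinge",
    # distribution-shape statistics (10)
    "fo_entropy_b16", "fo_uniformity_b16", "fo_entropy_b32",
    "fo_uniformity_b32", "fo_entropy_b64", "fo_uniformity_b64",
    "fo_qskew", "fo_qcd", "fo_sem", "fo_idr"
  )
}

#' Compute the 44 first-order statistics of a lesion
#'
#' All statistics describe the marginal HU distribution of the masked voxels,
#' ignoring spatial arrangement. Percentiles use linear interpolation between
#' order statistics (R quantile type 7). Skewness is Fisher `m3/m2^1.5` and
#' kurtosis is excess `m4/m2^2 - 3`. The mode is the most frequent integer HU
#' value, ties resolved to the smallest. Entropy (base 2) and uniformity are
#' computed on equal-width bin occupancies at B = 16, 32, 64 via
#' [discretize_equal_width()]. Degenerate lesions (single voxel or constant
#' value) return 0 for dispersion and shape terms that are otherwise
#' undefined, so downstream matrices stay finite; such zero-variance columns
#' are removed by the model-building preprocessing anyway.
#'
#' @param lesion a [voxel_lesion()].
#' @return named numeric vector of length 44 (see [firstorder_names()]).
#' @export
compute_firstorder <- function(lesion) {
  v <- as.numeric(lesion$values)
  n <- length(v)
  if (n == 0L) stop("empty lesion")
  m <- mean(v)
  med <- stats::median(v)
  degenerate <- n == 1L || min(v) == max(v)

  ctr <- v - m
  m2 <- mean(ctr^2)
  s2 <- if (n > 1L) stats::var(v) else 0
  s <- sqrt(s2)
  skew <- if (degenerate || m2 == 0) 0 else mean(ctr^3) / m2^1.5
  kurt <- if (degenerate || m2 == 0) 0 else mean(ctr^4) / m2^2 - 3

  tab <- table(lesion$values)
  mode_hu <- as.numeric(names(tab)[which.max(tab)])  # which.max: first = smallest

  q <- stats::quantile(v, probs = c(1, 5, 10, 20, 25, 30, 40, 60, 70, 75,
                                    80, 90, 95, 99) / 100,
                       names = FALSE, type = 7)
  q1 <- q[5]; q3 <- q[10]
  iqr <- q3 - q1

  k5 <- floor(0.05 * n)
  vs <- sort(v)
  wins <- vs
  if (k5 > 0L) {
    wins[seq_len(k5)] <- vs[k5 + 1L]
    wins[(n - k5 + 1L):n] <- vs[n - k5]
  }

  ent_unif <- unlist(lapply(c(16L, 32L, 64L), function(B) {
    bins <- discretize_equal_width(lesion, B)$bins
    p <- tabulate(bins, nbins = B) / n
    p <- p[p > 0]
    c(-sum(p * log2(p)), sum(p^2))
  }))

  out <- c(
    m, med, mode_hu, s, s2, skew, kurt, min(v), max(v), max(v) - min(v),
    iqr, mean(abs(ctr)), stats::median(abs(v - med)), sqrt(mean(v^2)),
    mean(v^2), if (degenerate || m == 0) 0 else s / abs(m),
    q,
    mean(v, trim = 0.05), mean(v, trim = 0.10), mean(wins), (q1 + q3) / 2,
    ent_unif,
    if (iqr == 0) 0 else (q3 - 2 * med + q1) / iqr,
    if ((q3 + q1) == 0) 0 else (q3 - q1) / (q3 + q1),
    if (degenerate) 0 else s / sqrt(n),
    q[12] - q[3]
  )
  names(out) <- firstorder_names()
  out
}
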