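#' Discretize a lesion into B equal-width gray levels
#'
#' Equal-width ("equally sized") binning splits the lesion's HU range
#' `[min, max]` into `B` bins of identical width: a voxel with value `v` gets
#' label `min(B, floor((v - min) / ((max - min) / B)) + 1)`. A constant
#' lesion maps entirely to label 1.
#'
#' @param lesion a [voxel_lesion()].
#' @param B number of gray levels (one of 16, 32, 64 in the full pipeline;
#'   any B >= 2 is accepted).
#' @return a `discretized_lesion`: list with `bins` (integer labels in
#'   `1..B`, aligned with `lesion$coords`), `B`, `scheme = "equal_width"`,
#'   `parent` (lesion id).
#' @export
discretize_equal_width <- function(lesion, B) {
  stopifnot(B >= 2)
  v <- as.numeric(lesion$values)
  lo <- min(v); hi <- max(v)
  bins <- if (hi == lo) rep(1L, length(v))
          else pmin(B, floor((v - lo) / ((hi - lo) / B)) + 1L)
  structure(list(bins = as.integer(bins), B = as.integer(B),
                 scheme = "equal_width", parent = lesion$lesion_id),
            class = "discretized_lesion")
}

#' Discretize a lesion into B equal-probability gray levels
#'
#' Equal-probability ("equally probable") binning assigns labels by rank so
#' every bin receives the same number of voxels up to one: voxels are sorted
#' by `(value, coordinate order)` — ties in value broken by stable original
#' order for determinism — and the k-th of n voxels gets label
#' `floor((k-1) * B / n) + 1`.
#'
#' @inheritParams discretize_equal_width
#' @return a `discretized_lesion` with `scheme = "equal_prob"`.
#' @export
discretize_equal_prob <- function(lesion, B) {
  stopifnot(B >= 2)
  n <- length(lesion$values)
  ord <- order(lesion$values)             # stable in R: ties keep input order
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  bins <- pmin(as.integer(B), floor((ranks - 1) * B / n) + 1L)
  structure(list(bins = as.integer(bins), B = as.integer(B),
                 scheme = "equal_prob", parent = lesion$lesion_id),
            class = "discretized_lesion")
}

#' All six discretized copies of a lesion
#'
#' Both schemes at B in {16, 32, 64}, the six gray-level images every texture
#' and geometry feature is computed on.
#'
#' @param lesion a [voxel_lesion()].
#' @return named list of 6 `discretized_lesion` objects, in order
#'   `ew16, ew32, ew64, ep16, ep32, ep64`.
#' @export
discretize_all <- function(lesion) {
  out <- c(
    lapply(c(16L, 32L, 64L), function(B) discretize_equal_width(lesion, B)),
    lapply(c(16L, 32L, 64L), function(B) discretize_equal_prob(lesion, B))
  )
  names(out) <- c("ew16", "ew32", "ew64", "ep16", "ep32", "ep64")
  out
}

# short code used in feature names: ew16, ep32, ...
.scheme_code <- function(d) {
  paste0(if (d$scheme == "equal_width") "ew" else "ep", d$B)
}
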