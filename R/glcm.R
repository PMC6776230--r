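#' Build a gray-level co-occurrence matrix
#'
#' Counts ordered pairs `(bin(p), bin(p + distance * offset))` over voxel
#' pairs that both lie inside the mask (pairs with one endpoint outside the
#' segmentation are skipped), symmetrizes by adding the transpose, and
#' normalizes to sum 1. If no pair exists for the offset the all-zero matrix
#' is returned flagged empty (`attr(, "empty")`).
#'
#' @param dlesion a `discretized_lesion`.
#' @param coords integer coordinate matrix of the parent lesion, aligned
#'   with `dlesion$bins`.
#' @param offset integer length-3 direction, one of the 13 unique 3D
#'   directions.
#' @param distance integer step length (>= 1).
#' @return B x B matrix of co-occurrence probabilities.
#' @export
build_glcm <- function(dlesion, coords, offset, distance = 1L) {
  nbr <- .neighbor_index(coords, as.integer(offset) * as.integer(distance))
  sp <- .glcm_sparse(dlesion$bins, dlesion$B, nbr)
  B <- dlesion$B
  m <- matrix(0, B, B)
  if (is.null(sp)) {
    attr(m, "empty") <- TRUE
    return(m)
  }
  m[(sp$j - 1L) * B + sp$i] <- sp$p
  attr(m, "empty") <- FALSE
  m
}

# cached per-B index structures
.glcm_cache <- new.env(parent = emptyenv())
.glcm_grids <- function(B) {
  key <- as.character(B)
  if (is.null(.glcm_cache[[key]])) {
    iv <- rep(seq_len(B), B)        # row index of cell k = (j-1)*B + i
    jv <- rep(seq_len(B), each = B)
    .glcm_cache[[key]] <- list(
      iv = iv, jv = jv,
      tperm = (iv - 1L) * B + jv    # index of the transposed cell
    )
  }
  .glcm_cache[[key]]
}

# sparse symmetric normalized co-occurrence: list(i, j, p) over nonzero
# cells, or NULL when no pair exists
.glcm_sparse <- function(bins, B, nbr) {
  ok <- which(!is.na(nbr))
  if (length(ok) == 0L) return(NULL)
  g <- .glcm_grids(B)
  # cell index with i = first voxel's bin (column-major: (j-1)*B + i)
  cnt <- tabulate((bins[nbr[ok]] - 1L) * B + bins[ok], nbins = B * B)
  sym <- cnt + cnt[g$tperm]
  nz <- which(sym > 0L)
  list(i = g$iv[nz], j = g$jv[nz], p = sym[nz] / sum(sym[nz]))
}

#' Names of the 19 per-matrix GLCM statistics
#' @return character vector of length 19.
#' @export
glcm_statistic_names <- function() {
  c("asm", "contrast", "correlation", "variance", "idm",
    "sumavg", "sumvar", "sumentropy", "entropy", "diffvar",
    "diffentropy", "imc1", "imc2", "maxprob", "autocorr",
    "clustershade", "clusterprom", "dissimilarity", "idn")
}

# statistics on the sparse representation; identities HXY1 = HXY2 = HX + HY
# (exact for any joint with marginals summing to 1) replace the textbook
# double sums in the informational measures of correlation
.glcm_stats_sparse <- function(i, j, p, B) {
  ind <- seq_len(B)
  px <- numeric(B)
  agg <- rowsum(p, i)
  px[as.integer(rownames(agg))] <- agg
  mu <- sum(ind * px)
  sig2 <- sum((ind - mu)^2 * px)

  d <- i - j
  ad <- abs(d)
  asm <- sum(p * p)
  contrast <- sum(d * d * p)
  autocorr <- sum(i * j * p)
  correlation <- if (sig2 == 0) 0 else (autocorr - mu^2) / sig2
  variance <- sum((i - mu)^2 * p)
  idm <- sum(p / (1 + d * d))
  idn <- sum(p / (1 + ad / B))
  dissimilarity <- sum(ad * p)
  maxprob <- max(p)

  ps <- rowsum(p, i + j)
  ks <- as.numeric(rownames(ps))
  sumavg <- sum(ks * ps)
  sumvar <- sum((ks - sumavg)^2 * ps)
  sumentropy <- -sum(ps * log2(ps))

  pd <- rowsum(p, ad)
  kd <- as.numeric(rownames(pd))
  davg <- sum(kd * pd)
  diffvar <- sum((kd - davg)^2 * pd)
  diffentropy <- -sum(pd * log2(pd))

  entropy <- -sum(p * log2(p))
  pxnz <- px[px > 0]
  hx <- -sum(pxnz * log2(pxnz))
  imc1 <- if (hx == 0) 0 else (entropy - 2 * hx) / hx
  imc2 <- sqrt(max(0, 1 - exp(-2 * (2 * hx - entropy))))

  cs <- i + j - 2 * mu
  cs2 <- cs * cs * p
  clustershade <- sum(cs2 * cs)
  clusterprom <- sum(cs2 * cs * cs)

  c(asm, contrast, correlation, variance, idm, sumavg, sumvar,
    sumentropy, entropy, diffvar, diffentropy, imc1, imc2, maxprob,
    autocorr, clustershade, clusterprom, dissimilarity, idn)
}

#' Haralick-family statistics of one co-occurrence matrix
#'
#' Standard definitions on the symmetric, normalized matrix: angular second
#' moment, contrast, correlation, sum-of-squares variance, inverse difference
#' moment, sum average/variance/entropy, entropy, difference
#' variance/entropy, the two informational measures of correlation, maximum
#' probability, autocorrelation, cluster shade and prominence, dissimilarity,
#' and inverse difference normalized. Logarithms are base 2 with
#' `0 * log(0) := 0`. An empty matrix yields all zeros.
#'
#' @param m matrix from [build_glcm()].
#' @return named numeric vector of length 19.
#' @export
glcm_statistics <- function(m) {
  nm <- glcm_statistic_names()
  if (isTRUE(attr(m, "empty")) || sum(m) == 0) {
    out <- numeric(19L)
    names(out) <- nm
    return(out)
  }
  B <- nrow(m)
  nz <- which(m > 0)
  i <- (nz - 1L) %% B + 1L
  j <- (nz - 1L) %/% B + 1L
  out <- .glcm_stats_sparse(i, j, as.vector(m[nz]) / sum(m), B)
  names(out) <- nm
  out
}

# 19 stats x 13 directions x 3 distances -> mean and range aggregates.
# `nbrs` is a list indexed [[distance]][[direction]] of neighbor-index
# vectors, precomputed once per lesion and shared across discretizations.
.glcm_block_from_context <- function(bins, B, code, nbrs) {
  stat_names <- glcm_statistic_names()
  zero <- numeric(19L)
  out <- numeric(0)
  for (d in 1:3) {
    stats_mat <- vapply(1:13, function(k) {
      sp <- .glcm_sparse(bins, B, nbrs[[d]][[k]])
      if (is.null(sp)) zero else .glcm_stats_sparse(sp$i, sp$j, sp$p, B)
    }, zero)
    mu <- rowMeans(stats_mat)
    rg <- apply(stats_mat, 1L, max) - apply(stats_mat, 1L, min)
    v <- c(mu, rg)
    names(v) <- c(paste0("glcm_", code, "_d", d, "_mean_", stat_names),
                  paste0("glcm_", code, "_d", d, "_range_", stat_names))
    out <- c(out, v)
  }
  out
}

.glcm_neighbors <- function(coords) {
  dirs <- .directions13()
  lapply(1:3, function(d)
    lapply(seq_len(nrow(dirs)), function(k)
      .neighbor_index(coords, dirs[k, ] * d)))
}

#' The 114 co-occurrence features of one discretized lesion
#'
#' For distances 1, 2, 3 the 19 Haralick-family statistics are computed on
#' each of the 13 unique 3D direction matrices and aggregated by their mean
#' and their range (max - min) over directions: 19 x 2 x 3 = 114 named
#' values. Feature names encode scheme, bin count, distance, aggregation and
#' statistic (e.g. `glcm_ep32_d1_mean_contrast`).
#'
#' @param dlesion a `discretized_lesion`.
#' @param coords coordinate matrix aligned with `dlesion$bins`.
#' @return named numeric vector of length 114.
#' @export
compute_glcm_block <- function(dlesion, coords) {
  .glcm_block_from_context(dlesion$bins, dlesion$B, .scheme_code(dlesion),
                           .glcm_neighbors(coords))
}
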