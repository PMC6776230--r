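#' Build a gray-level run-length matrix
#'
#' Counts maximal runs of equal bin label along lines of the given direction,
#' restricted to mask voxels: a gap in the mask terminates a run. Entry
#' `R[i, j]` is the number of maximal runs of gray level `i` and length `j`.
#'
#' @param dlesion a `discretized_lesion`.
#' @param coords coordinate matrix aligned with `dlesion$bins`.
#' @param offset one of the 13 unique 3D directions.
#' @return B x Lmax integer matrix of run counts.
#' @export
build_glrlm <- function(dlesion, coords, offset) {
  ctx <- .run_context(coords, offset)
  runs <- .runs_from_context(dlesion$bins, ctx)
  Lmax <- max(runs$length)
  m <- matrix(0L, dlesion$B, Lmax)
  cnt <- tabulate((runs$level - 1L) * Lmax + runs$length,
                  nbins = dlesion$B * Lmax)
  m[] <- matrix(cnt, dlesion$B, Lmax, byrow = TRUE)
  m
}

# Ordering of voxels into directed lines: position t along the direction and
# a line identifier constant on each line. Depends only on geometry, so it is
# precomputed once per lesion and shared across the 6 discretizations.
.run_context <- function(coords, offset) {
  axis <- which(offset != 0)[1]
  t <- coords[, axis] * offset[axis]
  base <- coords - outer(t, as.integer(offset))
  linekey <- .coord_key(base + max(abs(t)) + 1L)
  ord <- order(linekey, t)
  list(ord = ord, linekey = linekey[ord], t = t[ord])
}

# maximal runs (level, length) given bin labels and a run context
.runs_from_context <- function(bins, ctx) {
  b <- bins[ctx$ord]
  n <- length(b)
  newrun <- c(TRUE, ctx$linekey[-1] != ctx$linekey[-n] |
                ctx$t[-1] != ctx$t[-n] + 1L | b[-1] != b[-n])
  starts <- which(newrun)
  lens <- diff(c(starts, n + 1L))
  list(level = b[starts], length = lens)
}

#' Names of the 11 run-length statistics
#' @return character vector of length 11.
#' @export
glrlm_statistic_names <- function() {
  c("sre", "lre", "gln", "rln", "rp", "lglre", "hglre",
    "srlgle", "srhgle", "lrlgle", "lrhgle")
}

.glrlm_stats_one <- function(level, len, n_voxels) {
  nr <- length(len)
  if (nr == 0L) return(numeric(11L))
  inv_j2 <- 1 / len^2; j2 <- len^2
  inv_i2 <- 1 / level^2; i2 <- level^2
  gl_counts <- rowsum(rep(1, nr), level)
  rl_counts <- rowsum(rep(1, nr), len)
  c(sre = sum(inv_j2) / nr,
    lre = sum(j2) / nr,
    gln = sum(gl_counts^2) / nr,
    rln = sum(rl_counts^2) / nr,
    rp = nr / n_voxels,
    lglre = sum(inv_i2) / nr,
    hglre = sum(i2) / nr,
    srlgle = sum(inv_i2 * inv_j2) / nr,
    srhgle = sum(i2 * inv_j2) / nr,
    lrlgle = sum(inv_i2 * j2) / nr,
    lrhgle = sum(i2 * j2) / nr)
}

#' The 11 classic run-length statistics, averaged over the 13 directions
#'
#' Short/long-run emphasis, gray-level and run-length non-uniformity, run
#' percentage, low/high gray-level run emphasis and the four combined
#' emphases (Galloway / Chu / Dasarathy-Holder definitions), computed per
#' direction and then averaged over the 13 unique 3D directions.
#'
#' @param matrices list of 13 matrices from [build_glrlm()].
#' @param n_voxels number of mask voxels (for run percentage).
#' @return named numeric vector of length 11.
#' @export
glrlm_statistics <- function(matrices, n_voxels) {
  per_dir <- vapply(matrices, function(m) {
    idx <- which(m > 0, arr.ind = TRUE)
    lev <- rep(idx[, 1], m[idx])
    len <- rep(idx[, 2], m[idx])
    .glrlm_stats_one(lev, len, n_voxels)
  }, numeric(11L))
  out <- rowMeans(per_dir)
  names(out) <- glrlm_statistic_names()
  out
}

.glrlm_block_from_context <- function(bins, B, code, run_ctxs, n_voxels) {
  per_dir <- vapply(run_ctxs, function(ctx) {
    runs <- .runs_from_context(bins, ctx)
    .glrlm_stats_one(runs$level, runs$length, n_voxels)
  }, numeric(11L))
  out <- rowMeans(per_dir)
  names(out) <- paste0("glrlm_", code, "_", glrlm_statistic_names())
  out
}

#' The 11 run-length features of one discretized lesion
#'
#' @param dlesion a `discretized_lesion`.
#' @param coords coordinate matrix aligned with `dlesion$bins`.
#' @return named numeric vector of length 11 (e.g. `glrlm_ep64_sre`).
#' @export
compute_glrlm_block <- function(dlesion, coords) {
  dirs <- .directions13()
  ctxs <- lapply(seq_len(nrow(dirs)), function(k) .run_context(coords, dirs[k, ]))
  .glrlm_block_from_context(dlesion$bins, dlesion$B, .scheme_code(dlesion),
                            ctxs, nrow(coords))
}
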