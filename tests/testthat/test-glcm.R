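dlesion_from <- function(bins, B, scheme = "equal_prob") {
  structure(list(bins = as.integer(bins), B = as.integer(B), scheme = scheme,
                 parent = "test"), class = "discretized_lesion")
}

test_that("co-occurrence counting handles the hand-checked cases", {
  coords <- cbind(c(0L, 1L), 0L, 0L)
  d <- dlesion_from(c(1L, 2L), 4L)
  m <- build_glcm(d, coords, c(1, 0, 0), 1L)
  expected <- matrix(0, 4, 4)
  expected[1, 2] <- expected[2, 1] <- 0.5
  expect_equal(unclass(m), expected, ignore_attr = TRUE)

  const <- dlesion_from(rep(1L, 8), 4L)
  coords8 <- cbind(0:7, 0L, 0L)
  mc <- build_glcm(const, coords8, c(1, 0, 0), 1L)
  expect_equal(mc[1, 1], 1)
  expect_equal(sum(mc), 1)

  # no pair exists: flagged empty, statistics all zero
  iso <- build_glcm(dlesion_from(c(1L, 2L), 4L),
                    cbind(c(0L, 5L), 0L, 0L), c(1, 0, 0), 1L)
  expect_true(attr(iso, "empty"))
  expect_true(all(glcm_statistics(iso) == 0))
})

test_that("matrix statistics match hand evaluation", {
  m <- matrix(0, 2, 2)
  m[1, 2] <- m[2, 1] <- 0.5
  s <- glcm_statistics(m)
  expect_equal(unname(s["contrast"]), 1)
  expect_equal(unname(s["asm"]), 0.5)
  expect_equal(unname(s["dissimilarity"]), 1)

  m1 <- matrix(0, 3, 3); m1[1, 1] <- 1
  s1 <- glcm_statistics(m1)
  expect_equal(unname(s1[c("contrast", "asm", "maxprob")]), c(0, 1, 1))

  B <- 8L
  u <- matrix(1 / B^2, B, B)
  expect_equal(unname(glcm_statistics(u)["entropy"]), 2 * log2(B))
})

test_that("matrices and statistics match the brute-force oracle", {
  set.seed(207)
  dirs <- oracle_directions()
  for (rep in 1:12) {
    les <- random_lesion(dims = c(4, 4, 3), fill = 0.7)
    d <- discretize_equal_prob(les, 4L)
    for (k in sample(13, 4)) {
      dist <- sample(1:3, 1)
      m <- build_glcm(d, les$coords, dirs[k, ], dist)
      mo <- oracle_glcm(d$bins, les$coords, dirs[k, ], dist, 4L)
      expect_equal(unclass(m), mo, tolerance = 1e-12, ignore_attr = TRUE)
      if (sum(mo) > 0) {
        expect_equal(sum(m), 1, tolerance = 1e-12)
        expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
      }
    }
  }
})

test_that("the informational measures follow their definitions", {
  # cross-check the marginal-identity shortcut against the double sums
  set.seed(208)
  les <- random_lesion(dims = c(4, 4, 2), fill = 0.8)
  d <- discretize_equal_width(les, 4L)
  m <- build_glcm(d, les$coords, c(1, 0, 0), 1L)
  s <- glcm_statistics(m)
  p <- unclass(m)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  hxy <- -sum(p[nz] * log2(p[nz]))
  pp <- outer(px, py)
  hxy1 <- -sum(p[nz] * log2(pp[nz]))
  nz2 <- pp > 0
  hxy2 <- -sum(pp[nz2] * log2(pp[nz2]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  expect_equal(unname(s["entropy"]), hxy, tolerance = 1e-12)
  expect_equal(unname(s["imc1"]), (hxy - hxy1) / hx, tolerance = 1e-12)
  expect_equal(unname(s["imc2"]),
               sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))), tolerance = 1e-12)
})

test_that("the per-image block has 114 features with sane aggregates", {
  set.seed(209)
  les <- random_lesion(dims = c(5, 5, 3), fill = 0.7)
  d <- discretize_equal_prob(les, 16L)
  blk <- compute_glcm_block(d, les$coords)
  expect_length(blk, 114L)
  expect_true(all(grepl("^glcm_ep16_d[123]_(mean|range)_", names(blk))))
  expect_true(all(blk[grepl("_range_", names(blk))] >= -1e-12))

  # mean aggregate equals the direction-averaged statistics
  dirs <- oracle_directions()
  stats1 <- sapply(1:13, function(k)
    glcm_statistics(build_glcm(d, les$coords, dirs[k, ], 1L)))
  expect_equal(unname(blk[paste0("glcm_ep16_d1_mean_",
                                 glcm_statistic_names())]),
               unname(rowMeans(stats1)), tolerance = 1e-12)

  const <- voxel_lesion(rep(80L, 30), cbind(0:29, 0L, 0L), c(1, 1, 1))
  dc <- discretize_equal_width(const, 16L)
  blkc <- compute_glcm_block(dc, const$coords)
  expect_true(all(blkc[grepl("contrast", names(blkc))] == 0))
})

test_that("13-direction mean aggregates are invariant to 90-degree rotation", {
  set.seed(210)
  les <- random_lesion(dims = c(4, 4, 4), fill = 0.7)
  d <- discretize_equal_prob(les, 4L)
  rot_coords <- cbind(les$coords[, 2],
                      max(les$coords[, 1]) - les$coords[, 1],
                      les$coords[, 3])
  blk <- compute_glcm_block(d, les$coords)
  blk_rot <- compute_glcm_block(d, rot_coords)
  means <- grepl("_mean_", names(blk))
  expect_equal(blk[means], blk_rot[means], tolerance = 1e-10)
})
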