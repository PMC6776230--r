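# Fixture builders and independent brute-force oracles. The oracles
# deliberately share no code with the package internals: plain double loops
# and direct formula evaluation on tiny inputs.

# random small lesion on a dims grid with ~fill fraction of voxels masked
random_lesion <- function(dims = c(4, 4, 3), fill = 0.6, hu_range = c(-50, 160),
                          id = "rand") {
  grid <- as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                                z = 0:(dims[3] - 1)))
  n <- max(2L, rbinom(1, nrow(grid), fill))
  sel <- sort(sample(nrow(grid), n))
  voxel_lesion(values = sample(hu_range[1]:hu_range[2], n, replace = TRUE),
               coords = grid[sel, , drop = FALSE],
               spacing = runif(3, 0.3, 1.2), lesion_id = id)
}

oracle_directions <- function() {
  rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0), c(1,0,1),
        c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1), c(1,1,-1), c(1,-1,1),
        c(1,-1,-1))
}

# brute-force symmetric normalized GLCM: double loop over voxel pairs
oracle_glcm <- function(bins, coords, offset, distance, B) {
  m <- matrix(0, B, B)
  n <- nrow(coords)
  for (a in seq_len(n)) {
    target <- coords[a, ] + offset * distance
    for (b in seq_len(n)) {
      if (all(coords[b, ] == target)) {
        m[bins[a], bins[b]] <- m[bins[a], bins[b]] + 1
      }
    }
  }
  m <- m + t(m)
  if (sum(m) > 0) m <- m / sum(m)
  m
}

# brute-force GLRLM: walk every line in the given direction
oracle_glrlm <- function(bins, coords, offset, B) {
  n <- nrow(coords)
  key <- function(v) paste(v, collapse = ",")
  lookup <- new.env()
  for (a in seq_len(n)) assign(key(coords[a, ]), bins[a], envir = lookup)
  runs <- list()
  for (a in seq_len(n)) {
    prev <- coords[a, ] - offset
    prev_bin <- mget(key(prev), envir = lookup, ifnotfound = NA)[[1]]
    # a run starts here iff the predecessor is absent or differently binned
    if (!is.na(prev_bin) && prev_bin == bins[a]) next
    len <- 1L
    cur <- coords[a, ] + offset
    repeat {
      cur_bin <- mget(key(cur), envir = lookup, ifnotfound = NA)[[1]]
      if (is.na(cur_bin) || cur_bin != bins[a]) break
      len <- len + 1L
      cur <- cur + offset
    }
    runs[[length(runs) + 1L]] <- c(bins[a], len)
  }
  lmax <- max(vapply(runs, `[`, numeric(1), 2))
  m <- matrix(0, B, lmax)
  for (r in runs) m[r[1], r[2]] <- m[r[1], r[2]] + 1
  m
}

# brute-force exposed-face surface area
oracle_surface <- function(coords, spacing) {
  n <- nrow(coords)
  keys <- apply(coords, 1, paste, collapse = ",")
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  total <- 0
  for (a in seq_len(n)) {
    for (axis in 1:3) {
      for (sgn in c(-1, 1)) {
        nb <- coords[a, ]
        nb[axis] <- nb[axis] + sgn
        if (!(paste(nb, collapse = ",") %in% keys)) total <- total + face[axis]
      }
    }
  }
  total
}

# brute-force pair-counting AUC with 0.5 for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# direct-formula first-order statistics, independent of the package code
oracle_firstorder <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  med <- median(v)
  m2 <- sum((v - m)^2) / n
  s <- sqrt(sum((v - m)^2) / (n - 1))
  degenerate <- n == 1 || min(v) == max(v)
  counts <- table(v)
  mode_hu <- as.numeric(names(counts))[which(counts == max(counts))][1]
  probs <- c(1, 5, 10, 20, 25, 30, 40, 60, 70, 75, 80, 90, 95, 99) / 100
  q <- quantile(v, probs, names = FALSE)  # type 7 linear interpolation
  q1 <- q[5]; q3 <- q[10]
  k5 <- floor(0.05 * n)
  vs <- sort(v)
  wins <- c(rep(vs[k5 + 1], k5), vs[(k5 + 1):(n - k5)], rep(vs[n - k5], k5))
  ent <- function(B) {
    lo <- min(v); hi <- max(v)
    b <- if (hi == lo) rep(1, n) else pmin(B, floor((v - lo) / ((hi - lo) / B)) + 1)
    p <- as.vector(table(factor(b, levels = 1:B))) / n
    p <- p[p > 0]
    c(-sum(p * log2(p)), sum(p^2))
  }
  eu <- c(ent(16), ent(32), ent(64))
  out <- c(m, med, mode_hu,
           if (degenerate) 0 else s, if (n > 1) s^2 else 0,
           if (degenerate) 0 else sum((v - m)^3) / n / m2^1.5,
           if (degenerate) 0 else sum((v - m)^4) / n / m2^2 - 3,
           min(v), max(v), max(v) - min(v), q3 - q1,
           sum(abs(v - m)) / n, median(abs(v - med)),
           sqrt(sum(v^2) / n), sum(v^2) / n,
           if (degenerate || m == 0) 0 else s / abs(m),
           q,
           mean(v, trim = 0.05), mean(v, trim = 0.10), mean(wins),
           (q1 + q3) / 2,
           eu,
           if (q3 == q1) 0 else (q3 - 2 * med + q1) / (q3 - q1),
           if (q3 + q1 == 0) 0 else (q3 - q1) / (q3 + q1),
           if (degenerate) 0 else s / sqrt(n),
           q[12] - q[3])
  unname(out)
}

# Pearson chi-square statistic by direct formula
oracle_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# small labeled feature matrix with a few informative columns, for ML tests
toy_classification <- function(n = 60, p = 12, informative = 3, seed = 99,
                               delta = 1.5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  for (j in seq_len(informative)) X[y == 1L, j] <- X[y == 1L, j] + delta
  list(X = X, y = y)
}
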