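#' Voxel surface area of a point set
#'
#' Sum of exposed-face areas: a face is exposed if the 6-neighbor across it
#' is not part of the set. Face areas follow the anisotropic spacing (the
#' x-normal face has area `spacing_y * spacing_z`, etc.).
#'
#' @param coords integer coordinate matrix (possibly 0 rows).
#' @param spacing numeric length-3 spacing in mm.
#' @return surface area in mm^2.
#' @export
surface_area <- function(coords, spacing) {
  if (is.null(coords) || nrow(coords) == 0L) return(0)
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  total <- 0
  for (axis in 1:3) {
    for (sgn in c(1L, -1L)) {
      off <- c(0L, 0L, 0L); off[axis] <- sgn
      total <- total + face[axis] * sum(is.na(.neighbor_index(coords, off)))
    }
  }
  total
}

.fractal_scales <- c(1L, 2L, 4L, 8L, 16L)

# per-scale box occupancy summaries for one point set
.box_summaries <- function(coords) {
  n <- nrow(coords)
  origin <- c(min(coords[, 1]), min(coords[, 2]), min(coords[, 3]))
  c0 <- sweep(coords, 2L, origin)
  t(vapply(.fractal_scales, function(eps) {
    b <- c0 %/% eps
    key <- .coord_key(b, origin = c(0, 0, 0),
                      extent = c(max(b[, 1]), max(b[, 2]), max(b[, 3])) + 1)
    cnt <- tabulate(match(key, unique(key)))
    p <- cnt / n
    c(N = length(cnt), I = -sum(p * log2(p)), C = log2(sum(p^2)))
  }, numeric(3L)))
}

.ls_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Fractal box-counting, information, and correlation dimensions
#'
#' Cubic box grids of side eps in {1, 2, 4, 8, 16} voxels are overlaid,
#' anchored at the point set's bounding-box origin. Per scale,
#' `N(eps)` is the number of occupied boxes, `I(eps) = -sum p_b log2 p_b`
#' the occupancy entropy, and `C(eps) = log2 sum p_b^2` the log second
#' moment, with `p_b` the occupancy fraction of box `b`. The dimensions are
#' least-squares slopes: `log2 N` and `I` against `log2(1/eps)`, and `C`
#' against `log2(eps)` — sign conventions chosen so all three are
#' non-negative for ordinary sets. A single point yields all zeros.
#'
#' @param coords integer coordinate matrix of the point set.
#' @return named numeric vector `boxdim`, `infodim`, `corrdim`.
#' @export
fractal_dimensions <- function(coords) {
  out <- c(boxdim = 0, infodim = 0, corrdim = 0)
  if (is.null(coords) || nrow(coords) <= 1L) return(out)
  s <- .box_summaries(coords)
  x <- -log2(.fractal_scales)          # log2(1/eps)
  out["boxdim"] <- .ls_slope(x, log2(s[, "N"]))
  out["infodim"] <- .ls_slope(x, s[, "I"])
  out["corrdim"] <- .ls_slope(-x, s[, "C"])
  out
}

#' The 1125 surface and fractal-dimension features of a lesion
#'
#' Five parameters on the original mask — total surface area (mm^2), volume
#' (mm^3), and the box-counting, information, and correlation dimensions —
#' plus, for each of the 6 discretized images and each gray level
#' `g in 1..B`: the surface of the g-level sub-mask, its ratio to the total
#' surface, and the three fractal dimensions of the sub-mask. Empty gray
#' levels yield 0 for all five of their features. The gray-level sub-masks
#' partition the mask, and a fragmented sub-mask's surface can exceed the
#' total surface, so ratios live in `[0, Inf)`.
#'
#' @param lesion a [voxel_lesion()].
#' @param dlesions list of 6 discretized lesions from [discretize_all()].
#' @return named numeric vector of length 1125
#'   (e.g. `geom_surface`, `geom_ep16_g07_surfratio`).
#' @export
compute_geometry_block <- function(lesion, dlesions = discretize_all(lesion)) {
  coords <- lesion$coords
  spacing <- lesion$spacing
  n <- nrow(coords)
  total_surface <- surface_area(coords, spacing)
  fd <- fractal_dimensions(coords)
  out <- c(geom_surface = total_surface,
           geom_volume = n * prod(spacing),
           geom_boxdim = unname(fd["boxdim"]),
           geom_infodim = unname(fd["infodim"]),
           geom_corrdim = unname(fd["corrdim"]))

  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  # 6 axis-neighbor index vectors, shared by all discretizations
  axis_nbrs <- list()
  k <- 0L
  for (axis in 1:3) for (sgn in c(1L, -1L)) {
    off <- c(0L, 0L, 0L); off[axis] <- sgn
    k <- k + 1L
    axis_nbrs[[k]] <- list(nbr = .neighbor_index(coords, off), area = face[axis])
  }

  for (d in dlesions) {
    B <- d$B
    bins <- d$bins
    code <- .scheme_code(d)
    # exposed area per voxel within its own gray-level sub-mask
    ea <- numeric(n)
    for (an in axis_nbrs) {
      exposed <- is.na(an$nbr) | bins[an$nbr] != bins
      exposed[is.na(exposed)] <- TRUE
      ea <- ea + an$area * exposed
    }
    surf_g <- numeric(B)
    agg <- rowsum(ea, bins)
    surf_g[as.integer(rownames(agg))] <- agg
    idx_by_level <- split(seq_len(n), factor(bins, levels = seq_len(B)))
    vals <- unlist(lapply(seq_len(B), function(g) {
      idx <- idx_by_level[[g]]
      if (length(idx) == 0L) return(numeric(5L))
      fdg <- if (length(idx) == 1L) c(0, 0, 0)
             else fractal_dimensions(coords[idx, , drop = FALSE])
      c(surf_g[g], surf_g[g] / total_surface, fdg)
    }), use.names = FALSE)
    names(vals) <- as.vector(t(outer(sprintf("geom_%s_g%02d", code, seq_len(B)),
                                     c("surf", "surfratio", "boxdim",
                                       "infodim", "corrdim"), paste, sep = "_")))
    out <- c(out, vals)
  }
  out
}
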