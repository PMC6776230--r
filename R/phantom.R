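#' Configuration for the synthetic plaque phantom generator
#'
#' The generator emulates contrast-enhanced coronary plaque cross sections as
#' segmented voxel sets: an annular or crescent-shaped vessel-wall mask a few
#' slices thick, filled with fibrous-tissue attenuation, where advanced
#' lesions additionally carry a spatially contiguous low-attenuation
#' (necrotic/lipid) core — optionally ring-shaped, the napkin-ring analog.
#'
#' Defaults mirror the study conditions this pipeline is exercised under:
#' 445 lesions at 30% advanced prevalence, 0.4 x 0.4 mm in-plane spacing with
#' 0.6 mm through-plane increment, 3-slice slabs so all 13 3D texture
#' directions are exercisable, fibrous tissue N(90, 25) HU and core
#' N(20, 15) HU so the 30 HU low-attenuation threshold is meaningful.
#'
#' @param n_lesions number of lesions in a cohort.
#' @param prevalence_advanced fraction of advanced lesions in `[0,1]`.
#' @param spacing_mm positive length-3 voxel spacing (x, y, z) in mm.
#' @param slab_thickness_vox number of z slices (>= 1).
#' @param wall_radius_range_vox outer wall radius range in voxels (min >= 3).
#' @param hu_fibrous `(mean, sd)` HU of fibrous wall tissue.
#' @param hu_core `(mean, sd)` HU of the low-attenuation core.
#' @param core_fraction_range range of the fraction of mask voxels occupied
#'   by the core of an advanced lesion.
#' @param matched_marginal if `TRUE`, each early lesion's voxel values are a
#'   random spatial permutation of an advanced-style draw on the same mask,
#'   so the two classes have identical per-lesion HU histograms and differ
#'   only in spatial arrangement.
#' @param pattern_label_noise probability that the generative visual-pattern
#'   label (homogeneous / heterogeneous / napkin-ring) is flipped to a random
#'   other category, emulating imperfect visual reading.
#' @param seed integer seed; each lesion derives its own RNG stream from
#'   `(seed, lesion index)` so cohorts are reproducible.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_lesions = 445L,
                           prevalence_advanced = 0.30,
                           spacing_mm = c(0.4, 0.4, 0.6),
                           slab_thickness_vox = 3L,
                           wall_radius_range_vox = c(5L, 12L),
                           hu_fibrous = c(90, 25),
                           hu_core = c(20, 15),
                           core_fraction_range = c(0.15, 0.40),
                           matched_marginal = TRUE,
                           pattern_label_noise = 0.25,
                           seed = 1L) {
  cfg <- list(n_lesions = as.integer(n_lesions),
              prevalence_advanced = prevalence_advanced,
              spacing_mm = as.numeric(spacing_mm),
              slab_thickness_vox = as.integer(slab_thickness_vox),
              wall_radius_range_vox = as.numeric(wall_radius_range_vox),
              hu_fibrous = as.numeric(hu_fibrous),
              hu_core = as.numeric(hu_core),
              core_fraction_range = as.numeric(core_fraction_range),
              matched_marginal = isTRUE(matched_marginal),
              pattern_label_noise = pattern_label_noise,
              seed = as.integer(seed))
  if (cfg$n_lesions < 1L) stop("n_lesions must be >= 1")
  if (cfg$prevalence_advanced < 0 || cfg$prevalence_advanced > 1)
    stop("prevalence_advanced must be in [0,1]")
  if (any(cfg$spacing_mm <= 0)) stop("spacing_mm must be strictly positive")
  if (cfg$slab_thickness_vox < 1L) stop("slab_thickness_vox must be >= 1")
  if (cfg$wall_radius_range_vox[1] < 3)
    stop("wall radius minimum must be >= 3 voxels")
  if (any(cfg$core_fraction_range < 0) || any(cfg$core_fraction_range > 1) ||
      cfg$pattern_label_noise < 0 || cfg$pattern_label_noise > 1)
    stop("fractions must be in [0,1]")
  class(cfg) <- "phantom_config"
  cfg
}

.pattern_levels <- c("homogeneous", "heterogeneous", "napkin-ring")

# Evaluate `expr` under a private RNG stream, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Per-lesion stream seed: the index-th draw of a generator seeded with the
# cohort seed. Draw-by-draw (prefix-stable), so lesion `i` gets the same
# stream whether generated alone or as part of any cohort, and the seeds
# carry no arithmetic structure in the lesion index.
.lesion_seed <- function(seed, index) {
  .with_seed(seed, sample.int(2147483646L, index, replace = TRUE))[index]
}

.lesion_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(2147483646L, n, replace = TRUE))
}

#' Generate one synthetic plaque lesion
#'
#' Early lesions are an annular/crescent wall filled with fibrous-distributed
#' HU plus a mild smooth in-plane gradient. Advanced lesions add a contiguous
#' low-HU core blob occupying a fraction drawn from `core_fraction_range`;
#' with probability 0.3 the core is ring-shaped. The visual-pattern label
#' follows the generative rule (no core = homogeneous; blob core =
#' heterogeneous; ring core = napkin-ring) and is then flipped to a random
#' other category with probability `pattern_label_noise`.
#'
#' With `matched_marginal = TRUE`, an early lesion is built by drawing an
#' advanced-style lesion and spatially permuting its voxel values, so the HU
#' multiset is preserved exactly while all spatial structure is destroyed.
#'
#' @param config a [phantom_config()].
#' @param advanced logical: generate an advanced lesion?
#' @param lesion_index integer index used (with `config$seed`) to derive this
#'   lesion's private RNG stream.
#' @param stream_seed optional precomputed stream seed (used by
#'   [generate_cohort()] to avoid rederiving seeds lesion by lesion).
#' @return a `phantom_lesion`: list with `volume` (3D int HU array), `mask`
#'   (3D 0/1 array), `spacing`, `label_advanced`, `label_pattern`,
#'   `lesion_id`.
#' @export
generate_lesion <- function(config, advanced, lesion_index = 1L,
                            stream_seed = NULL) {
  if (is.null(stream_seed))
    stream_seed <- .lesion_seed(config$seed, lesion_index)
  .with_seed(stream_seed, {
    for (attempt in seq_len(100L)) {
      les <- .try_generate_lesion(config, advanced, lesion_index)
      if (!is.null(les)) return(les)
    }
    stop("failed to generate a valid lesion mask in 100 attempts")
  })
}

.try_generate_lesion <- function(config, advanced, lesion_index) {
  R <- stats::runif(1, config$wall_radius_range_vox[1], config$wall_radius_range_vox[2])
  r <- R * stats::runif(1, 0.35, 0.60)
  nz <- config$slab_thickness_vox
  half <- ceiling(R) + 2L
  n_side <- 2L * half + 1L
  cx <- half  # 0-based center

  g <- expand.grid(x = 0:(n_side - 1L), y = 0:(n_side - 1L))
  d2 <- sqrt((g$x - cx)^2 + (g$y - cx)^2)
  in_ring <- d2 >= r & d2 <= R
  # crescent: sometimes remove one angular sector (annulus stays connected)
  if (stats::runif(1) < 0.5) {
    theta <- atan2(g$y - cx, g$x - cx)
    a0 <- stats::runif(1, -pi, pi)
    width <- stats::runif(1, pi / 3, 5 * pi / 6)
    dtheta <- ((theta - a0 + pi) %% (2 * pi)) - pi
    in_ring <- in_ring & !(abs(dtheta) <= width / 2)
  }
  sel2d <- which(in_ring)
  if (length(sel2d) * nz < 10L) return(NULL)

  coords <- do.call(rbind, lapply(0:(nz - 1L), function(z)
    cbind(g$x[sel2d], g$y[sel2d], z)))
  n <- nrow(coords)
  if (!.is_single_component(coords)) return(NULL)

  dist2d <- rep(d2[sel2d], nz)
  # fibrous background with a mild smooth in-plane gradient
  grad <- stats::rnorm(2, 0, 1.5)
  values <- stats::rnorm(n, config$hu_fibrous[1], config$hu_fibrous[2]) +
    grad[1] * (coords[, 1] - cx) + grad[2] * (coords[, 2] - cx)

  core_idx <- integer(0)
  ring_core <- FALSE
  if (advanced) {
    frac <- stats::runif(1, config$core_fraction_range[1], config$core_fraction_range[2])
    n_core <- max(1L, round(frac * n))
    ring_core <- stats::runif(1) < 0.3
    if (ring_core) {
      rho <- stats::runif(1, r + 0.15 * (R - r), R - 0.15 * (R - r))
      core_idx <- order(abs(dist2d - rho))[seq_len(n_core)]
    } else {
      core_idx <- .grow_blob(coords, n_core)
    }
    values[core_idx] <- stats::rnorm(length(core_idx),
                                     config$hu_core[1], config$hu_core[2])
  }

  pattern <- if (!advanced) "homogeneous"
             else if (ring_core) "napkin-ring" else "heterogeneous"
  if (!advanced && config$matched_marginal) {
    # draw an advanced-style value field on this mask, then permute it
    frac <- stats::runif(1, config$core_fraction_range[1], config$core_fraction_range[2])
    n_core <- max(1L, round(frac * n))
    if (stats::runif(1) < 0.3) {
      rho <- stats::runif(1, r + 0.15 * (R - r), R - 0.15 * (R - r))
      idx <- order(abs(dist2d - rho))[seq_len(n_core)]
    } else {
      idx <- .grow_blob(coords, n_core)
    }
    values[idx] <- stats::rnorm(length(idx), config$hu_core[1], config$hu_core[2])
    values <- values[sample.int(n)]
    pattern <- "homogeneous"
  }

  if (stats::runif(1) < config$pattern_label_noise)
    pattern <- sample(setdiff(.pattern_levels, pattern), 1L)

  volume <- array(-100L, dim = c(n_side, n_side, nz))
  mask <- array(0L, dim = c(n_side, n_side, nz))
  lin <- coords[, 1] + 1L + n_side * (coords[, 2] + n_side * coords[, 3])
  volume[lin] <- as.integer(round(values))
  mask[lin] <- 1L
  structure(list(volume = volume, mask = mask,
                 spacing = config$spacing_mm,
                 label_advanced = as.integer(advanced),
                 label_pattern = pattern,
                 core_coords = coords[core_idx, , drop = FALSE],
                 lesion_id = sprintf("lesion_%04d", lesion_index)),
            class = "phantom_lesion")
}

# Contiguous blob of size n_core grown by randomized BFS over the 26-neighbor
# graph restricted to the mask.
.grow_blob <- function(coords, n_core) {
  n <- nrow(coords)
  if (n_core >= n) return(seq_len(n))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nbr <- vapply(seq_len(nrow(offs)),
                function(i) .neighbor_index(coords, offs[i, ]), integer(n))
  inblob <- logical(n)
  frontier <- sample.int(n, 1L)
  inblob[frontier] <- TRUE
  size <- 1L
  while (size < n_core) {
    cand <- unique(as.vector(nbr[inblob, , drop = FALSE]))
    cand <- cand[!is.na(cand)]
    cand <- cand[!inblob[cand]]
    if (length(cand) == 0L) break
    take <- min(length(cand), n_core - size,
                max(1L, ceiling(length(cand) / 2)))
    add <- cand[sample.int(length(cand), take)]
    inblob[add] <- TRUE
    size <- size + take
  }
  which(inblob)
}

# Single 26-connected component check via BFS over neighbor lookups.
.is_single_component <- function(coords) {
  n <- nrow(coords)
  if (n == 1L) return(TRUE)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nbr <- vapply(seq_len(nrow(offs)),
                function(i) .neighbor_index(coords, offs[i, ]), integer(n))
  seen <- logical(n)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- unique(as.vector(nbr[frontier, , drop = FALSE]))
    nxt <- nxt[!is.na(nxt)]
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Convert a phantom lesion to the masked voxel representation
#'
#' @param lesion a `phantom_lesion`.
#' @return a [voxel_lesion()].
#' @export
as_voxel_lesion <- function(lesion) {
  idx <- which(lesion$mask == 1L)
  coords <- arrayInd(idx, dim(lesion$mask)) - 1L
  voxel_lesion(values = lesion$volume[idx], coords = coords,
               spacing = lesion$spacing, lesion_id = lesion$lesion_id)
}

#' Generate a labeled cohort of synthetic plaque lesions
#'
#' Exactly `round_half_up(n_lesions * prevalence_advanced)` lesions are
#' advanced (round-half-up so 445 lesions at 30% prevalence give 134
#' advanced). The assignment of advanced status to lesion indices and every
#' lesion's content are deterministic given `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return list with `lesions` (list of `phantom_lesion`) and `labels`
#'   (data.frame: `lesion_id`, `label_advanced`, `label_pattern`).
#' @export
generate_cohort <- function(config) {
  n <- config$n_lesions
  n_adv <- floor(n * config$prevalence_advanced + 0.5)
  advanced <- logical(n)
  if (n_adv > 0L)
    advanced[.with_seed(as.integer((as.numeric(config$seed) + 1) %% 2147483647),
                        sample.int(n, n_adv))] <- TRUE
  seeds <- .lesion_seeds(config$seed, n)
  lesions <- lapply(seq_len(n), function(i)
    generate_lesion(config, advanced[i], lesion_index = i,
                    stream_seed = seeds[i]))
  labels <- data.frame(
    lesion_id = vapply(lesions, `[[`, character(1), "lesion_id"),
    label_advanced = vapply(lesions, `[[`, integer(1), "label_advanced"),
    label_pattern = vapply(lesions, `[[`, character(1), "label_pattern"),
    stringsAsFactors = FALSE)
  list(lesions = lesions, labels = labels)
}

#' Write a phantom cohort to disk as NRRD image/mask pairs plus a labels CSV
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param encoding NRRD encoding, `"raw"` or `"gzip"`.
#' @return invisible path of the labels CSV.
#' @export
write_cohort <- function(cohort, dir, encoding = "gzip") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (les in cohort$lesions) {
    write_lesion(les$volume, les$mask, les$spacing,
                 file.path(dir, paste0(les$lesion_id, "_img.nrrd")),
                 file.path(dir, paste0(les$lesion_id, "_msk.nrrd")),
                 encoding = encoding)
  }
  labels_path <- file.path(dir, "labels.csv")
  utils::write.csv(cohort$labels, labels_path, row.names = FALSE)
  invisible(labels_path)
}
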