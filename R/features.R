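#' Extract the full 1919-feature radiomic vector of one lesion
#'
#' Runs the six discretizations and the four feature families and
#' concatenates them in fixed block order: 44 first-order statistics, 6 x 114
#' co-occurrence features, 6 x 11 run-length features, and 1125 surface /
#' fractal geometry features — 1919 uniquely named parameters per cross
#' section. Deterministic: the same lesion always yields the same vector.
#'
#' @param lesion a [voxel_lesion()].
#' @return named numeric vector of length 1919.
#' @export
extract_features <- function(lesion) {
  dlesions <- discretize_all(lesion)
  coords <- lesion$coords
  n <- nrow(coords)

  fo <- compute_firstorder(lesion)

  nbrs <- .glcm_neighbors(coords)
  glcm <- unlist(lapply(dlesions, function(d)
    .glcm_block_from_context(d$bins, d$B, .scheme_code(d), nbrs)),
    use.names = TRUE)
  names(glcm) <- sub("^(ew|ep)[0-9]+\\.", "", names(glcm))

  dirs <- .directions13()
  ctxs <- lapply(seq_len(nrow(dirs)), function(k) .run_context(coords, dirs[k, ]))
  glrlm <- unlist(lapply(dlesions, function(d)
    .glrlm_block_from_context(d$bins, d$B, .scheme_code(d), ctxs, n)),
    use.names = TRUE)
  names(glrlm) <- sub("^(ew|ep)[0-9]+\\.", "", names(glrlm))

  geom <- compute_geometry_block(lesion, dlesions)

  c(fo, glcm, glrlm, geom)
}

#' The 1919-name feature dictionary
#'
#' @return data.frame with columns `feature` and `block`
#'   (`firstorder` / `glcm` / `glrlm` / `geometry`), in output order.
#' @export
feature_names <- function() {
  codes <- c("ew16", "ew32", "ew64", "ep16", "ep32", "ep64")
  glcm <- unlist(lapply(codes, function(code)
    unlist(lapply(1:3, function(d)
      paste0("glcm_", code, "_d", d, "_",
             rep(c("mean", "range"), each = 19L), "_",
             rep(glcm_statistic_names(), 2L))))))
  glrlm <- unlist(lapply(codes, function(code)
    paste0("glrlm_", code, "_", glrlm_statistic_names())))
  geom <- c("geom_surface", "geom_volume", "geom_boxdim", "geom_infodim",
            "geom_corrdim",
            unlist(lapply(codes, function(code) {
              B <- as.integer(sub("^(ew|ep)", "", code))
              as.vector(t(outer(sprintf("geom_%s_g%02d", code, seq_len(B)),
                                c("surf", "surfratio", "boxdim", "infodim",
                                  "corrdim"), paste, sep = "_")))
            })))
  data.frame(
    feature = c(firstorder_names(), glcm, glrlm, geom),
    block = c(rep("firstorder", length(firstorder_names())),
              rep("glcm", length(glcm)), rep("glrlm", length(glrlm)),
              rep("geometry", length(geom))),
    stringsAsFactors = FALSE)
}

#' Extract features for a whole cohort
#'
#' @param lesions list of `phantom_lesion` or [voxel_lesion()] objects.
#' @param labels optional labels data.frame (joined by `lesion_id`).
#' @param baselines if `TRUE`, append the histogram baselines
#'   (`base_lowatt_area`, `base_mean_hu`) to each row.
#' @return data.frame: `lesion_id`, 1919 feature columns, baselines, and any
#'   label columns. One row per lesion, no missing values.
#' @export
extract_cohort <- function(lesions, labels = NULL, baselines = TRUE) {
  vls <- lapply(lesions, function(l)
    if (inherits(l, "phantom_lesion")) as_voxel_lesion(l) else l)
  n_feat <- 1919L + if (baselines) 2L else 0L
  mat <- vapply(vls, function(vl) {
    fv <- extract_features(vl)
    if (baselines)
      fv <- c(fv, base_lowatt_area = low_attenuation_area(vl),
              base_mean_hu = mean_hu(vl))
    fv
  }, numeric(n_feat))
  out <- data.frame(lesion_id = vapply(vls, `[[`, character(1), "lesion_id"),
                    t(mat), check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(labels)) out <- merge(out, labels, by = "lesion_id", sort = FALSE)
  out
}

#' Filter a cohort record table on exclusion flags
#'
#' Removes records flagged as having no visible plaque or being purely
#' calcified (partial-volume effects of dense calcium preclude soft-tissue
#' texture analysis), and reports the counts removed per reason in the
#' `"exclusions"` attribute.
#'
#' @param records data.frame with logical/0-1 columns `no_visible_plaque`
#'   and `purely_calcified`.
#' @return the retained rows; `attr(, "exclusions")` is a named vector with
#'   counts `no_visible_plaque`, `purely_calcified`, `analyzed`.
#' @export
filter_cohort <- function(records) {
  stopifnot(all(c("no_visible_plaque", "purely_calcified") %in% names(records)))
  no_plaque <- as.logical(records$no_visible_plaque)
  calcified <- !no_plaque & as.logical(records$purely_calcified)
  keep <- !no_plaque & !calcified
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(no_visible_plaque = sum(no_plaque),
                               purely_calcified = sum(calcified),
                               analyzed = sum(keep))
  out
}
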