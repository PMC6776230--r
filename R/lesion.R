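#' Masked voxel representation of one plaque cross-section lesion
#'
#' A `voxel_lesion` is the unit every feature module consumes: the Hounsfield
#' unit (HU) values of the voxels covered by the plaque segmentation mask,
#' their integer grid coordinates, and the physical voxel spacing.
#'
#' @param values integer vector of HU values, one per masked voxel.
#' @param coords integer matrix with `length(values)` rows and columns
#'   `x`, `y`, `z`: 0-based grid indices. Physical position is
#'   `index * spacing`.
#' @param spacing numeric length-3 vector of strictly positive voxel
#'   spacings in mm (in-plane x, in-plane y, through-plane z).
#' @param lesion_id character identifier.
#'
#' @return An object of class `voxel_lesion`: a list with elements
#'   `values`, `coords`, `spacing`, `lesion_id`.
#' @export
voxel_lesion <- function(values, coords, spacing, lesion_id = "lesion") {
  values <- as.integer(values)
  coords <- matrix(as.integer(coords), ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (length(values) < 1L)
    stop("empty lesion: a voxel_lesion needs at least one voxel")
  if (nrow(coords) != length(values))
    stop("values and coords must have the same length")
  if (anyDuplicated(.coord_key(coords)) > 0L)
    stop("duplicate voxel coordinates")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers (mm)")
  structure(list(values = values, coords = coords, spacing = spacing,
                 lesion_id = as.character(lesion_id)),
            class = "voxel_lesion")
}

#' @export
print.voxel_lesion <- function(x, ...) {
  cat(sprintf("<voxel_lesion '%s': %d voxels, HU [%d, %d], spacing %.3g x %.3g x %.3g mm>\n",
              x$lesion_id, length(x$values), min(x$values), max(x$values),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# Unique integer key for coordinate triples; coordinates are shifted to be
# non-negative first so the key works for any integer grid.
.coord_key <- function(coords, origin = NULL, extent = NULL) {
  if (is.null(origin)) origin <- c(min(coords[, 1]), min(coords[, 2]), min(coords[, 3]))
  cx <- coords[, 1] - origin[1]; cy <- coords[, 2] - origin[2]; cz <- coords[, 3] - origin[3]
  if (is.null(extent)) extent <- c(max(cx), max(cy), max(cz)) + 1
  # doubles hold exact integers well beyond any realistic grid size here
  cx + extent[1] * (cy + extent[2] * cz)
}

# Index of each voxel's neighbor at coords + offset, NA when the neighbor is
# not part of the lesion. Shared by GLCM, GLRLM, and surface-area code.
.neighbor_index <- function(coords, offset) {
  origin <- c(min(coords[, 1]), min(coords[, 2]), min(coords[, 3])) - 3L * max(abs(offset), 1L)
  extent <- c(max(coords[, 1]), max(coords[, 2]), max(coords[, 3])) - origin + 8L * max(abs(offset), 1L)
  key <- .coord_key(coords, origin, extent)
  nkey <- (coords[, 1] + offset[1] - origin[1]) +
    extent[1] * ((coords[, 2] + offset[2] - origin[2]) +
                   extent[2] * (coords[, 3] + offset[3] - origin[3]))
  match(nkey, key)
}

# The 13 unique 3D directions (one per axis pair up to sign).
.directions13 <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0),
    c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
}
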