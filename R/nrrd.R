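#' Read an NRRD volume
#'
#' Minimal NRRD reader covering the files this pipeline exchanges: 3D arrays,
#' attached or detached headers, `raw` or `gzip` encoding, little- or
#' big-endian integer types. Spacing is taken from `space directions` (the
#' diagonal) or, failing that, from `spacings`.
#'
#' @param path path to a `.nrrd` (attached) or `.nhdr` (detached) file.
#' @return list with `data` (3D array), `spacing` (numeric length 3, mm;
#'   `NA` if the header carries none), and `header` (named character vector).
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    sep <- regexpr(":", line, fixed = TRUE)
    if (sep < 0L) next
    key <- tolower(trimws(substr(line, 1L, sep - 1L)))
    val <- trimws(sub("^=", "", trimws(substring(line, sep + 1L))))
    header[key] <- val
  }
  dims <- as.integer(strsplit(header[["sizes"]], "\\s+")[[1]])
  if (length(dims) != 3L) stop("only 3D NRRD volumes are supported")
  type <- .nrrd_type(header[["type"]])
  encoding <- tolower(header[["encoding"]])
  endian <- if (!is.na(header["endian"])) header[["endian"]] else "little"

  n <- prod(dims)
  if (!is.na(header["data file"])) {
    datafile <- file.path(dirname(path), header[["data file"]])
    raw_bytes <- readBin(datafile, "raw", n = file.info(datafile)$size)
  } else {
    raw_bytes <- readBin(con, "raw", n = 1e9)
  }
  if (encoding == "gzip") {
    raw_bytes <- memDecompress(raw_bytes, type = "gzip")
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding: ", encoding)
  }
  vals <- readBin(raw_bytes, what = type$what, n = n, size = type$size,
                  signed = type$signed, endian = endian)
  if (length(vals) != n) stop("NRRD payload shorter than sizes field implies")

  spacing <- rep(NA_real_, 3L)
  if (!is.na(header["space directions"])) {
    vecs <- regmatches(header[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", header[["space directions"]]))[[1]]
    if (length(vecs) == 3L) {
      m <- t(vapply(vecs, function(v)
        as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
      spacing <- sqrt(rowSums(m^2))
    }
  } else if (!is.na(header["spacings"])) {
    spacing <- as.numeric(strsplit(header[["spacings"]], "\\s+")[[1]])
  }
  list(data = array(vals, dim = dims), spacing = spacing, header = header)
}

.nrrd_type <- function(type) {
  type <- tolower(type)
  if (type %in% c("short", "int16", "signed short", "int16_t"))
    list(what = "integer", size = 2L, signed = TRUE)
  else if (type %in% c("uchar", "unsigned char", "uint8", "uint8_t"))
    list(what = "integer", size = 1L, signed = FALSE)
  else if (type %in% c("int", "int32", "signed int", "int32_t"))
    list(what = "integer", size = 4L, signed = TRUE)
  else if (type %in% c("ushort", "unsigned short", "uint16", "uint16_t"))
    list(what = "integer", size = 2L, signed = FALSE)
  else if (type %in% c("float")) list(what = "numeric", size = 4L, signed = TRUE)
  else if (type %in% c("double")) list(what = "numeric", size = 8L, signed = TRUE)
  else stop("unsupported NRRD type: ", type)
}

#' Write a 3D array as an attached-header NRRD file
#'
#' @param data 3D numeric/integer array.
#' @param path output path.
#' @param spacing numeric length-3 voxel spacing in mm, recorded as diagonal
#'   `space directions`.
#' @param type `"short"` (int16) or `"uchar"` (uint8).
#' @param encoding `"raw"` or `"gzip"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(data, path, spacing = c(1, 1, 1), type = "short",
                       encoding = "raw") {
  stopifnot(length(dim(data)) == 3L, type %in% c("short", "uchar"),
            encoding %in% c("raw", "gzip"))
  size <- if (type == "short") 2L else 1L
  header <- c(
    "NRRD0004",
    sprintf("type: %s", type),
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", dim(data)[1], dim(data)[2], dim(data)[3]),
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            spacing[1], spacing[2], spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    sprintf("encoding: %s", encoding),
    "space origin: (0,0,0)"
  )
  payload_con <- rawConnection(raw(0), "wb")
  writeBin(as.integer(data), payload_con, size = size, endian = "little")
  payload <- rawConnectionValue(payload_con)
  close(payload_con)
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(header, con, sep = "\n")
  writeLines("", con, sep = "\n")
  writeBin(payload, con)
  invisible(path)
}

#' Read a segmented lesion from an NRRD image/mask pair
#'
#' Returns the voxels where the mask equals 1, with their HU values and
#' 0-based grid coordinates; spacing is taken from the image header. The two
#' grids must agree in shape and spacing; mask values other than 0/1 are
#' rejected.
#'
#' @param image_path path to the HU image NRRD.
#' @param mask_path path to the binary segmentation mask NRRD.
#' @param lesion_id identifier for the returned lesion.
#' @return a [voxel_lesion()].
#' @export
read_lesion <- function(image_path, mask_path, lesion_id = NULL) {
  img <- read_nrrd(image_path)
  msk <- read_nrrd(mask_path)
  if (!identical(dim(img$data), dim(msk$data)))
    stop("image and mask grid shapes differ")
  if (all(is.finite(img$spacing)) && all(is.finite(msk$spacing)) &&
      any(abs(img$spacing - msk$spacing) > 1e-6))
    stop("image and mask spacing differ")
  bad <- setdiff(unique(as.vector(msk$data)), c(0, 1))
  if (length(bad))
    stop("mask contains values other than {0,1}: ", paste(bad, collapse = ", "))
  idx <- which(msk$data == 1)
  if (length(idx) == 0L) stop("empty lesion: mask selects no voxels")
  coords <- arrayInd(idx, dim(msk$data)) - 1L
  if (is.null(lesion_id))
    lesion_id <- sub("\\.(nrrd|nhdr)$", "", basename(image_path))
  voxel_lesion(values = img$data[idx], coords = coords,
               spacing = img$spacing, lesion_id = lesion_id)
}

#' Write a lesion volume and its mask as NRRD files
#'
#' The image is written as int16 HU, the mask as uint8 {0,1}; spacing is
#' recorded in both headers. Round-trips losslessly through [read_lesion()].
#'
#' @param volume 3D integer HU array.
#' @param mask 3D 0/1 array of the same shape.
#' @param spacing numeric length-3 spacing in mm.
#' @param image_path,mask_path output paths.
#' @param encoding `"raw"` or `"gzip"`.
#' @return invisible list of the two paths.
#' @export
write_lesion <- function(volume, mask, spacing, image_path, mask_path,
                         encoding = "raw") {
  if (!identical(dim(volume), dim(mask)))
    stop("volume and mask shapes differ")
  write_nrrd(volume, image_path, spacing = spacing, type = "short",
             encoding = encoding)
  write_nrrd(mask, mask_path, spacing = spacing, type = "uchar",
             encoding = encoding)
  invisible(list(image = image_path, mask = mask_path))
}
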