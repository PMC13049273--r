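# 3D scalar volumes with physical geometry, and MetaImage (MHD) input/output.

#' Grid geometry of a 3D volume
#'
#' @param dim integer length-3 voxel counts (x, y, z).
#' @param spacing voxel spacing in mm (length 3, > 0).
#' @param origin physical position of the center of voxel (1,1,1) in mm.
#' @param direction 3 x 3 direction-cosine matrix (defaults to identity).
#' @return object of class `grid_geometry`.
#' @export
grid_geometry <- function(dim, spacing, origin = c(0, 0, 0), direction = diag(3)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1),
            length(spacing) == 3, all(spacing > 0),
            length(origin) == 3, all(dim(as.matrix(direction)) == c(3, 3)))
  structure(list(dim = dim, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = as.matrix(direction)),
            class = "grid_geometry")
}

#' Centered grid geometry covering a physical extent
#'
#' Convenience constructor: voxel centers symmetric about `center` with the given
#' spacing, covering `extent` mm along each axis.
#'
#' @param extent physical extent in mm (length 3).
#' @param spacing voxel spacing in mm (length 3 or scalar).
#' @param center physical center of the grid in mm.
#' @return a [grid_geometry()].
#' @export
centered_geometry <- function(extent, spacing, center = c(0, 0, 0)) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  dim <- pmax(1L, as.integer(round(extent / spacing)))
  origin <- center - (dim - 1) / 2 * spacing
  grid_geometry(dim, spacing, origin)
}

#' Physical coordinates of every voxel center
#'
#' @param geom a [grid_geometry()].
#' @return `prod(dim) x 3` matrix in voxel-linear (x fastest) order, mm.
#' @export
grid_points <- function(geom) {
  idx <- as.matrix(expand.grid(i = seq_len(geom$dim[1]) - 1,
                               j = seq_len(geom$dim[2]) - 1,
                               k = seq_len(geom$dim[3]) - 1))
  phys <- t(geom$direction %*% (t(idx) * geom$spacing)) +
    matrix(geom$origin, nrow(idx), 3, byrow = TRUE)
  unname(phys)
}

#' Convert between voxel indices and physical coordinates
#'
#' Indices are 1-based; the transform round-trips to better than 1e-9 mm.
#'
#' @param geom a [grid_geometry()].
#' @param index n x 3 matrix of 1-based voxel indices.
#' @param phys n x 3 matrix of physical coordinates (mm).
#' @return the transformed n x 3 matrix.
#' @export
index_to_physical <- function(geom, index) {
  index <- as_points(index)
  t(geom$direction %*% (t(index - 1) * geom$spacing)) +
    matrix(geom$origin, nrow(index), 3, byrow = TRUE)
}

#' @rdname index_to_physical
#' @export
physical_to_index <- function(geom, phys) {
  phys <- as_points(phys)
  rel <- t(solve(geom$direction) %*% t(phys - matrix(geom$origin, nrow(phys), 3, byrow = TRUE)))
  sweep(rel, 2, geom$spacing, "/") + 1
}

geometry_equal <- function(a, b, tol = 1e-6) {
  all(a$dim == b$dim) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

#' Construct an image volume
#'
#' A 3D scalar array with physical geometry, a mandatory units tag and free-form
#' provenance metadata.  This is the common container for DWI signal volumes, ADC
#' maps (micron^2/ms), b-maps (dimensionless, integer-scaled) and percent bias maps.
#'
#' @param data 3D numeric array (x, y, z).
#' @param geom a [grid_geometry()] matching `dim(data)`.
#' @param units one of "micron2/ms", "dimensionless", "percent", "a.u.", "label".
#' @param meta named list of provenance metadata.
#' @return object of class `image_volume`.
#' @export
image_volume <- function(data, geom, units, meta = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (missing(units)) stop("a units tag is mandatory")
  units <- match.arg(units, c("micron2/ms", "dimensionless", "percent", "a.u.", "label"))
  if (!all(dim(data) == geom$dim)) stop("data dimensions do not match geometry")
  structure(list(data = data, geom = geom, units = units, meta = meta),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(x$geom$dim, collapse = " x "),
      " voxels, spacing ", paste(format(x$geom$spacing), collapse = " x "),
      " mm, units: ", x$units, "\n", sep = "")
  invisible(x)
}

#' Voxel volume of an image grid
#' @param x an [image_volume()] or [grid_geometry()].
#' @return voxel volume in mm^3.
#' @export
voxel_volume <- function(x) {
  g <- if (inherits(x, "image_volume")) x$geom else x
  prod(g$spacing)
}

#' Crop an image volume to an index window
#'
#' @param vol an [image_volume()].
#' @param i,j,k index ranges (vectors of 1-based indices) to retain.
#' @return cropped [image_volume()] with geometry updated so voxel centers keep their
#'   physical positions.
#' @export
crop_volume <- function(vol, i, j, k) {
  stopifnot(inherits(vol, "image_volume"))
  d <- vol$data[i, j, k, drop = FALSE]
  new_origin <- index_to_physical(vol$geom, cbind(min(i), min(j), min(k)))[1, ]
  geom <- grid_geometry(dim(d), vol$geom$spacing, new_origin, vol$geom$direction)
  image_volume(d, geom, vol$units, vol$meta)
}

# -- MetaImage (MHD) I/O -------------------------------------------------------------

mhd_types <- c(MET_DOUBLE = "double", MET_FLOAT = "double",
               MET_INT = "integer", MET_SHORT = "integer",
               MET_USHORT = "integer", MET_UCHAR = "integer")
mhd_sizes <- c(MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_INT = 4L, MET_SHORT = 2L,
               MET_USHORT = 2L, MET_UCHAR = 1L)

#' Read / write an image volume in MetaImage (MHD) format
#'
#' Plain-text `.mhd` header plus a raw little-endian data file.  Geometry (spacing,
#' offset, direction cosines) round-trips to 1e-9 mm and voxel data round-trip
#' bit-exactly (`MET_DOUBLE` for floating point, `MET_INT` for integer volumes such
#' as label maps and b-maps).  The units tag is carried in a `Units` header line, an
#' extension that standard readers ignore.
#'
#' @param path path to the `.mhd` header file.
#' @return [read_mhd()] returns an [image_volume()]; [write_mhd()] returns `path`
#'   invisibly.
#' @export
read_mhd <- function(path) {
  if (!file.exists(path)) stop("MHD header not found: ", path)
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stop("malformed MHD header, missing: ", paste(miss, collapse = ", "))
  if (as.integer(kv$NDims) != 3) stop("only 3D MHD volumes are supported")
  dim3 <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  if (length(dim3) != 3 || any(is.na(dim3))) stop("malformed DimSize in MHD header")
  etype <- kv$ElementType
  if (!etype %in% names(mhd_types)) stop("unsupported ElementType: ", etype)
  spacing <- if (!is.null(kv$ElementSpacing)) {
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]])
  } else c(1, 1, 1)
  origin <- if (!is.null(kv$Offset)) as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  direction <- if (!is.null(kv$TransformMatrix)) {
    matrix(as.numeric(strsplit(kv$TransformMatrix, "\\s+")[[1]]), 3, 3, byrow = TRUE)
  } else diag(3)
  units <- kv$Units %||% "a.u."
  datafile <- kv$ElementDataFile
  if (datafile == "LOCAL") stop("LOCAL data storage is not supported")
  datapath <- file.path(dirname(path), datafile)
  if (!file.exists(datapath)) stop("MHD data file not found: ", datapath)
  n <- prod(dim3)
  expect_bytes <- n * mhd_sizes[[etype]]
  if (file.size(datapath) != expect_bytes) {
    stop(sprintf("MHD size mismatch: header implies %d bytes, file has %d",
                 expect_bytes, file.size(datapath)))
  }
  con <- file(datapath, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = mhd_types[[etype]], n = n,
                  size = mhd_sizes[[etype]], endian = "little",
                  signed = !etype %in% c("MET_USHORT", "MET_UCHAR"))
  arr <- array(vals, dim = dim3)
  image_volume(arr, grid_geometry(dim3, spacing, origin, direction), units,
               meta = list(source = path, element_type = etype))
}

#' @param vol an [image_volume()].
#' @param element_type `MET_DOUBLE` (default for floating point) or `MET_INT`,
#'   `MET_SHORT`, `MET_USHORT`, `MET_UCHAR` for integer data.
#' @rdname read_mhd
#' @export
write_mhd <- function(path, vol, element_type = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  if (is.null(element_type)) {
    element_type <- if (is.integer(vol$data) ||
                        isTRUE(all(vol$data == round(vol$data)) &&
                               max(abs(vol$data)) < .Machine$integer.max &&
                               vol$units %in% c("label", "dimensionless"))) {
      "MET_INT"
    } else "MET_DOUBLE"
  }
  if (!element_type %in% names(mhd_types)) stop("unsupported ElementType: ", element_type)
  rawname <- sub("\\.mhd$", ".raw", basename(path))
  if (identical(rawname, basename(path))) rawname <- paste0(basename(path), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", paste(format(t(vol$geom$direction), digits = 17), collapse = " ")),
    paste("Offset =", paste(format(vol$geom$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$geom$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(vol$geom$dim, collapse = " ")),
    paste("Units =", vol$units),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", rawname))
  writeLines(header, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  vals <- as.vector(vol$data)
  if (mhd_types[[element_type]] == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = mhd_sizes[[element_type]], endian = "little")
  invisible(path)
}

#' Apply DICOM-style display-value scaling
#'
#' Converts stored (integer) pixel values to physical values via
#' `physical = slope * stored + intercept`.  The b-map convention stores the
#' dimensionless trace corrector as integers scaled by 1e4 at isocenter, i.e.
#' `slope = 1e-4`, `intercept = 0`.
#'
#' @param stored numeric vector/array of stored values.
#' @param slope rescale slope (finite, non-zero).
#' @param intercept rescale intercept.
#' @param inverse if `TRUE`, map physical values back to stored values.
#' @return rescaled values, same shape as `stored`.
#' @export
apply_display_scaling <- function(stored, slope, intercept = 0, inverse = FALSE) {
  if (!is.finite(slope) || slope == 0) stop("rescale slope must be finite and non-zero")
  if (inverse) (stored - intercept) / slope else slope * stored + intercept
}
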