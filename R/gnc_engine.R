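# b-map construction, two-point trace ADC fitting, gradient-nonlinearity correction
# (GNC) and fractional ADC bias maps.

#' Bundle a two-point trace DWI acquisition
#'
#' @param s0 [image_volume()] of the b = 0 s/mm^2 signal.
#' @param sb [image_volume()] of the trace diffusion-weighted signal (geometric mean
#'   over the three directions) at the nominal b-value.
#' @param b_nominal nominal b-value in s/mm^2 (> 0).
#' @param dirs [direction_set()] used for the trace acquisition.
#' @param table_offset couch offset of the imaging station in mm (see [make_bmap()]).
#' @param mask logical array of voxels inside the imaged object; defaults to
#'   `s0 > 0 & sb > 0`.
#' @return object of class `dwi_series`.
#' @export
dwi_series <- function(s0, sb, b_nominal = 800, dirs = direction_set(),
                       table_offset = 0, mask = NULL) {
  stopifnot(inherits(s0, "image_volume"), inherits(sb, "image_volume"), b_nominal > 0)
  if (!geometry_equal(s0$geom, sb$geom)) stop("S0 and DW volumes must share geometry")
  if (is.null(mask)) mask <- s0$data > 0 & sb$data > 0
  if (any(mask & (s0$data <= 0 | sb$data <= 0))) {
    stop("signals must be positive within the object mask")
  }
  if (!inherits(dirs, "direction_set")) dirs <- direction_set(dirs)
  structure(list(s0 = s0, sb = sb, b_nominal = b_nominal, dirs = dirs,
                 table_offset = table_offset, mask = mask),
            class = "dwi_series")
}

# magnet-frame coordinates of voxel centers: couch-frame grid shifted by the
# station table offset along superior-inferior
magnet_points <- function(geom, table_offset) {
  pts <- grid_points(geom)
  pts[, 3] <- pts[, 3] - table_offset
  pts
}

#' Build a b-map for an imaging station
#'
#' Evaluates the trace b-value corrector `cbar(r) = tr(L'L)/3` at the magnet-frame
#' position of every voxel center and stores it integer-scaled so the isocenter value
#' is 1e4 (the on-scanner DICOM convention).  Grid coordinates are couch-frame; the
#' station table offset shifts them along superior-inferior into the magnet frame
#' (`z_magnet = z_couch - offset`), so two stations sampling the same magnet-frame
#' location yield identical values regardless of their offsets.
#'
#' @param model a [coil_model()].
#' @param geom a [grid_geometry()] in couch coordinates (mm).
#' @param dirs a [direction_set()]; the trace corrector is triad-invariant, the
#'   argument is validated for orthonormality.
#' @param table_offset station couch offset in mm.
#' @return an [image_volume()] of class `bmap` with integer values
#'   `v = round(1e4 * cbar)`, units "dimensionless", and the table offset recorded in
#'   `meta$table_offset`.
#' @export
make_bmap <- function(model, geom, dirs = direction_set(), table_offset = 0) {
  stopifnot(inherits(model, "coil_model"))
  if (!inherits(dirs, "direction_set")) dirs <- direction_set(dirs)
  pts <- magnet_points(geom, table_offset)
  r <- sqrt(rowSums(pts^2))
  if (any(r > validity_radius(model))) {
    stop(sprintf(
      "station grid reaches %.0f mm from isocenter (offset %.0f mm), beyond the validity radius %.0f mm",
      max(r), table_offset, validity_radius(model)))
  }
  v <- round(1e4 * cbar_at(model, pts))
  vol <- image_volume(array(v, dim = geom$dim), geom, "dimensionless",
                      meta = list(kind = "bmap", table_offset = table_offset,
                                  coil = model$name))
  class(vol) <- c("bmap", class(vol))
  vol
}

#' Percent b-value bias map
#'
#' `beta(r) = 100 * ((v(r) / 1e4) - 1)`, zero at isocenter by construction.
#'
#' @param bmap a b-map from [make_bmap()] (or any [image_volume()] holding
#'   integer-scaled `1e4 * cbar` values).
#' @return an [image_volume()] in percent units.
#' @export
bias_percent <- function(bmap) {
  stopifnot(inherits(bmap, "image_volume"))
  image_volume(100 * (bmap$data / 1e4 - 1), bmap$geom, "percent",
               meta = c(bmap$meta[setdiff(names(bmap$meta), "kind")],
                        list(kind = "bias_percent")))
}

#' Fit the two-point trace ADC map
#'
#' Mono-exponential inversion `ADC = ln(S0 / Sb) / b`, reported in micron^2/ms.
#' Voxels where the diffusion-weighted signal meets or exceeds S0 are floored at
#' zero and flagged out of the validity mask; non-positive signals inside the object
#' mask are excluded and counted.
#'
#' @param dwi a [dwi_series()].
#' @return an [image_volume()] in micron^2/ms with attributes `mask` (logical array
#'   of valid voxels) and `corrected = FALSE`; the number of excluded voxels is in
#'   `meta$n_excluded`.
#' @export
fit_adc <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_series"))
  s0 <- dwi$s0$data
  sb <- dwi$sb$data
  mask <- dwi$mask
  bad <- mask & (s0 <= 0 | sb <= 0)
  mask[bad] <- FALSE
  adc <- array(0, dim = dim(s0))
  # 1 mm^2/s = 1000 micron^2/ms
  adc[mask] <- 1000 * log(s0[mask] / sb[mask]) / dwi$b_nominal
  floored <- mask & sb >= s0
  adc[floored] <- 0
  mask[floored] <- FALSE
  vol <- image_volume(adc, dwi$s0$geom, "micron2/ms",
                      meta = list(corrected = FALSE,
                                  b_nominal = dwi$b_nominal,
                                  table_offset = dwi$table_offset,
                                  n_excluded = sum(bad),
                                  n_floored = sum(floored)))
  attr(vol, "mask") <- mask
  attr(vol, "corrected") <- FALSE
  vol
}

#' Apply gradient-nonlinearity correction to an ADC map
#'
#' Divides the measured trace ADC voxelwise by the trace b-value corrector
#' `cbar = v / 1e4`.  For isotropic diffusion the measured trace ADC equals
#' `cbar * ADC_true`, so the correction is exact in the noiseless limit.
#'
#' @param adc uncorrected ADC [image_volume()] from [fit_adc()].
#' @param bmap geometrically aligned b-map from [make_bmap()].
#' @return corrected ADC [image_volume()] (attribute `corrected = TRUE`).
#' @export
apply_gnc <- function(adc, bmap) {
  stopifnot(inherits(adc, "image_volume"), inherits(bmap, "image_volume"))
  if (!geometry_equal(adc$geom, bmap$geom)) {
    stop("ADC map and b-map geometries do not match")
  }
  if (any(bmap$data <= 0)) stop("b-map must be positive everywhere")
  out <- adc
  out$data <- adc$data / (bmap$data / 1e4)
  out$meta$corrected <- TRUE
  attr(out, "mask") <- attr(adc, "mask")
  attr(out, "corrected") <- TRUE
  out
}

#' Fractional ADC bias map
#'
#' Percent difference of uncorrected versus corrected ADC,
#' `100 * (ADC - ADC_GNC) / ADC_GNC`.  On a noiseless uniform phantom this
#' reproduces the model bias map ([bias_percent()]) voxelwise, which is the phantom
#' validation logic for an on-scanner correction.
#'
#' @param adc uncorrected ADC [image_volume()].
#' @param adc_gnc corrected ADC [image_volume()] on the same grid and mask.
#' @return [image_volume()] in percent with attribute `mask` (voxels with
#'   `ADC_GNC > 0` inside the shared mask).
#' @export
fractional_adc_bias <- function(adc, adc_gnc) {
  stopifnot(inherits(adc, "image_volume"), inherits(adc_gnc, "image_volume"))
  if (!geometry_equal(adc$geom, adc_gnc$geom)) stop("volumes are not aligned")
  mask <- attr(adc, "mask")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(adc$data))
  mask <- mask & adc_gnc$data > 0
  out <- array(NA_real_, dim = dim(adc$data))
  out[mask] <- 100 * (adc$data[mask] - adc_gnc$data[mask]) / adc_gnc$data[mask]
  vol <- image_volume(out, adc$geom, "percent", meta = list(kind = "fractional_adc_bias"))
  attr(vol, "mask") <- mask
  vol
}

#' In-plane 3x3 median smoothing
#'
#' Per-voxel median over the 3-voxel neighborhood along each of the two configured
#' in-plane axes (a 3 x 3 window, truncated at volume edges).  A display aid for
#' maps; it is never applied before statistics.
#'
#' @param vol an [image_volume()].
#' @param axes the two in-plane axes (default x-y planes, `c(1, 2)`).
#' @return smoothed [image_volume()].
#' @export
median_smooth3 <- function(vol, axes = c(1, 2)) {
  stopifnot(inherits(vol, "image_volume"), length(axes) == 2, all(axes %in% 1:3))
  d <- vol$data
  dims <- dim(d)
  out <- d
  off <- expand.grid(a = -1:1, b = -1:1)
  perp <- setdiff(1:3, axes)
  n <- prod(dims)
  stack <- matrix(NA_real_, nrow = n, ncol = nrow(off))
  idx <- arrayInd(seq_len(n), dims)
  for (w in seq_len(nrow(off))) {
    shifted <- idx
    shifted[, axes[1]] <- idx[, axes[1]] + off$a[w]
    shifted[, axes[2]] <- idx[, axes[2]] + off$b[w]
    ok <- shifted[, axes[1]] >= 1 & shifted[, axes[1]] <= dims[axes[1]] &
      shifted[, axes[2]] >= 1 & shifted[, axes[2]] <= dims[axes[2]]
    lin <- rep(NA_integer_, n)
    lin[ok] <- (shifted[ok, 3] - 1) * dims[1] * dims[2] +
      (shifted[ok, 2] - 1) * dims[1] + shifted[ok, 1]
    stack[, w] <- d[lin]
  }
  out[] <- apply(stack, 1, stats::median, na.rm = TRUE)
  vol$data <- out
  vol$meta$smoothed <- "median3"
  vol
}
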