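# Region-of-interest statistics, histograms, intra-subject nonuniformity, the
# across-site heterogeneity index and deviations from the cohort ADC trend.

#' Site groupings for bone-marrow analysis
#'
#' Middle vertebrae (MV: L2, L3, L4), edge vertebrae (EV: T12, L1, L5, S1, plus T11
#' when present), bilateral ilium (I) and bilateral trochanter (T).
#'
#' @param include_t11 include T11 in the edge-vertebra group.
#' @return named list of site-label character vectors (disjoint).
#' @export
site_groups <- function(include_t11 = TRUE) {
  ev <- c("T12", "L1", "L5", "S1")
  if (include_t11) ev <- c("T11", ev)
  groups <- list(MV = c("L2", "L3", "L4"), EV = ev,
                 I = c("RI", "LI"), T = c("RT", "LT"))
  stopifnot(!anyDuplicated(unlist(groups)),
            all(unlist(groups) %in% names(site_codes())))
  groups
}

#' Per-site ROI statistics
#'
#' Statistics over the voxels of each labeled site, optionally restricted to values
#' above a lower threshold (the ADC analysis uses `threshold = 0.01` micron^2/ms to
#' drop voxels with no diffusion contrast).  Sites absent from the label map (or
#' with no voxel above threshold) are simply absent from the result, mirroring
#' variable vertebra coverage across subjects.
#'
#' @param vol an [image_volume()] of values.
#' @param labels an [image_volume()] of integer site labels on the same grid.
#' @param threshold optional lower bound; only voxels with `value > threshold` are
#'   included.
#' @param mask optional logical array further restricting the voxels.
#' @param dictionary named integer vector mapping site labels to codes; defaults to
#'   [site_codes()].
#' @return data.frame with one row per present site: `site`, `n`, `volume_cm3`,
#'   `mean`, `median`, `sd`, `min`, `max`, `range`.
#' @export
roi_statistics <- function(vol, labels, threshold = NULL, mask = NULL,
                           dictionary = site_codes()) {
  stopifnot(inherits(vol, "image_volume"), inherits(labels, "image_volume"))
  if (!geometry_equal(vol$geom, labels$geom)) {
    stop("value volume and label map geometries do not match")
  }
  keep <- labels$data > 0
  if (!is.null(mask)) keep <- keep & mask
  vv <- voxel_volume(vol)
  rows <- list()
  for (s in names(dictionary)) {
    sel <- keep & labels$data == dictionary[[s]]
    vals <- vol$data[sel]
    if (!is.null(threshold)) vals <- vals[vals > threshold]
    if (length(vals) == 0) next
    rows[[s]] <- data.frame(
      site = s, n = length(vals), volume_cm3 = length(vals) * vv / 1000,
      mean = mean(vals), median = stats::median(vals),
      sd = if (length(vals) > 1) stats::sd(vals) else 0,
      min = min(vals), max = max(vals), range = max(vals) - min(vals))
  }
  if (length(rows) == 0) {
    return(data.frame(site = character(), n = integer(), volume_cm3 = numeric(),
                      mean = numeric(), median = numeric(), sd = numeric(),
                      min = numeric(), max = numeric(), range = numeric()))
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}

#' Histogram with zero-anchored, left-closed bins
#'
#' Bin edges are integer multiples of `bin_size` (anchored at 0, so histograms are
#' reproducible regardless of the data range), bins are left-closed/right-open, and
#' masses are normalized either to total count or to total ROI volume (identical on
#' a uniform grid, where each voxel carries the same volume).
#'
#' @param values numeric vector.
#' @param bin_size bin width (> 0); e.g. 0.5 for percent bias maps, 0.05
#'   micron^2/ms for ADC.
#' @param normalization "count" or "volume".
#' @param voxel_volume_mm3 voxel volume, required for `normalization = "volume"`.
#' @return data.frame with `left`, `right` bin edges and normalized `mass`
#'   (summing to 1), or an empty data.frame for empty input.
#' @export
build_histogram <- function(values, bin_size, normalization = c("count", "volume"),
                            voxel_volume_mm3 = 1) {
  normalization <- match.arg(normalization)
  if (bin_size <= 0) stop("bin_size must be positive")
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    return(data.frame(left = numeric(), right = numeric(), mass = numeric()))
  }
  idx <- floor(values / bin_size)
  counts <- table(idx)
  k <- as.numeric(names(counts))
  mass <- if (normalization == "count") {
    as.numeric(counts) / length(values)
  } else {
    as.numeric(counts) * voxel_volume_mm3 / (length(values) * voxel_volume_mm3)
  }
  data.frame(left = k * bin_size, right = (k + 1) * bin_size, mass = mass)
}

#' Intra-subject bias nonuniformity
#'
#' The spread (max minus min) of the site-mean bias across the bone sites of one
#' subject: the amount of purely technical ADC nonuniformity the correction
#' removes.
#'
#' @param site_means numeric vector of per-site mean values (e.g. percent bias) for
#'   one subject; `NA` entries are dropped.
#' @return `max - min` (>= 0), or `NA` with a warning when fewer than 2 sites are
#'   available.
#' @export
intra_subject_nonuniformity <- function(site_means) {
  x <- site_means[is.finite(site_means)]
  if (length(x) < 2) {
    warning("nonuniformity undefined with fewer than 2 sites")
    return(NA_real_)
  }
  max(x) - min(x)
}

#' Across-site heterogeneity (coefficient of variation)
#'
#' `100 * SD / mean` of the site-mean ADC values of one subject; scale invariant.
#'
#' @param site_means numeric vector of per-site mean ADC for one subject (mean > 0).
#' @return percent CV, or `NA` with a warning for fewer than 2 sites.
#' @export
heterogeneity_cv <- function(site_means) {
  x <- site_means[is.finite(site_means)]
  if (length(x) < 2) {
    warning("CV undefined with fewer than 2 sites")
    return(NA_real_)
  }
  m <- mean(x)
  if (m <= 0) stop("mean must be positive for a CV")
  100 * stats::sd(x) / m
}

#' Deviation from the cohort ADC heterogeneity trend
#'
#' The reference trend across site groups for corrected marrow ADC is: ilium
#' highest, then edge vertebrae, mid vertebrae, trochanter lowest.  Flags mark a
#' subject deviating from it: ilium below trochanter, ilium below mid-vertebrae,
#' edge below mid-vertebrae.  Strict inequalities; exact ties (measure-zero on
#' real data) do not raise a flag, and a missing group leaves its flag `NA`.
#'
#' @param group_means named numeric vector with entries `T`, `I`, `MV`, `EV` (any
#'   subset).
#' @return named logical vector: `ilium_below_trochanter`, `ilium_below_mid`,
#'   `edge_below_mid`.
#' @export
trend_deviation <- function(group_means) {
  g <- function(nm) if (nm %in% names(group_means)) group_means[[nm]] else NA_real_
  flag <- function(a, b) {
    if (is.na(a) || is.na(b)) NA else a < b
  }
  c(ilium_below_trochanter = flag(g("I"), g("T")),
    ilium_below_mid = flag(g("I"), g("MV")),
    edge_below_mid = flag(g("EV"), g("MV")))
}
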