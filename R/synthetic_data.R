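# Digital reference objects: a uniform diffusion phantom and a virtual bone-marrow
# cohort with multi-station coverage, fat-fraction-dependent signal and
# repositioning jitter, so the full correction and repeatability analysis runs
# without any acquired data.

#' Bone-site label dictionary
#'
#' Integer codes for the bone-marrow sites: right/left trochanter (RT/LT),
#' right/left posterior ilium (RI/LI), thoracic T11/T12, lumbar L1-L5 and sacral S1
#' vertebral bodies.  0 is background.
#'
#' @return named integer vector (site label -> code).
#' @export
site_codes <- function() {
  c(RT = 1L, LT = 2L, RI = 3L, LI = 4L, T11 = 5L, T12 = 6L, L1 = 7L,
    L2 = 8L, L3 = 9L, L4 = 10L, L5 = 11L, S1 = 12L)
}

#' Default bone-site geometry and tissue parameters
#'
#' Ellipsoidal sites in a patient frame anchored at the L3 vertebral body
#' (x patient-left, y posterior-to-anterior, z superior, mm).  Trochanters sit
#' laterally at +-105 mm and 80 mm inferior of L3, ilia at +-50 mm, vertebral bodies
#' on the midline with a 32 mm superior-inferior pitch.  Semi-axes reproduce
#' plausible adult ROI volumes (trochanter ~88 cm^3, ilium ~72 cm^3, vertebra
#' ~20-22 cm^3).  `adc_true` defaults are the site-group means observed for
#' myelofibrosis marrow after correction; `ff` is the proton-density fat fraction
#' used to scale the water signal.
#'
#' @return data.frame with one row per site: `site`, `code`, `group` (T, I, MV, EV),
#'   `station`, center `cx, cy, cz`, semi-axes `ax, ay, az` (mm), `adc_true`
#'   (micron^2/ms), `ff`.
#' @export
default_sites <- function() {
  vx <- c(17.5, 19.7, 15)   # mid-vertebra semi-axes -> 21.7 cm^3
  ve <- c(17.0, 18.8, 15)   # edge-vertebra semi-axes -> 20.1 cm^3
  sites <- rbind(
    data.frame(site = "RT", group = "T", station = "pelvis",
               cx = -105, cy = 0, cz = -80, ax = 34, ay = 25, az = 24.8),
    data.frame(site = "LT", group = "T", station = "pelvis",
               cx = 105, cy = 0, cz = -80, ax = 34, ay = 25, az = 24.8),
    data.frame(site = "RI", group = "I", station = "pelvis",
               cx = -50, cy = -30, cz = -60, ax = 30, ay = 24, az = 24),
    data.frame(site = "LI", group = "I", station = "pelvis",
               cx = 50, cy = -30, cz = -60, ax = 30, ay = 24, az = 24),
    data.frame(site = "T11", group = "EV", station = "spine",
               cx = 0, cy = -20, cz = 128, ax = ve[1], ay = ve[2], az = ve[3]),
    data.frame(site = "T12", group = "EV", station = "spine",
               cx = 0, cy = -20, cz = 96, ax = ve[1], ay = ve[2], az = ve[3]),
    data.frame(site = "L1", group = "EV", station = "spine",
               cx = 0, cy = -20, cz = 64, ax = ve[1], ay = ve[2], az = ve[3]),
    data.frame(site = "L2", group = "MV", station = "spine",
               cx = 0, cy = -20, cz = 32, ax = vx[1], ay = vx[2], az = vx[3]),
    data.frame(site = "L3", group = "MV", station = "spine",
               cx = 0, cy = -20, cz = 0, ax = vx[1], ay = vx[2], az = vx[3]),
    data.frame(site = "L4", group = "MV", station = "spine",
               cx = 0, cy = -20, cz = -32, ax = vx[1], ay = vx[2], az = vx[3]),
    data.frame(site = "L5", group = "EV", station = "spine",
               cx = 0, cy = -20, cz = -64, ax = ve[1], ay = ve[2], az = ve[3]),
    data.frame(site = "S1", group = "EV", station = "spine",
               cx = 0, cy = -20, cz = -96, ax = ve[1], ay = ve[2], az = ve[3]))
  grp_adc <- c(T = 0.519, I = 0.628, MV = 0.577, EV = 0.591)
  grp_ff <- c(T = 0.12, I = 0, MV = -0.03, EV = -0.03)
  sites$code <- site_codes()[sites$site]
  sites$adc_true <- unname(grp_adc[sites$group])
  sites$ff <- pmin(0.85, pmax(0.02, 0.20 + unname(grp_ff[sites$group])))
  sites
}

#' Imaging-station layout of the virtual exam
#'
#' Two couch stations: a lumbar-spine station (table offset 230 mm) whose grid is
#' centered 15 mm superior of isocenter, and a pelvis station (offset 120 mm) whose
#' grid is centered 40 mm superior, so that the pelvic sites it measures sit near
#' isocenter while edge vertebrae in the spine station reach 100+ mm offsets.  The
#' patient anchor places L3 at isocenter in the spine station; in the magnet frame a
#' patient point p maps to `p + (0, 0, anchor)` per station.
#'
#' @param spacing voxel spacing in mm.
#' @return data.frame with station name, table offset, anchor shift and grid
#'   specification (extent and magnet-frame center).
#' @export
default_stations <- function(spacing = 3) {
  data.frame(
    station = c("spine", "pelvis"),
    table_offset = c(230, 120),
    anchor = c(0, 110),
    ext_x = c(140, 330), ext_y = c(100, 100), ext_z = c(260, 250),
    cen_x = 0, cen_y = -15, cen_z = c(15, 40),
    spacing = spacing)
}

# couch-frame grid of one station row; anatomy couch position = p + anchor + offset
station_geometry <- function(st) {
  centered_geometry(
    extent = c(st$ext_x, st$ext_y, st$ext_z),
    spacing = st$spacing,
    center = c(st$cen_x, st$cen_y, st$cen_z + st$table_offset))
}

#' Specify a uniform diffusion phantom acquisition
#'
#' An oblong torso-size gel shell imaged as a coronal slab: field of view 400 mm
#' superior-inferior by 200 mm right-left, matching a whole-torso quality-assurance
#' scan.  The preset true diffusivity of 2.13 micron^2/ms is the room-temperature
#' value for a sodium-polyacrylate gel.
#'
#' @param shell_semi ellipsoid semi-axes of the gel shell, mm (x, y, z).
#' @param fov_mm in-plane field of view (x, z), mm.
#' @param slab_mm slab thickness along y, mm.
#' @param spacing voxel spacing, mm.
#' @param adc_true true diffusivity, micron^2/ms (> 0).
#' @param s0 baseline signal level, a.u.
#' @param sigma Rician noise level (complex-channel SD, a.u.); 0 for noiseless.
#' @param b_nominal nominal b-value, s/mm^2.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shell_semi = c(90, 60, 180), fov_mm = c(200, 400),
                         slab_mm = 6, spacing = 2, adc_true = 2.13,
                         s0 = 1000, sigma = 0, b_nominal = 800) {
  if (adc_true <= 0) stop("true diffusivity must be positive")
  if (sigma < 0) stop("noise sigma must be non-negative")
  structure(list(shell_semi = shell_semi, fov_mm = fov_mm, slab_mm = slab_mm,
                 spacing = spacing, adc_true = adc_true, s0 = s0, sigma = sigma,
                 b_nominal = b_nominal),
            class = "phantom_spec")
}

# magnitude-MRI (Rician) corruption of a signal array
rician <- function(s, sigma) {
  if (sigma == 0) return(s)
  n <- length(s)
  sqrt((s + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

# simulate a two-point trace acquisition at given magnet-frame points:
# per-direction DW signal S0*exp(-b*c_k*ADC), Rician noise per direction image
# before geometric-mean trace formation; returns list(s0, sb) vectors
simulate_trace_signals <- function(model, points, s0_vals, adc_vals, b_nominal,
                                   dirs, sigma) {
  bd <- b_nominal * adc_vals / 1000          # b * ADC, dimensionless
  if (sigma == 0) {
    cb <- cbar_at(model, points)
    return(list(s0 = s0_vals, sb = s0_vals * exp(-cb * bd)))
  }
  ck <- direction_correctors_at(model, points, dirs)
  sb <- rep(1, length(s0_vals))
  for (k in 1:3) {
    sb <- sb * rician(s0_vals * exp(-ck[, k] * bd), sigma)
  }
  list(s0 = rician(s0_vals, sigma), sb = sb^(1 / 3))
}

#' Simulate the uniform phantom DWI
#'
#' Builds the coronal slab grid, applies the coil model's spatially varying b-value
#' voxelwise (`S_b(r) = S0 exp(-b_nom cbar(r) ADC_true)` for the trace image, with
#' optional per-direction Rician noise), and returns the acquisition together with
#' the ground-truth ADC volume.
#'
#' @param spec a [phantom_spec()].
#' @param model a [coil_model()].
#' @param dirs a [direction_set()].
#' @param table_offset couch offset, mm (0 centers the phantom at isocenter).
#' @param seed optional integer seed for the noise realization.
#' @return list with `dwi` (a [dwi_series()]), `truth` (ADC [image_volume()]),
#'   `mask` (logical array of shell voxels).
#' @export
generate_phantom <- function(spec, model, dirs = direction_set(),
                             table_offset = 0, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(model, "coil_model"))
  if (!is.null(seed)) set.seed(seed)
  geom <- centered_geometry(
    extent = c(spec$fov_mm[1], spec$slab_mm, spec$fov_mm[2]),
    spacing = spec$spacing,
    center = c(0, 0, table_offset))
  pts_couch <- grid_points(geom)
  pts <- pts_couch
  pts[, 3] <- pts[, 3] - table_offset
  mask_v <- (pts[, 1] / spec$shell_semi[1])^2 + (pts[, 2] / spec$shell_semi[2])^2 +
    (pts[, 3] / spec$shell_semi[3])^2 <= 1
  s0_vals <- ifelse(mask_v, spec$s0, 0)
  adc_vals <- ifelse(mask_v, spec$adc_true, 0)
  sig <- simulate_trace_signals(model, pts, s0_vals, adc_vals, spec$b_nominal,
                                dirs, spec$sigma)
  mask <- array(mask_v, dim = geom$dim)
  s0 <- image_volume(array(sig$s0, geom$dim), geom, "a.u.", meta = list(kind = "S0"))
  sb <- image_volume(array(sig$sb, geom$dim), geom, "a.u.",
                     meta = list(kind = "DW", b = spec$b_nominal))
  truth <- image_volume(array(adc_vals, geom$dim), geom, "micron2/ms",
                        meta = list(kind = "truth"))
  list(dwi = dwi_series(s0, sb, spec$b_nominal, dirs, table_offset, mask = mask),
       truth = truth, mask = mask)
}

#' Specify one virtual subject
#'
#' @param sites site table as from [default_sites()] (columns may be edited; site
#'   volumes should stay within a factor ~3 of the defaults and ROIs must not
#'   overlap).
#' @param stations station layout as from [default_stations()].
#' @param position_offset rigid positioning offset of the subject (R-L, A-P, S-I),
#'   mm, applied to all sites.
#' @param s0 baseline water signal at zero fat fraction, a.u.
#' @param sigma Rician noise level, a.u.
#' @param b_nominal nominal b-value, s/mm^2.
#' @param grade myelofibrosis fibrosis grade (0-3), carried as metadata.
#' @param sex,age demographics carried as metadata.
#' @param subject_id identifier.
#' @return object of class `subject_spec`.
#' @export
subject_spec <- function(sites = default_sites(), stations = default_stations(),
                         position_offset = c(0, 0, 0), s0 = 1000, sigma = 12,
                         b_nominal = 800, grade = 2, sex = "F", age = 65,
                         subject_id = "S01") {
  stopifnot(is.data.frame(sites), is.data.frame(stations),
            length(position_offset) == 3)
  if (sigma < 0) stop("noise sigma must be non-negative")
  vol_default <- 4 / 3 * pi * c(T = 34 * 25 * 24.8, I = 30 * 24 * 24,
                                MV = prod(c(17.5, 19.7, 15)),
                                EV = prod(c(17, 18.8, 15))) / 1000
  vol <- 4 / 3 * pi * sites$ax * sites$ay * sites$az / 1000
  ratio <- vol / vol_default[sites$group]
  if (any(ratio > 3 | ratio < 1 / 3)) {
    stop("site volumes must stay within a factor 3 of the defaults")
  }
  vert <- sites[grepl("^(T1[12]|L[1-5]|S1)$", sites$site), ]
  ord <- match(c("T11", "T12", "L1", "L2", "L3", "L4", "L5", "S1"), vert$site)
  cz <- vert$cz[ord[!is.na(ord)]]
  if (any(diff(cz) >= 0)) stop("vertebra centers must decrease along superior-inferior order")
  structure(list(sites = sites, stations = stations,
                 position_offset = as.numeric(position_offset),
                 s0 = s0, sigma = sigma, b_nominal = b_nominal,
                 grade = grade, sex = sex, age = age, subject_id = subject_id),
            class = "subject_spec")
}

# rasterize ellipsoidal site labels on a station grid (couch frame); sites must be
# fully inside the grid to be retained, mirroring variable vertebra coverage
rasterize_sites <- function(sites, geom, shift) {
  pts <- grid_points(geom)
  lab <- integer(nrow(pts))
  lo <- geom$origin
  hi <- index_to_physical(geom, matrix(geom$dim, 1))[1, ]
  present <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cen <- c(sites$cx[i], sites$cy[i], sites$cz[i]) + shift
    semi <- c(sites$ax[i], sites$ay[i], sites$az[i])
    if (any(cen - semi < lo) || any(cen + semi > hi)) next
    inside <- ((pts[, 1] - cen[1]) / semi[1])^2 +
      ((pts[, 2] - cen[2]) / semi[2])^2 +
      ((pts[, 3] - cen[3]) / semi[3])^2 <= 1
    if (any(lab[inside] != 0)) {
      stop("overlapping site labels: ", sites$site[i], " collides with ",
           names(site_codes())[unique(lab[inside][lab[inside] != 0])][1])
    }
    lab[inside] <- sites$code[i]
    present[i] <- any(inside)
  }
  list(labels = lab, present = present)
}

#' Simulate one subject scan (both stations)
#'
#' Rasterizes the ellipsoidal bone-site labels on each station grid, scales the
#' water signal by `(1 - FF)` so high-fat sites have low contrast-to-noise, applies
#' the coil model's b-value bias voxelwise and adds Rician noise.  The couch-frame
#' anatomy position of patient point p in station s is
#' `p + position_offset + (0, 0, anchor_s + table_offset_s)`.
#'
#' @param spec a [subject_spec()].
#' @param model a [coil_model()].
#' @param dirs a [direction_set()].
#' @param seed optional integer seed.
#' @param timepoint timepoint index carried as metadata.
#' @return object of class `subject_scan`: list with one entry per station
#'   (`dwi`, `labels`, `truth`), the per-site truth table `site_table` (site,
#'   station, present, true ADC, FF, magnet-frame center), and the spec metadata.
#' @export
generate_subject <- function(spec, model, dirs = direction_set(), seed = NULL,
                             timepoint = 1L) {
  stopifnot(inherits(spec, "subject_spec"), inherits(model, "coil_model"))
  if (!is.null(seed)) set.seed(seed)
  stations <- list()
  site_rows <- list()
  for (si in seq_len(nrow(spec$stations))) {
    st <- spec$stations[si, ]
    geom <- station_geometry(st)
    shift <- spec$position_offset + c(0, 0, st$anchor + st$table_offset)
    ssites <- spec$sites[spec$sites$station == st$station, , drop = FALSE]
    ras <- rasterize_sites(ssites, geom, shift)
    lab <- ras$labels
    ff <- adc <- numeric(length(lab))
    for (i in seq_len(nrow(ssites))) {
      vox <- lab == ssites$code[i]
      ff[vox] <- ssites$ff[i]
      adc[vox] <- ssites$adc_true[i]
    }
    pts <- magnet_points(geom, st$table_offset)
    s0_vals <- ifelse(lab > 0, spec$s0 * (1 - ff), 0)
    sig <- simulate_trace_signals(model, pts, s0_vals, adc, spec$b_nominal,
                                  dirs, spec$sigma)
    mask <- array(lab > 0, geom$dim)
    s0 <- image_volume(array(sig$s0, geom$dim), geom, "a.u.", meta = list(kind = "S0"))
    sb <- image_volume(array(sig$sb, geom$dim), geom, "a.u.",
                       meta = list(kind = "DW", b = spec$b_nominal))
    labels <- image_volume(array(as.integer(lab), geom$dim), geom, "label",
                           meta = list(dictionary = as.list(site_codes())))
    truth <- image_volume(array(adc, geom$dim), geom, "micron2/ms",
                          meta = list(kind = "truth"))
    stations[[st$station]] <- list(
      dwi = dwi_series(s0, sb, spec$b_nominal, dirs, st$table_offset, mask = mask),
      labels = labels, truth = truth)
    cen_mag <- cbind(ssites$cx + spec$position_offset[1],
                     ssites$cy + spec$position_offset[2],
                     ssites$cz + spec$position_offset[3] + st$anchor)
    site_rows[[st$station]] <- data.frame(
      site = ssites$site, station = st$station, present = ras$present,
      adc_true = ssites$adc_true, ff = ssites$ff,
      mx = cen_mag[, 1], my = cen_mag[, 2], mz = cen_mag[, 3])
  }
  structure(list(stations = stations,
                 site_table = do.call(rbind, unname(site_rows)),
                 subject_id = spec$subject_id, timepoint = timepoint,
                 grade = spec$grade, sex = spec$sex, age = spec$age,
                 position_offset = spec$position_offset, sigma = spec$sigma),
            class = "subject_scan")
}

#' Specify a virtual cohort
#'
#' Subject-level true ADC is a shared subject effect plus site-group means and a
#' fibrosis-grade trend, so inter-site ADC correlations and grade trends emerge in
#' the analysis.  Repositioning across timepoints draws per-axis Gaussian jitter
#' plus, with probability `shift_prob`, a one-vertebra (32 mm)
#' superior-inferior landmarking shift.
#'
#' @param n_subjects number of subjects.
#' @param timepoints per-subject scan counts (scalar or length `n_subjects`).
#' @param jitter_sd per-axis repositioning SD (R-L, A-P, S-I), mm.
#' @param shift_prob probability of a +-32 mm vertebra landmark shift per timepoint.
#' @param ff_low,ff_high ranges of the bimodal ilium fat-fraction distribution.
#' @param p_low probability a subject falls in the low-fat component (analysable).
#' @param adc_group site-group mean true ADC, micron^2/ms.
#' @param adc_subject_sd SD of the shared subject-level ADC effect.
#' @param adc_site_sd SD of the residual site-level ADC perturbation.
#' @param grade_effect added to true ADC per fibrosis-grade step above 2.
#' @param sigma Rician noise level, a.u.
#' @param seed master seed; the same spec and seed reproduce the cohort exactly.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, timepoints = 2,
                        jitter_sd = c(8, 6, 12), shift_prob = 0.5,
                        ff_low = c(0.04, 0.38), ff_high = c(0.46, 0.73),
                        p_low = 22 / 41,
                        adc_group = c(T = 0.519, I = 0.628, MV = 0.577, EV = 0.591),
                        adc_subject_sd = 0.11, adc_site_sd = 0.045,
                        grade_effect = 0.04, sigma = 12, seed = 20260923) {
  stopifnot(n_subjects >= 1, all(timepoints >= 1), length(jitter_sd) == 3)
  structure(list(n_subjects = n_subjects,
                 timepoints = rep(timepoints, length.out = n_subjects),
                 jitter_sd = jitter_sd, shift_prob = shift_prob,
                 ff_low = ff_low, ff_high = ff_high, p_low = p_low,
                 adc_group = adc_group, adc_subject_sd = adc_subject_sd,
                 adc_site_sd = adc_site_sd, grade_effect = grade_effect,
                 sigma = sigma, seed = seed),
            class = "cohort_spec")
}

#' Draw the virtual cohort
#'
#' Deterministic given the spec and its master seed: subject-level parameters and
#' per-scan noise seeds are all derived from `spec$seed`, so changing only the seed
#' changes the realizations but not the configured truth model.
#'
#' @param spec a [cohort_spec()].
#' @param model a [coil_model()] (only needed when `materialize = TRUE`).
#' @param materialize if `TRUE`, simulate every scan now and return them; if
#'   `FALSE`, return the per-subject specifications and truth table only (scans can
#'   be produced later with [generate_subject()], e.g. one at a time to bound
#'   memory).
#' @return list with `subjects` (per subject: `spec`, per-timepoint `offsets` and
#'   `seeds`, and when materialized `scans`) and `truth`, a data.frame of configured
#'   per-subject-site true ADC and fat fraction.
#' @export
generate_cohort <- function(spec, model = NULL, materialize = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  base_sites <- default_sites()
  subjects <- list()
  truth_rows <- list()
  for (j in seq_len(spec$n_subjects)) {
    id <- sprintf("S%02d", j)
    grade <- sample(1:3, 1, prob = c(0.3, 0.35, 0.35))
    sex <- sample(c("F", "M"), 1, prob = c(2 / 3, 1 / 3))
    age <- round(stats::rnorm(1, 65, 8))
    low_fat <- stats::runif(1) < spec$p_low
    ff_il <- if (low_fat) stats::runif(1, spec$ff_low[1], spec$ff_low[2]) else
      stats::runif(1, spec$ff_high[1], spec$ff_high[2])
    subj_eff <- stats::rnorm(1, 0, spec$adc_subject_sd)
    sites <- base_sites
    grp_delta <- c(T = 0.12, I = 0, MV = -0.03, EV = -0.03)
    sites$ff <- pmin(0.85, pmax(0.02, ff_il + unname(grp_delta[sites$group]) +
                                  stats::rnorm(nrow(sites), 0, 0.02)))
    sites$adc_true <- pmax(0.15, unname(spec$adc_group[sites$group]) + subj_eff +
                             spec$grade_effect * (grade - 2) +
                             stats::rnorm(nrow(sites), 0, spec$adc_site_sd))
    ntp <- spec$timepoints[j]
    offsets <- matrix(0, ntp, 3)
    for (tp in seq_len(ntp)) {
      off <- stats::rnorm(3, 0, spec$jitter_sd)
      if (stats::runif(1) < spec$shift_prob) {
        off[3] <- off[3] + 32 * sample(c(-1, 1), 1)
      }
      offsets[tp, ] <- off
    }
    seeds <- sample.int(2^30, ntp)
    sspec <- subject_spec(sites = sites, position_offset = c(0, 0, 0),
                          sigma = spec$sigma, grade = grade, sex = sex, age = age,
                          subject_id = id)
    subjects[[id]] <- list(spec = sspec, offsets = offsets, seeds = seeds)
    truth_rows[[id]] <- data.frame(subject = id, site = sites$site,
                                   group = sites$group, adc_true = sites$adc_true,
                                   ff = sites$ff, grade = grade, sex = sex,
                                   age = age)
  }
  out <- list(subjects = subjects, truth = do.call(rbind, unname(truth_rows)),
              spec = spec)
  if (materialize) {
    if (is.null(model)) stop("a coil model is required to materialize scans")
    for (id in names(out$subjects)) {
      su <- out$subjects[[id]]
      scans <- list()
      for (tp in seq_len(nrow(su$offsets))) {
        sp <- su$spec
        sp$position_offset <- su$offsets[tp, ]
        scans[[tp]] <- generate_subject(sp, model, seed = su$seeds[tp],
                                        timepoint = tp)
      }
      out$subjects[[id]]$scans <- scans
    }
  }
  out
}
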