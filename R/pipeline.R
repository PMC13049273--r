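# End-to-end analysis: scan -> b-map -> ADC fit -> correction -> per-site rows of a
# tidy cohort table, plus cohort-level summaries and test-retest pairing.

#' Analyze one subject scan
#'
#' For every station: build the b-map, fit the two-point ADC, apply the
#' correction, and extract per-site ROI statistics of the percent bias map and the
#' ADC maps before/after correction (ADC voxels below `adc_threshold` are
#' excluded, dropping voxels without diffusion contrast).
#'
#' @param scan a `subject_scan` from [generate_subject()].
#' @param model a [coil_model()].
#' @param dirs a [direction_set()].
#' @param adc_threshold lower ADC bound in micron^2/ms.
#' @return data.frame with one row per present site: identifiers, bias statistics
#'   (percent), ADC statistics before/after correction, configured truth, fat
#'   fraction and demographics.
#' @export
analyze_scan <- function(scan, model, dirs = direction_set(), adc_threshold = 0.01) {
  stopifnot(inherits(scan, "subject_scan"), inherits(model, "coil_model"))
  rows <- list()
  for (st_name in names(scan$stations)) {
    st <- scan$stations[[st_name]]
    bmap <- make_bmap(model, st$dwi$s0$geom, dirs, st$dwi$table_offset)
    bias <- bias_percent(bmap)
    adc <- fit_adc(st$dwi)
    adc_gnc <- apply_gnc(adc, bmap)
    mask <- attr(adc, "mask")
    bias_st <- roi_statistics(bias, st$labels)
    adc_st <- roi_statistics(adc, st$labels, threshold = adc_threshold, mask = mask)
    gnc_st <- roi_statistics(adc_gnc, st$labels, threshold = adc_threshold, mask = mask)
    for (s in bias_st$site) {
      b <- bias_st[bias_st$site == s, ]
      a <- adc_st[adc_st$site == s, ]
      g <- gnc_st[gnc_st$site == s, ]
      info <- scan$site_table[scan$site_table$site == s, ]
      rows[[paste(st_name, s)]] <- data.frame(
        subject = scan$subject_id, timepoint = scan$timepoint, site = s,
        station = st_name, n = b$n, volume_cm3 = b$volume_cm3,
        bias_mean = b$mean, bias_median = b$median, bias_sd = b$sd,
        bias_min = b$min, bias_max = b$max,
        adc_mean = if (nrow(a)) a$mean else NA_real_,
        adc_median = if (nrow(a)) a$median else NA_real_,
        adc_sd = if (nrow(a)) a$sd else NA_real_,
        adc_gnc_mean = if (nrow(g)) g$mean else NA_real_,
        adc_gnc_median = if (nrow(g)) g$median else NA_real_,
        adc_gnc_sd = if (nrow(g)) g$sd else NA_real_,
        adc_true = if (nrow(info)) info$adc_true else NA_real_,
        ff = if (nrow(info)) info$ff else NA_real_,
        grade = scan$grade, sex = scan$sex, age = scan$age)
    }
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}

#' Analyze a whole virtual cohort
#'
#' Materializes each scan on demand (bounding memory to one scan at a time when
#' the cohort was generated with `materialize = FALSE`) and stacks the per-site
#' rows into a tidy table, one row per subject x timepoint x site.  A per-subject
#' ilium fat fraction (`ff_ilium`, mean of RI/LI) and the site group are attached
#' for the selection and grouping rules.
#'
#' @param cohort output of [generate_cohort()].
#' @param model a [coil_model()].
#' @param dirs a [direction_set()].
#' @param adc_threshold lower ADC bound in micron^2/ms.
#' @param progress print one line per subject.
#' @return `cohort_table` data.frame.
#' @export
analyze_cohort <- function(cohort, model, dirs = direction_set(),
                           adc_threshold = 0.01, progress = FALSE) {
  grp <- default_sites()[, c("site", "group")]
  rows <- list()
  for (id in names(cohort$subjects)) {
    su <- cohort$subjects[[id]]
    ntp <- nrow(su$offsets)
    for (tp in seq_len(ntp)) {
      scan <- if (!is.null(su$scans)) su$scans[[tp]] else {
        sp <- su$spec
        sp$position_offset <- su$offsets[tp, ]
        generate_subject(sp, model, dirs, seed = su$seeds[tp], timepoint = tp)
      }
      rows[[paste(id, tp)]] <- analyze_scan(scan, model, dirs, adc_threshold)
    }
    if (progress) message("analyzed ", id, " (", ntp, " timepoint(s))")
  }
  tab <- do.call(rbind, unname(rows))
  tab$group <- grp$group[match(tab$site, grp$site)]
  ffi <- tapply(ifelse(tab$site %in% c("RI", "LI"), tab$ff, NA), tab$subject,
                mean, na.rm = TRUE)
  tab$ff_ilium <- as.numeric(ffi[tab$subject])
  rownames(tab) <- NULL
  tab
}

#' Per-subject site-group means
#'
#' Combines the sites of each group (T, I, MV, EV) within subject and timepoint,
#' weighting site means by their voxel counts — equivalent to pooling the ROI
#' histograms before taking the mean.
#'
#' @param cohort_table from [analyze_cohort()].
#' @param value column to combine (e.g. `"adc_mean"`, `"adc_gnc_mean"`,
#'   `"bias_mean"`).
#' @return data.frame with `subject`, `timepoint`, `group`, `value` columns.
#' @export
group_means <- function(cohort_table, value = "adc_gnc_mean") {
  stopifnot(value %in% names(cohort_table))
  key <- interaction(cohort_table$subject, cohort_table$timepoint,
                     cohort_table$group, drop = TRUE)
  ok <- !is.na(cohort_table[[value]])
  agg <- tapply(seq_len(nrow(cohort_table))[ok], key[ok], function(i) {
    w <- cohort_table$n[i]
    sum(w * cohort_table[[value]][i]) / sum(w)
  })
  parts <- do.call(rbind, strsplit(names(agg), ".", fixed = TRUE))
  data.frame(subject = parts[, 1], timepoint = as.integer(parts[, 2]),
             group = parts[, 3], value = as.numeric(agg))
}

#' Test-retest pairs within subjects
#'
#' Forms every unordered pair of timepoints within each subject (a subject with
#' 2, 2, 4, 5 and 6 timepoints yields 1 + 1 + 6 + 10 + 15 = 33 pairs) for a given
#' site or group column, then runs the Bland-Altman analysis across pairs.
#'
#' @param cohort_table from [analyze_cohort()].
#' @param value column to pair (e.g. `"bias_mean"`, `"adc_mean"`).
#' @param sites optional site subset.
#' @return list with `pairs` (data.frame of subject, site, timepoints, test and
#'   retest values) and `ba` (a [bland_altman()] across all pairs).
#' @export
test_retest_pairs <- function(cohort_table, value = "bias_mean", sites = NULL) {
  tab <- cohort_table
  if (!is.null(sites)) tab <- tab[tab$site %in% sites, , drop = FALSE]
  rows <- list()
  for (id in unique(tab$subject)) {
    for (s in unique(tab$site[tab$subject == id])) {
      sub <- tab[tab$subject == id & tab$site == s, ]
      sub <- sub[order(sub$timepoint), ]
      tps <- sub$timepoint
      if (length(tps) < 2) next
      cmb <- utils::combn(seq_along(tps), 2)
      for (c_i in seq_len(ncol(cmb))) {
        i <- cmb[1, c_i]; j <- cmb[2, c_i]
        rows[[length(rows) + 1]] <- data.frame(
          subject = id, site = s, tp_test = tps[i], tp_retest = tps[j],
          test = sub[[value]][i], retest = sub[[value]][j])
      }
    }
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) < 2) stop("fewer than 2 test-retest pairs")
  list(pairs = pairs, ba = bland_altman(pairs$test, pairs$retest))
}

#' Site-group summary of the correction effect
#'
#' The cohort summary: per site group, ROI volume, mean ADC before and after
#' correction (mean +/- SD across subjects at the chosen timepoint) and the paired
#' two-sided p-value for the correction effect.
#'
#' @param cohort_table from [analyze_cohort()].
#' @param timepoint which timepoint to summarize.
#' @return data.frame with one row per group.
#' @export
gnc_summary_table <- function(cohort_table, timepoint = 1) {
  tab <- cohort_table[cohort_table$timepoint == timepoint, ]
  pre <- group_means(tab, "adc_mean")
  post <- group_means(tab, "adc_gnc_mean")
  vol <- group_means(tab, "volume_cm3")
  rows <- list()
  for (g in c("T", "I", "MV", "EV")) {
    a <- pre$value[pre$group == g]
    b <- post$value[post$group == g]
    sub_a <- pre$subject[pre$group == g]
    sub_b <- post$subject[post$group == g]
    common <- intersect(sub_a, sub_b)
    a <- a[match(common, sub_a)]; b <- b[match(common, sub_b)]
    p <- if (length(common) >= 2) paired_t(a, b)$p else NA_real_
    rows[[g]] <- data.frame(
      group = g, n_subjects = length(common),
      volume_cm3 = mean(vol$value[vol$group == g]),
      adc_mean = mean(a), adc_sd = stats::sd(a),
      adc_gnc_mean = mean(b), adc_gnc_sd = stats::sd(b),
      p_gnc = p)
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}
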