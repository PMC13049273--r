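# Bland-Altman, paired t, correlation, ANOVA, Bonferroni and cohort selection.

test_that("Bland-Altman handles degenerate and closed-form cases", {
  ba <- bland_altman(c(3, 4, 5), c(1, 2, 3))    # constant difference 2
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$loa_half, 0)
  same <- bland_altman(1:5, 1:5)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(same$loa, c(0, 0))
  expect_equal(ba$loa_half, 1.96 * ba$sd_diff)   # exact definition
  set.seed(31)
  d <- stats::rnorm(20000, 0, 2.143)
  ba2 <- bland_altman(d, rep(0, length(d)))
  expect_lt(abs(ba2$loa_half - 1.96 * 2.143) / (1.96 * 2.143), 0.03)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("paired t matches the closed form and the sign-flip enumeration", {
  d <- c(1, 2, 3, 4, 5)
  res <- paired_t(d, rep(0, 5))
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(5))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(-abs(t_oracle), 4), tolerance = 1e-12)
  # one-sided p is half the two-sided p in the hypothesized direction
  res1 <- paired_t(d, rep(0, 5), alternative = "greater")
  expect_equal(res1$p, res$p / 2, tolerance = 1e-12)
  # exact sign-flip enumeration: all-positive is the unique maximal pattern
  expect_equal(signflip_p(d), 1 / 32)
  # enumeration and t-distribution p agree in order of magnitude at n = 8
  set.seed(12)
  for (i in 1:4) {
    d8 <- stats::rnorm(8, 0.5, 1)
    p_t <- paired_t(d8, rep(0, 8), alternative = "greater")$p
    p_perm <- signflip_p(d8)
    expect_lt(abs(p_t - p_perm), 0.05)
  }
  expect_warning(pz <- paired_t(c(1, 1, 1), c(1, 1, 1)), "zero-variance")
  expect_equal(pz$p, 1)
  expect_equal(pz$t, 0)
  expect_warning(pc <- paired_t(c(2, 3, 4), c(1, 2, 3)), "zero-variance")
  expect_equal(pc$p, 1)
  expect_error(paired_t(1, 1), "at least 2")
})

test_that("Pearson correlation covers exact and null cases", {
  x <- c(0.1, 0.5, 0.9, 1.4, 2.2)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(14)
  n <- 400
  a <- stats::rnorm(n)
  b <- sample(a)
  expect_lt(abs(pearson_r(a, b)$r), 3 / sqrt(n))
  expect_warning(rz <- pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(rz$r))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("one-way ANOVA matches t^2 and the sum-of-squares oracle", {
  g <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(one_way_anova(g)$F, 0)
  set.seed(17)
  a <- stats::rnorm(8, 0); b <- stats::rnorm(10, 0.7)
  res2 <- one_way_anova(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)
  # explicit between/within sum-of-squares for three groups
  gs <- list(stats::rnorm(6), stats::rnorm(7, 0.3), stats::rnorm(5, -0.2))
  res3 <- one_way_anova(gs)
  allv <- unlist(gs)
  gm <- mean(allv)
  ssb <- sum(vapply(gs, function(v) length(v) * (mean(v) - gm)^2, 1))
  ssw <- sum(vapply(gs, function(v) sum((v - mean(v))^2), 1))
  F_oracle <- (ssb / 2) / (ssw / (length(allv) - 3))
  expect_equal(res3$F, F_oracle, tolerance = 1e-10)
  expect_error(one_way_anova(list(1:3)), ">= 2 groups")
  expect_error(one_way_anova(list(1:3, 5)), ">= 2 groups")
})

test_that("multiple-comparison threshold is alpha/k and monotone", {
  expect_equal(multiple_comparison_threshold(0.05, 6), 0.05 / 6)
  expect_equal(multiple_comparison_threshold(0.05, 1), 0.05)
  ks <- 1:10
  th <- vapply(ks, function(k) multiple_comparison_threshold(0.05, k), 1)
  expect_true(all(diff(th) < 0))
})

test_that("fat-fraction selection uses a strict bound and logs exclusions", {
  tab <- data.frame(subject = rep(c("A", "B", "C"), each = 2),
                    ff_ilium = rep(c(0.20, 0.38, 0.53), each = 2))
  kept <- select_subjects(tab, 0.40)
  expect_setequal(unique(kept$subject), c("A", "B"))
  expect_equal(attr(kept, "excluded"), "C")
  # boundary: exactly 0.40 is excluded
  tab$ff_ilium[tab$subject == "B"] <- 0.40
  kept2 <- select_subjects(tab, 0.40)
  expect_setequal(unique(kept2$subject), "A")
  # constructed cohort with 22 below-threshold subjects retains exactly those
  ffs <- c(stats::runif(22, 0.05, 0.39), stats::runif(19, 0.41, 0.72))
  big <- data.frame(subject = sprintf("S%02d", 1:41), ff_ilium = ffs)
  kept3 <- select_subjects(big, 0.40)
  expect_equal(nrow(kept3), 22)
  expect_setequal(kept3$subject, sprintf("S%02d", 1:22))
  # missing fat fraction excludes the subject with a warning
  big$ff_ilium[1] <- NA
  expect_warning(kept4 <- select_subjects(big, 0.40), "excluded")
  expect_equal(nrow(kept4), 21)
})

test_that("corrected means separate true site differences that bias masks", {
  # directional property: a true trochanter < edge-vertebrae difference opposed by
  # positive trochanter bias is detected more often after correction
  m <- default_coil_model()
  spec <- cohort_spec(n_subjects = 8, timepoints = 1, sigma = 8,
                      adc_group = c(T = 0.55, I = 0.63, MV = 0.58, EV = 0.60),
                      adc_subject_sd = 0.08, adc_site_sd = 0.02, seed = 99)
  tab <- analyze_cohort(generate_cohort(spec), m)
  pre <- group_means(tab, "adc_mean")
  post <- group_means(tab, "adc_gnc_mean")
  wide <- function(g, d, ids) d$value[d$group == g][
    match(ids, d$subject[d$group == g])]
  ids <- Reduce(intersect, list(pre$subject[pre$group == "EV"],
                                pre$subject[pre$group == "T"]))
  p_pre <- paired_t(wide("EV", pre, ids), wide("T", pre, ids),
                    alternative = "greater")$p
  p_post <- paired_t(wide("EV", post, ids), wide("T", post, ids),
                     alternative = "greater")$p
  expect_lt(p_post, p_pre)
})
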