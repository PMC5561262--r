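test_that("bias_percent reproduces printed trueness values", {
  cases <- rbind(
    c(7.9, 7.3, 8.2),        # mixed-template specificity check
    c(104.1, 99.94, 4.2),    # simplex vs certified value
    c(10.7, 10, 7.0),
    c(1.03, 0.91, 13.2),
    c(1.06, 0.91, 16.5),
    c(91.39, 94.20, -3.0),
    c(2.42, 2.70, -10.4),
    c(2.89, 2.26, 27.9),
    c(0.53, 0.48, 10.4),
    c(0.97, 0.91, 6.6))
  expect_equal(bias_percent(cases[, 1], cases[, 2]), cases[, 3])
  expect_identical(bias_percent(5, 5), 0)
  expect_error(bias_percent(1, 0), "positive")
  # unrounded values are available for threshold comparisons
  expect_equal(bias_percent(7.9, 7.3, digits = NA), 100 * 0.6 / 7.3)
})

test_that("dilution_adjusted_assigned divides and rounds half-up", {
  expect_equal(dilution_adjusted_assigned(96.3, 2), 48.2)  # not 48.1
  expect_equal(dilution_adjusted_assigned(10, 1), 10.0)
  expect_equal(dilution_adjusted_assigned(100, 4), 25.0)
  expect_equal(bias_percent(58.9, dilution_adjusted_assigned(96.3, 2)),
               22.2)
  expect_error(dilution_adjusted_assigned(10, 0.5), ">= 1")
})

test_that("rsd_percent uses the n-1 standard deviation and flags undefined", {
  expect_equal(rsd_percent(c(10, 10, 10)), 0)
  expect_equal(round(rsd_percent(c(8, 12)), 1), 28.3)
  expect_equal(rsd_percent(c(100, 110, 90)), 10)
  expect_true(is.na(rsd_percent(5)))
  expect_true(is.na(rsd_percent(c(-1, 1))))
})

test_that("bias and RSD agree with brute-force recomputation", {
  set.seed(31)
  for (i in 1:25) {
    v <- rnorm(sample(2:12, 1), mean = runif(1, 1, 100), sd = runif(1, 0, 9))
    a <- runif(1, 0.5, 120)
    expect_equal(rsd_percent(v),
                 100 * sqrt(sum((v - mean(v))^2) / (length(v) - 1)) / mean(v))
    expect_equal(bias_percent(mean(v), a, digits = NA),
                 (mean(v) / a - 1) * 100)
  }
})

test_that("determine_lod finds the last level of the unbroken positive run", {
  s <- list(mk_level("l1", 200, 200, 5), mk_level("l2", 50, 50, 8),
            mk_level("l3", 12, 12, 20), mk_level("l4", 3, 3, 40,
                                                 n_negative = 1))
  lod <- determine_lod(s)
  expect_identical(lod$level_id, "l3")
  expect_equal(lod$assigned, 12)

  all_pos <- s; all_pos[[4]] <- mk_level("l4", 3, 3, 40)
  expect_identical(determine_lod(all_pos)$level_id, "l4")

  # value reported is the mean measured copy number of the passing level
  s18 <- list(mk_level("hi", 40, 39, 10),
              mk_level("mid", 20, 18, 30),
              mk_level("lo", 5, 4, 50, n_negative = 2))
  expect_equal(determine_lod(s18)$value, 18)

  top_neg <- list(mk_level("a", 100, 100, 5, n_negative = 1),
                  mk_level("b", 10, 10, 10))
  expect_false(determine_lod(top_neg)$defined)
  expect_error(determine_lod(s[1]), "two levels")
})

test_that("determine_loq requires a consistent RSD < 25% run", {
  s <- list(mk_level("l1", 1000, 1000, 5), mk_level("l2", 100, 100, 12),
            mk_level("l3", 40, 40, 24), mk_level("l4", 8, 8, 40))
  expect_identical(determine_loq(s)$level_id, "l3")

  # a failing intermediate level breaks consistency below it
  s2 <- list(mk_level("l1", 1000, 1000, 5), mk_level("l2", 100, 100, 30),
             mk_level("l3", 40, 40, 20), mk_level("l4", 8, 8, 40))
  expect_identical(determine_loq(s2)$level_id, "l1")

  # 38-copy level at RSD 12.6 vs 8-copy level at 26.6
  s3 <- list(mk_level("top", 400, 391, 10.1),
             mk_level("loq", 40, 38, 12.6),
             mk_level("below", 8, 8, 26.6))
  loq <- determine_loq(s3)
  expect_equal(loq$value, 38)
  expect_identical(loq$level_id, "loq")
})

test_that("LOD/LOQ rules are monotone under degradation", {
  set.seed(77)
  for (rep in 1:10) {
    n_lev <- sample(4:7, 1)
    assigned <- sort(10^runif(n_lev, 0, 3), decreasing = TRUE)
    s <- lapply(seq_len(n_lev), function(i)
      mk_level(paste0("L", i), assigned[i], assigned[i],
               runif(1, 0, 40), n_negative = sample(0:1, 1, prob = c(.8, .2))))
    base_lod <- determine_lod(s); base_loq <- determine_loq(s)
    # flip one replicate negative somewhere: LOD can only move up
    i <- sample(n_lev, 1)
    worse <- s
    worse[[i]] <- mk_level(paste0("L", i), assigned[i], assigned[i], 10,
                           n_negative = 1)
    new_lod <- determine_lod(worse)
    if (base_lod$defined && new_lod$defined)
      expect_gte(new_lod$assigned, base_lod$assigned)
    # raise one RSD above the limit: LOQ can only move up
    worse2 <- s
    worse2[[i]] <- mk_level(paste0("L", i), assigned[i], assigned[i], 60)
    new_loq <- determine_loq(worse2)
    if (base_loq$defined && new_loq$defined)
      expect_gte(new_loq$assigned, base_loq$assigned)
  }
})

test_that("relative limits follow the same rules on the GM% scale", {
  s <- list(mk_level("2%", 2, 1.9, 8), mk_level("0.5%", 0.5, 0.52, 15),
            mk_level("0.1%", 0.1, 0.11, 22),
            mk_level("0.01%", 0.01, 0.013, 45, n_negative = 1))
  lims <- determine_relative_limits(s)
  expect_identical(lims$loq_rel$level_id, "0.1%")
  expect_identical(lims$lod_rel$level_id, "0.1%")

  expect_equal(relative_from_absolute(39, 50000), 0.08)
  expect_equal(relative_from_absolute(100, 50000), 0.2)
})

test_that("practical limits round up to the nearest ten copies", {
  expect_equal(practical_limit(38), 40)
  expect_equal(practical_limit(18), 20)
  expect_equal(practical_limit(40), 40)
})

test_that("dynamic_range_fit measures linearity on the raw scale", {
  a <- c(1, 10, 100, 500, 2500)
  f <- dynamic_range_fit(a, 2 * a)
  expect_equal(f$r2, 1)
  expect_equal(f$slope, 2)
  expect_true(f$pass)

  # pass/fail honours the 0.98 boundary on either side
  set.seed(5)
  noisy <- a * (1 + rnorm(5, 0, 0.6))
  r2 <- cor(a, noisy)^2
  expect_identical(dynamic_range_fit(a, noisy)$pass, r2 >= 0.98)
  expect_error(dynamic_range_fit(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(dynamic_range_fit(1:2, 1:2), "three")
})

test_that("evaluate_acceptance applies context-specific limits", {
  th <- mpr_thresholds()
  b <- evaluate_acceptance(list(bias_percent = 27.9), th, "quantification")
  expect_false(b$pass[b$check == "bias"])
  expect_true(evaluate_acceptance(list(bias_percent = -24.9), th,
                                  "quantification")$pass)
  r <- evaluate_acceptance(list(rsd_percent = 41.78), th, "repeatability")
  expect_false(r$pass)
  expect_match(r$reason, "35")
  expect_true(evaluate_acceptance(list(rsd_percent = 46.66), th,
                                  "low_copy")$pass)
  expect_false(evaluate_acceptance(list(rsd_percent = 52.48), th,
                                   "low_copy")$pass)
  # purity: identical inputs give identical verdicts
  expect_identical(evaluate_acceptance(list(bias_percent = 3,
                                            rsd_percent = 12), th),
                   evaluate_acceptance(list(bias_percent = 3,
                                            rsd_percent = 12), th))
  expect_error(evaluate_acceptance(list(bias_percent = 1), th, "bogus"))
  expect_error(evaluate_acceptance(list(), th))
})

test_that("robustness_compare enforces the 25% deviation rule", {
  o <- mk_level("60x", NA, 10, 10)
  expect_true(robustness_compare(o, mk_level("60x", NA, 10, 10))$pass)
  r <- robustness_compare(o, mk_level("60x", NA, 12, 15))
  expect_equal(r$deviation_percent, 20.0)
  expect_true(r$pass)
  r2 <- robustness_compare(o, mk_level("60x", NA, 13, 15))
  expect_equal(r2$deviation_percent, 30.0)
  expect_false(r2$pass)
  # modified-protocol RSD above 35% fails even at small deviation
  r3 <- robustness_compare(o, mk_level("60x", NA, 10.5, 37.4))
  expect_false(r3$pass)
  expect_match(r3$reasons, "RSD")
  expect_error(robustness_compare(mk_level("x", NA, 0, 0), o), "nonzero")
})

test_that("interlab_summary separates RSD_r per lab from pooled RSD_R", {
  res <- list(labA = c(10, 10), labB = c(12, 12))
  s <- interlab_summary(res, assigned = 11)
  expect_equal(round(s$rsd_R, 1), 10.5)     # sd 1.1547 / mean 11
  expect_equal(s$per_lab$rsd_r, c(0, 0))

  # identical result sets: pooled RSD_R matches the within-lab RSD up to
  # the n-1 degrees-of-freedom factor sqrt(2(n-1)/(2n-1)) (exact under
  # the pooled-replicates convention; converges to equality in n)
  same <- list(a = c(9, 10, 11), b = c(9, 10, 11))
  s2 <- interlab_summary(same)
  n <- 3
  expect_equal(s2$rsd_R,
               rsd_percent(c(9, 10, 11)) * sqrt(2 * (n - 1) / (2 * n - 1)))

  # per-lab bias against the assigned value
  s3 <- interlab_summary(list(NIB = 1.03, NVI = 1.06), assigned = 0.91)
  expect_equal(s3$per_lab$bias_percent, c(13.2, 16.5))
  expect_true(all(is.na(s3$per_lab$rsd_r)))  # single results: bias only
  expect_error(interlab_summary(list(a = 1)), "two labs")
})
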