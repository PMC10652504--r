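# Frequency criteria: eligibility, threshold resolution and the mutually
# exclusive BA1/BS1/PM2 evaluation.

test_that("population eligibility applies the allele-number and presence rules", {
  recs <- list(frequency_record("AFR", 10, 5000),
               frequency_record("EAS", 10, 1500),
               frequency_record("NFE", 3, 100000),
               frequency_record("AMR", 8, 9000, founder_effect = TRUE))
  ben <- eligible_populations(recs, for_benign = TRUE)
  expect_equal(vapply(ben, function(r) r$population, character(1)), "AFR")
  path <- eligible_populations(recs, for_benign = FALSE)
  expect_setequal(vapply(path, function(r) r$population, character(1)),
                  c("AFR", "NFE"))
  # the boundary is strictly more than 2000 alleles
  expect_length(eligible_populations(list(frequency_record("X", 6, 2000))), 0)
  expect_length(eligible_populations(list(frequency_record("X", 6, 2001))), 1)
})

test_that("built-in thresholds reproduce the category/inheritance table", {
  thr <- resolve_thresholds(t_gene("AR", category = "cancer"))
  expect_equal(thr$ba1, 0.05)
  expect_equal(thr$bs1_s, 0.01)
  expect_equal(thr$pm2_p, 0.0004)
  expect_equal(thr$pm2_m, 0.00004)
  thr2 <- resolve_thresholds(t_gene("AD"))
  expect_equal(thr2$bs1_s, 0.001)
  expect_equal(thr2$pm2_p, 0.00001)
  expect_true(is.na(thr2$pm2_m))
  # AD/AR and the X-linked refinements group with the recessive row
  for (mode in c("AD_AR", "XL", "XLR", "XLD")) {
    expect_equal(resolve_thresholds(t_gene(mode))$bs1_s, 0.01)
  }
})

test_that("threshold ordering invariant holds for every built-in row", {
  for (cat in c("general", "cancer")) {
    for (mode in c("AD", "AR")) {
      thr <- resolve_thresholds(t_gene(mode, category = cat))
      expect_true(thr$ba1 > thr$bs1_s)
      expect_true(thr$bs1_s > thr$pm2_p)
      if (!is.na(thr$pm2_m)) expect_true(thr$pm2_p >= thr$pm2_m)
    }
  }
  expect_error(frequency_thresholds(0.001, 0.01, 0.0001), "ordering")
})

test_that("per-gene overrides pass through and exception genes require them", {
  ov <- list(ba1 = 0.02, bs1_s = 0.005, pm2_p = 1e-4, pm2_m = 1e-5)
  thr <- resolve_thresholds(t_gene(frequency_overrides = ov))
  expect_equal(thr$ba1, 0.02)
  expect_equal(thr$pm2_m, 1e-5)
  expect_error(resolve_thresholds(t_gene(ba1_exception = TRUE)),
               "exception list")
})

test_that("frequency evaluation picks the printed cut-offs", {
  g_ad <- t_gene("AD")
  # stand-alone benign at >= 0.05
  expect_equal(strength_of(evaluate_frequency(t_freq(12000), g_ad)), "A")
  expect_equal(evaluate_frequency(t_freq(10000), g_ad)$criterion, "BA1")
  # strong benign above 0.1% for dominant genes
  expect_equal(evaluate_frequency(t_freq(400), g_ad)$criterion, "BS1")
  # cancer recessive: supporting between 0.004% and 0.04%
  g_car <- t_gene("AR", category = "cancer")
  call <- evaluate_frequency(t_freq(60), g_car)  # 0.0003
  expect_equal(call$criterion, "PM2")
  expect_equal(call$strength, "P")
  # general recessive: absent variant is below the moderate cut-off
  g_ar <- t_gene("AR")
  call2 <- evaluate_frequency(t_freq(0), g_ar)
  expect_equal(call2$criterion, "PM2")
  expect_equal(call2$strength, "M")
  # dominant "absent required": zero count in every eligible population
  call3 <- evaluate_frequency(t_freq(0), g_ad)
  expect_equal(paste0(call3$criterion, "_", call3$strength), "PM2_M")
  expect_match(call3$rationale, "absent")
  # presence anywhere blocks the dominant moderate call but allows supporting
  call4 <- evaluate_frequency(t_freq(1), g_ad)
  expect_equal(paste0(call4$criterion, "_", call4$strength), "PM2_P")
})

test_that("no eligible populations withholds the rarity call with a rationale", {
  call <- evaluate_frequency(t_freq(0, founder = TRUE), t_gene())
  expect_false(call$applied)
  expect_match(call$rationale, "insufficient population data")
})

test_that("boundary comparisons follow the printed symbols", {
  g <- t_gene("AD")
  # BS1 is strict: exactly 0.1% does not fire
  expect_null(evaluate_frequency(t_freq(200), g))        # 0.001 exactly
  expect_equal(evaluate_frequency(t_freq(201), g)$criterion, "BS1")
  # PM2 is strict: exactly the supporting cut-off does not fire
  expect_null(evaluate_frequency(t_freq(2), g))          # 1e-5 exactly
  # BA1 is inclusive at 0.05
  expect_equal(evaluate_frequency(t_freq(10000), g)$criterion, "BA1")
})

test_that("frequency criteria are mutually exclusive over an allele-count grid", {
  genes <- list(t_gene("AD"), t_gene("AR"),
                t_gene("AD", category = "cancer"),
                t_gene("AR", category = "cancer"))
  acs <- c(0, 1, 2, 5, 8, 20, 60, 100, 201, 500, 2000, 4000, 10000, 12000)
  for (g in genes) {
    prev_rank <- NULL
    for (ac in acs) {
      call <- evaluate_frequency(t_freq(ac), g)
      n_applied <- if (!is.null(call) && call$applied) 1 else 0
      expect_lte(n_applied, 1)
      # monotonicity: more alleles can never move the call toward pathogenic
      rank <- if (is.null(call) || !call$applied) 0
      else switch(paste0(call$criterion, "_", call$strength),
                  BA1_A = -2, BS1_S = -1, PM2_P = 1, PM2_M = 2)
      if (!is.null(prev_rank)) expect_lte(rank, prev_rank)
      prev_rank <- rank
    }
  }
})

test_that("invalid frequency records are rejected with diagnostics", {
  expect_error(frequency_record("NFE", 10, 5), "exceeds allele_number")
  expect_error(frequency_record("NFE", -1, 5), "nonnegative")
})
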