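# Case-level criteria: scoring systems, proband and meiosis counting, and
# the boolean-gated benign criteria.

test_that("recessive scoring adds per-observation points and ladders correctly", {
  obs <- function(...) {
    lapply(list(...), function(x) {
      if (x == "consang") recessive_obs("homozygous", consanguineous = TRUE)
      else recessive_obs(x)
    })
  }
  r <- score_pm3(obs("in_trans_with_PLP"), "AR")
  expect_equal(r$ss, 1.0)
  expect_equal(strength_of(r$call), "M")
  r2 <- score_pm3(obs("consang"), "AR")
  expect_equal(r2$ss, 0.25)
  expect_null(r2$call)
  r3 <- score_pm3(obs("in_trans_with_PLP", "in_trans_with_PLP",
                      "phase_unknown", "homozygous", "homozygous"), "AR")
  expect_equal(r3$ss, 3.5)
  expect_equal(strength_of(r3$call), "S")
  r4 <- score_pm3(obs("phase_unknown"), "AR")
  expect_equal(strength_of(r4$call), "P")
  # dominant-only genes refuse the criterion with a rationale
  r5 <- score_pm3(obs("in_trans_with_PLP"), "AD")
  expect_false(r5$call$applied)
})

test_that("recessive scoring is additive and the ladder is monotone", {
  pool <- list(recessive_obs("in_trans_with_PLP"),
               recessive_obs("phase_unknown"),
               recessive_obs("homozygous"),
               recessive_obs("homozygous", consanguineous = TRUE))
  unit <- c(1.0, 0.5, 0.5, 0.25)
  rank <- c(none = 0, P = 1, M = 2, S = 3, VS = 4)
  # exhaustive multisets up to size 5 drawn from the four observation kinds
  grid <- expand.grid(a = 0:5, b = 0:5, c = 0:5, d = 0:5)
  grid <- grid[rowSums(grid) <= 5, ]
  prev <- NULL
  for (i in seq_len(nrow(grid))) {
    counts <- as.integer(grid[i, ])
    obs <- unlist(lapply(1:4, function(k) rep(pool[k], counts[k])),
                  recursive = FALSE)
    r <- score_pm3(obs, "AR")
    expect_equal(r$ss, sum(counts * unit))
    s <- if (is.null(r$call)) "none" else r$call$strength
    expected <- if (r$ss >= 4) "VS" else if (r$ss >= 2) "S"
    else if (r$ss >= 1) "M" else if (r$ss >= 0.5) "P" else "none"
    expect_equal(s, expected)
  }
})

test_that("confirmed and assumed de novo observations score on separate ladders", {
  r <- score_de_novo(list(denovo_obs(TRUE, "highly_specific")))
  expect_equal(r$ps2_ss, 2.0)
  expect_equal(labels_of(r$calls), "PS2_S")
  r2 <- score_de_novo(list(denovo_obs(FALSE, "consistent")))
  expect_equal(r2$pm6_ss, 0.5)
  expect_equal(labels_of(r2$calls), "PM6_P")
  r3 <- score_de_novo(list(denovo_obs(FALSE, "consistent_high_heterogeneity")))
  expect_equal(r3$pm6_ss, 0.25)
  expect_length(r3$calls, 0)
  r4 <- score_de_novo(rep(list(denovo_obs(FALSE, "inconsistent")), 3))
  expect_equal(r4$pm6_ss, 0)
  expect_length(r4$calls, 0)
  # mixed cohorts feed both pools
  r5 <- score_de_novo(list(denovo_obs(TRUE, "consistent"),
                           denovo_obs(FALSE, "highly_specific")))
  expect_setequal(labels_of(r5$calls), c("PS2_M", "PM6_M"))
  # confirmed observations score double the assumed ladder
  r6 <- score_de_novo(list(denovo_obs(TRUE, "consistent_high_heterogeneity")))
  expect_equal(r6$ps2_ss, 0.5)
  expect_equal(labels_of(r6$calls), "PS2_P")
})

test_that("meiosis counting uses the dominant and recessive tiers", {
  expect_null(score_pp1(2, "AD"))
  expect_equal(strength_of(score_pp1(3, "AD")), "P")
  expect_equal(strength_of(score_pp1(4, "AD")), "P")
  expect_equal(strength_of(score_pp1(5, "AD")), "M")
  expect_equal(strength_of(score_pp1(6, "AD")), "M")
  expect_equal(strength_of(score_pp1(7, "AD")), "S")
  expect_equal(strength_of(score_pp1(12, "AD")), "S")
  expect_null(score_pp1(0, "AR"))
  expect_equal(strength_of(score_pp1(1, "AR")), "P")
  expect_equal(strength_of(score_pp1(2, "AD_AR")), "M")
  expect_equal(strength_of(score_pp1(3, "AR")), "S")
})

test_that("PS4 strong clauses fire independently of proband counting", {
  g <- t_gene()
  cc <- case_level_data(case_control = list(odds_ratio = 8, ci_low = 1.4))
  expect_equal(strength_of(evaluate_ps4(cc, g, NULL)), "S")
  # an interval including 1 blocks the case-control clause
  cc2 <- case_level_data(case_control = list(odds_ratio = 8, ci_low = 0.9))
  expect_null(evaluate_ps4(cc2, g, NULL))
  expect_equal(strength_of(evaluate_ps4(
    case_level_data(founder_variant = TRUE), g, NULL)), "S")
  expect_equal(strength_of(evaluate_ps4(
    case_level_data(vcep_pathogenic = TRUE), g, NULL)), "S")
})

test_that("PS4 proband counting needs rarity, dominance and the right ladder", {
  pm2 <- criterion_call("PM2", "P")
  count <- function(n, gene, pm2_call = pm2) {
    strength_of(evaluate_ps4(case_level_data(proband_count = n), gene,
                             pm2_call))
  }
  g <- t_gene()
  expect_equal(count(1, g), "P")
  expect_equal(count(2, g), "P")
  expect_equal(count(3, g), "M")
  expect_equal(count(4, g), "M")
  expect_equal(count(5, g), "S")
  gc <- t_gene(category = "cancer")
  expect_true(is.na(count(1, gc)))
  expect_equal(count(2, gc), "P")
  expect_equal(count(6, gc), "M")
  expect_equal(count(9, gc), "M")
  expect_equal(count(10, gc), "S")
  # blocked without the rarity precondition
  blocked <- evaluate_ps4(case_level_data(proband_count = 6), g, NULL)
  expect_false(blocked$applied)
  # recessive-only genes do not count probands here
  expect_null(evaluate_ps4(case_level_data(proband_count = 6), t_gene("AR"),
                           pm2))
})

test_that("BS2 clauses follow inheritance, penetrance and carrier counts", {
  carriers <- function(het = 0, hom = 0, hemi = 0) {
    case_level_data(healthy_carrier_counts = list(het = het, hom = hom,
                                                  hemi = hemi))
  }
  expect_equal(strength_of(evaluate_bs2(
    case_level_data(in_house_positive_genotype_no_phenotype = TRUE),
    t_gene(high_penetrance_early_onset = TRUE))), "S")
  expect_equal(strength_of(evaluate_bs2(
    carriers(hom = 1), t_gene(category = "cancer"))), "S")
  expect_equal(strength_of(evaluate_bs2(
    carriers(hom = 1), t_gene("AR", complete_penetrance = TRUE))), "S")
  expect_null(evaluate_bs2(carriers(hom = 1), t_gene("AR")))
  expect_equal(strength_of(evaluate_bs2(
    carriers(het = 3, hom = 1), t_gene(pediatric_green_list = TRUE))), "S")
  expect_null(evaluate_bs2(carriers(het = 4),
                           t_gene(pediatric_green_list = TRUE)))
  expect_equal(strength_of(evaluate_bs2(carriers(hemi = 1), t_gene("XLR"))),
               "S")
  expect_equal(strength_of(evaluate_bs2(carriers(het = 5), t_gene("XLD"))),
               "S")
  expect_null(evaluate_bs2(carriers(het = 3), t_gene("XLD")))
})

test_that("BS4 is restricted to high-penetrance early-onset genes", {
  d <- case_level_data(nonsegregation_observed = TRUE)
  expect_equal(strength_of(evaluate_bs4(
    d, t_gene(high_penetrance_early_onset = TRUE))), "S")
  expect_null(evaluate_bs4(d, t_gene()))
  expect_null(evaluate_bs4(case_level_data(),
                           t_gene(high_penetrance_early_onset = TRUE)))
})

test_that("PP4 needs all four conditions and upgrades on pathognomonic evidence", {
  pm2 <- criterion_call("PM2", "M")
  base <- function(...) {
    case_level_data(comprehensive_test = TRUE,
                    family_history_consistent = TRUE,
                    phenotype_specific_single_etiology = TRUE, ...)
  }
  expect_equal(strength_of(evaluate_pp4(base(), pm2)), "P")
  expect_equal(strength_of(evaluate_pp4(
    base(pathognomonic_extra_evidence = TRUE), pm2)), "S")
  expect_null(evaluate_pp4(base(), NULL))
  no_test <- case_level_data(family_history_consistent = TRUE,
                             phenotype_specific_single_etiology = TRUE)
  expect_null(evaluate_pp4(no_test, pm2))
})

test_that("BP5 applies only to dominant childhood-onset genes with an alternate cause", {
  d <- case_level_data(alternate_molecular_cause = TRUE,
                       variant_noncontributory = TRUE)
  expect_equal(strength_of(evaluate_bp5(
    d, t_gene(ad_childhood_onset = TRUE))), "P")
  expect_null(evaluate_bp5(d, t_gene("AR", ad_childhood_onset = TRUE)))
  expect_null(evaluate_bp5(d, t_gene()))
  expect_null(evaluate_bp5(case_level_data(alternate_molecular_cause = TRUE),
                           t_gene(ad_childhood_onset = TRUE)))
})
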