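# Conflict resolution, combining rules and the Bayesian posterior.

test_that("mutually exclusive sets keep the strongest call", {
  res <- resolve_conflicts(list(criterion_call("BA1", "A"),
                                criterion_call("PM2", "M")))
  expect_equal(labels_of(res), "BA1_A")
  res2 <- resolve_conflicts(list(criterion_call("PS1", "S"),
                                 criterion_call("PM5", "M")))
  expect_equal(labels_of(res2), "PS1_S")
  res3 <- resolve_conflicts(list(criterion_call("PM2", "M")))
  expect_equal(labels_of(res3), "PM2_M")
  # equal-strength cross-direction ties resolve toward pathogenic with a warning
  res4 <- resolve_conflicts(list(criterion_call("PP1", "S"),
                                 criterion_call("BS4", "S")))
  expect_equal(labels_of(res4), "PP1_S")
  expect_match(applied_calls(res4)[[1]]$rationale, "pathogenic direction")
  # suppressed calls stay in the audit trail, demoted
  expect_length(res, 2)
  expect_false(res[[2]]$applied)
})

test_that("caution groups cap co-counting members", {
  trio <- list(criterion_call("PM3", "S"), criterion_call("PS4", "M"),
               criterion_call("PP1", "P"))
  res <- resolve_conflicts(trio, caution_cap = 2)
  expect_setequal(labels_of(res), c("PM3_S", "PS4_M"))
  res_all <- resolve_conflicts(trio, caution_cap = 3)
  expect_length(labels_of(res_all), 3)
  # pairs are unaffected at the default cap
  pair <- resolve_conflicts(list(criterion_call("PS2", "S"),
                                 criterion_call("PM6", "M")))
  expect_length(labels_of(pair), 2)
})

test_that("the enumerated combining rules classify their minimal sets", {
  tier_of <- function(calls) classify_rule_based(calls)
  p <- function(code, s) criterion_call(code, s)
  r <- tier_of(list(p("PVS1", "VS"), p("PM2", "P")))
  expect_equal(r$tier, "likely_pathogenic")
  expect_equal(r$matched_rule, "3B")
  r2 <- tier_of(list(p("PS4", "S"), p("PS3", "S")))
  expect_equal(r2$tier, "pathogenic")
  expect_equal(r2$matched_rule, "4E")
  r3 <- tier_of(list(p("PM2", "M")))
  expect_equal(r3$tier, "VUS")
  r4 <- tier_of(list(p("BA1", "A")))
  expect_equal(r4$tier, "benign")
  expect_equal(r4$matched_rule, "1A")
  r5 <- tier_of(list(p("PVS1", "VS"), p("PM3", "M")))
  expect_equal(r5$tier, "likely_pathogenic")
  expect_equal(r5$matched_rule, "3A")
  # conflicting directions log both rule sets and stay uncertain
  r6 <- tier_of(list(p("BS1", "S"), p("BS2", "S"), p("PS3", "S"),
                     p("PS2", "S")))
  expect_equal(r6$tier, "VUS")
  expect_true("1B" %in% r6$benign_rules)
  expect_true("4E" %in% r6$pathogenic_rules)
})

test_that("rule-based classification equals a brute-force matcher on all small count vectors", {
  # independent matcher over strength-count vectors
  oracle <- function(pVS, pS, pM, pP, bS, bP, ba1, has_3b) {
    path <- c("4A" = pVS >= 1 && pS >= 1, "4B" = pVS >= 1 && pM >= 2,
              "4C" = pVS >= 1 && pM >= 1 && pP >= 1,
              "4D" = pVS >= 1 && pP >= 2, "4E" = pS >= 2,
              "4F" = pS >= 1 && pM >= 3,
              "4G" = pS >= 1 && pM >= 2 && pP >= 2,
              "4H" = pS >= 1 && pM >= 1 && pP >= 4)
    lp <- c("3A" = pVS >= 1 && pM >= 1, "3B" = has_3b,
            "3C" = pS >= 1 && pM >= 1, "3D" = pS >= 1 && pP >= 2,
            "3E" = pM >= 3, "3F" = pM >= 2 && pP >= 2,
            "3G" = pM >= 1 && pP >= 4)
    ben <- c("1A" = ba1, "1B" = bS >= 2)
    lb <- c("2A" = bS >= 1 && bP >= 1, "2B" = bP >= 2)
    path_side <- any(path) || any(lp)
    ben_side <- any(ben) || any(lb)
    if (path_side && ben_side) return("VUS")
    if (any(path)) return("pathogenic")
    if (any(lp)) return("likely_pathogenic")
    if (any(ben)) return("benign")
    if (any(lb)) return("likely_benign")
    "VUS"
  }
  # pools of distinct criteria per direction/strength; the first VS is
  # PVS1 and the first pathogenic P is PM2 so rule 3B is exercised
  pools <- list(pVS = c("PVS1", "PS2", "PS3", "PM3", "PM6", "PM3"),
                pS = c("PS3", "PS1", "PS4", "PM1", "PS2", "PM6"),
                pM = c("PM2", "PM1", "PM4", "PM5", "PS1", "PM3"),
                pP = c("PM2", "PP1", "PP2", "PP3", "PP4", "PM3"),
                bS = c("BS1", "BS2", "BS3", "BS4", "BS1", "BS2"),
                bP = c("BP4", "BP5", "BP7", "BP3", "BS3", "BP4"))
  strength_for <- c(pVS = "VS", pS = "S", pM = "M", pP = "P",
                    bS = "S", bP = "P")
  grids <- expand.grid(pVS = 0:2, pS = 0:3, pM = 0:4, pP = 0:4,
                       bS = 0:2, bP = 0:2, ba1 = 0:1)
  grids <- grids[rowSums(grids) <= 6, ]
  for (i in seq_len(nrow(grids))) {
    g <- grids[i, ]
    calls <- list()
    for (slot in names(pools)) {
      k <- g[[slot]]
      if (k > 0) {
        calls <- c(calls, lapply(pools[[slot]][seq_len(k)], function(code) {
          criterion_call(code, strength_for[[slot]])
        }))
      }
    }
    if (g$ba1 == 1) calls <- c(calls, list(criterion_call("BA1", "A")))
    has_3b <- g$pVS >= 1 && g$pP >= 1   # PVS1_VS and PM2_P by construction
    got <- classify_rule_based(calls)$tier
    want <- oracle(g$pVS, g$pS, g$pM, g$pP, g$bS, g$bP, g$ba1 == 1, has_3b)
    expect_identical(got, want, info = paste(unlist(g), collapse = ","))
  }
})

test_that("the odds-of-pathogenicity ladder is exponentially scaled", {
  expect_equal(signif(evidence_odds("P"), 3), 2.08)
  expect_equal(signif(evidence_odds("M"), 3), 4.33)
  expect_equal(signif(evidence_odds("S"), 3), 18.7)
  expect_equal(evidence_odds("VS"), 350)
  # exponent additivity: two moderates equal one strong
  expect_equal(evidence_odds("M") * evidence_odds("M"), evidence_odds("S"))
  expect_equal(evidence_odds("P")^8, 350, tolerance = 1e-12)
})

test_that("the posterior reproduces the published consistency checks", {
  two_strong <- list(criterion_call("PS3", "S"), criterion_call("PS4", "S"))
  expect_equal(round(compute_posterior(two_strong, prior = 0.10), 3), 0.975)
  vs_m <- list(criterion_call("PVS1", "VS"), criterion_call("PM2", "M"))
  expect_equal(round(compute_posterior(vs_m, prior = 0.10), 3), 0.994)
  expect_equal(compute_posterior(list(), prior = 0.10), 0.10)
  expect_error(compute_posterior(list(), prior = 1.2), "prior")
})

test_that("the posterior is monotone and depends only on the net point total", {
  set.seed(42)
  path_pool <- list(criterion_call("PP1", "P"), criterion_call("PM2", "M"),
                    criterion_call("PS3", "S"), criterion_call("PVS1", "VS"))
  ben_pool <- list(criterion_call("BP4", "P"), criterion_call("BS3", "M"),
                   criterion_call("BS1", "S"))
  for (i in seq_len(1000)) {
    calls <- c(sample(path_pool, sample(0:3, 1), replace = TRUE),
               sample(ben_pool, sample(0:3, 1), replace = TRUE))
    base <- compute_posterior(calls, prior = 0.10)
    extra_p <- path_pool[[sample(4, 1)]]
    expect_gte(compute_posterior(c(calls, list(extra_p)), prior = 0.10), base)
    extra_b <- ben_pool[[sample(3, 1)]]
    expect_lte(compute_posterior(c(calls, list(extra_b)), prior = 0.10), base)
  }
  # additivity: equal net totals give equal posteriors
  a <- list(criterion_call("PS3", "S"), criterion_call("PM2", "M"),
            criterion_call("PM5", "M"))      # 4 + 2 + 2 = 8 points
  b <- list(criterion_call("PVS1", "VS"))    # 8 points
  expect_equal(compute_posterior(a), compute_posterior(b))
})

test_that("posterior categories use the published pathogenic-side boundaries", {
  expect_equal(posterior_category(0.994), "pathogenic")
  expect_equal(posterior_category(0.975), "likely_pathogenic")
  expect_equal(posterior_category(0.99), "likely_pathogenic")
  expect_equal(posterior_category(0.50), "VUS")
  expect_equal(posterior_category(0.05), "likely_benign")
  expect_equal(posterior_category(0.0005), "benign")
})

test_that("the consistency audit flags exactly the two inconsistent rules", {
  audit <- audit_consistency(prior = 0.10)
  expect_equal(nrow(audit), 19)
  flagged <- audit$rule[!audit$consistent]
  expect_setequal(flagged, c("4E", "3A"))
  expect_equal(audit$post_p[audit$rule == "4E"], 0.975)
  expect_equal(audit$post_p[audit$rule == "3A"], 0.994)
  # the null-variant rule sits inside the likely pathogenic range
  expect_equal(audit$post_tier[audit$rule == "3B"], "likely_pathogenic")
  expect_equal(audit$post_p[audit$rule == "3B"], 0.988)
})
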