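# Conflict resolution, the enumerated combining rules, and the Bayesian
# posterior probability of pathogenicity.

# Mutually exclusive criterion sets: within each, only the strongest
# applied call survives.
exclusivity_sets <- list(
  c("BA1", "BS1", "PM2"),
  c("PP3", "BP7", "BP4"),  # same-direction ties prefer the silent-variant rule
  c("PVS1", "PM4", "BP3"),
  c("PS1", "PM5"),
  c("PS3", "BS3"),
  c("PP1", "BS4")
)

# Caution groups: criteria that may overlap but whose simultaneous use
# requires caution; at most the `cap` strongest members count.
caution_groups <- list(
  c("PM1", "PP2"),
  c("PM1", "PM5"),
  c("PS2", "PM6"),
  c("PM3", "PS4", "PP1")
)

#' Resolve inter-criterion conflicts
#'
#' Enforces the mutual-exclusivity sets (frequency criteria; computational
#' criteria; protein-length/null criteria; PS1/PM5; PS3/BS3; PP1/BS4) by
#' keeping only the strongest applied call of each set, breaking
#' equal-strength ties toward the pathogenic direction (with a logged
#' warning in the rationale) and, within a direction, by the set's listed
#' order.  Caution groups (PM1/PP2, PM1/PM5, PS2/PM6, PM3/PS4/PP1) remain
#' co-applicable but are capped so that at most the `caution_cap` strongest
#' members count.  Suppressed calls are demoted to `applied = FALSE` and
#' kept for the audit trail.
#'
#' @param calls List of [criterion_call()]s from the criterion modules.
#' @param caution_cap Maximum number of co-counting members per caution
#'   group (default 2).
#' @return The full list of calls with losers demoted.
#' @export
resolve_conflicts <- function(calls, caution_cap = 2) {
  calls <- Filter(Negate(is.null), calls)
  idx_of <- function(code) {
    which(vapply(calls, function(x) x$criterion == code && isTRUE(x$applied),
                 logical(1)))
  }
  demote <- function(i, why) {
    calls[[i]]$applied <<- FALSE
    calls[[i]]$rationale <<- paste0(calls[[i]]$rationale, " | suppressed: ", why)
  }
  for (set in exclusivity_sets) {
    hits <- unlist(lapply(set, idx_of))
    if (length(hits) <= 1) next
    ranks <- vapply(hits, function(i) strength_rank[[calls[[i]]$strength]],
                    numeric(1))
    top <- hits[ranks == max(ranks)]
    if (length(top) > 1) {
      dirs <- vapply(top, function(i) calls[[i]]$direction, character(1))
      if (any(dirs == "pathogenic") && any(dirs == "benign")) {
        top <- top[dirs == "pathogenic"]
        calls[[top[1]]]$rationale <- paste0(
          calls[[top[1]]]$rationale,
          " | warning: equal-strength conflict resolved toward the pathogenic direction")
      }
      # within a direction, the set's listed order decides
      ord <- match(vapply(top, function(i) calls[[i]]$criterion, character(1)),
                   set)
      top <- top[order(ord)][1]
    }
    for (i in setdiff(hits, top)) {
      demote(i, paste0("mutually exclusive with ", calls[[top]]$criterion,
                       " (strongest rule is chosen)"))
    }
  }
  for (grp in caution_groups) {
    hits <- unlist(lapply(grp, idx_of))
    if (length(hits) <= caution_cap) next
    ranks <- vapply(hits, function(i) strength_rank[[calls[[i]]$strength]],
                    numeric(1))
    ord <- match(vapply(hits, function(i) calls[[i]]$criterion, character(1)),
                 grp)
    keep <- hits[order(-ranks, ord)][seq_len(caution_cap)]
    for (i in setdiff(hits, keep)) {
      demote(i, paste0("caution cap: at most ", caution_cap,
                       " of {", paste(grp, collapse = ", "), "} may count"))
    }
  }
  calls
}

# Tallies of applied calls by direction and strength.
strength_counts <- function(calls) {
  calls <- applied_calls(calls)
  cnt <- function(dir, s) {
    sum(vapply(calls, function(x) x$direction == dir && x$strength == s,
               logical(1)))
  }
  list(
    p = list(VS = cnt("pathogenic", "VS"), S = cnt("pathogenic", "S"),
             M = cnt("pathogenic", "M"), P = cnt("pathogenic", "P")),
    b = list(S = cnt("benign", "S"), M = cnt("benign", "M"),
             P = cnt("benign", "P")),
    ba1 = any(vapply(calls, function(x) x$criterion == "BA1", logical(1))),
    pvs1_vs = any(vapply(calls, function(x)
      x$criterion == "PVS1" && x$strength == "VS", logical(1))),
    pm2_p = any(vapply(calls, function(x)
      x$criterion == "PM2" && x$strength == "P", logical(1)))
  )
}

# The 19 combining rules.  Counts are read as minima ("at least"); tier
# precedence (pathogenic over likely pathogenic, benign over likely
# benign) resolves the overlaps that upper bounds would otherwise encode.
combining_rules <- list(
  list(id = "1A", tier = "benign",
       match = function(n) n$ba1),
  list(id = "1B", tier = "benign",
       match = function(n) n$b$S >= 2),
  list(id = "2A", tier = "likely_benign",
       match = function(n) n$b$S >= 1 && n$b$P >= 1),
  list(id = "2B", tier = "likely_benign",
       match = function(n) n$b$P >= 2),
  list(id = "3A", tier = "likely_pathogenic",
       match = function(n) n$p$VS >= 1 && n$p$M >= 1),
  list(id = "3B", tier = "likely_pathogenic",
       match = function(n) n$pvs1_vs && n$pm2_p),
  list(id = "3C", tier = "likely_pathogenic",
       match = function(n) n$p$S >= 1 && n$p$M >= 1),
  list(id = "3D", tier = "likely_pathogenic",
       match = function(n) n$p$S >= 1 && n$p$P >= 2),
  list(id = "3E", tier = "likely_pathogenic",
       match = function(n) n$p$M >= 3),
  list(id = "3F", tier = "likely_pathogenic",
       match = function(n) n$p$M >= 2 && n$p$P >= 2),
  list(id = "3G", tier = "likely_pathogenic",
       match = function(n) n$p$M >= 1 && n$p$P >= 4),
  list(id = "4A", tier = "pathogenic",
       match = function(n) n$p$VS >= 1 && n$p$S >= 1),
  list(id = "4B", tier = "pathogenic",
       match = function(n) n$p$VS >= 1 && n$p$M >= 2),
  list(id = "4C", tier = "pathogenic",
       match = function(n) n$p$VS >= 1 && n$p$M >= 1 && n$p$P >= 1),
  list(id = "4D", tier = "pathogenic",
       match = function(n) n$p$VS >= 1 && n$p$P >= 2),
  list(id = "4E", tier = "pathogenic",
       match = function(n) n$p$S >= 2),
  list(id = "4F", tier = "pathogenic",
       match = function(n) n$p$S >= 1 && n$p$M >= 3),
  list(id = "4G", tier = "pathogenic",
       match = function(n) n$p$S >= 1 && n$p$M >= 2 && n$p$P >= 2),
  list(id = "4H", tier = "pathogenic",
       match = function(n) n$p$S >= 1 && n$p$M >= 1 && n$p$P >= 4)
)

#' Apply the combining rules
#'
#' Evaluates all 19 enumerated combining rules on the resolved applied
#' calls.  On the pathogenic side, any matching pathogenic rule (4A-4H)
#' outranks the likely pathogenic rules (3A-3G); likewise benign (1A-1B)
#' over likely benign (2A-2B).  Matches in both directions, or no match at
#' all, classify as a variant of uncertain significance.
#'
#' @param calls List of resolved [criterion_call()]s.
#' @return List with `tier`, `matched_rule` (rule id or `NA`),
#'   `pathogenic_rules` and `benign_rules` (all matching rule ids, for the
#'   audit of conflicting matches).
#' @export
classify_rule_based <- function(calls) {
  n <- strength_counts(calls)
  matched <- Filter(function(r) isTRUE(r$match(n)), combining_rules)
  ids <- vapply(matched, `[[`, character(1), "id")
  tiers <- vapply(matched, `[[`, character(1), "tier")
  path_ids <- ids[tiers %in% c("pathogenic", "likely_pathogenic")]
  ben_ids <- ids[tiers %in% c("benign", "likely_benign")]
  pick <- function(ids, tiers, hi, lo) {
    if (any(tiers == hi)) list(tier = hi, rule = ids[tiers == hi][1])
    else list(tier = lo, rule = ids[tiers == lo][1])
  }
  if (length(path_ids) > 0 && length(ben_ids) > 0) {
    return(list(tier = "VUS", matched_rule = NA_character_,
                pathogenic_rules = path_ids, benign_rules = ben_ids))
  }
  if (length(path_ids) > 0) {
    r <- pick(path_ids, tiers[tiers %in% c("pathogenic", "likely_pathogenic")],
              "pathogenic", "likely_pathogenic")
    return(list(tier = r$tier, matched_rule = r$rule,
                pathogenic_rules = path_ids, benign_rules = character(0)))
  }
  if (length(ben_ids) > 0) {
    r <- pick(ben_ids, tiers[tiers %in% c("benign", "likely_benign")],
              "benign", "likely_benign")
    return(list(tier = r$tier, matched_rule = r$rule,
                pathogenic_rules = character(0), benign_rules = ben_ids))
  }
  list(tier = "VUS", matched_rule = NA_character_,
       pathogenic_rules = character(0), benign_rules = character(0))
}

#' Odds of pathogenicity for one evidence strength
#'
#' The exponentially scaled odds of the Bayesian framework: very strong
#' evidence carries odds 350:1 and the lower strengths carry the 1/2, 1/4
#' and 1/8 exponents, i.e. 18.7:1, 4.33:1 and 2.08:1 for strong, moderate
#' and supporting (to three significant figures).
#'
#' @param strength `"P"`, `"M"`, `"S"` or `"VS"`.
#' @return The odds as an exact numeric (`350^(points/8)`).
#' @export
evidence_odds <- function(strength) {
  strength <- match.arg(strength, c("P", "M", "S", "VS"))
  350 ^ (strength_points[[strength]] / 8)
}

# Net evidence points of a resolved call list: pathogenic minus benign,
# with supporting/moderate/strong/very strong worth 1/2/4/8 and the
# stand-alone benign call worth `ba1_points`.
net_points <- function(calls, ba1_points = 8) {
  calls <- applied_calls(calls)
  if (length(calls) == 0) return(0)
  pts <- vapply(calls, function(x) {
    p <- if (x$strength == "A") ba1_points else strength_points[[x$strength]]
    if (x$direction == "pathogenic") p else -p
  }, numeric(1))
  sum(pts)
}

posterior_from_points <- function(points, prior) {
  odds <- 350 ^ (points / 8)
  odds * prior / ((odds - 1) * prior + 1)
}

#' Bayesian posterior probability of pathogenicity
#'
#' Combines the applied calls into a net evidence-point total (supporting
#' 1, moderate 2, strong 4, very strong 8; benign calls subtract, the
#' stand-alone benign call subtracting `ba1_points`), converts it to
#' combined odds `350^(points/8)`, and applies Bayes' rule at the given
#' prior:
#' `Post_P = odds * prior / ((odds - 1) * prior + 1)`.
#'
#' @param calls List of resolved [criterion_call()]s.
#' @param prior Prior probability of pathogenicity, in (0, 1); default 0.10.
#' @param ba1_points Benign points carried by the stand-alone frequency
#'   call on the Bayesian path (default 8; the rule-based path honours it
#'   as stand-alone regardless).
#' @return The posterior probability (full precision; reports round to 3
#'   decimals).
#' @export
compute_posterior <- function(calls, prior = 0.10, ba1_points = 8) {
  if (!is.numeric(prior) || length(prior) != 1 || prior <= 0 || prior >= 1) {
    stop("prior must lie strictly inside (0, 1)")
  }
  posterior_from_points(net_points(calls, ba1_points), prior)
}

#' Posterior probability category
#'
#' Maps a posterior probability to the five-tier scale: pathogenic above
#' 0.99, likely pathogenic in `[0.90, 0.99]`, and - using the benign-side
#' boundaries of the underlying Bayesian framework, which this engine
#' imports as configurable defaults - likely benign in `[0.001, 0.10)` and
#' benign below 0.001; uncertain otherwise.
#'
#' @param post_p Posterior probability.
#' @param bounds Named list of boundaries: `pathogenic` (exclusive lower),
#'   `lp_low` (inclusive), `lb_high` (exclusive upper), `benign_high`
#'   (exclusive upper).
#' @return Tier label.
#' @export
posterior_category <- function(post_p,
                               bounds = list(pathogenic = 0.99, lp_low = 0.90,
                                             lb_high = 0.10,
                                             benign_high = 0.001)) {
  if (post_p > bounds$pathogenic) "pathogenic"
  else if (post_p >= bounds$lp_low) "likely_pathogenic"
  else if (post_p < bounds$benign_high) "benign"
  else if (post_p < bounds$lb_high) "likely_benign"
  else "VUS"
}

# Minimal satisfying call multisets for the consistency audit, expressed
# as evidence-point vectors.  3B is the specific PVS1_VS + PM2_P pair.
rule_minimal_sets <- list(
  `1A` = list(tier = "benign",            set = "BA1",            points = -8),
  `1B` = list(tier = "benign",            set = "S+S (benign)",   points = -8),
  `2A` = list(tier = "likely_benign",     set = "S+P (benign)",   points = -5),
  `2B` = list(tier = "likely_benign",     set = "P+P (benign)",   points = -2),
  `3A` = list(tier = "likely_pathogenic", set = "VS+M",           points = 10),
  `3B` = list(tier = "likely_pathogenic", set = "PVS1_VS+PM2_P",  points = 9),
  `3C` = list(tier = "likely_pathogenic", set = "S+M",            points = 6),
  `3D` = list(tier = "likely_pathogenic", set = "S+P+P",          points = 6),
  `3E` = list(tier = "likely_pathogenic", set = "M+M+M",          points = 6),
  `3F` = list(tier = "likely_pathogenic", set = "M+M+P+P",        points = 6),
  `3G` = list(tier = "likely_pathogenic", set = "M+P+P+P+P",      points = 6),
  `4A` = list(tier = "pathogenic",        set = "VS+S",           points = 12),
  `4B` = list(tier = "pathogenic",        set = "VS+M+M",         points = 12),
  `4C` = list(tier = "pathogenic",        set = "VS+M+P",         points = 11),
  `4D` = list(tier = "pathogenic",        set = "VS+P+P",         points = 10),
  `4E` = list(tier = "pathogenic",        set = "S+S",            points = 8),
  `4F` = list(tier = "pathogenic",        set = "S+M+M+M",        points = 10),
  `4G` = list(tier = "pathogenic",        set = "S+M+M+P+P",      points = 10),
  `4H` = list(tier = "pathogenic",        set = "S+M+P+P+P+P",    points = 10)
)

#' Bayesian consistency audit of the combining rules
#'
#' For each of the 19 combining rules, takes its minimal satisfying call
#' multiset, computes the posterior probability at the given prior,
#' rounds it to the 3 decimals used in reports, and checks whether the
#' posterior category agrees with the rule's asserted tier.  On defaults
#' this flags exactly the two rules known to be mathematically
#' inconsistent with the framework: two strong criteria asserting
#' pathogenic (posterior 0.975, the likely pathogenic range) and one very
#' strong plus one moderate asserting likely pathogenic (posterior 0.994,
#' the pathogenic range).
#'
#' @param prior Prior probability of pathogenicity (default 0.10).
#' @return Data frame with one row per rule: `rule`, `tier`, `minimal_set`,
#'   `points`, `post_p` (3 decimals), `post_tier`, `consistent`.
#' @export
audit_consistency <- function(prior = 0.10) {
  rows <- lapply(names(rule_minimal_sets), function(id) {
    r <- rule_minimal_sets[[id]]
    pp <- round(posterior_from_points(r$points, prior), 3)
    pt <- posterior_category(pp)
    data.frame(rule = id, tier = r$tier, minimal_set = r$set,
               points = r$points, post_p = pp, post_tier = pt,
               consistent = identical(pt, r$tier),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
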