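---
title: "Methods: criterion modulation, conflict resolution and the Bayesian posterior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: criterion modulation, conflict resolution and the Bayesian posterior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acmgrules)
```

## Scope and assumptions

`acmgrules` classifies constitutional sequence variants (SNVs and small
indels) in Mendelian disease genes. It assumes evidence has already been
curated upstream: allele counts per population, the molecular consequence
on the primary transcript, previously classified variants at the same
residue, case-level observations, in-silico scores and functional-assay
verdicts all arrive in the evidence record. Structural, mitochondrial and
somatic variants, and oligogenic inheritance, are out of scope, as is any
live database retrieval.

Two gates precede every classification. First, the gene–disease
association must have clinical validity of at least *limited*; disputed,
refuted or uncurated genes are refused with a logged reason rather than
classified (the behaviour for uncurated genes is a deliberate design
choice — silently classifying on an unvalidated association would be
misleading). Second, genes owned by a Variant Curation Expert Panel are
delegated: their gene-specific workflows supersede the general rules, so
the engine emits a delegation marker and stops. Transcript context is
fixed by the reference priority MANE Select → RefSeq Select → MANE
Clinical Plus → RefSeq, with the largest transcript chosen among plain
RefSeq candidates and lexicographic identifier order breaking exact ties
(a determinism choice; the tie is otherwise unspecified).

## Frequency criteria

BA1, BS1 and PM2 are mutually exclusive and are evaluated on populations
that are founder-effect-free and have strictly more than 2,000 alleles
tested. The presence requirement (variant seen in at least 5 alleles)
applies only to the benign-direction criteria: requiring presence for PM2
would make "absent from controls" unusable, so rarity is assessed on all
founder-free, well-sampled populations. Frequencies are compared as exact
rationals `AC/AN`, never as pre-rounded percentages, to avoid boundary
artifacts, and the comparison directions follow the printed symbols:
BA1 at `>= 0.05`, BS1 strictly `>`, PM2 strictly `<`.

The built-in threshold table, by gene category and inheritance grouping
(AD versus AR, AD/AR or X-linked — the X-linked refinements XLR and XLD
use the X-linked grouping here):

| category | inheritance | BS1_S | PM2_P | PM2_M |
|----------|-------------|-------|--------|--------|
| cancer | AD | > 0.1% | < 0.004% | absent |
| cancer | AR, AD/AR, XL | > 1% | < 0.04% | < 0.004% |
| general | AD | > 0.1% | < 0.001% | absent |
| general | AR, AD/AR, XL | > 1% | < 0.01% | < 0.001% |

"Absent" means an allele count of zero in *every* eligible population;
ineligible populations are ignored, not treated as absent. When no
population passes eligibility at all, the rarity call is withheld with an
"insufficient population data" rationale — asserting PM2 without
evaluable controls would manufacture evidence. Genes on the stand-alone
exception list have no default thresholds and must carry explicit
per-gene overrides; even then the stand-alone call itself is withheld for
them (BS1 remains assessable), because exception-list membership means
the 5% rule is known to misfire for that locus.

## Variant-type criteria

**PVS1** applies to null variants only (nonsense, frameshift, canonical
splice site, initiation codon, exon deletion) and only where loss of
function is the established disease mechanism — by haploinsufficiency
curation, or, uncurated, by `pLI > 0.9` or `o/e < 0.35`. Strength comes
from a decision table shipped as an editable CSV
(`inst/extdata/pvs1_decision_table.csv`): NMD-predicted truncations are
very strong; NMD-escaping truncations are strong when the affected region
is critical and moderate otherwise; in-frame exon skipping is weighted by
region criticality; initiation-codon variants are moderate. The table is
configuration rather than code because laboratories legitimately tune
these downgrades.

**PS1/PM5** (same-residue precedent) aggregate independent report counts
across the supplied prior-variant records — the engine does not attempt
to deduplicate literature reports. PS1 pre-empts PM5, and both are
suppressed outright when a deleterious splice prediction (SpliceAI
≥ 0.8) or functional evidence of aberrant splicing makes a pure missense
mechanism uncertain. Suppression rather than downgrade is a deliberate
reading of an ambiguous caution: the suppressed call stays visible in
the audit trail, so a curator can reinstate it manually.

**PM1** gives strong weight to three curated domain classes
(cysteine-parity-altering substitutions in EGF-like repeats of NOTCH3,
glycine substitutions in collagen genes, Cys/His substitutions in C2H4
zinc fingers) and moderate weight under regional missense constraint
< 0.4 or inside configured literature hotspot intervals. The NOTCH3
cysteine-parity condition is a boolean supplied by the annotator;
sequence-level EGF-repeat annotation is out of scope.

**PM4** (protein-length change) requires the variant to be rare (a PM2
call at either level), excludes repeat regions (> 3 identical units),
and weighs 1–2 residue indels supporting, ≥ 3 residues moderate.
Stop-loss variants are mapped to moderate: the length tiers are only
stated for indels, and a stop-loss extends the protein by well over
three residues in essentially every transcript. **PP2** requires at
least three reported pathogenic missense variants *and* regional
constraint Z > 3.09 (strict). **BP7** requires a synonymous variant with
SpliceAI ≤ 0.2 and GERP < 0; a missing score withholds the call.

BP1 and BP3 are policy-unapplied (with an override hook for exceptional
BP3 evidence), and PP5/BP6 are discontinued; all four remain in the
audit trail so every report enumerates 28 criteria.

## Case-level criteria

PM3 (recessive), PS2 (confirmed de novo) and PM6 (assumed de novo) share
an additive scoring system and the ladder P ≥ 0.5, M ≥ 1, S ≥ 2, VS ≥ 4.
Per-observation scores: in trans with a pathogenic/likely pathogenic
variant 1.0, phase unknown 0.5, homozygous 0.5 (0.25 with consanguineous
parents); confirmed de novo 2.0/1.0/0.5/0 by phenotype specificity;
assumed de novo 1.0/0.5/0.25/0. Mixed cohorts may emit PS2 and PM6
together — the criteria pool different probands — and the classifier's
caution policy caps their joint contribution.

PP1 counts segregating meioses: 3–4/5–6/≥ 7 for dominant conditions,
1/2/≥ 3 where inheritance has a recessive component (XLR counts with the
recessive tiers, XLD with the dominant — the tiers are stated only for
AD and AR, so the X-linked modes follow their dominant/recessive
character). PS4 is strong for case-control odds ratios > 5 with a
confidence interval excluding 1, for founder variants and for
expert-panel-curated pathogenic variants; otherwise probands are counted
only for dominant conditions (AD, the AD side of AD/AR, XLD) and only
when the rarity precondition (PM2 at either level) holds — cancer genes
at 2–5/6–9/≥ 10 and other genes at 1–2/3–4/≥ 5 for P/M/S. BS2, BS4, PP4
and BP5 are boolean-gated clauses over penetrance/onset flags carried in
the gene configuration; the engine does not infer those properties.

## Conflict resolution and combining rules

Six mutual-exclusivity sets are enforced after evaluation: {BA1, BS1,
PM2}, {PP3, BP4, BP7}, {PVS1, PM4, BP3}, {PS1, PM5}, {PS3, BS3},
{PP1, BS4}. The strongest call survives; equal-strength ties across
directions resolve toward the pathogenic direction with a logged warning
(conservative for follow-up: a false pathogenic lean surfaces for manual
review, a silently dropped pathogenic call would not), and same-direction
ties follow a fixed order in which the more specific criterion wins
(e.g. BP7 over BP4 for silent variants). Caution groups ({PM1, PP2},
{PM1, PM5}, {PS2, PM6}, {PM3, PS4, PP1}) remain co-applicable but only
the two strongest members count by default (configurable). Suppressed
calls are demoted, not deleted, so the audit trail shows both the
evidence and the policy that set it aside.

The 19 combining rules are evaluated on the resolved strength counts.
Count conditions are read as minima ("at least"): the upper bounds that
appear in phrasings like "1 Strong AND 1–2 Moderate" are subsumed by
tier precedence, because any call set exceeding the upper bound also
matches a pathogenic-tier rule, which outranks the likely-pathogenic
match. Matches in both directions, or no match, yield VUS with all
matching rule identifiers logged.

## The Bayesian posterior

Each strength maps to exponentially scaled odds of pathogenicity —
350 for very strong and its 1/2, 1/4 and 1/8 exponents (18.7, 4.33,
2.08) for strong, moderate, supporting. Equivalently, evidence points
1/2/4/8 per strength combine additively; benign evidence subtracts; and

```
OddsPath = 350^(points/8),
Post_P = OddsPath * prior / ((OddsPath - 1) * prior + 1).
```

The default prior is 0.10. It is not a value this engine estimates; it
is the operating point of the framework the odds were calibrated in, and
it is exposed as a configuration parameter (`engine_config(prior = …)`,
`--prior` on the CLI).

Two boundary choices deserve explanation:

* **BA1 in the posterior.** Treating any frequency evidence as absolute
  is contrary to Bayesian reasoning, so the rule-based path honours BA1
  as stand-alone while the posterior path scores it as 8 benign points
  (configurable). Both outputs are reported side by side rather than
  merged.
* **Category boundaries.** The pathogenic side uses Post_P > 0.99
  (pathogenic) and 0.90–0.99 inclusive (likely pathogenic). The benign
  side (< 0.001 benign, 0.001–0.10 likely benign) is imported from the
  calibration framework, is configurable, and is labelled as imported in
  the documentation because those two numbers are not restated in the
  modulation standard itself.

`audit_consistency()` re-derives the published consistency analysis: it
takes each rule's minimal satisfying multiset, computes its posterior at
the default prior, rounds to the three decimals used in all reports, and
compares the resulting category with the rule's asserted tier. Rounding
before categorising matters: the six-point likely-pathogenic minimal
sets sit at Post_P 0.8999…, which is 0.900 at report precision and hence
inside the likely-pathogenic range — the same convention under which the
published analysis finds exactly two inconsistent rules (two strongs
asserting pathogenic at 0.975; very strong plus moderate asserting
likely pathogenic at 0.994). The audit evaluates the arithmetic of each
rule, not the biological co-occurrence feasibility of its multiset.

## Synthetic data

The package generates all of its own test data.

* `gold_fixture_set()` builds 96 hand-constructed evidence records, each
  with its expected applied-call set and tier; together they exercise
  every clause tag in `clause_tags()` and every combining rule. A
  five-record subset ships as `inst/extdata/demo_evidence.json` for the
  readers and the CLI demo.
* `random_cohort(n, seed, clause_prevalence)` injects named clauses into
  a neutral base record with configured probabilities, resolving the
  mutually exclusive frequency clauses toward the strongest drawn. It is
  seeded and reproducible.

These cohorts emulate evidence *combinations*, not biology: allele
frequencies, report counts and scores are placed just beyond the
relevant thresholds rather than drawn from realistic human
allele-frequency spectra or literature-report distributions. Passing
tests therefore demonstrate that the rules engine implements its
specification faithfully — they say nothing about upstream annotation
quality, which this engine deliberately treats as someone else's
problem.

## Numerical choices and problem sizes

* Frequencies and thresholds are exact doubles; no percentage rounding
  anywhere in the decision path.
* Reported posteriors are rounded to 3 decimals; the data model keeps
  full precision.
* The property suites run on fixed seeds: exhaustive report-count grids
  (4^4) for PS1/PM5, observation multisets to size 5 for the scoring
  systems, a 0.05-resolution score grid for PP3/BP4/BP7 exclusivity,
  1,000 random call multisets for posterior monotonicity, all
  strength-count vectors with at most six calls (about 1,700) against a
  brute-force rule matcher, and a 4,000-record random cohort for the
  prevalence check — sizes chosen so the full suite stays in the
  low minutes while the binomial tolerance (3 standard errors) remains
  meaningful.

## Known limitations

* The loss-of-function decision table is a deliberately coarse rendering
  of the full published decision tree; laboratories needing the complete
  tree should extend the shipped CSV.
* Functional-assay strength arrives pre-curated; the assay-validation
  flowchart itself is not implemented.
* Proband/report deduplication across publications is the curator's
  responsibility; the engine sums what it is given.
* Gene-level flags (penetrance, onset, green-list membership, domain
  class) are configuration, not inference.
* VCF input carries the same flat encoding as the TSV columns in INFO
  fields; it is a convenience for pipelines already emitting annotated
  VCFs, not a general-purpose VCF interpreter.
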