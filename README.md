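# acmgrules

A deterministic, auditable rules engine for classifying constitutional
(germline) sequence variants under laboratory-modulated ACMG/AMP
criteria, with a Bayesian posterior probability of pathogenicity reported
alongside the rule-based five-tier call.

## Who this is for

Clinical-genomics engineers and variant scientists who already have
curated, pre-annotated evidence for each variant — population allele
counts, molecular consequence, case-level observations, in-silico scores,
functional-assay outcomes — and need a reproducible engine that turns
that evidence into criterion calls, resolves conflicts, applies the
combining rules and documents every decision. The engine never queries
databases or touches reference genomes; evidence arrives as JSON, TSV or
a minimally annotated VCF.

## The model

Each of the 28 ACMG/AMP criteria (PVS1, PS1–4, PM1–6, PP1–5, BA1, BS1–4,
BP1–7) is evaluated with a modulated strength: stand-alone (A), very
strong (VS), strong (S), moderate (M) or supporting (P). Key modulations
implemented here include:

* **Frequency criteria** (BA1/BS1/PM2): mutually exclusive, evaluated on
  founder-free populations with more than 2,000 alleles tested (benign
  calls additionally require presence in ≥ 5 alleles), with per
  gene-category and inheritance-mode thresholds (e.g. BS1_S above 0.1%
  for dominant, 1% for recessive conditions; BA1 at allele frequency
  ≥ 0.05) and a per-gene override hook.
* **Scoring systems** for PM3 (in-trans observations), PS2/PM6 (de novo
  observations): additive per-proband scores with the shared ladder
  P ≥ 0.5, M ≥ 1, S ≥ 2, VS ≥ 4.
* **Counting systems** for PS4 (unrelated probands, dominant conditions,
  rarity precondition) and PP1 (segregating meioses).
* **PVS1** through a configurable loss-of-function decision table gated
  on the disease mechanism (haploinsufficiency curation, else pLI > 0.9
  or o/e < 0.35).
* **In-silico thresholds**: REVEL > 0.7 / < 0.4 for missense PP3/BP4,
  SpliceAI delta ≥ 0.8 / ≤ 0.2 for noncoding, BP7 for silent variants
  with SpliceAI ≤ 0.2 and GERP < 0.

Applied criteria combine in two ways, reported side by side:

1. **Rule-based tier** — the 19 enumerated combining rules (1A–1B benign,
   2A–2B likely benign, 3A–3G likely pathogenic, 4A–4H pathogenic);
   conflicting directions yield VUS.
2. **Bayesian posterior** — each strength maps to exponentially scaled
   odds of pathogenicity (2.08, 4.33, 18.7 and 350 for P/M/S/VS);
   evidence points (1/2/4/8, benign negative) combine as

   ```
   OddsPath = 350^(points/8)
   Post_P   = OddsPath * prior / ((OddsPath - 1) * prior + 1)
   ```

   with a default prior of 0.10.

Every classification carries a 28-entry audit trail recording, for each
criterion, whether it applied, at which strength, and the clause that
decided it.

## Worked example

```r
library(acmgrules)
recs <- read_evidence(system.file("extdata", "demo_evidence.json",
                                  package = "acmgrules"))
cls <- classify_variants(recs)
for (cl in cls) print(cl)
```

```
<classification> ba1_standalone - classified
  tier: benign (rule 1A)
  Post_P: 0.000 (benign range, prior 0.1)
  applied: BA1_A
<classification> pvs1_vs_pm2p - classified
  tier: likely_pathogenic (rule 3B)
  Post_P: 0.988 (likely_pathogenic range, prior 0.1)
  applied: PVS1_VS, PM2_P
<classification> bp7_silent - classified
  tier: VUS
  Post_P: 0.051 (likely_benign range, prior 0.1)
  applied: BP7_P
<classification> pm3_very_strong - classified
  tier: likely_pathogenic (rule 3A)
  Post_P: 0.994 (pathogenic range, prior 0.1)
  applied: PM2_M, PM3_VS
<classification> no_evidence - classified
  tier: VUS
  Post_P: 0.100 (VUS range, prior 0.1)
```

The first record is a common variant: the stand-alone frequency
criterion alone classifies it benign. The second is a nonsense variant,
absent-but-for-one-allele, in a haploinsufficient gene: PVS1 at very
strong plus PM2 at supporting matches rule 3B (likely pathogenic), and
its posterior (0.988) sits inside the likely-pathogenic range — the two
views agree. The fourth record shows them disagreeing in a documented
way: a recessive variant with a very strong in-trans scoring total
matches the "1 Very Strong + 1 Moderate" rule (likely pathogenic) while
its posterior, 0.994, already exceeds the pathogenic bound — exactly the
inconsistency the rule audit flags:

```r
audit <- audit_consistency()
audit[!audit$consistent, c("rule", "tier", "minimal_set", "post_p", "post_tier")]
#>    rule              tier minimal_set post_p         post_tier
#> 5    3A likely_pathogenic        VS+M  0.994        pathogenic
#> 16   4E        pathogenic         S+S  0.975 likely_pathogenic
```

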