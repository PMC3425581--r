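# aersrank

Prescription-normalized ranked-risk analysis of spontaneous adverse-event
reports, for pharmacovigilance analysts who need to compare reporting rates
across drugs with very different market sizes.

Spontaneous reporting databases (FDA AERS/FAERS and kin) hold case safety
reports: suspected drugs with role codes, coded reaction terms, outcomes,
reporter occupations. Raw counts mislead — a drug prescribed 40× more often
files more reports at the same true rate, drug names appear under hundreds
of variants and misspellings, and the same clinical event is often reported
repeatedly. `aersrank` turns raw quarterly extracts into comparable
statistics through an auditable pipeline:

1. **Read** legacy dollar-delimited quarterly tables (DEMO/DRUG/REAC/OUTC/RPSR),
   logging every malformed line.
2. **Consolidate** drug-name variants via a curated synonym dictionary with
   optional Levenshtein-distance matching (ties are never guessed).
3. **Deduplicate** follow-up versions (latest per case key) and independently
   submitted duplicates (conservative field-agreement heuristic), logging
   every drop.
4. **Match** reports against named adverse-event categories (term sets,
   exact or substring).
5. **Normalize and rank**: with NRx the summed new-prescription count,

   ```
   PR_d  = NRx_d / max(NRx)                  (prescribing ratio)
   r_dc  = n_dc / PR_d                       (normalized rate)
   RR_dc = round(100 * r_dc / max_d' r_d'c)  (ranked risk; top drug = 100)
   ```

plus yearly trends, outcome/reporter stratifications, a peak-prescription
sensitivity analysis, and a synthetic report generator with ground-truth
labels so every stage is testable without FDA data.

## Worked example: statins and myalgia

The package ships the published inputs for the six-statin muscle-safety
comparison (July 2005 – March 2011): summed NRx totals and the per-drug
myalgia report counts by suspect role.

```r
library(aersrank)

pr <- prescribing_ratios(statin_nrx())
cts <- statin_myalgia_counts()
cts <- cts[match(pr$drug, cts$drug), ]
build_risk_table("Myalgia", pr$drug, cts$primary_count, cts$all_count, pr$pr)
```

```
  category         drug primary_count all_count     pr primary_rate all_rate ranked_primary ranked_all
1  Myalgia rosuvastatin          1641      2019 0.2901         5657     6960            100        100
2  Myalgia  fluvastatin           103       184 0.0265         3887     6943             69        100
3  Myalgia atorvastatin          2751      3667 0.8604         3197     4262             57         61
4  Myalgia  pravastatin           257       541 0.2275         1130     2378             20         34
5  Myalgia  simvastatin          1003      1827 1.0000         1003     1827             18         26
6  Myalgia   lovastatin            67       189 0.2153          311      878              6         13
```

Read: rosuvastatin generates the most myalgia reports per unit of
prescribing and anchors both rankings at 100. Fluvastatin — rarely
prescribed (PR 0.0265) with only 103 primary-suspect reports — lands at 69:
the ranking exposes a high per-prescription reporting rate that raw counts
hide. Simvastatin, with the largest market share, ranks near the bottom
despite having the third-highest raw count. Two cells sit one unit from
their published counterparts (the rosuvastatin all-suspect rate and the
lovastatin primary ranked risk, which falls exactly on a .50 rounding
boundary); the vignette discusses both.

End-to-end on synthetic data:

```r
gen <- generate_reports(simulation_config(n_reports = 2000, seed = 1))
res <- run_pipeline(run_config(gen$paths, output_dir = tempfile()))
res$tables$risk          # per-category risk tables
truth_compare(res$cases, gen$truth, default_muscle_categories())
```

A command-line front end with `run`, `simulate`, `match-drugs`, `dedup` and
`rank` subcommands is installed at `inst/cli/aersrank.R`.

## Not in scope

Disproportionality statistics (PRR/ROR/EBGM), confidence intervals, MedDRA
hierarchy traversal, probabilistic record linkage, and any acquisition of
FDA or prescription data.
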