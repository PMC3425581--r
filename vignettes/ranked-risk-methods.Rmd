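---
title: "Prescription-normalized ranked risk from spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prescription-normalized ranked risk from spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aersrank)
```

## The problem

Spontaneous reporting systems such as the FDA's AERS/FAERS collect
case safety reports — a patient, one or more suspected drugs, one or more
coded adverse reactions, severity outcomes, and the reporter's occupation.
Raw report counts cannot be compared across drugs: a drug prescribed forty
times more often will generate more reports at the same true event rate, the
same drug appears under hundreds of name variants, and the same clinical
event is frequently reported more than once. `aersrank` implements a
complete, auditable pipeline that addresses each distortion in turn and ends
in a simple comparative statistic, the **ranked risk**.

The worked example shipped with the package is the class of HMG-CoA
reductase inhibitors (statins) and muscle/tendon adverse events — a setting
where six drugs with very different market shares (simvastatin's summed
new-prescription total is nearly forty times fluvastatin's) must be compared
on muscle-toxicity reporting.

## The model

For drug $d$ in a comparison set $D$, let $N_d$ be its summed
new-prescription count (NRx) over the study window. The *prescribing ratio*
is

$$\mathrm{PR}_d = \frac{N_d}{\max_{d' \in D} N_{d'}},$$

so the most-prescribed drug has $\mathrm{PR} = 1$. For an adverse-event
category $c$ (a named set of coded reaction terms), let $n_{dc}$ be the
number of deduplicated case reports that both match $c$ and list $d$ in the
requested suspect role (primary suspect only, or primary-or-secondary for
the "all suspect" analysis). The *normalized rate* and *ranked risk* are

$$r_{dc} = \frac{n_{dc}}{\mathrm{PR}_d}, \qquad
\mathrm{RR}_{dc} = \left\lfloor 100 \cdot
  \frac{r_{dc}}{\max_{d'} r_{d'c}} \right\rceil,$$

where $\lfloor \cdot \rceil$ is rounding half away from zero. The
highest-rate drug in each category is therefore pinned at 100 and the others
are expressed relative to it. The statistic is deliberately scale-free:
multiplying every NRx by a constant, or every count by a constant, changes
nothing.

Assumptions worth stating: reporting propensity per prescription is taken as
comparable across the drugs (no adjustment for time on market, media
attention, or channeling of fragile patients to particular drugs), and NRx
is taken as proportional to exposure. These are strong assumptions — the
ranked risk is a reporting-rate comparison, not an incidence estimate, and
the package computes no confidence intervals because the denominator is a
market-size proxy rather than a sampled population.

## Pipeline stages and their parameters

1. **Reading** (`read_quarter()`): legacy dollar-delimited quarterly tables
   (DEMO, DRUG, REAC, OUTC, RPSR). The delimiter, per-table columns and
   date format are configurable via `aers_dialect()`. Malformed lines are
   never silently dropped: they land in a rejects log with line numbers,
   and row-count conservation (read = assembled + excluded + rejected) is
   asserted in the run manifest.
2. **Assembly** (`assemble_cases()`): tables join on the report instance
   key (ISR). A report needs at least one drug and one reaction; missing
   demographics degrade to unknown values rather than excluding the report.
   Receipt-date windowing (`filter_date_window()`, default July 2005 –
   March 2011) keeps undated reports and flags them, since the source
   convention for missing dates is unknown.
3. **Name consolidation** (`normalize_name()`, `match_drug()`,
   `annotate_cases()`): verbatim names are case-folded, stripped of
   bracketed qualifiers, punctuation and trailing dosage/form tokens, then
   looked up in a curated synonym dictionary. Fuzzy matching by Levenshtein
   distance (default `max_distance = 1`) is a safety net only: an exact
   dictionary hit always wins, and a tie between two canonical drugs at
   equal distance is never guessed. The shipped statin dictionary is small
   and hand-checked; users consolidating other drug classes supply their
   own two-column CSV.
4. **Deduplication** (`dedup_versions()`, `dedup_heuristic()`): first,
   follow-up versions sharing a case key collapse to the latest receipt
   (ties broken by largest ISR, deterministically). Second, independently
   submitted duplicates are detected by exact agreement on canonical drug
   set, reaction-term set, sex and age, with receipt dates within a
   configurable window (default 30 days); the earliest report survives.
   The field-agreement rule is deliberately conservative — a report with
   any missing blocking field matches nothing, because absence of evidence
   is not agreement. Every drop is logged with its surviving partner.
   The pipeline consolidates names before deduplicating because the
   duplicate heuristic compares canonical drug sets; running it on verbatim
   names would miss duplicates reported under different name variants.
5. **Category matching** (`event_category()`, `case_matches()`): categories
   are term sets with `EXACT_TERM` (default — reactions are coded terms) or
   `SUBSTRING` matching for deliberately broad catch-alls. A report counts
   at most once per (drug, category) cell regardless of how many reactions
   match. The packaged broad categories (joints/tendons, muscle
   atrophy/injury, coordination/weakness) are editable defaults: category
   definitions are study choices, not fixed vocabulary.
6. **Metrics** (`prescribing_ratios()`, `risk_table()`, `combined_risk()`,
   `yearly_trend()`, `stratify()`, `sensitivity_peak_rx()`): as defined
   above, plus combined-category risks (summing per-category counts, so a
   report matching $k$ categories contributes $k$; a `unique_case` mode is
   available), yearly primary-suspect trends with an UNKNOWN bucket for
   undated reports, non-exclusive outcome strata, exclusive reporter strata
   with percentages, and a sensitivity variant that rebuilds prescribing
   ratios from peak annual prescription counts.

### Numerical choices

All displayed ratios and rates round half away from zero
(`round_half_up()`): prescribing ratios to 4 decimals, normalized rates and
ranked risks to integers, combined-risk percentages to one decimal. Full
precision is kept internally so rounding never cascades. This choice
reproduces the published statin myalgia table to within one unit in every
cell; two cells disagree by exactly one unit under *any* single consistent
rounding rule (the rosuvastatin all-suspect rate, printed 6,959 where
2,019/0.2901 = 6,959.67, and the lovastatin primary ranked risk, printed 5
where the ratio sits exactly on the 5.50 boundary), which the tests document
rather than match cell-exactly.

"All suspect" means primary or secondary suspect; concomitant and
interacting mentions are excluded by default (`include_concomitant = TRUE`
widens this), since the suspect/concomitant distinction is precisely what
the role codes encode.

## The synthetic report generator

Real AERS extracts are large and cannot ship with a package, so
`generate_reports()` produces quarterly files with known ground truth.
The generator emulates: report counts per (drug, category) proportional to
prescribing weight × category rate; drug names emitted verbatim, corrupted
by bounded random character edits (never in the first three characters, so
distance-1 matching stays meaningful) or by dosage-suffix injection;
follow-up versions sharing the case key with later dates; duplicate
submissions cloning field values under fresh ISR and case keys with receipt
dates shifted 0–7 days; configurable reporter-occupation and outcome mixes;
uniform receipt dates. Identical configs (including the seed) produce
byte-identical files.

Every report carries at least one background reaction term plus a
Poisson(1) number of further background terms in addition to any category
term. Single-reaction reports are rare in spontaneous-reporting data, and
the richer term sets both exercise the once-per-case counting rule and keep
the duplicate heuristic's blocking key informative, so that independent
reports essentially never collide on it by chance at the corpus sizes used
in the tests.

What the generator does **not** emulate: the MedDRA hierarchy (terms are
flat strings), secular reporting trends and market-entry effects, dose
fields, correlated missingness, or the messy free-text of real name
variants beyond random edits. Passing recovery tests therefore demonstrate
that the pipeline's bookkeeping is correct — counts, joins, dedup, matching
and arithmetic — not that the heuristics would achieve the same
precision/recall on real FAERS data.

The default configuration gives the six statins distinct myalgia reporting
tiers (two high-rate, two intermediate, two low-rate drugs) over four
muscle categories with a large background pool, prescribing weights
proportional to the published NRx totals, 5% duplicate and 5% follow-up
rates, 20% name corruption at one edit, and receipt dates spanning the
July 2005 – March 2011 study window.

## Validation strategy

The test suite validates each stage against an independent oracle rather
than against itself: a hand-written dynamic-programming Levenshtein
distance checks the fuzzy matcher (which internally uses `utils::adist()`),
a brute-force group-by-and-maximize checks version dedup, hand-joined
fixtures check assembly, and generator ground truth checks the end-to-end
counts. Statistical recovery uses corpora of 10,000 reports across 5 seeds
(mean recovered ranked risks within 3 points of the configured truth);
exactness checks (zero-noise equality of pipeline tables and truth) use
1,000–2,000 reports, sizes at which chance collisions of the duplicate
heuristic's blocking key are vanishingly rare.

## Known limitations

* The ranked risk inherits every bias of spontaneous reporting:
  under-reporting, stimulated reporting, and channeling are unadjusted, and
  fluvastatin-style low-volume drugs have noisy numerators.
* The duplicate heuristic trades recall for precision; probabilistic record
  linkage is out of scope.
* The packaged broad category term lists are starting points; a real study
  should curate its own lists against the current MedDRA release.
* Disproportionality statistics (PRR, ROR, EBGM) are intentionally not
  provided; the package computes the prescription-denominator statistic it
  documents, nothing else.
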