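# dmtpv

Pharmacovigilance analysis of multiple sclerosis disease-modifying
therapies (DMTs) in pregnant and lactating women, from spontaneous
adverse-event reports.

Women with multiple sclerosis are often of childbearing age, and exposure
to DMTs during pregnancy or breastfeeding happens — planned or not — while
pre-marketing trials exclude this population almost entirely. Spontaneous
reporting databases such as EudraVigilance are therefore one of the few
real-world safety sources for it. `dmtpv` implements, as a reusable and
tested R workflow, the complete analysis of such reports for glatiramer
(the established comparator) versus three newer monoclonal antibodies:
natalizumab, alemtuzumab and ocrelizumab. It is aimed at
pharmacovigilance analysts and pharmacoepidemiologists who want every
step — case selection, event grouping, descriptive tables,
disproportionality — scripted, auditable and re-runnable offline.

## What it does

1. **Ingest** EudraVigilance-style line listings (CSV, one row per
   individual case safety report with a packed reaction cell, or an
   unpacked one-row-per-event form), with validation and exact round-trip
   writing (`read_line_listing()`, `write_line_listing()`).
2. **Select** pregnancy/breastfeeding cases by exposure preferred terms,
   a retrieval word list ("foetal", "premature", "milk", ...) and
   route-of-administration codes (transplacental/transmammary), then
   exclude paternal-exposure and adult-age-conflict reports, with a full
   per-drug audit (`select_cases()`).
3. **Group** every reaction term into exactly one of ten event groups:
   five pregnancy-and-neonatal SMQ subtopics, four subject-specific
   "other ADR" groups (maternal/foetal/neonatal/infant), and terms not
   indicating an ADR (`assign_groups()`).
4. **Describe** the case set: characteristics, group/term distribution,
   seriousness and outcomes (`tabulate_characteristics()`,
   `tabulate_seriousness_outcome()`).
5. **Compare reporting** via the reporting odds ratio. For target event
   count `a` (drug of interest), other events `b`, and comparator counts
   `c`, `d`:

   ROR = (a/c)/(b/d) = ad/bc,  95% CI = exp( ln ROR ± z₀.₉₇₅ √(1/a + 1/b + 1/c + 1/d) )

   computed for every event group and for every preferred term reported
   in ≥ 3 cases for each drug (`run_disproportionality()`). A ROR above 1
   is a reporting disproportion — a signal for evaluation, never evidence
   of causation.

Because the source database cannot be redistributed, the package ships two
synthetic substitutes (module `synthetic_data`): a deterministic
**exact-count case set** whose marginal tables equal the published ones
cell for cell (`fixture_exact_counts()`), and a seeded stochastic
generator with truth labels for testing selection and grouping
(`generate_cases()`).

## Worked example

```r
library(dmtpv)

fx  <- fixture_exact_counts()          # 1236 cases, 3590 events
sel <- select_cases(fx$cases)          # keyword/route selection + audit
asg <- assign_groups(sel$selected)     # one of ten groups per event

mean_events_per_case(sel$selected)
#> [1] 2.9

eligible_pts(asg)
#> [1] "Abortion spontaneous"       "Multiple sclerosis relapse"

res <- run_disproportionality(asg, comparator = "glatiramer")
subset(res, target == "Abortion spontaneous", c(drug, a, b, c, d, ror))
#>           drug   a    b  c   d       ror
#> 10 alemtuzumab  13  653 42 678 0.3213739
#> 21 natalizumab 235 1708 42 678 2.2210606
#> 32 ocrelizumab  31  230 42 678 2.1757764
```

Rounded to two decimals with their Woolf intervals these read: spontaneous
abortion is reported about twice as often, relative to all other events,
with natalizumab (ROR 2.22, 1.58–3.12) and ocrelizumab (2.18, 1.34–3.54)
than with glatiramer, and about three times less often with alemtuzumab
(0.32, 0.17–0.60). For multiple sclerosis relapse the same call yields
0.34 (natalizumab), 0.17 (alemtuzumab) and 0.45 (ocrelizumab, CI crossing
1).

## Analysis workflow

The numbered drivers under `analysis/` run the study end to end and write
their tables under `results/`:

```sh
Rscript analysis/01_build_case_set.R      # per-drug line listings
Rscript analysis/02_select_cases.R        # selection + audit
Rscript analysis/03_descriptive_tables.R  # characteristics, groups, outcomes
Rscript analysis/04_disproportionality.R  # ROR table + forest text
```

`run_pipeline()` performs the same four stages in one call and writes a
JSON manifest for reproducibility.

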