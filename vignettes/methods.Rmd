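---
title: "Methods: selection, event grouping and disproportionality for DMT reports in pregnancy and lactation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection, event grouping and disproportionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmtpv)
```

## The problem and the data model

Spontaneous adverse-event reports (individual case safety reports, ICSRs)
are the main real-world safety source for drug exposure in pregnancy and
lactation, a population that pre-marketing trials exclude. `dmtpv` analyses
such reports for four multiple sclerosis disease-modifying therapies:
glatiramer, the long-established comparator, against the monoclonal
antibodies natalizumab, alemtuzumab and ocrelizumab.

An ICSR is one report about one patient: a list of drug mentions
(suspect or concomitant, each possibly with a route of administration) and
a list of reaction events, each coded as a MedDRA-style preferred term (PT)
with an outcome and regulatory seriousness criteria, plus reporter, region,
age-group and baby-sex metadata. The package stores a collection
relationally (`icsr_set`: one table each for cases, drug mentions and
events) and reads/writes the public per-drug export style: a UTF-8 CSV with
one row per case and the reactions packed into one cell as
`PT (duration – outcome – criterion; criterion)`, plus an unpacked
one-row-per-event dialect that is easier to diff and test. Reading is
strict about structure (missing columns and duplicate case ids are errors)
but lenient about vocabulary: an unrecognised outcome or seriousness string
degrades to `unknown`/`none` with a warning, because real exports vary in
quality, and discarding a whole export over one label would bias every
downstream count. Case ids are unique within one drug's export only; a case
retrieved under two drugs is a legitimate observation in each per-drug
analysis and is kept once per drug.

## Case selection

Selection is two-step. **Inclusion**: a case is retrieved when any event PT
matches an exposure term exactly ("maternal exposure during pregnancy",
"exposure via breast milk", ...), or contains one of the retrieval words
(foetal, placental, premature, milk, breastfeeding, maternal, neonatal,
baby, abortion, still birth, malformation, congenital, foetal death), or
any drug mention carries a pregnancy/lactation route (transplacental,
transmammary, maternal exposure timing unspecified). Matching is
case-insensitive substring matching over whitespace-normalised text, exact
list before word list; the vocabulary ships as an editable YAML resource
because the word list is a retrieval convention, not a closed grammar.

**Exclusion**: reports of paternal drug exposure are dropped outright
(any PT containing "paternal"). The second exclusion targets reports that
the word search pulls in because a child-related word describes the *adult*
patient (e.g. "premature menopause"). No operational rule for this is
recorded in the source description, so the package's rule is a documented
approximation, deliberately narrow: a shipped list of adult-condition terms
fires only when the case carries no other pregnancy/lactation evidence —
no exposure PT, no exposure route, no other word-matching PT. Every firing
is visible in the per-case selection log for manual review.

Each selected case then receives exactly one exposure class, in the
priority order *during pregnancy* > *breastfeeding* > *before pregnancy* >
*timing unspecified* > *not specified*, evaluated over exposure PTs first
and routes only as a fallback (transplacental counting as during-pregnancy,
transmammary as breastfeeding). The priority order makes the classes
mutually exclusive, resolving the rare case that carries both pregnancy and
breastfeeding coding in favour of pregnancy, which dominates these data.
The audit reconciles, per drug: retrieved = included + inclusion miss +
excluded by each rule; selection is idempotent by construction.

## Event grouping

Every event of every selected case is assigned to exactly one of ten
groups: five pregnancy-and-neonatal SMQ subtopics (termination of pregnancy
and risk of abortion; pregnancy, labour and delivery complications;
neonatal disorders; congenital, familial and genetic disorders; foetal
disorders), four subject-specific "other ADR" groups (maternal, foetal,
neonatal, infant), and "terms not indicating an ADR" — exposure coding of
the special condition and conditions merely predisposing to an ADR.

Licensed MedDRA SMQ membership cannot be redistributed, so the group
definitions ship as an editable YAML term list seeded with every PT printed
in the published group tables, each under its published group, plus a few
canonical members. The resource carries a version tag and records that the
narrow-versus-broad SMQ scope of the original query is unstated. Within the
resource a PT may belong to at most one subtopic (validated on load).

Precedence is: non-ADR list first, then the five subtopic lists, then the
subject-specific fallback — chosen because the non-ADR terms are tabulated
separately from all ADR groups, and because subtopic membership is a
property of the term, not of who experienced it. The subject (mother,
foetus, neonate, infant) is inferred from explicit PT wording first
("anaemia neonatal" is neonatal wherever it appears) and from the case's
child age group otherwise; a case with no child involved defaults to the
mother. Wording wins over the case field because a child-age case can and
does carry maternal events. An unresolvable subject falls back to the
maternal group with a warning rather than an error, keeping the partition
total.

## Descriptive outputs

Percentages are recomputed from counts, rounded half-up to one decimal.
Case-level blocks (characteristics, exposure classes, case seriousness) use
the per-drug case totals as denominator; event-level blocks (seriousness
criteria, outcomes) the per-drug event totals — the convention that
reproduces the published percentages. The baby-sex block is tabulated over
the cases involving a child while keeping the case-total denominator, as in
the published table. A case is serious exactly when one of its events
carries a serious criterion. Within each group, the most-reported terms are
ranked by their total count over all drugs, ties broken alphabetically (the
source is silent on ties; alphabetical is deterministic and
order-independent).

## Disproportionality

For a target event set (a group or a single PT), drug of interest *D* and
comparator *C* (glatiramer):

* `a` = target events reported with *D*, `b` = all its other events,
* `c` = target events with *C*, `d` = all its other events,

ROR = (a/c)/(b/d) = ad/bc, with the log-normal (Woolf) interval
`exp(ln ROR ± z₁₋α/₂ · √(1/a + 1/b + 1/c + 1/d))`, α = 0.05,
z = 1.959964. The interval method is not named in the source; Woolf was
identified by recomputing the printed bounds from the printed counts, which
it reproduces to two decimals. Two further conventions matter and were
fixed the same way:

* **Denominators include the non-ADR events**: `b = 720 − a` for
  glatiramer's 720 total events, and so on. Only this convention
  reproduces the printed estimates.
* **Zero cells are not corrected**: no Haldane–Anscombe ½; the result is
  flagged "not estimable" instead. The ≥3-case eligibility rule avoids
  zeros at term level, and a zero group-level cell is information ("no
  such event reported"), not a quantity to shift.

Term-level analysis is restricted to PTs reported in at least three
*cases* for each of the four drugs (distinct reporting cases, matching the
stated rule; the 2×2 cells themselves are event counts). Exposure-coding
terms are not candidates. Significance means the 95% CI excludes 1 —
equivalent to p < 0.05 under the same normal approximation — with no
multiplicity adjustment, matching the original analysis. Rounding to two
decimals happens at reporting time only.

On the exact-count case set the estimates that recompute consistently from
the published count table are, to two decimals: spontaneous abortion
2.22 (1.58–3.12) natalizumab, 2.18 (1.34–3.54) ocrelizumab,
0.32 (0.17–0.60) alemtuzumab; MS relapse 0.17/0.34/0.45; termination group
0.37 (alemtuzumab) and 2.06 (ocrelizumab); pregnancy/labour/delivery
0.13 (alemtuzumab); neonatal disorders 2.80 (1.70–4.61) and congenital
disorders 1.70 (1.07–2.69) for natalizumab. A handful of published
group-level figures (natalizumab termination 0.16; the maternal-other,
neonatal-other and infant-other RORs; one CI bound of 3.85; a
pregnancy/labour point of 2.10 where the counts give 2.11) are *not*
consistent with the published count table under any convention tried —
they may derive from case-level counts or typography. The package treats
the count table as authoritative, reports what it implies, and the test
suite asserts exactly those recomputable values.

## Synthetic case sets

No report-level data can be shipped, so the package generates its own.

**The exact-count set** (`fixture_exact_counts()`) is deterministic and
platform-independent: 1236 cases and 3590 events whose per-drug totals,
characteristics blocks, group and printed-term counts, and
seriousness/outcome distributions equal the published tables cell for
cell. Only marginals are published, so the joint layout is a convention:
attributes are assigned over case indices in fixed ranges, arranged so
that every structural constraint holds — each case matches an inclusion
rule, child-subject events sit in cases with that child age group, serious
cases are exactly the cases holding a serious event, fatal events carry
the results-in-death criterion. The unprinted remainder of each event
group is filled with placeholder terms labelled "(synthetic ...)",
numbered per drug so no placeholder accumulates counts across drugs; group
totals — the quantities the analysis consumes — are exact, term-level
detail beyond the printed terms is a stand-in.

**The stochastic generator** (`generate_cases()`) draws case sets under a
configuration whose defaults are the published study conditions: per-drug
case counts 839/201/100/96, events per case 1 + Poisson(mean − 1) with the
per-drug published means (2.9 overall), term frequencies proportional to
the published group table, and all categorical mixtures from the published
tables. One root seed spawns a per-drug substream derived from the drug
name, so adding or removing a drug leaves the other drugs' draws
untouched. Planted-rejection fractions (paternal exposure, adult-age
conflict, no matching keyword) default to 0 — the generator emulates the
*selected* set — and are switched on in tests, where selection must
reproduce the plant with zero error. Truth labels accompany every case and
event.

What the synthetic sets do *not* emulate: duplicate reports across
national gateways, reporting-date dynamics, narrative text, term-level
co-occurrence structure, and the full appendix-level term detail. Tests
passing on them show that the pipeline's logic is faithful to the stated
rules and published margins — not that the rules themselves would retrieve
the identical case set from the live database.

## Numerical and operational choices

* Half-up rounding for all reported percentages (1 dp) and RORs/CIs
  (2 dp); internal comparisons always use unrounded values.
* Matching normalises whitespace and case; packed-cell grammar uses the
  en-dash field separator of the emulated export, and the event boundary
  `"), "` so terms may contain commas.
* Problem sizes: the test suite runs the full pipeline on the 1236-case
  exact-count set, property checks on 1000 random 2×2 tables against exact
  integer arithmetic, a 2000-replicate null-coverage simulation
  (two arms of 500 events, event probability 0.1), and generator-marginal
  checks at 10,000 cases — all chosen to be decisive yet quick on one CPU.
* Degenerate inputs: empty collections tabulate to zero tables; an empty
  case set has an undefined mean events per case (error); a missing
  comparator is a configuration error; zero-cell 2×2 tables are flagged,
  never corrected.

## Limitations

Everything a spontaneous-reporting analysis inherits: no denominator of
treated patients, reporting bias, variable report quality, no causality
assessment — a ROR is a reporting signal, not a risk estimate. Specific to
this package: the SMQ term resource is an approximation of licensed
membership (editable, versioned); the adult-age-conflict exclusion is a
documented guess at an unstated rule; and term-level results beyond the
printed top terms rest on synthetic placeholders.
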