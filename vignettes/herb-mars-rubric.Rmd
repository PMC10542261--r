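---
title: "Selecting herbal quality-control markers with a modified Herb MaRS rubric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting herbal quality-control markers with a modified Herb MaRS rubric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbmars)
```

## The problem

Herbal raw materials vary widely in chemical composition with climate,
cultivation, harvest and genotype.  Phytochemical standardization —
establishing consistent levels of one or a few *chemical markers* — is how
manufacturers and regulators keep batches of a material (and the products
made from it) comparable.  A good marker is bioactive in a way that matches
the product's therapeutic claim, present at a measurable concentration, and
practical: a pure analytical reference standard can be bought and a
published assay method exists.

The Herbal Chemical Marker Ranking System (Herb MaRS) ranks candidate
compounds for this purpose.  The original system awards a single holistic
0–5 mark; the modified rubric implemented here decomposes the judgement
into six additive components so that every point is auditable:

| component | meaning | points |
|-----------|---------|--------|
| A | documented constituent of the material | 0/1 |
| B | distinct indication symptoms addressed by documented bioactivities | 0–3 |
| C | reported concentration ≥ 5 ppm | 0/1 |
| D | reported concentration ≥ 50 ppm | 0/1 |
| E | analytical reference standard commercially available | 0/1 |
| F | assay method published | 0/1 |

The total, `A + B + C + D + E + F`, lies in 0–8; 8 marks the most suitable
marker.  A compound is *suitable* when it reaches at least 5 points **and**
has both a standard (E = 1) and a method (F = 1): the threshold alone is
not enough, because a well-evidenced compound that cannot be bought or
assayed cannot serve in routine quality control.  Each marker is also
assigned an analytical role from its concentration: *quantitative* at
≥ 50 ppm, *qualitative* (identity monitoring only) below, *unassigned*
when no concentration was ever reported.

Two side rules complete the decision layer.  Compounds flagged as
toxicants carry `must_screen = TRUE` regardless of score — toxicants are
screened mandatorily, whatever their merit as markers.  And compounds with
attached regulatory maxima (*negative markers*, e.g. anthraquinone
glycosides in oral aloe products, capped at 10 ppm by the International
Aloe Science Council and at 0 ppm by the EMA and FDA) receive a
per-authority compliance verdict; a 0 ppm limit makes any positive
concentration non-compliant.

## Component semantics and the choices behind them

**Component A** is stored as an explicit `documented_constituent` flag
rather than derived from the activities list.  The source ranking table
awards A = 1 to compounds with no individually documented bioactivity at
all (e.g. bemadienolide), so A cannot mean "has documented activity";
encoding it as data reproduces the published table without inventing
evidence.

**Component B** counts *distinct* symptoms, capped at 3, over activities
flagged `relevant_to_indication`.  Symptom strings are matched
case-insensitively after trimming and whitespace collapsing — no stemming,
no synonym expansion — so the count is deterministic and auditable.  The
"well-elucidated mechanism" language attached to the 3-point level is
recorded as free text on each activity but not enforced computationally:
no operational definition of "well-elucidated" exists, and any attempt to
score prose would be arbitrary.

**Components C and D** come from a single scalar concentration in ppm
(mass fraction).  Published concentration reports are free text in three
dialects — percent w/w, mg/g, ppm — parsed by `parse_concentration()` and
converted with fixed factors (1% = 10,000 ppm; 1 mg/g = 1,000 ppm).  A
reported *range* collapses to the arithmetic midpoint of its converted
bounds.  Midpoint is the only parameter-free reduction and reproduces
every arithmetically consistent row of the case-study table; the
provenance (`point` vs `range_midpoint`) is kept on the value.  Both
thresholds are inclusive (`>= 5`, `>= 50`), which also fixes the role
boundary: exactly 50 ppm is quantitative, consistent with D's wording.
The matrix a concentration refers to (essential oil, leaf, gel, latex) is
carried as metadata but never rescales the value: a percentage *of
essential oil* is scored as printed, exactly as the source table does.  No
density corrections are applied — %, mg/g and ppm are all treated as w/w.

**Components E and F** are pure availability flags: non-empty standards /
methods lists.

## Cost normalization

For quantitative work the practical cost of a marker is the price of the
smallest amount sufficient for one calibration — taken as 1 mg (or 1 mL
for liquids).  `unit_cost()` divides the pack price by the numeric pack
size in the listing's own denomination (€/mg, €/mL or €/g; no cross-unit
conversion), and rounds half-up to one decimal, the convention of the
published cost column.  `cost_summary()` pools one value per listing (not
per compound) across denominations — deliberately, because that is how the
published column and its summary statistics are constructed — and reports
min/max/mean/sample-sd with the owning compounds of the extremes.  Because
pooling €/mg with €/g is not physically meaningful, a per-denomination
breakdown is attached as a corrective, and an unrounded variant
(`use_rounded = FALSE`) is exposed alongside the printed-column one.  The
sample (n − 1) standard deviation is used; over the packaged dataset it
reproduces the published dispersion to one decimal.

## Auditing scored tables

Published scored tables can disagree with themselves.  `audit_dataset()`
recomputes every component from the recorded evidence and reports three
kinds of inconsistency without repairing any of them: `sum_mismatch`
(printed components do not add to the printed total), `derivation_mismatch`
(a printed A–D differs from what the evidence derives, e.g. a ≥ 50 ppm
point granted to a 15 ppm midpoint) and `availability_mismatch` (printed
E/F contradicts the attached standards/methods lists).  On the packaged
dataset the auditor finds one sum mismatch (polygodial: components sum to
4 against a printed 3), four derivation mismatches (mahmoodin's C and D
granted on an undetermined concentration; the two 0.01–0.02 mg/g ginger
rows granted D at a 15 ppm midpoint) and one availability mismatch
(zingerone's F with no published method).  Printed values stay
authoritative in the dataset; recomputed values live alongside in the
findings.

Ranking (`rank_compounds()`) orders by total descending with ties broken
by compound name ascending after Unicode NFC normalization and case
folding, compared byte-wise in the C locale — the source table specifies
no ordering among equal scores, and this rule is deterministic across
platforms (it places "1,8-cineol" before "α-terpineol" among the 8-point
eucalyptus markers).

## The packaged dataset

`hm_fixture_dataset()` loads the fully encoded case study: seven medicinal
plants widely used in Ugandan herbal manufacturing and 35 candidate-marker
dossiers, with the printed component scores kept verbatim for auditing.
Since the study's entire dataset is its printed tables, the package
reproduces the study end-to-end at desk scale: per-compound totals,
per-plant marker lists (none for *Warburgia ugandensis*, whose compounds
lack standards and methods; epicatechin excluded for *Mangifera indica*
for want of a standard), the €0.6–€498 unit-cost range and its mean, and
the table's own inconsistencies.

Two encoding notes.  Reports that give two concentrations for different
matrices (aloin in leaf and latex; azadirachtin in seeds and leaves) are
encoded with their first clause — the alternative clause would not change
any score, as both exceed 50 ppm.  Dual-compound listings ("aloin A and
B") are encoded as separate records per plant context, matching their
separate standard listings; likewise catechin appears once per plant, with
distinct identifiers, because scores are per plant context.

## The synthetic generator

`generate_dataset()` produces datasets with known ground truth so every
pipeline stage is testable without any external data.  Its defaults mirror
the structure of the case study: every candidate a documented constituent,
symptom-coverage levels weighted toward well-studied compounds
(0.1/0.2/0.3/0.4 over levels 0–3, close to the empirical 3/8/9/15 split),
70% of concentrations determined (25 of 35 in the case study),
concentrations log-uniform over 10–10^6 ppm (the case-study midpoints span
15 to 973,200 ppm), and 80% availability of standards and methods.
Toxicants are absent from the case study, so `p_toxic` defaults to 0.

The generator writes evidence, not scores: symptom lists are sized to the
drawn level, and the drawn ppm is re-expressed in a random unit as a point
value or a symmetric range whose midpoint equals the drawn value, so the
scorer must recover the truth exactly (the rubric is integer-valued; the
recovery tolerance is zero).  With `corrupt_k > 0` the true scores are
planted as recorded scores everywhere and then corrupted on `corrupt_k`
records, one field each — a total (sum mismatch), a component A–D with the
total kept consistent (derivation mismatch), or E (availability mismatch) —
and the returned ledger is exactly what the auditor must find.  All
generation is driven by one seed and restores the session RNG state.

What the generator does *not* emulate: real literature text, correlated
evidence (compounds of one plant sharing activities), vendor price
structure, or multi-plant datasets.  Passing synthetic tests therefore
demonstrates correctness of the arithmetic and the audit round-trip, not
robustness to the editorial messiness of real tables — that is what the
packaged case study covers.

## Numerical and degenerate-input choices

* Rounding of unit costs is half-up (`floor(10x + 0.5) / 10`), not R's
  default round-half-even; the published column rounds 12.65 to 12.7.
* A cost summary over a single listing reports sd = 0 with a
  `single_listing` flag rather than `NA`, keeping the summary printable.
* `validate_record()` returns violations as data and never throws;
  `read_dataset()` aggregates *all* schema violations into one error
  rather than failing at the first.
* Undetermined concentrations use an explicit sentinel
  (`provenance = "undetermined"`), force C = D = 0, and make the
  analytical role `unassigned`; regulatory verdicts on them are
  `not_evaluable`.
* Regulatory maxima are inclusive: a 10 ppm measurement satisfies a
  10 ppm limit.
* `score_components()` takes the owning plant optionally; when supplied,
  symptom counting is additionally restricted to the plant's indication
  symptoms (a no-op on validated records, where coverage is an
  invariant).

## Problem sizes

The test suite exercises the exhaustive 96-vector component space, the
35-record case study, and seeded synthetic datasets of 50–500 records for
property checks; the parameter-recovery and total-distribution checks run
at 10,000 records.  All of it completes in well under a minute on a single
core.

## Known limitations

* Symptom matching is string equality after normalization; "sore throat"
  and "pharyngitis" are different symptoms.  Ontology mapping is out of
  scope by design.
* The rubric inherits the source table's granularity: bioavailability and
  stability-indication, present in the original holistic Herb MaRS, have
  no component here.
* Costs are list prices per pack; vendor markups, shipping and
  calibration formats needing more than 1 mg are not modelled.
* A dossier holds one concentration report; multi-matrix reports must be
  reduced to one clause by the encoder.
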