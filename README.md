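# herbmars

Marker selection for the quality control of herbal raw materials, using a
modified Herbal Chemical Marker Ranking System (Herb MaRS).

## Who this is for

Manufacturers, regulators and pharmacognosy researchers who must decide
*which compound to measure* when standardizing an herbal material that has
no pharmacopoeial monograph.  The package encodes the whole decision as
data and auditable arithmetic: structured evidence dossiers in, scored and
ranked marker shortlists out, with every point traceable to a recorded
fact.

## The rubric

Each candidate compound is scored on six additive components,

```
total = A + B + C + D + E + F          (0 ≤ total ≤ 8)
```

| component | meaning | points |
|---|---|---|
| A | documented constituent of the material | 0/1 |
| B | distinct indication symptoms its documented bioactivities address | 0–3 |
| C | reported concentration ≥ 5 ppm | 0/1 |
| D | reported concentration ≥ 50 ppm | 0/1 |
| E | analytical reference standard commercially available | 0/1 |
| F | assay method published | 0/1 |

Concentrations reported as percent w/w, mg/g or ppm are normalized to ppm
(1% = 10,000 ppm; 1 mg/g = 1,000 ppm); ranges collapse to their midpoint.
A compound is **suitable** as a marker iff `total ≥ 5` *and* E = F = 1,
and is assigned a **quantitative** role at ≥ 50 ppm, **qualitative**
below, **unassigned** when no concentration was ever determined.
Reference-standard pack prices normalize to € per mg/mL/g
(`price ÷ pack size`, half-up to 1 dp).  Toxicants are flagged for
mandatory screening regardless of score, and *negative markers* (e.g.
aloin in oral aloe products) are checked against regulatory maxima
(ISC 10 ppm; EMA/FDA 0 ppm).

The package ships the complete case study that motivated the rubric:
seven medicinal plants widely used in Ugandan herbal manufacturing and 35
candidate-marker dossiers, including the scores as printed in the source
ranking table so they can be audited against the rubric.

## Worked example

```r
library(herbmars)

fx <- hm_fixture_dataset()
fx
#> <hm_dataset> schema 1.0: 7 plants, 35 compounds, 3 limits

tabs <- assess_dataset(fx)        # score + rank every compound, per plant
tabs[["Eucalyptus globulus"]]
#> <hm_ranked_table> Eucalyptus globulus (4 compounds)
#>   8/8  1,8-cineol               quantitative  [marker]
#>   8/8  α-terpineol              quantitative  [marker]
#>   7/8  aromadendrine            quantitative  [marker]
#>   6/8  globulol                 quantitative  [marker]
```

All four eucalyptus compounds reach the suitability bar (≥ 5 points with
standard and method), so all four are markers; the two 8-point compounds
are tie-broken alphabetically.  For *Mangifera indica*, epicatechin
(5 points but no purchasable standard) drops out:

```r
vapply(select_markers(tabs[["Mangifera indica"]]), `[[`, "", "name")
#> [1] "catechin"    "gallic acid" "mangiferin"  "quercetin"

cost_summary(fx)
#> <hm_cost_summary> n=37  min=0.6 (EG02)  max=498.0 (AI01)  mean=62.5  sd=101.5
```

Unit costs across the 37 priced standard listings range from €0.6/mg
(α-terpineol) to €498/mg (azadirachtin), mean €62.5 ± 101.5.  The auditor
recomputes every printed score from the recorded evidence and reports the
source table's own inconsistencies without repairing them:

```r
audit_dataset(fx)$detail
#> mahmoodin: recorded C=1, recomputed 0 (component derived from the evidence differs)
#> mahmoodin: recorded D=1, recomputed 0 (component derived from the evidence differs)
#> 12-gingerol: recorded D=1, recomputed 0 (component derived from the evidence differs)
#> 6-shogaol: recorded D=1, recomputed 0 (component derived from the evidence differs)
#> zingerone: recorded F=1, recomputed 0 (0 assay method(s) attached)
#> polygodial: recorded TOTAL=3, recomputed 4 (recorded components do not sum to the recorded total)
```

Negative-marker compliance rides along on each assessment:

```r
assess_compound(fx$compounds[[5]])
#> <hm_assessment> aloin A (AV01)
#>   A=1 B=3 C=1 D=1 E=1 F=1  total 8/8
#>   suitable: TRUE | role: quantitative | must_screen: FALSE
#>   limits: International Aloe Science Council 10 ppm -> non_compliant; ...
```

Aloin is simultaneously a first-rate positive marker for laxative aloe
products and a non-compliant negative marker for over-the-counter
nutraceuticals — both facts are reported, neither overrides the other.

Synthetic datasets with known ground truth (and optionally planted
corruption, for exercising the auditor) come from the seeded generator:

```r
sim <- generate_dataset(simulation_config(n_compounds = 100, seed = 42,
                                          corrupt_k = 5))
nrow(audit_dataset(sim$dataset))   # recovers exactly the 5 planted faults
#> [1] 5
```

A thin command-line front end over the same functions lives at
`inst/cli/herbmars.R` (subcommands `score`, `rank`, `audit`, `costs`,
`simulate`, `fixture`).

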