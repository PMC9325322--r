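# pimddi

Screening oral anticoagulant use in elderly patients for potentially
inappropriate medications (PIM), bleeding-risk drug–drug interactions
(DDI) and their overlap (PIM–DDI), phenotyping hospitalizations for
bleeding adverse drug events (ADE), and modelling bleeding risk — across
linked primary-care dispensing and hospital data.

## The problem

Oral anticoagulants — warfarin (B01AA03) and the direct oral
anticoagulants apixaban (B01AF02), rivaroxaban (B01AF01) and dabigatran
(B01AE07) — are potentially inappropriate medications in the elderly
under the Beers criteria:

* **Apixaban** — patient ≥ 65 years with renal impairment
* **Dabigatran / Rivaroxaban** — patient ≥ 75 years, or ≥ 65 years with
  renal impairment
* **Warfarin** — patient ≥ 65 years combined with amiodarone,
  cotrimoxazole, ciprofloxacin, a macrolide other than azithromycin, or
  an NSAID

A DDI whose anticoagulant member is itself a PIM (a *PIM–DDI*) may
compound the inappropriate character of the prescription: a
pharmacokinetic inhibition (CYP2C9/2C19, CYP3A4, P-glycoprotein, or
combined CYP3A4 + P-gp) raises anticoagulant exposure, a
pharmacodynamic partner (antiplatelets, NSAIDs, heparins, …) raises the
bleeding effect. `pimddi` operationalizes this screening for
epidemiological cohorts:

1. **Drug eras** from dispensing claims (`[dispense, dispense + supply]`)
   and in-hospital administrations (maximal runs of administration
   dates), merged per patient, drug and setting.
2. **Exposure windows**: the 30 days before the index admission
   (primary care) and the index stay itself (hospital).
3. **Knowledge-base screening** with ATC pattern matching (prefix
   wildcards, exclusion lists such as `J01FA*!J01FA10`) and dual-source
   severity harmonization (Theriaque levels 1–2 and Micromedex
   contraindicated/major → *major*; Theriaque 3 / Micromedex moderate →
   *moderate*; Theriaque 4 → *minor*; conflicts resolve to the more
   severe class).
4. **Bleeding-ADE phenotype** on the index stay: any of (i) an ICD-10
   bleeding diagnosis, (ii) INR > 5 (strict), (iii) hemoglobin ≤ 11 g/dL
   (men) / ≤ 10 g/dL (women), (iv) administration of an antidote
   (B02BA02, V03AB37, V03AB38, B02BD01).
5. **Treatment pathway** per patient: continued, discontinued (for
   bleeding > surgery > other), initiated in hospital.
6. **Risk models**: multivariable logistic regression (odds ratios with
   Wald 95% CIs) and SMOTE-rebalanced random forest / gradient boosting /
   RBF-SVM classifiers with 10-fold cross-validated tuning, ROC
   threshold selection at the point closest to (sensitivity,
   specificity) = (1, 1), and gain-based variable importance.

Because linked claims/hospital data cannot be shipped, the package
includes a synthetic-cohort generator (`generate_cohort()`) that plants
prevalences, a logistic outcome model and pathway mix, and emits raw
tables from which the detection pipeline recovers every planted flag
exactly — the basis of the test suite.

## Worked example

A 12-patient micro-cohort exercising every rule branch ships with the
package:

```r
library(pimddi)
we  <- make_worked_example()
scr <- screen_cohort(we$tables)
scr
#> <pimddi screening result>
#>   patients (any exposure): 12  excluded (no exposure): 0
#>   modelling cohort (pre-admission exposure): 11
#>   PIM findings: 9   DDI events: 9  (PIM-DDI: 6 )
#>   bleeding ADE: 5 of 11
aggregate_flows(scr$pathway)
#> # A tibble: 6 × 4
#>   category                  n denominator   pct
#> 1 continued                 5          11  45.5
#> 2 discontinued              6          11  54.5
#> 3 discontinued_bleeding     4           6  66.7
#> 4 discontinued_surgery      1           6  16.7
#> 5 discontinued_other        1           6  16.7
#> 6 initiated_in_hospital     1          12   8.3
```

Of the 12 patients, 11 were dispensed an anticoagulant in the 30 days
before admission (the modelling denominator; patient P07 starts
apixaban in hospital). Nine PIM findings cover both settings — e.g.
P01 (dabigatran, 80 y) triggers the age rule, P02 (apixaban, 70 y,
coded N18.9) the age-with-renal rule, and P03 (warfarin 68 y +
amiodarone) a Beers combination whose concurrent paracetamol makes a
warfarin–amiodarone–paracetamol triple. Five bleeding ADEs fire once
per criterion branch (diagnosis, INR 6.1, Hb 9.8 F / 11.0 M boundary,
antidote). `summarise_screen_patients(scr)` reproduces the shipped
`expected_findings.csv` exactly.

On synthetic cohorts, `tidy(fit_bleeding_logistic(scr$cohort))` returns
the odds-ratio table and `tune_and_train()` /
`select_threshold()` / `evaluate_model()` run the rebalanced
classification workflow; `autoplot()` methods and `plot_roc()` /
`plot_importance()` draw the standard displays.

## Knowledge base

The shipped `inst/extdata/kb.json` is a curated mini-KB (39 interaction
rules, 4 Beers rules, bleeding/antidote/renal code sets). Its schema is
documented in `?load_kb`; rules carry a per-rule `source` field so a
licensed full database (Theriaque, Micromedex, …) can be swapped in;
`kb_validate()` reports rule-level problems in a replacement file.
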