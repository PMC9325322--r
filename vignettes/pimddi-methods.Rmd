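---
title: "Methods: screening anticoagulant prescriptions and modelling bleeding risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening anticoagulant prescriptions and modelling bleeding risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pimddi)
```

This vignette documents the models, rules and numerical choices behind
`pimddi`, in the spirit of a statistical methods section: what each
component assumes, which tunable parameters matter, what the synthetic
data generator does and does not emulate, and where the design was
genuinely open.

## Cohort semantics and drug eras

The unit of analysis is a patient with an *index hospital admission*
and up to one year of look-back. Five tables feed the pipeline:
demographics, primary-care dispensing claims, in-hospital drug
administrations, hospital stays with ICD-10 codes, and INR/hemoglobin
results. Patients must be at least 65 at the index admission and
infra-day stays are excluded; both are enforced at load.

Dispensing claims carry no explicit treatment duration, so exposure is
materialized as *drug eras*: a dispensing covers
`[dispense_date, dispense_date + supply_days]`. The default
`supply_days = 30` reflects the monthly dispensing convention of French
community pharmacy; it is configurable per record because sources
differ. Hospital eras are maximal runs of administration dates.
Intervals are closed on both ends; intervals of the same
(patient, drug, setting) merge when the gap between them is at most
`gap_tolerance_days` (default 0: overlapping or touching intervals
merge). Era construction is idempotent and preserves covered days — the
test suite checks the day sets against a brute-force per-record oracle.

Two setting windows anchor all detection, both closed:

* primary care: `[admission - 30 d, admission - 1 d]`;
* hospital: `[admission, discharge]` of the index stay.

Co-exposure requires at least one day of era overlap after clipping both
eras to the window. The source material specifies the windows but not an
overlap rule; one day is the weakest assumption that still means
"simultaneously in the body for a calendar day", and the DDI detector is
tested against a day-by-day co-exposure scan.

## Knowledge base and severity harmonization

Screening is rule-driven: each interaction rule is an unordered pair of
ATC patterns (full codes or prefix wildcards with optional exclusions,
e.g. macrolides except azithromycin, `J01FA*!J01FA10`), a mechanism
class (`PD`, `PK_CYP2C9_2C19`, `PK_CYP3A4`, `PK_PGP`,
`PK_CYP3A4_PGP`), and severities from up to two vendor scales. The
harmonized scale maps Theriaque 1–2 and Micromedex
contraindicated/major to *major*, Theriaque 3 and Micromedex moderate
to *moderate*, and Theriaque 4 to *minor*. When the two sources
disagree the more severe harmonized class wins — a deliberately
pharmacovigilance-conservative rule, chosen because merged drug
databases rarely document a conflict policy and under-calling severity
is the costlier error in screening. Harmonization is total over all 19
valid input combinations and monotone; the tests enumerate the whole
table.

The shipped mini-KB covers the Beers anticoagulant conditions and the
bleeding-risk pairs most relevant to anticoagulated elderly patients
(dual CYP3A4/P-gp inhibitors with apixaban and rivaroxaban, P-gp
inhibitors with dabigatran, CYP2C9/2C19-inhibiting SSRIs with warfarin
and rivaroxaban, and pharmacodynamic partners: salicylates, NSAIDs,
tramadol, paracetamol, atorvastatin, levothyroxine, heparins).
Severity levels without a published value ship as Theriaque level 3
and are tagged `curated-default` so they are auditable and
replaceable. The temporary DOAC–heparin co-prescription around an
in-hospital switch is modelled as a pharmacodynamic pair and can be
excluded (`include_heparin_switch = FALSE`) for analyses that do not
consider a switch overlap a true interaction.

## PIM, PIM–DDI and renal impairment

DOAC rules are age/renal conditions evaluated at the index admission;
warfarin is inappropriate only *in combination*, when a Beers partner
era overlaps the warfarin era inside the setting window. When several
rules apply, the age-alone rule is reported (most specific first:
`age_ge_75`, then `age_ge_65_renal`, then `warfarin_combo`).

A DDI event is a PIM–DDI when its anticoagulant member has a PIM
finding in the same setting, or when the pair itself is a warfarin
Beers combination — in that case the pair is simultaneously the
interaction and the reason the anticoagulant is inappropriate, and any
*further* drug overlapping the combination inherits the PIM–DDI flag
(this is how warfarin–amiodarone–paracetamol triples arise; pairwise
events share a `combo_id` so triples can be reported).

Renal impairment is not observable directly in claims. The default
determination is the presence of any code from the configurable
`renal_impairment_icd10` set (default `N18*`, `N19`) in the 1-year
look-back including the index stay; a `renal_override` column is
honoured for cohorts with laboratory-based (eGFR) flags.

## The bleeding-ADE phenotype

A hospitalization is a bleeding ADE when any of four criteria fires on
the index stay: a bleeding ICD-10 diagnosis (prefix matching against a
user-replaceable code set), INR strictly above 5, hemoglobin at or
below 11 g/dL for men / 10 g/dL for women (inclusive), or
administration of an anticoagulant antidote. The boundary semantics
follow the clinical definitions: an INR of exactly 5.0 does not fire, a
hemoglobin exactly at the threshold does. The hemoglobin criterion's
default is *threshold-only* because the operative cut-offs are the
sex-specific "minimum usual values"; a *delta* mode additionally
requires a drop of at least 2 g/dL from the pre-stay maximum, for
cohorts with baseline measurements. All fired criteria are recorded,
the composite is exactly the disjunction (property-tested), and adding
qualifying evidence can never unset the phenotype.

The phenotype's intended denominator is patients with primary-care
anticoagulant exposure in the 30 days before the stay; bleeding codes
in *prior* stays feed the previous-bleeding-event covariate instead.

## Treatment pathway

Each patient receives exactly one label: `continued` (exposed in both
settings — molecule switches count as continued, anticoagulation-level
semantics, with molecule detail available from the exposure table),
`discontinued_bleeding` / `discontinued_surgery` /
`discontinued_other` (pre-admission exposure only), or
`initiated_in_hospital`. The discontinuation reason uses the precedence
bleeding > surgery > other: the sources report both reasons without
stating an order, and attributing a discontinuation to the bleed when
both are present is the clinically conservative reading. The residual
bucket deliberately pools causes that claims cannot distinguish (short
stays without a hospital prescription, unreconciled discontinuations,
switches to parenteral therapy, untracked administrations).

## Regression and the classification workflow

The logistic model regresses the bleeding outcome on the standard
covariate set — age (years, untransformed, so odds ratios are per
year), sex, history of stroke, previous bleeding event, diabetes,
renal, liver disease, cancer, hypertension, and the PIM, DDI and
PIM–DDI indicators — by maximum likelihood, reporting exponentiated
coefficients with Wald 95% intervals and raw p-values (no multiplicity
correction, matching how such tables are conventionally reported).
Perfect separation and rank-deficient designs raise diagnostic errors
naming the offending covariate rather than returning unstable
estimates.

The machine-learning workflow is: outcome-stratified 80/20 split;
SMOTE rebalancing (`k = 5`, the algorithm's canonical neighbourhood);
grid search by stratified 10-fold cross-validation maximizing mean ROC
AUC (random forest: 200/500 trees × depth 3/6/unlimited; gradient
boosting: 200/500 trees × depth 3/6 × learning rate 0.05/0.1; RBF-SVM:
cost 0.1/1/10 — small conventional grids, since none were prescribed);
refit on the full rebalanced training sample; threshold chosen among
observed score cut-points minimizing the Euclidean distance of
(sensitivity, specificity) to (1, 1), ties toward higher sensitivity;
evaluation on the untouched test sample (accuracy, sensitivity,
specificity at the threshold; AUC by trapezoidal integration over
unique cut-points). By default SMOTE runs *inside* each
cross-validation fold, on the analysis part only — rebalancing before
the fold split leaks held-out information into the synthetic rows — but
`rebalance = "before_cv"` exists for compatibility with workflows that
rebalanced once up front, since published descriptions are often
ambiguous on the order. Thresholds carry a provenance tag and
`evaluate_model()` refuses one selected on test data; a dedicated test
asserts the refusal. Variable importance is gain-based (split gain for
boosting, impurity gain for forests), normalized to sum to one; SVMs
have no gain decomposition and are refused.

## The synthetic cohort generator

`generate_cohort()` exists so that every pipeline component can be
validated end-to-end with known truth. It works *flags first, records
second*: per patient it draws the anticoagulant molecule (warfarin
46.6%, rivaroxaban 23.9%, apixaban 18.3%, dabigatran 11.6%), the PIM /
DDI / PIM–DDI flags at the planted prevalences (defaults 22.9%, 47.2%,
19.5%), comorbidities, the pathway (48.6% continuation), and a
bleeding outcome from a planted logistic model (odds ratios 1.03/year
for age, 4.23 previous bleed, 1.98 renal, 2.68 cancer, 1.72
hypertension and liver, 1.29 diabetes, 1.23 PIM–DDI, 1.19 male, 1.17
stroke, 1.15 DDI, 1.08 PIM) whose intercept is calibrated by root
finding so the cohort-expected event rate equals the 17.1% target to
within numerical tolerance. It then writes records that realize exactly
those flags: rule-consistent ages and renal codes, Beers or
non-interacting partner dispensings, bleeding diagnoses / INR /
hemoglobin / antidote records for the assigned ADE criterion, normal
values otherwise, and hospital administrations for continued therapy
and initiators (0.4437 initiators per primary-care patient).

Three draws deserve comment:

* A warfarin Beers-combo PIM *is* a DDI, so warfarin PIM patients are
  PIM–DDI with probability one and the DOAC PIM–DDI probability is
  compensated to keep the marginal on target; the configuration
  validator rejects target mixes that make this impossible.
* Because every anticoagulant interaction of a PIM patient is a
  PIM–DDI, a patient planted as "PIM without PIM–DDI" must carry no
  interacting partner; the non-PIM stratum carries the remaining DDI
  mass.
* Ages are shaped to agree with the drawn PIM flag (a non-PIM
  rivaroxaban patient must be 65–74 without renal codes), so the
  marginal age distribution (truncated normal, mean 79, SD 8 on
  [65, 100]) is approximate while Beers-rule consistency is exact. This
  is the price of planting prevalence targets that a cohort of mostly
  ≥ 75-year-olds could not otherwise produce.

DDI patients receive one guaranteed partner plus a Poisson number of
extras (mean 2), giving roughly three distinct interaction pairs per
DDI patient and a cohort mean near 1.5 pairs per patient, alongside
non-interacting co-medications for a realistic polymedication count.

What the generator does **not** emulate: record-linkage errors (inputs
arrive pre-linked), dosing and dose adjustment, correlated comorbidity
structure beyond the renal–PIM coupling, seasonal or calendar effects,
coding noise, missing or duplicated records, and hospital-setting
prevalence targets (hospital-side findings are emergent from the
pathway mechanics, not planted). Passing the closed-loop tests
therefore shows the detection logic is faithful to its rules, not that
the rules would perform identically on real claims, where coding
practice and data quality dominate.

## Numerical choices and problem sizes

Printed percentages use half-up rounding to one decimal, matching how
epidemiological tables are typeset (base R rounds half to even); exact
counts and denominators are always carried alongside. Dates are
ISO-8601 calendar dates. ATC matching is case-insensitive and
whitespace-stripped; ICD-10 codes are compared dotless with prefix
semantics. The Charlson score uses the Quan ICD-10 coding algorithm
with the original weights — a deliberate choice among several published
mappings, shipped as a plain-text fixture so it can be replaced — with
the standard supersedence for the diabetes, malignancy and liver
hierarchies.

The test and validation suites run at sizes chosen to balance
statistical resolution against runtime on a single CPU: closed-loop
flag recovery at 400–800 patients, prevalence recovery at 5000
(binomial exact confidence intervals), logistic parameter recovery at
n = 4000 over 50 seeded replicates (each planted coefficient must fall
inside its Wald interval in at least 90% of replicates), and the
classification workflow demonstrations at a few hundred rows with
reduced grids. The acceptance script uses one 5000-patient cohort and
the default gradient-boosting grid restricted to 200 trees.

## Known limitations

* The shipped bleeding ICD-10 set is a curated core (hemorrhage,
  anticoagulant adverse-effect and post-hemorrhagic anemia codes); a
  production deployment should substitute a validated full list.
* The mini-KB is intentionally small; prevalence comparisons against
  full-database screenings will undercount interactions outside it.
* PIM–DDI semantics are anticoagulant-centred: interactions between two
  non-anticoagulant co-medications are out of scope.
* Classification metrics on synthetic cohorts reflect the planted
  signal-to-noise, which is modest by construction (a logistic outcome
  with moderate odds ratios); they are a workflow check, not a
  performance claim about real data.
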