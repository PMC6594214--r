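# ckdcdss

Chronic kidney disease (CKD) is usually detected and managed in primary
care, from laboratory values that already sit in the EHR — which makes it a
natural target for electronic clinical decision support (eCDSS). `ckdcdss`
implements such a decision-support system around **triple-marker testing**
(serum creatinine, serum cystatin C, urine albumin-creatinine ratio, ACR),
together with everything needed to study it in a pragmatic
cluster-randomized trial: synthetic EHR generation, EHR-based cohort
selection, panel-size-balanced provider randomization, alert-trigger
simulation, nephrologist safety surveillance, implementation-funnel and
blood-pressure outcome metrics, and the cluster-trial power arithmetic.

It is aimed at implementation scientists, trialists and informaticists who
want an executable, testable model of a CKD decision-support workflow.

## The core logic

Patients are stratified from the triple-marker panel:

* **high risk** iff eGFR_Cys < 60 mL/min/1.73m² and/or ACR > 30 mg/g,
* **low risk** otherwise (the only action is repeat testing in 6 months).

High-risk patients receive individualized recommendations across five care
domains — statin initiation (age ≥ 50, not already on one), potassium
management, ACEi/ARB initiation or titration for albuminuria, nephrology
referral for the highest-risk (eGFR_Cys < 30; K > 5.5 mEq/L; ACR > 300
mg/g; SBP > 150 mmHg despite ≥ 3 agents including a diuretic; > 3% 5-year
kidney-failure risk by the 4-variable KFRE), and patient education in the
patient's preferred language.

Supporting equations: CKD-EPI 2009 (creatinine) and CKD-EPI 2012
(cystatin C) eGFR, and the 4-variable 5-year kidney failure risk equation.
The cluster-design arithmetic uses the design effect `1 + (m-1)ρ` and

    δ = (t_{1-α/2, 2(k-1)} + t_{power, 2(k-1)}) · σ · sqrt(2·DE / (k·m))

## Worked example

```r
library(ckdcdss)

# 1. a synthetic primary-care panel: 81 providers, ~12 patients each
ehr <- generate_population(generator_config(n_providers = 81,
                                            patients_per_provider = 12,
                                            seed = 2024))

# 2. eligibility cascade
cohort <- build_cohort(ehr)
cohort$funnel
#> Participant selection funnel
#>   screened:            972
#>   initially eligible:  744
#>   automated exclusion: 174 (23.4%)
#>   manual exclusion:    0
#>   distributed to arms: 570
#>   opt-out/withdrawn:   0
#>   included:            570 (100.0% retention)

# 3. randomize providers to three arms, balanced on panel size
included <- cohort$decisions$patient_id[cohort$decisions$eligible]
panel_sizes <- table(factor(ehr$patients$provider_id[
  ehr$patients$patient_id %in% included], levels = ehr$providers$provider_id))
prov <- data.frame(provider_id = names(panel_sizes),
                   panel_size = as.integer(panel_sizes))
asg <- randomize_providers(prov, seed = 11)
assignment_balance_report(asg)$per_arm
#>          arm n_providers n_patients
#> 1      ecdss          27        192
#> 2 ecdss_plus          27        188
#> 3 usual_care          27        190

# 4. simulate the intervention workflow and compute the reach/adoption funnel
pats <- merge(ehr$patients[ehr$patients$patient_id %in% included,
                           c("patient_id", "provider_id")],
              asg[, c("provider_id", "arm")])
log <- simulate_trial(pats, seed = 99)
funnel_report(log, pats)
#> Implementation funnel (pooled intervention arms)
#>   triple_marker_completed     216 /  380  (56.8%)
#>   pcp_visit_after_labs        161 /  216  (74.5%)
#>   bpa_opened                  126 /  161  (78.3%)
#>   smartset_signed             106 /  126  (84.1%)
#>   pharmacist_call_completed    45 /   50  (90%)
```

Each funnel line is a stage of the intervention: of 380 intervention-arm
patients, 216 completed the triple-marker labs, 161 of those saw their own
PCP afterwards (so the alert displayed), the alert was opened for 126, and
orders were signed for 106; 45 of the 50 signed eCDSS+ patients got their
pharmacist call.

A single high-risk patient through the rules engine:

```r
st <- patient_state(age = 67, sex = "male",
                    panel = triple_marker_panel(scr = 1.6, scys = 1.7,
                                                acr = 420, age = 67,
                                                sex = "male"),
                    potassium = 5.2, recent_sbp = 138,
                    active_med_classes = "acei_arb",
                    preferred_language = "Spanish")
recommend(st)
#> CKD recommendation set (risk tier: high)
#>   actions: acei_arb_titrate, bp_target_reminder, education_ckd_general,
#>            education_diet, education_nsaid_avoidance, nephrology_referral,
#>            potassium_diet_counseling, statin_initiation
#>   referral criteria met: acr_gt_300, kfre_gt_3pct
#>   education language: Spanish
```

Here eGFR_Cys ≈ 37 puts the patient in the high tier; ACR 420 mg/g exceeds
the 300 referral cutoff and the computed KFRE (≈ 11.6%) exceeds 3%, so a
nephrology referral is recommended; the potassium of 5.2 lands in the
dietary-counseling band; and since an ACEi/ARB is already active, the
proteinuria action is titration rather than initiation.

Design-stage power for the trial's cluster design (23 providers/arm, 15
patients/provider, ICC 0.025, SD 5 mmHg):

```r
round(detectable_difference(power_design()), 2)
#> [1] 1.27
```

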