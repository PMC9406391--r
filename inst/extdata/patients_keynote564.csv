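id,histology,eligible,baseline_prob,milestone_months,hr,hr_grid,notes
I,clear cell,yes,0.414,24,0.68,,"pT3a pN0 M0; 10.6 cm; grade 4; necrosis; renal vein invasion; sarcomatoid. Nomogram display rounds to 41.1%; the decision chain uses 41.4%."
II,clear cell,yes,0.872,24,0.68,,"pT3a pN0 M0; 7.0 cm; grade 2; renal vein invasion; no necrosis or sarcomatoid features."
III,clear cell,no,0.68,24,0.68,,"pT2b pN0 M0; 10.3 cm; grade 3; necrosis; not high-risk enough for trial entry."
IV,clear cell,yes,,24,0.68,,"pT3a pN0 M1 NED; solitary resected lung metastasis; no nomogram covers M1 NED status."
V,papillary I,no,0.946,24,,0.5,"pT3a pN0 M0; 13.9 cm; grade 2; renal vein invasion. HR 0.5 is an optimistic best-case bound."
VI,papillary II,no,0.414,24,,0.84,"pT3 pN0 M0; 10.4 cm; grade 4; necrosis; sarcomatoid. HR 0.84 = 0.68 + (1-0.68)/2: immune-checkpoint efficacy roughly halved vs clear cell; full sensitivity grid 0.68;0.72;0.76;0.80;0.84."
VII,chromophobe,no,0.979,24,,0.5,"pT2a pN0 M0; 9.5 cm; low grade. HR 0.5 is an optimistic best-case bound."
VIII,chromophobe,no,,24,,,"pT2b pN0 M0; 11.4 cm; sarcomatoid (high grade). Nomogram output of 91.3% implausible for sarcomatoid chromophobe; treated as not estimable."
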