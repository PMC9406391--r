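label,milestone_months,control_prob,hr,reported_treated_prob
Immune checkpoint therapy vs. placebo (12 mo),12,0.762,0.68,0.857
Immune checkpoint therapy vs. placebo (24 mo),24,0.681,0.68,0.773
Immune checkpoint therapy vs. placebo (6 mo),6,0.603,0.70,0.749
Chemotherapy vs. placebo (36 mo),36,0.46,0.45,0.71
Targeted therapy vs. placebo (24 mo),24,0.52,0.20,0.89
Targeted therapy vs. placebo (36 mo),36,0.804,0.57,0.875
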