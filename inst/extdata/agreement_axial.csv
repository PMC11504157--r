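subject_id,ground_truth_ml,predicted_ml
P01,2992.23,3004.72
P02,1078.51,1117.47
P03,1121.51,1195.16
P04,2169.31,2162.39
P05,1740.32,1763.23
P06,316.14,324.86
P07,310.54,346.36
P08,2836.07,2794.3
P09,1770.83,1970.3
P10,682.89,684.51
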