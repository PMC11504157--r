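subject_id,ground_truth_ml,predicted_ml
P01,3573.87,2753.84
P02,1328.97,1614.76
P03,1374.44,1303.08
P04,2557.89,1515.7
P05,1995.45,2039.09
P06,248.8,434.7
P07,312.48,317.74
P08,3310.56,3078.19
P09,2034.05,2540.41
P10,666.63,764.95
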