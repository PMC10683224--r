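fold,accuracy_pct,sensitivity_pct,specificity_pct,precision_pct,f1,auc
1,93.83,84.38,100,100,0.9153,0.9566
2,95.00,90.63,97.92,96.67,0.9355,0.9785
3,95.00,96.77,93.88,90.91,0.9375,0.9921
4,88.61,87.10,89.58,84.38,0.8571,0.9516
5,90.91,82.76,95.83,82.31,0.8727,0.9231
6,93.59,90.00,95.83,93.10,0.9153,0.9701
7,96.20,90.32,100,100,0.9492,0.9758
8,94.87,93.55,95.74,93.55,0.9355,0.9629
9,92.31,83.33,97.92,96.15,0.8929,0.9688
10,92.21,93.33,91.49,87.50,0.9032,0.9496
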