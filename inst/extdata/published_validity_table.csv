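age_group,method,apdc_sensitivity,apdc_specificity,apdc_ppv,apdc_npv,apdc_f,eddc_sensitivity,eddc_specificity,eddc_ppv,eddc_npv,eddc_f
0-19,as_recorded,75.1,99.7,93.6,98.6,0.83,72.2,99.6,93.5,98.0,0.81
0-19,most_recent,79.9,99.7,94.4,98.9,0.87,80.1,99.6,93.4,98.5,0.86
0-19,era,83.0,99.4,88.9,99.0,0.86,82.5,99.2,88.5,98.7,0.85
0-19,msm,82.3,99.5,89.6,99.0,0.86,81.7,99.3,89.1,98.6,0.85
0-19,ever_reported,87.8,99.1,85.2,99.3,0.87,85.3,98.9,85.0,98.9,0.85
20-39,as_recorded,72.5,99.6,91.7,98.2,0.81,75.8,99.4,92.3,97.8,0.83
20-39,most_recent,68.5,99.5,91.0,97.9,0.78,81.3,99.2,90.3,98.3,0.86
20-39,era,83.4,99.3,89.0,98.9,0.86,89.7,98.8,87.4,99.0,0.89
20-39,msm,82.9,99.4,89.9,98.9,0.86,89.2,98.9,88.2,99.0,0.89
20-39,ever_reported,85.0,99.1,86.4,99.0,0.86,91.5,98.6,85.6,99.2,0.88
40-64,as_recorded,88.0,99.8,97.5,98.8,0.93,81.0,99.7,96.5,97.9,0.88
40-64,most_recent,88.4,99.8,97.8,98.8,0.93,82.3,99.6,96.3,98.1,0.89
40-64,era,93.9,99.2,92.2,99.4,0.93,91.2,99.2,92.7,99.0,0.92
40-64,msm,93.9,99.4,94.6,99.4,0.94,91.3,99.2,92.9,99.0,0.92
40-64,ever_reported,94.6,99.0,91.1,99.4,0.93,92.4,99.0,91.4,99.2,0.92
65plus,as_recorded,83.6,99.8,93.8,99.3,0.88,75.1,99.8,93.4,99.1,0.83
65plus,most_recent,80.9,99.7,91.3,99.2,0.86,77.0,99.8,94.6,99.2,0.85
65plus,era,89.9,99.3,84.2,99.6,0.87,84.7,99.5,87.1,99.5,0.86
65plus,msm,89.7,99.3,84.5,99.6,0.87,84.4,99.6,88.1,99.4,0.86
65plus,ever_reported,90.9,99.1,81.9,99.6,0.86,85.4,99.4,83.5,99.5,0.84
Total,as_recorded,84.4,99.7,95.3,99.0,0.90,77.4,99.7,94.7,98.5,0.85
Total,most_recent,83.2,99.7,94.4,99.0,0.88,80.4,99.7,94.5,98.7,0.87
Total,era,90.9,99.3,88.3,99.4,0.90,88.0,99.3,89.8,99.2,0.89
Total,msm,90.7,99.3,89.5,99.4,0.90,87.7,99.4,90.4,99.2,0.89
Total,ever_reported,92.0,99.1,86.4,99.5,0.89,89.3,99.1,87.4,99.3,0.88
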