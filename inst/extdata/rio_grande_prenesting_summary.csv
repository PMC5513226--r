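band_id,days_prenest,fate,nest_in_50,area50_ha,nest_in_95,area95_ha,nest_in_99,area99_ha,mean_dist_m,sd_dist_m,min_dist_m,min_dist_censored,day_closest
8058,45,fail,In,99.44,In,599.71,In,859.53,385.82,292.10,6.47,FALSE,3
A587-12,33,fail,Out,164.28,Out,592.93,Out,2760.9,1149.99,496.98,355.37,FALSE,18
A587-13,36,fail,Out,55.28,In,850.06,In,1347.6,672.81,419.41,32.06,FALSE,5
A590,45,fail,Out,62.74,In,669.23,In,1121.2,586.05,430.03,52.30,FALSE,30
8009,44,fail,Out,1170.7,In,5437.83,In,7461.24,3267.51,1459.30,368.22,FALSE,2
8013,45,fail,Out,198.69,In,920.86,In,1338.1,1931.40,565.44,24.07,FALSE,2
8016,45,fail,Out,102.96,In,673.65,In,1061.6,829.89,382.81,30.22,FALSE,7
8021,46,fail,In,165.44,In,597.1,In,788.68,755.88,398.89,3.51,FALSE,2
8024,44,fail,Out,169.19,In,649.88,In,852.21,719.25,501.32,64.88,FALSE,13
8026,45,fail,Out,143.73,In,595.19,In,812.9,689.30,320.36,109.37,FALSE,12
8028,46,fail,Out,178.09,In,983.36,In,1390,1238.30,598.61,185.07,FALSE,3
8029,43,fail,In,1437.05,In,3237.7,In,20417.14,6859.76,4249.15,36.04,FALSE,12
21270,39,fail,Out,299.19,In,1772,In,2780.9,1149.74,906.23,24.03,FALSE,2
8061,45,fail,In,1844.2,In,16251.03,In,24134.74,3452.15,5812.75,88.56,FALSE,33
8063,45,fail,Out,125.97,In,1177.8,In,1630.4,3398.78,1489.65,2.77,FALSE,2
8503,44,fail,Out,72.38,In,414.46,In,619.38,893.82,470.09,2.51,FALSE,2
A588,45,success,Out,105.93,In,520.24,In,783.02,702.86,488.21,29.73,FALSE,4
A589,25,fail,Out,60.97,Out,291.09,Out,447.92,1301.07,428.38,662.18,FALSE,3
A591,45,success,Out,116.69,In,590.77,In,924.31,706.44,456.13,18.93,FALSE,1
8134,41,fail,Out,85.6,In,625.05,In,1036.4,1563.82,642.83,139.50,FALSE,3
8094,44,fail,Out,104.99,Out,658.12,Out,971.9,2102.48,395.29,1259.96,FALSE,1
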