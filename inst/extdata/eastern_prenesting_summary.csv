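band_id,days_prenest,fate,nest_in_50,area50_ha,nest_in_95,area95_ha,nest_in_99,area99_ha,mean_dist_m,sd_dist_m,min_dist_m,min_dist_censored,day_closest
48,45,fail,Out,157.44,Out,1251.9,Out,1506.5,4231.81,1283.99,1359.08,FALSE,3
50,45,fail,Out,49.17,In,427,In,846.64,384.35,495.99,31.04,FALSE,6
51,46,fail,Out,510.94,In,3217.7,In,4681,4315.20,2742.93,156.31,FALSE,4
132,45,fail,In,429.72,In,2050.2,In,2846.2,1890.91,1986.24,34.48,FALSE,5
133,45,fail,Out,115.05,Out,433.37,Out,603.28,1210.52,552.76,367.19,FALSE,5
134,45,fail,Out,162.96,Out,1109.5,In,1610.6,4502.91,1550.50,83.75,FALSE,1
135,45,fail,Out,489.29,In,2347.9,In,3573,3424.63,2359.39,99.34,FALSE,8
136,45,fail,Out,230.73,In,1079.8,In,1556.1,1349.59,751.92,192.39,FALSE,7
369,45,fail,In,341.75,In,1625.8,In,2235.4,1101.39,1132.95,51.12,FALSE,2
371,45,fail,Out,274.24,Out,1213.1,In,1850.5,1535.42,734.1937,503.43,FALSE,9
372,45,fail,Out,275.82,In,1078.8,In,1460.8,1157.97,701.54,40.03,FALSE,29
656,45,fail,Out,532.92,In,2090.1,In,2790.9,1678.61,832.08,4.95,FALSE,2
657,45,fail,Out,69.67,In,610.64,In,939.36,778.53,593.07,112.53,FALSE,1
658,45,fail,Out,124.62,In,757.84,In,1084.3,1259.55,419.53,205.37,FALSE,7
660,45,fail,In,269.76,In,1010.6,In,1409.7,668.63,378.85,53.29,FALSE,32
661,45,fail,Out,85.32,In,673.81,In,1135.1,1464.33,513.21,51.07,FALSE,1
662,45,success,Out,36.99,Out,284.86,Out,423.65,1511.46,315.58,824.96,FALSE,44
663,45,fail,Out,114.97,In,849.53,In,1305.7,4208.09,1408.03,175.35,FALSE,4
667,45,fail,Out,311.37,In,2012.5,In,3008.9,1626.79,676.84,112.42,FALSE,44
710,45,fail,Out,43.78,Out,363.07,In,620.35,1904.47,544.77,86.46,FALSE,2
777,45,fail,Out,73.36,In,380.65,In,522.73,621.78,386.48,1,TRUE,5
13210,45,fail,Out,155.37,Out,650.39,Out,899.11,1957.31,645.75,816.38,FALSE,41
13181,45,success,Out,115.95,In,694.57,In,1045,1776.36,713.76,73.90,FALSE,4
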