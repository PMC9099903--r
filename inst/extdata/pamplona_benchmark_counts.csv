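zone,method,n,TP,FP,FN,p,r,F1,consistent
1,GSV,700,635,911,51,41.07,92.57,56.90,TRUE
1,ALS,700,608,655,64,48.14,90.48,62.84,TRUE
1,GSV+GSV,700,581,271,95,68.19,85.95,76.05,TRUE
1,GSV+ML,700,581,304,95,65.65,85.95,74.44,TRUE
1,ALS+GSV,700,542,146,141,78.78,79.36,79.07,TRUE
1,ALS+ML,700,509,51,186,90.89,73.24,81.12,TRUE
2,GSV,215,112,351,73,24.19,60.54,34.57,TRUE
2,ALS,215,164,205,36,44.44,82.00,57.64,TRUE
2,GSV+GSV,215,91,104,104,46.67,46.67,46.67,TRUE
2,GSV+ML,215,98,120,92,44.95,51.58,48.04,TRUE
2,ALS+GSV,215,102,66,103,60.71,49.76,54.69,TRUE
2,ALS+ML,215,141,68,66,67.46,68.12,67.79,TRUE
3,GSV,652,461,420,177,52.33,72.26,60.70,TRUE
3,ALS,652,490,367,132,57.18,78.78,66.26,TRUE
3,GSV+GSV,652,409,137,227,74.91,64.31,69.20,TRUE
3,GSV+ML,652,421,142,221,74.78,65.58,69.88,TRUE
3,ALS+GSV,652,421,87,219,82.87,65.78,73.34,TRUE
3,ALS+ML,652,393,55,251,87.72,61.02,71.98,TRUE
6,GSV,366,306,345,44,47.00,87.43,61.14,TRUE
6,ALS,366,341,314,20,52.06,94.46,67.13,TRUE
6,GSV+GSV,366,282,97,75,74.41,78.99,76.63,TRUE
6,GSV+ML,366,278,102,77,73.16,78.31,75.65,TRUE
6,ALS+GSV,366,308,82,52,78.97,85.56,82.13,TRUE
6,ALS+ML,366,298,76,61,79.68,83.01,81.31,TRUE
8,GSV,839,759,1228,54,38.20,93.36,54.21,TRUE
8,ALS,839,772,718,50,51.81,93.92,66.78,TRUE
8,GSV+GSV,839,707,358,105,66.38,87.07,75.33,TRUE
8,GSV+ML,839,711,389,98,64.64,87.89,74.49,TRUE
8,ALS+GSV,839,707,270,113,72.36,86.22,78.69,TRUE
8,ALS+ML,839,612,207,217,74.73,73.82,74.27,TRUE
pooled,GSV,2772,2273,3255,399,41.12,85.07,55.44,TRUE
pooled,ALS,2772,2375,1541,252,50.99,86.42,64.13,FALSE
pooled,GSV+GSV,2772,2070,967,606,68.16,77.35,72.47,TRUE
pooled,GSV+ML,2772,2089,1057,583,66.40,78.18,71.81,TRUE
pooled,ALS+GSV,2772,2080,651,628,76.16,76.81,76.48,TRUE
pooled,ALS+ML,2772,1953,457,781,81.04,71.43,75.93,TRUE
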