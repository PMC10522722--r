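province,set,tp,fp,fn,tn,ua,pa,oa,ua_other,pa_other
Gansu,north,190,82,39,278,82.97,69.85,79.46,77.22,87.70
Hebei,north,2137,156,414,2549,83.77,93.20,89.16,94.23,86.03
Heilongjiang,north,921,130,709,3251,56.50,87.63,83.26,96.15,82.10
Henan,north,1145,544,906,3556,55.83,67.79,76.43,86.73,79.70
Inner Mongolia,north,1756,237,670,1816,72.38,88.11,79.75,88.46,73.05
Jilin,north,811,36,149,2106,84.48,95.75,94.04,98.32,93.39
Liaoning,north,1906,28,391,2647,82.98,98.55,91.57,98.95,87.13
Ningxia,north,592,498,66,835,89.97,54.31,71.67,62.64,92.67
Shaanxi,north,327,95,40,765,89.10,77.49,89.00,88.95,95.03
Shandong,north,4837,504,977,6645,83.20,90.56,88.58,92.95,87.18
Shanxi,north,485,175,95,1366,83.62,73.48,87.27,88.64,93.50
Tianjin,north,74,34,10,71,88.10,68.52,76.72,67.62,87.65
Xinjiang,north,69,21,58,170,54.33,76.67,75.16,89.01,74.56
Anhui,south,603,96,279,731,68.37,86.27,78.06,88.39,72.38
Chongqing,south,12,0,38,58,24.00,100.00,64.81,100.00,60.42
Guangxi,south,13,6,37,72,26.00,68.42,66.41,92.31,66.06
Guizhou,south,34,25,19,89,64.15,57.63,73.65,78.07,82.41
Hubei,south,158,99,187,1059,45.80,61.48,80.97,91.45,84.99
Hunan,south,9,0,24,68,27.27,100.00,76.24,100.00,73.91
Jiangsu,south,168,41,36,180,82.35,80.38,81.88,81.45,83.33
Sichuan,south,76,30,49,202,60.80,71.70,77.87,87.07,80.48
Yunnan,south,270,9,284,851,48.74,96.77,79.28,98.95,74.98
Heilongjiang,independent,1018,520,1275,5544,44.40,66.19,78.52,91.42,81.30
Jilin,independent,364,126,60,940,85.85,74.29,87.52,88.18,94.00
Liaoning,independent,463,60,117,1443,79.83,88.53,91.50,96.01,92.50
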