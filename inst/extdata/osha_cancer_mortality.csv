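duration_years,conc_f_ml,lung_per_100k,meso_per_100k,gi_per_100k,total_per_100k
1,0.1,7.2,6.9,0.7,14.8
1,0.2,"14,4",13.8,1.4,29.6
1,0.5,36.1,34.6,3.6,74.3
1,2.0,144,138,14.4,296.4
1,4.0,288,275,28.8,591.8
1,5.0,360,344,36.0,740.0
1,10.0,715,684,71.5,1470.5
20,0.1,139,73,13.9,225.9
20,0.2,278,146,27.8,451.8
20,0.5,692,362,69.2,1123.2
20,2.0,2713,1408,271.3,4392.3
20,4.0,5278,2706,527.8,8511.8
20,5.0,6509,3317,650.9,"10,476.9"
20,10.0,"12,177",6024,1217.7,"13,996.7"
45,0.1,231,82,23.1,336.1
45,0.2,460,164,46.0,670.0
45,0.5,1143,407,114.3,1664.3
45,2.0,4416,1554,441.6,6411.6
45,4.0,8441,2924,844.1,"12,209.1"
45,5.0,"10,318",3547,1031.8,"14,896.8"
45,10.0,"18,515",6141,1851.5,"26,507.5"
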