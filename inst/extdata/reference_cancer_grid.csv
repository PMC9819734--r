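factory,job,period_start,period_end,mean_f_ml,total_1y,inc_1y,total_10y,inc_10y,total_20y,inc_20y,total_25y,inc_25y
Harare,Saw cutting operator,1996,2000,0.19,23,0.02,219,0.22,439,0.44,555,0.56
Harare,Saw cutting operator,2001,2008,0.13,16,0.02,151,0.15,301,0.30,382,0.38
Harare,Saw cutting operator,2009,2016,0.07,9,0.01,81,0.08,163,0.16,209,0.21
Harare,Saw cutting operator,2018,2020,0.10,13,0.01,116,0.12,231,0.23,289,0.29
Harare,Fettling table operator,1996,2000,0.12,15,0.02,137,0.14,277,0.28,347,0.35
Harare,Fettling table operator,2001,2008,0.12,15,0.02,137,0.14,277,0.28,347,0.35
Harare,Fettling table operator,2018,2020,0.11,14,0.01,128,0.13,255,0.26,324,0.32
Harare,Moulded goods operator,1996,2000,0.11,14,0.01,128,0.13,255,0.26,324,0.32
Harare,Moulded goods operator,2001,2008,0.11,14,0.01,128,0.13,255,0.26,324,0.32
Harare,Moulded goods operator,2009,2016,0.05,7,0.01,59,0.06,116,0.12,151,0.15
Harare,Moulded goods operator,2018,2020,0.11,14,0.01,128,0.13,255,0.26,324,0.32
Harare,Kollergang operator,1996,2000,0.13,16,0.02,151,0.15,301,0.30,381,0.38
Harare,Kollergang operator,2001,2008,0.12,15,0.02,137,0.14,277,0.28,347,0.35
Harare,Kollergang operator,2009,2016,0.07,9,0.01,81,0.08,163,0.16,209,0.21
Harare,Kollergang operator,2018,2020,0.12,15,0.02,137,0.14,277,0.28,347,0.35
Harare,Ground hard waste operator,1996,2000,0.16,20,0.02,186,0.19,370,0.37,463,0.46
Harare,Ground hard waste operator,2001,2008,0.13,16,0.02,151,0.15,301,0.30,381,0.38
Harare,Ground hard waste operator,2009,2016,0.07,9,0.01,81,0.08,163,0.16,209,0.21
Harare,Ground hard waste operator,2018,2020,0.12,15,0.02,137,0.14,277,0.28,347,0.35
Harare,Laundry room operator,1996,2000,0.13,16,0.02,151,0.15,301,0.30,382,0.38
Harare,Laundry room operator,2001,2008,0.13,16,0.02,151,0.15,301,0.30,382,0.38
Harare,Laundry room operator,2009,2016,0.05,7,0.01,59,0.06,116,0.12,151,0.15
Harare,Laundry room operator,2018,2020,0.11,14,0.01,128,0.13,255,0.26,324,0.32
Harare,Overall factory,1996,2020,0.11,14,0.01,128,0.13,255,0.26,324,0.32
Bulawayo,Saw cutting operator,1996,2000,0.17,21,0.02,197,0.20,394,0.39,497,0.50
Bulawayo,Saw cutting operator,2001,2008,0.12,15,0.02,137,0.14,277,0.28,347,0.35
Bulawayo,Saw cutting operator,2009,2016,0.06,8,0.01,63,0.06,137,0.14,174,0.17
Bulawayo,Saw cutting operator,2018,2020,0.05,7,0.01,59,0.06,116,0.12,151,0.15
Bulawayo,Fettling table operator,1996,2000,0.17,21,0.02,197,0.20,394,0.39,497,0.56
Bulawayo,Fettling table operator,2001,2008,0.12,15,0.02,137,0.14,277,0.28,347,0.40
Bulawayo,Kollergang operator,1996,2000,0.14,17,0.02,163,0.16,324,0.32,404,0.40
Bulawayo,Kollergang operator,2001,2008,0.12,15,0.02,137,0.14,277,0.28,347,0.35
Bulawayo,Kollergang operator,2009,2016,0.07,9,0.01,81,0.08,163,0.16,209,0.21
Bulawayo,Kollergang operator,2018,2020,0.06,8,0.01,63,0.06,137,0.14,174,0.17
Bulawayo,Ground hard waste operator,1996,2000,0.13,16,0.02,151,0.15,301,0.30,381,0.38
Bulawayo,Ground hard waste operator,2001,2008,0.11,14,0.01,128,0.13,255,0.26,324,0.32
Bulawayo,Ground hard waste operator,2009,2016,0.07,9,0.01,81,0.08,163,0.16,209,0.21
Bulawayo,Ground hard waste operator,2018,2020,0.06,8,0.01,63,0.06,137,0.14,174,0.17
Bulawayo,Pipe joints operator,1996,2000,0.13,16,0.02,151,0.15,301,0.30,381,0.38
Bulawayo,Pipe joints operator,2001,2008,0.11,14,0.01,128,0.13,255,0.26,324,0.32
Bulawayo,Pipe joints operator,2009,2016,0.05,7,0.01,59,0.06,116,0.12,151,0.15
Bulawayo,Pipe joints operator,2018,2020,0.05,7,0.01,59,0.06,116,0.12,151,0.15
Bulawayo,Full-length pipe operator,1996,2000,0.13,16,0.02,151,0.15,301,0.30,381,0.38
Bulawayo,Full-length pipe operator,2001,2008,0.11,14,0.01,128,0.13,255,0.26,324,0.32
Bulawayo,Full-length pipe operator,2009,2016,0.07,9,0.01,81,0.08,163,0.16,209,0.21
Bulawayo,Multi-cutter operator,1996,2000,0.13,16,0.02,151,0.15,301,0.30,381,0.38
Bulawayo,Multi-cutter operator,2001,2008,0.12,15,0.02,137,0.14,277,0.28,347,0.34
Bulawayo,Multi-cutter operator,2009,2016,0.07,9,0.01,81,0.08,163,0.16,209,0.21
Bulawayo,Multi-cutter operator,2018,2020,0.04,6,0.01,48,0.05,105,0.10,116,0.12
Bulawayo,Overall factory,1996,2020,0.12,15,0.02,137,0.14,277,0.28,347,0.35
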