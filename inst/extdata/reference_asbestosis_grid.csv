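factory,job,period_start,period_end,mean_f_ml,ce_f_ml_years,incidence_pct,cases_per_100k,suspected_typo
Harare,Saw cutting operator,1996,2000,0.19,4.8,0.26,260,FALSE
Harare,Saw cutting operator,2001,2008,0.13,3.3,0.18,180,FALSE
Harare,Saw cutting operator,2009,2016,0.07,1.8,0.10,100,FALSE
Harare,Saw cutting operator,2018,2020,0.10,2.5,0.14,140,FALSE
Harare,Fettling table operator,1996,2000,0.12,3.0,0.17,170,FALSE
Harare,Fettling table operator,2001,2008,0.12,3.0,0.17,170,FALSE
Harare,Fettling table operator,2018,2020,0.11,2.8,0.15,150,FALSE
Harare,Moulded goods operator,1996,2000,0.11,2.8,0.15,150,FALSE
Harare,Moulded goods operator,2001,2008,0.11,2.8,0.15,150,FALSE
Harare,Moulded goods operator,2009,2016,0.05,1.3,0.07,70,FALSE
Harare,Moulded goods operator,2018,2020,0.11,2.8,0.15,150,FALSE
Harare,Kollergang operator,1996,2000,0.13,3.3,0.18,180,FALSE
Harare,Kollergang operator,2001,2008,0.12,3.0,0.17,180,TRUE
Harare,Kollergang operator,2009,2016,0.07,1.8,0.10,100,FALSE
Harare,Kollergang operator,2018,2020,0.12,3.0,0.17,170,FALSE
Harare,Ground hard waste operator,1996,2000,0.16,4.0,0.22,220,FALSE
Harare,Ground hard waste operator,2001,2008,0.13,3.3,0.18,180,FALSE
Harare,Ground hard waste operator,2009,2016,0.07,1.8,0.10,100,FALSE
Harare,Ground hard waste operator,2018,2020,0.12,3.0,0.17,170,FALSE
Harare,Laundry room operator,1996,2000,0.13,3.3,0.18,180,FALSE
Harare,Laundry room operator,2001,2008,0.13,3.3,0.18,180,FALSE
Harare,Laundry room operator,2009,2016,0.05,1.3,0.07,70,FALSE
Harare,Laundry room operator,2018,2020,0.11,2.8,0.15,150,FALSE
Harare,Overall factory,1996,2020,0.11,2.8,0.15,150,FALSE
Bulawayo,Saw cutting operator,1996,2000,0.17,4.3,0.24,240,FALSE
Bulawayo,Saw cutting operator,2001,2008,0.12,3.0,0.17,170,FALSE
Bulawayo,Saw cutting operator,2009,2016,0.06,1.5,0.08,80,FALSE
Bulawayo,Saw cutting operator,2018,2020,0.05,1.3,0.07,70,FALSE
Bulawayo,Fettling table operator,1996,2000,0.17,4.3,0.24,240,FALSE
Bulawayo,Fettling table operator,2001,2008,0.12,3.0,0.17,170,FALSE
Bulawayo,Kollergang operator,1996,2000,0.14,3.5,0.19,190,FALSE
Bulawayo,Kollergang operator,2001,2008,0.12,3.0,0.17,170,FALSE
Bulawayo,Kollergang operator,2009,2016,0.07,1.8,0.10,100,FALSE
Bulawayo,Kollergang operator,2018,2020,0.06,1.5,0.08,80,FALSE
Bulawayo,Ground hard waste operator,1996,2000,0.13,3.3,0.18,180,FALSE
Bulawayo,Ground hard waste operator,2001,2008,0.11,2.8,0.15,150,FALSE
Bulawayo,Ground hard waste operator,2009,2016,0.07,1.8,0.10,100,FALSE
Bulawayo,Ground hard waste operator,2018,2020,0.06,1.5,0.08,80,FALSE
Bulawayo,Pipe joints operator,1996,2000,0.13,3.3,0.18,180,FALSE
Bulawayo,Pipe joints operator,2001,2008,0.11,2.8,0.15,150,FALSE
Bulawayo,Pipe joints operator,2009,2016,0.05,1.3,0.07,70,FALSE
Bulawayo,Pipe joints operator,2018,2020,0.05,1.3,0.07,70,FALSE
Bulawayo,Full-length pipe operator,1996,2000,0.13,3.3,0.18,180,FALSE
Bulawayo,Full-length pipe operator,2001,2008,0.11,2.8,0.15,150,FALSE
Bulawayo,Full-length pipe operator,2009,2016,0.07,1.8,0.10,100,FALSE
Bulawayo,Multi-cutter operator,1996,2000,0.13,3.3,0.18,180,FALSE
Bulawayo,Multi-cutter operator,2001,2008,0.12,3.0,0.17,300,TRUE
Bulawayo,Multi-cutter operator,2009,2016,0.07,1.8,0.10,100,FALSE
Bulawayo,Multi-cutter operator,2018,2020,0.04,1.0,0.05,50,TRUE
Bulawayo,Overall factory,1996,2020,0.12,3.0,0.17,170,FALSE
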