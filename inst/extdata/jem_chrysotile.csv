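factory,job,period_start,period_end,mean_f_ml,sd_f_ml,n_samples,flag
Harare,Saw cutting operator,1996,2000,0.19,0.01,,FALSE
Harare,Saw cutting operator,2001,2008,0.13,0.02,,FALSE
Harare,Saw cutting operator,2009,2016,0.07,0.02,,FALSE
Harare,Saw cutting operator,2018,2020,0.10,0.02,,TRUE
Harare,Fettling table operator,1996,2000,0.12,0.04,,FALSE
Harare,Fettling table operator,2001,2008,0.12,0.02,,FALSE
Harare,Fettling table operator,2018,2020,0.11,0.03,,TRUE
Harare,Moulded goods operator,1996,2000,0.11,0.04,,FALSE
Harare,Moulded goods operator,2001,2008,0.11,0.04,,FALSE
Harare,Moulded goods operator,2009,2016,0.05,0.01,,FALSE
Harare,Moulded goods operator,2018,2020,0.11,0.02,,TRUE
Harare,Kollergang operator,1996,2000,0.13,0.04,,FALSE
Harare,Kollergang operator,2001,2008,0.12,0.02,,FALSE
Harare,Kollergang operator,2009,2016,0.07,0.02,,FALSE
Harare,Kollergang operator,2018,2020,0.12,0.01,,TRUE
Harare,Ground hard waste operator,1996,2000,0.16,0.03,,FALSE
Harare,Ground hard waste operator,2001,2008,0.13,0.03,,FALSE
Harare,Ground hard waste operator,2009,2016,0.07,0.02,,FALSE
Harare,Ground hard waste operator,2018,2020,0.12,0.01,,TRUE
Harare,Laundry room operator,1996,2000,0.13,0.03,,FALSE
Harare,Laundry room operator,2001,2008,0.13,0.02,,FALSE
Harare,Laundry room operator,2009,2016,0.05,0.01,,FALSE
Harare,Laundry room operator,2018,2020,0.11,0.02,,TRUE
Harare,Overall factory,1996,2020,0.11,,,FALSE
Bulawayo,Saw cutting operator,1996,2000,0.17,0.02,,FALSE
Bulawayo,Saw cutting operator,2001,2008,0.12,0.02,,FALSE
Bulawayo,Saw cutting operator,2009,2016,0.06,0.02,,FALSE
Bulawayo,Saw cutting operator,2018,2020,0.05,0.01,,TRUE
Bulawayo,Fettling table operator,1996,2000,0.17,0.06,,FALSE
Bulawayo,Fettling table operator,2001,2008,0.12,0.03,,FALSE
Bulawayo,Kollergang operator,1996,2000,0.14,0.03,,FALSE
Bulawayo,Kollergang operator,2001,2008,0.12,0.01,,FALSE
Bulawayo,Kollergang operator,2009,2016,0.07,0.03,,FALSE
Bulawayo,Kollergang operator,2018,2020,0.06,0.01,,TRUE
Bulawayo,Ground hard waste operator,1996,2000,0.13,0.04,,FALSE
Bulawayo,Ground hard waste operator,2001,2008,0.11,0.04,,FALSE
Bulawayo,Ground hard waste operator,2009,2016,0.07,0.02,,FALSE
Bulawayo,Ground hard waste operator,2018,2020,0.06,0.02,,TRUE
Bulawayo,Pipe joints operator,1996,2000,0.13,0.04,,FALSE
Bulawayo,Pipe joints operator,2001,2008,0.11,0.01,,FALSE
Bulawayo,Pipe joints operator,2009,2016,0.05,0.02,,FALSE
Bulawayo,Pipe joints operator,2018,2020,0.05,0.02,,FALSE
Bulawayo,Full-length pipe operator,1996,2000,0.13,0.04,,FALSE
Bulawayo,Full-length pipe operator,2001,2008,0.11,0.01,,FALSE
Bulawayo,Full-length pipe operator,2009,2016,0.07,0.02,,FALSE
Bulawayo,Multi-cutter operator,1996,2000,0.13,0.04,,FALSE
Bulawayo,Multi-cutter operator,2001,2008,0.12,0.01,,FALSE
Bulawayo,Multi-cutter operator,2009,2016,0.07,0.03,,FALSE
Bulawayo,Multi-cutter operator,2018,2020,0.04,0.01,,FALSE
Bulawayo,Overall factory,1996,2020,0.12,,,FALSE
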