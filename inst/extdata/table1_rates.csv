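animal_id,group,subgroup,sex,total_hours,gs_rate_per_day,swd_rate_per_hour
541,Control,littermate,F,388.738,0,1.0
833,Control,littermate,F,237.772,0,0
834,Control,littermate,F,229.378,0,0
841,Control,littermate,F,312.545,0,0.5
844,Control,littermate,M,218.905,0,0
157,Control,littermate,F,166.736,0,0
162,Control,littermate,M,147.056,0,0
570,Control,C57,F,160.217,0,1.125
571,Control,C57,M,207.417,0,0
576,Pten,Pten,M,265.171,0.402,11.688
662,Pten,Pten,F,412.196,0.815,16.125
677,Pten,Pten,F,173.978,0,10.188
681,Pten,Pten,M,324.945,1.551,4.0625
832,Pten,Pten,M,416.008,0.519,11.188
842,Pten,Pten,F,260.195,0,12.438
867,Pten,Pten,M,427.933,0,7.964
538,PtenRap,PtenRap,M,438.481,0,11.125
664,PtenRap,PtenRap,M,266.227,1.262,10.688
665,PtenRap,PtenRap,M,400.567,0.299,11
666,PtenRap,PtenRap,M,389.0367,0,10.75
943,PtenRap,PtenRap,M,312.383,0,7.417
999,PtenRap,PtenRap,M,272.4,0,5.5
574,PtenRic,PtenRic,F,319.483,0,10
676,PtenRic,PtenRic,F,284.317,0,7.5
678,PtenRic,PtenRic,F,238.584,0.453,4.1875
811,PtenRic,PtenRic,M,307.438,0,3.0625
941,PtenRic,PtenRic,M,295.691,0,5.75
41,PtenRic,PtenRic,F,397.683,0,8.625
42,PtenRic,PtenRic,M,421.85,0.554,7.5
933,PtRapRic,PtRapRic,M,286.467,0,1.875
940,PtRapRic,PtRapRic,M,234.533,0,0.625
997,PtRapRic,PtRapRic,M,209.497,0,0
40,PtRapRic,PtRapRic,F,220.717,0,0.875
158,PtRapRic,PtRapRic,F,154.228,0,0
161,PtRapRic,PtRapRic,M,168.006,0,0
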