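class_id,name,S0,T10_s,T2star0_s,vP,PS_per_min,enhancement_mode,curve_params
1,csf,11000,4.0,0.5,0,0,none,"{}"
2,nawm,9726,0.99,0.065,0.0057,2.75e-4,patlak,"{}"
3,wmh,9402,1.20,0.070,0.0072,3.91e-4,patlak,"{}"
4,stroke,9858,1.27,0.070,0.0105,7.25e-4,patlak,"{}"
5,cortical_gm,9298,1.34,0.060,0.012,3.85e-4,patlak,"{}"
6,subcortical_gm,9298,1.34,0.060,0.012,3.85e-4,patlak,"{}"
7,meninges,9000,1.20,0.050,NA,NA,extracerebral_curve,"{""form"":""exponential"",""a"":1.5,""tau_s"":120}"
8,muscle,9000,0.87,0.035,NA,NA,extracerebral_curve,"{""form"":""exponential"",""a"":1.0,""tau_s"":150}"
9,mandible_vertebrae,8000,0.55,0.025,NA,NA,extracerebral_curve,"{""form"":""power"",""b"":0.3,""p"":0.4,""tref_s"":300}"
10,skull_diploe,9500,0.58,0.030,NA,NA,extracerebral_curve,"{""form"":""exponential"",""a"":0.8,""tau_s"":200}"
11,skull_inner_table,3000,0.35,0.010,NA,NA,extracerebral_curve,"{""form"":""exponential"",""a"":0.2,""tau_s"":300}"
12,skull_outer_table,3000,0.35,0.010,NA,NA,extracerebral_curve,"{""form"":""exponential"",""a"":0.2,""tau_s"":300}"
13,vessels,9700,1.43,0.060,NA,0,patlak,"{}"
14,skin,9200,0.60,0.030,NA,NA,extracerebral_curve,"{""form"":""exponential"",""a"":1.2,""tau_s"":100}"
15,adipose,12000,0.26,0.040,NA,NA,extracerebral_curve,"{""form"":""exponential"",""a"":0.15,""tau_s"":300}"
16,eyes,10000,3.0,0.20,NA,NA,extracerebral_curve,"{""form"":""power"",""b"":0.2,""p"":0.5,""tref_s"":600}"
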