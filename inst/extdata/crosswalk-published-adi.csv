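# method: ADI
# model: published
# source: RA calibration sample, n = 1791, partial credit model
direction,observed,observed_norm,predicted,predicted_norm
haq_to_pf10,0,NA,95,54.9
haq_to_pf10,0.125,NA,85,50.7
haq_to_pf10,0.25,NA,80,48.6
haq_to_pf10,0.375,NA,75,46.5
haq_to_pf10,0.5,NA,70,44.4
haq_to_pf10,0.625,NA,65,42.3
haq_to_pf10,0.75,NA,55,38.1
haq_to_pf10,0.875,NA,50,36
haq_to_pf10,1,NA,45,33.9
haq_to_pf10,1.125,NA,45,33.9
haq_to_pf10,1.25,NA,40,31.8
haq_to_pf10,1.375,NA,35,29.7
haq_to_pf10,1.5,NA,30,27.6
haq_to_pf10,1.625,NA,25,25.5
haq_to_pf10,1.75,NA,25,25.5
haq_to_pf10,1.875,NA,25,25.5
haq_to_pf10,2,NA,20,23.4
haq_to_pf10,2.125,NA,15,21.3
haq_to_pf10,2.25,NA,10,19.2
haq_to_pf10,2.375,NA,10,19.2
haq_to_pf10,2.5,NA,5,17
haq_to_pf10,2.625,NA,5,17
haq_to_pf10,2.75,NA,0,14.9
haq_to_pf10,2.875,NA,0,14.9
haq_to_pf10,3,NA,0,14.9
pf10_to_haq,100,57,0,NA
pf10_to_haq,95,54.9,0,NA
pf10_to_haq,90,52.8,0.125,NA
pf10_to_haq,85,50.7,0.125,NA
pf10_to_haq,80,48.6,0.25,NA
pf10_to_haq,75,46.5,0.375,NA
pf10_to_haq,70,44.4,0.5,NA
pf10_to_haq,65,42.3,0.625,NA
pf10_to_haq,60,40.2,0.625,NA
pf10_to_haq,55,38.1,0.75,NA
pf10_to_haq,50,36,1,NA
pf10_to_haq,45,33.9,1.125,NA
pf10_to_haq,40,31.8,1.25,NA
pf10_to_haq,35,29.7,1.375,NA
pf10_to_haq,30,27.6,1.5,NA
pf10_to_haq,25,25.5,1.75,NA
pf10_to_haq,20,23.4,2,NA
pf10_to_haq,15,21.3,2.125,NA
pf10_to_haq,10,19.2,2.25,NA
pf10_to_haq,5,17,2.625,NA
pf10_to_haq,0,14.9,2.75,NA
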