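compound_id,name,plant,documented_constituent,conc_raw,conc_determined,conc_low,conc_high,conc_unit,conc_basis,toxic,rec_a,rec_b,rec_c,rec_d,rec_e,rec_f,rec_total
EG01,aromadendrine,Eucalyptus globulus,TRUE,10–30% of essential oil,TRUE,10,30,percent_w_w,essential oil,FALSE,1,2,1,1,1,1,7
EG02,α-terpineol,Eucalyptus globulus,TRUE,0.50% of essential oil,TRUE,0.5,0.5,percent_w_w,essential oil,FALSE,1,3,1,1,1,1,8
EG03,globulol,Eucalyptus globulus,TRUE,10–11% of essential oil,TRUE,10,11,percent_w_w,essential oil,FALSE,1,1,1,1,1,1,6
EG04,"1,8-cineol",Eucalyptus globulus,TRUE,97.32% of essential oil,TRUE,97.32,97.32,percent_w_w,essential oil,FALSE,1,3,1,1,1,1,8
AV01,aloin A,Aloe vera,TRUE,0.1–0.6% of leaf,TRUE,0.1,0.6,percent_w_w,leaf,FALSE,1,3,1,1,1,1,8
AV02,aloin B,Aloe vera,TRUE,0.1–0.6% of leaf,TRUE,0.1,0.6,percent_w_w,leaf,FALSE,1,3,1,1,1,1,8
AV03,aloe emodin,Aloe vera,TRUE,0.09–0.29 mg/g of whole leaf,TRUE,0.09,0.29,mg_per_g,whole leaf,FALSE,1,2,1,1,1,1,7
AV04,acemannan,Aloe vera,TRUE,109–135 ppm of gel,TRUE,109,135,ppm,gel,FALSE,1,3,1,1,1,1,8
AV05,mannose 6-phosphate,Aloe vera,TRUE,ND,FALSE,,,,,FALSE,1,1,0,0,1,0,3
AC01,lupeol,Albizia coriaria,TRUE,1–6 mg/g of stem bark,TRUE,1,6,mg_per_g,stem bark,FALSE,1,3,1,1,1,1,8
AC02,lupenone,Albizia coriaria,TRUE,19–200 ppm of stem bark,TRUE,19,200,ppm,stem bark,FALSE,1,1,1,1,1,1,6
AC03,betulinic acid,Albizia coriaria,TRUE,1.2–10 mg/g of stem bark,TRUE,1.2,10,mg_per_g,stem bark,FALSE,1,3,1,1,1,1,8
AC04,catechin,Albizia coriaria,TRUE,0.2–12 mg/g of stem bark,TRUE,0.2,12,mg_per_g,stem bark,FALSE,1,3,1,1,1,1,8
MI01,mangiferin,Mangifera indica,TRUE,5–20 mg/g of leaves,TRUE,5,20,mg_per_g,leaves,FALSE,1,3,1,1,1,1,8
MI02,catechin,Mangifera indica,TRUE,71.4 mg/g of stem bark,TRUE,71.4,71.4,mg_per_g,stem bark,FALSE,1,3,1,1,1,1,8
MI03,epicatechin,Mangifera indica,TRUE,8.07 mg/g of stem bark,TRUE,8.07,8.07,mg_per_g,stem bark,FALSE,1,1,1,1,0,1,5
MI04,gallic acid,Mangifera indica,TRUE,2.08 mg/g of stem bark,TRUE,2.08,2.08,mg_per_g,stem bark,FALSE,1,3,1,1,1,1,8
MI05,quercetin,Mangifera indica,TRUE,0.76 to 1.16 mg/g of leaves,TRUE,0.76,1.16,mg_per_g,leaves,FALSE,1,3,1,1,1,1,8
AI01,azadirachtin,Azadirachta indica,TRUE,3.8 to 4.8 mg/g of seeds,TRUE,3.8,4.8,mg_per_g,seeds,FALSE,1,3,1,1,1,1,8
AI02,nimbin,Azadirachta indica,TRUE,0.018 to 0.64 mg/g of oil,TRUE,0.018,0.64,mg_per_g,oil,FALSE,1,3,1,1,1,1,8
AI03,nimbolide,Azadirachta indica,TRUE,0.9–6.7 mg/g of leaf,TRUE,0.9,6.7,mg_per_g,leaf,FALSE,1,2,1,1,1,1,7
AI04,mahmoodin,Azadirachta indica,TRUE,Not determined,FALSE,,,,,FALSE,1,2,1,1,0,0,5
ZO01,12-gingerol,Zingiber officinale,TRUE,0.01–0.02 mg/g of rhizome,TRUE,0.01,0.02,mg_per_g,rhizome,FALSE,1,2,1,1,0,1,6
ZO02,10-gingerol,Zingiber officinale,TRUE,0.2–0.4 mg/g of rhizome,TRUE,0.2,0.4,mg_per_g,rhizome,FALSE,1,2,1,1,1,1,7
ZO03,8-gingerol,Zingiber officinale,TRUE,0.4–0.5 mg/g of rhizome,TRUE,0.4,0.5,mg_per_g,rhizome,FALSE,1,1,1,1,1,1,6
ZO04,6-gingerol,Zingiber officinale,TRUE,1.1–2.0 mg/g of rhizome,TRUE,1.1,2,mg_per_g,rhizome,FALSE,1,3,1,1,1,1,8
ZO05,6-shogaol,Zingiber officinale,TRUE,0.01–0.02 mg/g of rhizome,TRUE,0.01,0.02,mg_per_g,rhizome,FALSE,1,3,1,1,1,1,8
ZO06,zingerone,Zingiber officinale,TRUE,ND,FALSE,,,,,FALSE,1,2,0,0,1,1,5
WU01,bemadienolide,Warburgia ugandensis,TRUE,ND,FALSE,,,,,FALSE,1,0,0,0,0,0,1
WU02,muzigadial,Warburgia ugandensis,TRUE,ND,FALSE,,,,,FALSE,1,1,0,0,0,0,2
WU03,polygodial,Warburgia ugandensis,TRUE,ND,FALSE,,,,,FALSE,1,2,0,0,1,0,3
WU04,warbuganal,Warburgia ugandensis,TRUE,ND,FALSE,,,,,FALSE,1,1,0,0,0,0,2
WU05,warbugadione,Warburgia ugandensis,TRUE,ND,FALSE,,,,,FALSE,1,0,0,0,0,0,1
WU06,ugandensidial,Warburgia ugandensis,TRUE,ND,FALSE,,,,,FALSE,1,1,0,0,0,0,2
WU07,ugandensolide,Warburgia ugandensis,TRUE,ND,FALSE,,,,,FALSE,1,0,0,0,0,0,1
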