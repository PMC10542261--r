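compound_id,vendor,grade,pack_value,pack_unit,price_eur
EG01,Sigma-Aldrich/Supelco,analytical standard,5,mg,530
EG01,Sigma-Aldrich/Supelco,"HPLC grade, >=95%",10,mg,221
EG01,Sigma-Aldrich/Supelco,">=95%, LC/MS-ELSD",1,mg,421
EG02,Sigma-Aldrich/Supelco,"analytical standard, >=95%",100,mg,63.9
EG03,Sigma-Aldrich,">=98.5% (sum of enantiomers, GC)",100,mg,247
EG04,Sigma-Aldrich/Supelco,analytical standard,1,mL,48.3
AV01,Sigma-Aldrich,analytical standard,10,mg,440
AV02,Sigma-Aldrich,Phyproof reference substance,10,mg,605
AV03,Sigma-Aldrich,analytical standard,10,mg,311
AV04,Toronto Research Chemicals,technical grade,10,mg,208.3
AV05,Sigma-Aldrich,">=98% (HPLC), sodium salt",100,mg,354
AC01,Sigma-Aldrich,analytical standard,10,mg,130
AC02,Toronto Research Chemicals,analytical standard,2.5,mg,170
AC03,Sigma-Aldrich/Supelco,analytical standard,10,mg,95.1
AC03,Sigma-Aldrich/Supelco,>=98% (HPLC),5,mg,70
AC04,Sigma-Aldrich/Supelco,analytical standard,10,mg,307
MI01,Sigma-Aldrich/Supelco,analytical standard,10,mg,108
MI02,Sigma-Aldrich/Supelco,analytical standard,10,mg,307
MI04,Sigma-Aldrich,Phyproof reference substance,10,mg,345
MI05,Sigma-Aldrich,USP reference standard,200,mg,357
MI05,Sigma-Aldrich,Phyproof reference substance,20,mg,253
MI05,Sigma-Aldrich,>=95% (HPLC),10,g,68.3
AI01,Sigma-Aldrich,Phyproof reference substance,5,mg,403
AI01,Sigma-Aldrich,~95%,0.5,mg,249
AI02,Toronto Research Chemicals,analytical standard,1,mg,105
AI03,Sigma-Aldrich,>=98%,5,mg,624
ZO02,Sigma-Aldrich,analytical standard,10,mg,546
ZO02,Sigma-Aldrich,>=98% (HPLC),5,mg,276
ZO02,Sigma-Aldrich,Phyproof reference substance,10,mg,472
ZO03,Sigma-Aldrich/Supelco,analytical standard,10,mg,489
ZO04,Sigma-Aldrich,analytical standard,10,mg,448
ZO04,Sigma-Aldrich,>=98% (HPLC),5,mg,358
ZO04,Sigma-Aldrich,Phyproof reference substance,10,mg,472
ZO05,Sigma-Aldrich,analytical standard,10,mg,538
ZO05,Sigma-Aldrich,Phyproof reference substance,10,mg,657
ZO06,Sigma-Aldrich,analytical standard,50,mg,84.5
WU03,Sigma-Aldrich,>=97% (HPLC),10,mg,216
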