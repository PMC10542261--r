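compound_id,technique,matrix,citation
EG01,GC-FID/MS,essential oil,CR25; CR101
EG02,GC-FID/MS,essential oil,CR25; CR101
EG03,GC-FID/MS,essential oil,CR25; CR101
EG04,GC-FID/MS,essential oil,CR25; CR101
AV01,HPLC-DAD/MS,aloe whole-leaf products,CR102
AV02,HPLC-DAD/MS,aloe whole-leaf products,CR102
AV03,HPLC-DAD/MS,aloe whole-leaf products,CR102
AV04,size-exclusion chromatography,aloe gel,CR103
AV04,UV-Vis,aloe gel,CR104
AC01,HPLC-DAD,triterpenoids,CR105; CR106
AC02,HPLC-DAD,triterpenoids in Albizia inundata,CR107
AC03,HPLC-DAD,betulinic acid in Albizia lebbeck,CR108
AC04,HPLC-DAD,Albizia lebbeck,CR109
MI01,HPLC-UV,mangiferin,CR110
MI02,HPLC-UV,phenolic compounds,CR111
MI03,HPLC,epicatechin,CR112; CR113
MI04,HPLC-UV,phenolic compounds,CR111
MI05,HPLC-UV,phenolic compounds,CR111
AI01,HPLC-UV,azadirachtins,CR114
AI02,HPLC-UV,nimbin,CR115
AI03,HPLC-UV,nimbolide,CR116
ZO01,HPLC-MS,gingerols and related compounds,CR119
ZO02,HPLC-MS,gingerols and related compounds,CR117
ZO03,HPLC-MS,gingerols and related compounds,CR117
ZO04,HPLC-MS,gingerols and related compounds,CR117
ZO05,HPLC-MS,gingerols and related compounds,CR119
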