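compound_id,activity_name,symptoms_addressed,relevant_to_indication,mechanism,citations
EG01,anti-inflammatory / antioxidant,inflammation,TRUE,reactive-oxygen-species scavenging; metal-ion chelation,CR16
EG01,"antibacterial (S. aureus, S. mutans)",tooth decay,TRUE,inhibits biofilm formation,CR17
EG02,anti-inflammatory / analgesic,pain; inflammation,TRUE,"suppresses monocyte superoxide production; inhibits release of serotonin, histamine, bradykinin and prostaglandins",CR26; CR27
EG02,antibacterial,sore throat,TRUE,"bacterial membrane disruption, as 1,8-cineole",CR18
EG03,"antibacterial (K. pneumoniae, S. aureus, P. aeruginosa)",sore throat,TRUE,,CR24; CR25
EG04,antibacterial,sore throat,TRUE,disruption of the bacterial cell membrane,CR18
EG04,anti-asthma / anti-bronchitis,congestion from asthma; bronchitis,TRUE,"downregulates IL-1b and TNF-a; bronchial muscle relaxation, reduced mucus secretion",CR19
EG04,analgesic / sedative,pain,TRUE,CNS modulation of glutamatergic and dopaminergic systems,CR22; CR23
EG04,antispasmodic / gastroprotective,,FALSE,promotes regeneration of gastric cells,CR20
AV01,laxative,constipation; git cleansing,TRUE,inhibits the Na+/K+ pump and Cl- channels; stimulates mucus secretion,CR28; CR29
AV01,antibacterial (H. pylori),toothache,TRUE,activates phagocytic leukocytes,CR33; CR34
AV02,laxative,constipation; git cleansing,TRUE,inhibits the Na+/K+ pump and Cl- channels; stimulates mucus secretion,CR28; CR29
AV02,antibacterial (H. pylori),toothache,TRUE,activates phagocytic leukocytes,CR33; CR34
AV03,laxative,constipation,TRUE,increases gastric motility; stimulates secretion of mucus and chloride ions,CR28; CR29
AV03,antibacterial (H. pylori),toothache,TRUE,inhibits H. pylori N-acetyltransferase,CR33; CR34
AV04,wound healing,wounds,TRUE,activates macrophages to release fibrogenic cytokines,CR35; CR36
AV04,anti-inflammatory,cracked lips; dry lips,TRUE,inhibits thromboxane A2; cyclooxygenase pathway,CR30
AV05,wound healing,wounds,TRUE,enhances fibroblast activity,CR37; CR38
AC01,anti-inflammatory / analgesic,fever,TRUE,"reduces PGE2, TNF-a and IL-1b production",CR42; CR43
AC01,immunomodulating / anti-asthmatic,congestion from asthma,TRUE,reduces eosinophil production,CR44
AC01,antibacterial,sore throat,TRUE,,CR45; CR46
AC02,immunomodulating / anti-asthmatic,congestion from asthma,TRUE,reduces eosinophil production,CR44
AC03,anti-inflammatory / analgesic,fever,TRUE,inhibits nitric-oxide and COX-2 production,CR49; CR50
AC03,antibacterial,sore throat,TRUE,excess ROS production damages bacterial DNA,CR51; CR52
AC03,antiviral (herpes simplex),catarrh,TRUE,inhibits viral plaque formation,CR48; CR53
AC04,anti-inflammatory / antioxidant,catarrh,TRUE,radical scavenging; activates Nrf2-regulated antioxidant enzymes,CR54
AC04,immunomodulatory / anti-allergenic,congestion from asthma,TRUE,reduces TNF-a and IL-1b infiltration of lung tissue,CR55
AC04,"antiviral (influenza A, SARS-CoV-2)",fever,TRUE,inhibits viral receptor binding,CR56; CR57; CR58
MI01,antioxidant / anti-inflammatory / antipyretic,sore throat,TRUE,ROS scavenging; downregulates NF-kB phosphorylation,CR59; CR60
MI01,antiallergic / anti-asthmatic,congestion from asthma,TRUE,inhibits the nitric-oxide / cyclic-GMP pathway,CR61; CR62
MI01,antibacterial (S. aureus),catarrh,TRUE,,CR63; CR64
MI02,antiviral (influenza A and B),catarrh,TRUE,inhibits receptor binding and sialidase activity,CR58
MI02,anti-inflammatory,congestion from asthma,TRUE,"regulates TNF-a, NF-kB and COX-2 in lung tissue",CR67; CR68
MI02,anti-allergenic,sore throat,TRUE,,CR67
MI03,antiviral / anti-inflammatory,catarrh,TRUE,regulates proinflammatory agents in lung tissue,CR58; CR67
MI04,antioxidant / anti-inflammatory,sore throat,TRUE,ROS scavenging; metal-ion chelation,CR50
MI04,"antimicrobial (P. aeruginosa, S. aureus)",whooping cough,TRUE,inhibits motility and adherence; membrane disruption,CR69; CR70
MI04,antiviral (influenza A and B),catarrh,TRUE,disruption of viral particles,CR71
MI05,antioxidant / anti-inflammatory,congestion from asthma,TRUE,inhibits cyclooxygenase and lipoxygenase enzymes,CR72; CR73; CR74
MI05,immunomodulatory / anti-allergic,sore throat,TRUE,"inhibits IL-6, IL-8 and TNF-a",CR75
MI05,antibacterial / antiviral,bronchitis,TRUE,inhibits nucleic-acid synthesis; blocks influenza hemagglutinin,CR76; CR78; CR79
AI01,anti-inflammatory / antipyretic / antioxidant,flu,TRUE,inhibits COX and LOX; modulates NF-kB,CR80
AI01,anti-gastric ulcer / wound healing,gastric ulcers,TRUE,,CR80
AI01,"antibacterial (S. aureus, MRSA)",sore throat,TRUE,inhibits biofilm formation,CR81
AI02,antipyretic / anti-inflammatory,flu,TRUE,suppresses inflammatory cytokines from neutrophils and macrophages,CR82; CR83; CR84
AI02,anti-gastric ulcer,gastric ulcers,TRUE,inhibits histamine H2 and muscarinic receptors,CR85
AI02,immunomodulatory / anti-allergic,sinusitis,TRUE,inhibits macrophage migration,CR86
AI03,antibacterial,sore throat; sinusitis,TRUE,,CR87
AI04,anti-inflammatory / antibacterial,flu; sore throat,TRUE,,CR88
ZO01,antibacterial,sore throat; whooping cough,TRUE,inhibits biofilm formation,CR92; CR93
ZO02,antibacterial,flu; sore throat,TRUE,inhibits biofilm formation,CR92; CR94
ZO03,antibacterial,sore throat,TRUE,inhibits biofilm formation,CR92
ZO04,antioxidant / anti-inflammatory / analgesic,fever,TRUE,ROS scavenging; inhibits prostaglandin production,CR89; CR90
ZO04,anti-asthmatic / anti-allergen,bronchial asthma,TRUE,reduced Ca2+ influx; beta-2 receptor activation,CR91
ZO04,antibacterial,sore throat,TRUE,inhibits biofilm formation,CR92; CR93
ZO05,antioxidant / anti-inflammatory / analgesic,fever,TRUE,ROS scavenging; inhibits prostaglandin production,CR89; CR90
ZO05,anti-asthmatic,bronchial asthma,TRUE,reduced proinflammatory cytokine production,CR91
ZO05,antibacterial,flu,TRUE,,CR92
ZO06,anti-inflammatory / antioxidant,fever,TRUE,reduces ROS production; metal-ion chelation,CR97
ZO06,antibacterial,sore throat,TRUE,dihydropterin pyrophosphokinase inhibition,
WU02,antimycobacterial,cough,TRUE,,CR99
WU03,anti-inflammatory / anti-allergic,rhinitis,TRUE,inhibits phospholipase A2 and neuropeptide release,CR98
WU03,antibacterial,cough,TRUE,,CR100
WU04,antibacterial,cough,TRUE,,CR100
WU06,antibacterial,cough,TRUE,,CR100
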