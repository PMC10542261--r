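plant,condition,symptoms
Eucalyptus globulus,oral and dental disorders,toothache; bad odor; tooth sensitivity; bleeding gums; tooth cavities; tooth decay; mouth sores
Eucalyptus globulus,respiratory tract disorders,cough; common cold; catarrh; sore throat; congestion from asthma; bronchitis; whooping cough; sinusitis; rhinitis; hiccups; fever; measles symptoms
Eucalyptus globulus,pain and inflammation,pain; inflammation
Aloe vera,oral and dental disorders,toothache; bad odor; tooth sensitivity; bleeding gums; tooth cavities; tooth decay
Aloe vera,gastrointestinal disorders,constipation; git cleansing
Aloe vera,respiratory tract disorders,cough; flu; sore throat; sinusitis
Aloe vera,skin and lip conditions,dry lips; cracked lips; painful lips; wounds
Albizia coriaria,respiratory tract disorders,whooping cough; catarrh; sore throat; congestion from asthma; bronchitis; fever; sinusitis
Mangifera indica,respiratory tract disorders,whooping cough; catarrh; sore throat; congestion from asthma; bronchitis
Azadirachta indica,respiratory tract disorders,cough; flu; sore throat; sinusitis
Azadirachta indica,gastrointestinal disorders,gastric ulcers; stomach ulcers; flatulence; constipation
Azadirachta indica,skin and lip conditions,dry lips; cracked lips; painful lips
Zingiber officinale,respiratory tract disorders,allergic cough; smokers cough; whooping cough; productive cough; flu; lung cleaning; sore throat; sinusitis; bronchial asthma; fever
Warburgia ugandensis,respiratory tract disorders,cough; flu; mouth sores; measles symptoms; common colds; sinusitis; rhinitis; asthma; catarrh; whooping cough; bronchial congestion; hiccups
Warburgia ugandensis,gastrointestinal ulcers,git ulcers
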