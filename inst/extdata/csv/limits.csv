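scope,authority,analyte,limit_ppm,direction
AV01,International Aloe Science Council,total anthraquinone glycosides (as aloin),10,maximum
AV01,European Medicines Agency,total anthraquinone glycosides (as aloin),0,maximum
AV01,Food and Drug Administration,total anthraquinone glycosides (as aloin),0,maximum
AV02,International Aloe Science Council,total anthraquinone glycosides (as aloin),10,maximum
AV02,European Medicines Agency,total anthraquinone glycosides (as aloin),0,maximum
AV02,Food and Drug Administration,total anthraquinone glycosides (as aloin),0,maximum
AV03,International Aloe Science Council,total anthraquinone glycosides (as aloin),10,maximum
AV03,European Medicines Agency,total anthraquinone glycosides (as aloin),0,maximum
AV03,Food and Drug Administration,total anthraquinone glycosides (as aloin),0,maximum
dataset,International Aloe Science Council,total anthraquinone glycosides (as aloin),10,maximum
dataset,European Medicines Agency,total anthraquinone glycosides (as aloin),0,maximum
dataset,Food and Drug Administration,total anthraquinone glycosides (as aloin),0,maximum
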