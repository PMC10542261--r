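# Builds the packaged evidence dataset (seven Ugandan medicinal plants,
# 35 candidate-marker dossiers) and writes the canonical JSON plus the
# flattened CSV view under inst/extdata/.  Run from the package root:
#   Rscript data-raw/build-fixture.R

suppressMessages(devtools::load_all(".", quiet = TRUE))

# ---- plants -----------------------------------------------------------------

plants <- list(
  hm_plant(
    "Eucalyptus globulus", "Myrtaceae", "both",
    part_used = "leaf oil",
    dosage_forms = c("mouth wash", "cough syrup", "pain balm"),
    indications = list(
      hm_indication("oral and dental disorders",
                    c("toothache", "bad odor", "tooth sensitivity",
                      "bleeding gums", "tooth cavities", "tooth decay",
                      "mouth sores")),
      hm_indication("respiratory tract disorders",
                    c("cough", "common cold", "catarrh", "sore throat",
                      "congestion from asthma", "bronchitis",
                      "whooping cough", "sinusitis", "rhinitis", "hiccups",
                      "fever", "measles symptoms")),
      hm_indication("pain and inflammation", c("pain", "inflammation"))
    )
  ),
  hm_plant(
    "Aloe vera", "Asphodelaceae", "cultivated",
    part_used = c("whole leaf", "gel", "latex"),
    dosage_forms = c("mouth wash", "aloe tablets", "cough syrup",
                     "lip balm"),
    indications = list(
      hm_indication("oral and dental disorders",
                    c("toothache", "bad odor", "tooth sensitivity",
                      "bleeding gums", "tooth cavities", "tooth decay")),
      hm_indication("gastrointestinal disorders",
                    c("constipation", "git cleansing")),
      hm_indication("respiratory tract disorders",
                    c("cough", "flu", "sore throat", "sinusitis")),
      hm_indication("skin and lip conditions",
                    c("dry lips", "cracked lips", "painful lips", "wounds"))
    )
  ),
  hm_plant(
    "Albizia coriaria", "Fabaceae", "wild",
    part_used = "stem bark", dosage_forms = "cough syrup",
    indications = list(
      hm_indication("respiratory tract disorders",
                    c("whooping cough", "catarrh", "sore throat",
                      "congestion from asthma", "bronchitis", "fever",
                      "sinusitis"))
    )
  ),
  hm_plant(
    "Mangifera indica", "Anacardiaceae", "both",
    part_used = c("stem bark", "leaves"), dosage_forms = "cough syrup",
    indications = list(
      hm_indication("respiratory tract disorders",
                    c("whooping cough", "catarrh", "sore throat",
                      "congestion from asthma", "bronchitis"))
    )
  ),
  hm_plant(
    "Azadirachta indica", "Meliaceae", "both",
    part_used = c("stem bark", "leaves", "seed oil"),
    dosage_forms = c("cough syrup", "antiulcer syrup", "lip balm"),
    indications = list(
      hm_indication("respiratory tract disorders",
                    c("cough", "flu", "sore throat", "sinusitis")),
      hm_indication("gastrointestinal disorders",
                    c("gastric ulcers", "stomach ulcers", "flatulence",
                      "constipation")),
      hm_indication("skin and lip conditions",
                    c("dry lips", "cracked lips", "painful lips"))
    )
  ),
  hm_plant(
    "Zingiber officinale", "Zingiberaceae", "cultivated",
    part_used = "rhizome", dosage_forms = "cough syrup",
    indications = list(
      hm_indication("respiratory tract disorders",
                    c("allergic cough", "smokers cough", "whooping cough",
                      "productive cough", "flu", "lung cleaning",
                      "sore throat", "sinusitis", "bronchial asthma",
                      "fever"))
    )
  ),
  hm_plant(
    "Warburgia ugandensis", "Canellaceae", "both",
    part_used = c("stem bark", "leaves"),
    dosage_forms = c("cough syrup", "antiulcer syrup"),
    indications = list(
      hm_indication("respiratory tract disorders",
                    c("cough", "flu", "mouth sores", "measles symptoms",
                      "common colds", "sinusitis", "rhinitis", "asthma",
                      "catarrh", "whooping cough", "bronchial congestion",
                      "hiccups")),
      hm_indication("gastrointestinal ulcers", "git ulcers")
    )
  )
)

# ---- shorthands -------------------------------------------------------------

act <- hm_activity
std <- hm_standard_listing
met <- hm_method_listing

gc_oil <- list(met("GC-FID/MS", "essential oil", "CR25; CR101"))
aloe_hplc <- list(met("HPLC-DAD/MS", "aloe whole-leaf products", "CR102"))

aloin_limits <- list(
  hm_regulatory_limit("International Aloe Science Council",
                      "total anthraquinone glycosides (as aloin)", 10),
  hm_regulatory_limit("European Medicines Agency",
                      "total anthraquinone glycosides (as aloin)", 0),
  hm_regulatory_limit("Food and Drug Administration",
                      "total anthraquinone glycosides (as aloin)", 0)
)

rec <- function(id, name, plant, activities, conc_raw, standards, methods,
                printed, documented = TRUE, limits = list()) {
  hm_compound_record(
    compound_id = id, name = name, plant = plant,
    documented_constituent = documented, activities = activities,
    concentration = parse_concentration(conc_raw),
    standards = standards, methods = methods,
    negative_marker_limits = limits,
    recorded_components = do.call(hm_component_scores,
                                  as.list(printed[1:6])),
    recorded_total = printed[7]
  )
}

compounds <- list(

  # -- Eucalyptus globulus ----------------------------------------------------
  rec("EG01", "aromadendrine", "Eucalyptus globulus",
      list(act("anti-inflammatory / antioxidant", "inflammation",
               mechanism = "reactive-oxygen-species scavenging; metal-ion chelation",
               citations = "CR16"),
           act("antibacterial (S. aureus, S. mutans)", "tooth decay",
               mechanism = "inhibits biofilm formation", citations = "CR17")),
      "10–30% of essential oil",
      list(std("Sigma-Aldrich/Supelco", "analytical standard", 5, "mg", 530),
           std("Sigma-Aldrich/Supelco", "HPLC grade, >=95%", 10, "mg", 221),
           std("Sigma-Aldrich/Supelco", ">=95%, LC/MS-ELSD", 1, "mg", 421)),
      gc_oil, c(1, 2, 1, 1, 1, 1, 7)),

  rec("EG02", "α-terpineol", "Eucalyptus globulus",
      list(act("anti-inflammatory / analgesic", c("pain", "inflammation"),
               mechanism = "suppresses monocyte superoxide production; inhibits release of serotonin, histamine, bradykinin and prostaglandins",
               citations = c("CR26", "CR27")),
           act("antibacterial", "sore throat",
               mechanism = "bacterial membrane disruption, as 1,8-cineole",
               citations = "CR18")),
      "0.50% of essential oil",
      list(std("Sigma-Aldrich/Supelco", "analytical standard, >=95%",
               100, "mg", 63.9)),
      gc_oil, c(1, 3, 1, 1, 1, 1, 8)),

  rec("EG03", "globulol", "Eucalyptus globulus",
      list(act("antibacterial (K. pneumoniae, S. aureus, P. aeruginosa)",
               "sore throat", citations = c("CR24", "CR25"))),
      "10–11% of essential oil",
      list(std("Sigma-Aldrich", ">=98.5% (sum of enantiomers, GC)",
               100, "mg", 247)),
      gc_oil, c(1, 1, 1, 1, 1, 1, 6)),

  rec("EG04", "1,8-cineol", "Eucalyptus globulus",
      list(act("antibacterial", "sore throat",
               mechanism = "disruption of the bacterial cell membrane",
               citations = "CR18"),
           act("anti-asthma / anti-bronchitis",
               c("congestion from asthma", "bronchitis"),
               mechanism = "downregulates IL-1b and TNF-a; bronchial muscle relaxation, reduced mucus secretion",
               citations = "CR19"),
           act("analgesic / sedative", "pain",
               mechanism = "CNS modulation of glutamatergic and dopaminergic systems",
               citations = c("CR22", "CR23")),
           act("antispasmodic / gastroprotective", character(),
               relevant_to_indication = FALSE,
               mechanism = "promotes regeneration of gastric cells",
               citations = "CR20")),
      "97.32% of essential oil",
      list(std("Sigma-Aldrich/Supelco", "analytical standard", 1, "mL",
               48.3)),
      gc_oil, c(1, 3, 1, 1, 1, 1, 8)),

  # -- Aloe vera --------------------------------------------------------------
  rec("AV01", "aloin A", "Aloe vera",
      list(act("laxative", c("constipation", "git cleansing"),
               mechanism = "inhibits the Na+/K+ pump and Cl- channels; stimulates mucus secretion",
               citations = c("CR28", "CR29")),
           act("antibacterial (H. pylori)", "toothache",
               mechanism = "activates phagocytic leukocytes",
               citations = c("CR33", "CR34"))),
      "0.1–0.6% of leaf",
      list(std("Sigma-Aldrich", "analytical standard", 10, "mg", 440)),
      aloe_hplc, c(1, 3, 1, 1, 1, 1, 8), limits = aloin_limits),

  rec("AV02", "aloin B", "Aloe vera",
      list(act("laxative", c("constipation", "git cleansing"),
               mechanism = "inhibits the Na+/K+ pump and Cl- channels; stimulates mucus secretion",
               citations = c("CR28", "CR29")),
           act("antibacterial (H. pylori)", "toothache",
               mechanism = "activates phagocytic leukocytes",
               citations = c("CR33", "CR34"))),
      "0.1–0.6% of leaf",
      list(std("Sigma-Aldrich", "Phyproof reference substance", 10, "mg",
               605)),
      aloe_hplc, c(1, 3, 1, 1, 1, 1, 8), limits = aloin_limits),

  rec("AV03", "aloe emodin", "Aloe vera",
      list(act("laxative", "constipation",
               mechanism = "increases gastric motility; stimulates secretion of mucus and chloride ions",
               citations = c("CR28", "CR29")),
           act("antibacterial (H. pylori)", "toothache",
               mechanism = "inhibits H. pylori N-acetyltransferase",
               citations = c("CR33", "CR34"))),
      "0.09–0.29 mg/g of whole leaf",
      list(std("Sigma-Aldrich", "analytical standard", 10, "mg", 311)),
      aloe_hplc, c(1, 2, 1, 1, 1, 1, 7), limits = aloin_limits),

  rec("AV04", "acemannan", "Aloe vera",
      list(act("wound healing", "wounds",
               mechanism = "activates macrophages to release fibrogenic cytokines",
               citations = c("CR35", "CR36")),
           act("anti-inflammatory", c("cracked lips", "dry lips"),
               mechanism = "inhibits thromboxane A2; cyclooxygenase pathway",
               citations = "CR30")),
      "109–135 ppm of gel",
      list(std("Toronto Research Chemicals", "technical grade", 10, "mg",
               208.3)),
      list(met("size-exclusion chromatography", "aloe gel", "CR103"),
           met("UV-Vis", "aloe gel", "CR104")),
      c(1, 3, 1, 1, 1, 1, 8)),

  rec("AV05", "mannose 6-phosphate", "Aloe vera",
      list(act("wound healing", "wounds",
               mechanism = "enhances fibroblast activity",
               citations = c("CR37", "CR38"))),
      "ND",
      list(std("Sigma-Aldrich", ">=98% (HPLC), sodium salt", 100, "mg",
               354)),
      list(), c(1, 1, 0, 0, 1, 0, 3)),

  # -- Albizia coriaria -------------------------------------------------------
  rec("AC01", "lupeol", "Albizia coriaria",
      list(act("anti-inflammatory / analgesic", "fever",
               mechanism = "reduces PGE2, TNF-a and IL-1b production",
               citations = c("CR42", "CR43")),
           act("immunomodulating / anti-asthmatic", "congestion from asthma",
               mechanism = "reduces eosinophil production",
               citations = "CR44"),
           act("antibacterial", "sore throat",
               citations = c("CR45", "CR46"))),
      "1–6 mg/g of stem bark",
      list(std("Sigma-Aldrich", "analytical standard", 10, "mg", 130)),
      list(met("HPLC-DAD", "triterpenoids", "CR105; CR106")),
      c(1, 3, 1, 1, 1, 1, 8)),

  rec("AC02", "lupenone", "Albizia coriaria",
      list(act("immunomodulating / anti-asthmatic", "congestion from asthma",
               mechanism = "reduces eosinophil production",
               citations = "CR44")),
      "19–200 ppm of stem bark",
      list(std("Toronto Research Chemicals", "analytical standard",
               2.5, "mg", 170)),
      list(met("HPLC-DAD", "triterpenoids in Albizia inundata", "CR107")),
      c(1, 1, 1, 1, 1, 1, 6)),

  rec("AC03", "betulinic acid", "Albizia coriaria",
      list(act("anti-inflammatory / analgesic", "fever",
               mechanism = "inhibits nitric-oxide and COX-2 production",
               citations = c("CR49", "CR50")),
           act("antibacterial", "sore throat",
               mechanism = "excess ROS production damages bacterial DNA",
               citations = c("CR51", "CR52")),
           act("antiviral (herpes simplex)", "catarrh",
               mechanism = "inhibits viral plaque formation",
               citations = c("CR48", "CR53"))),
      "1.2–10 mg/g of stem bark",
      list(std("Sigma-Aldrich/Supelco", "analytical standard", 10, "mg",
               95.1),
           std("Sigma-Aldrich/Supelco", ">=98% (HPLC)", 5, "mg", 70)),
      list(met("HPLC-DAD", "betulinic acid in Albizia lebbeck", "CR108")),
      c(1, 3, 1, 1, 1, 1, 8)),

  rec("AC04", "catechin", "Albizia coriaria",
      list(act("anti-inflammatory / antioxidant", "catarrh",
               mechanism = "radical scavenging; activates Nrf2-regulated antioxidant enzymes",
               citations = "CR54"),
           act("immunomodulatory / anti-allergenic", "congestion from asthma",
               mechanism = "reduces TNF-a and IL-1b infiltration of lung tissue",
               citations = "CR55"),
           act("antiviral (influenza A, SARS-CoV-2)", "fever",
               mechanism = "inhibits viral receptor binding",
               citations = c("CR56", "CR57", "CR58"))),
      "0.2–12 mg/g of stem bark",
      list(std("Sigma-Aldrich/Supelco", "analytical standard", 10, "mg",
               307)),
      list(met("HPLC-DAD", "Albizia lebbeck", "CR109")),
      c(1, 3, 1, 1, 1, 1, 8)),

  # -- Mangifera indica -------------------------------------------------------
  rec("MI01", "mangiferin", "Mangifera indica",
      list(act("antioxidant / anti-inflammatory / antipyretic", "sore throat",
               mechanism = "ROS scavenging; downregulates NF-kB phosphorylation",
               citations = c("CR59", "CR60")),
           act("antiallergic / anti-asthmatic", "congestion from asthma",
               mechanism = "inhibits the nitric-oxide / cyclic-GMP pathway",
               citations = c("CR61", "CR62")),
           act("antibacterial (S. aureus)", "catarrh",
               citations = c("CR63", "CR64"))),
      "5–20 mg/g of leaves",
      list(std("Sigma-Aldrich/Supelco", "analytical standard", 10, "mg",
               108)),
      list(met("HPLC-UV", "mangiferin", "CR110")),
      c(1, 3, 1, 1, 1, 1, 8)),

  rec("MI02", "catechin", "Mangifera indica",
      list(act("antiviral (influenza A and B)", "catarrh",
               mechanism = "inhibits receptor binding and sialidase activity",
               citations = "CR58"),
           act("anti-inflammatory", "congestion from asthma",
               mechanism = "regulates TNF-a, NF-kB and COX-2 in lung tissue",
               citations = c("CR67", "CR68")),
           act("anti-allergenic", "sore throat", citations = "CR67")),
      "71.4 mg/g of stem bark",
      list(std("Sigma-Aldrich/Supelco", "analytical standard", 10, "mg",
               307)),
      list(met("HPLC-UV", "phenolic compounds", "CR111")),
      c(1, 3, 1, 1, 1, 1, 8)),

  rec("MI03", "epicatechin", "Mangifera indica",
      list(act("antiviral / anti-inflammatory", "catarrh",
               mechanism = "regulates proinflammatory agents in lung tissue",
               citations = c("CR58", "CR67"))),
      "8.07 mg/g of stem bark",
      list(),
      list(met("HPLC", "epicatechin", "CR112; CR113")),
      c(1, 1, 1, 1, 0, 1, 5)),

  rec("MI04", "gallic acid", "Mangifera indica",
      list(act("antioxidant / anti-inflammatory", "sore throat",
               mechanism = "ROS scavenging; metal-ion chelation",
               citations = "CR50"),
           act("antimicrobial (P. aeruginosa, S. aureus)", "whooping cough",
               mechanism = "inhibits motility and adherence; membrane disruption",
               citations = c("CR69", "CR70")),
           act("antiviral (influenza A and B)", "catarrh",
               mechanism = "disruption of viral particles",
               citations = "CR71")),
      "2.08 mg/g of stem bark",
      list(std("Sigma-Aldrich", "Phyproof reference substance", 10, "mg",
               345)),
      list(met("HPLC-UV", "phenolic compounds", "CR111")),
      c(1, 3, 1, 1, 1, 1, 8)),

  rec("MI05", "quercetin", "Mangifera indica",
      list(act("antioxidant / anti-inflammatory", "congestion from asthma",
               mechanism = "inhibits cyclooxygenase and lipoxygenase enzymes",
               citations = c("CR72", "CR73", "CR74")),
           act("immunomodulatory / anti-allergic", "sore throat",
               mechanism = "inhibits IL-6, IL-8 and TNF-a",
               citations = "CR75"),
           act("antibacterial / antiviral", "bronchitis",
               mechanism = "inhibits nucleic-acid synthesis; blocks influenza hemagglutinin",
               citations = c("CR76", "CR78", "CR79"))),
      "0.76 to 1.16 mg/g of leaves",
      list(std("Sigma-Aldrich", "USP reference standard", 200, "mg", 357),
           std("Sigma-Aldrich", "Phyproof reference substance", 20, "mg",
               253),
           std("Sigma-Aldrich", ">=95% (HPLC)", 10, "g", 68.3)),
      list(met("HPLC-UV", "phenolic compounds", "CR111")),
      c(1, 3, 1, 1, 1, 1, 8)),

  # -- Azadirachta indica -----------------------------------------------------
  rec("AI01", "azadirachtin", "Azadirachta indica",
      list(act("anti-inflammatory / antipyretic / antioxidant", "flu",
               mechanism = "inhibits COX and LOX; modulates NF-kB",
               citations = "CR80"),
           act("anti-gastric ulcer / wound healing", "gastric ulcers",
               citations = "CR80"),
           act("antibacterial (S. aureus, MRSA)", "sore throat",
               mechanism = "inhibits biofilm formation",
               citations = "CR81")),
      "3.8 to 4.8 mg/g of seeds",
      list(std("Sigma-Aldrich", "Phyproof reference substance", 5, "mg",
               403),
           std("Sigma-Aldrich", "~95%", 0.5, "mg", 249)),
      list(met("HPLC-UV", "azadirachtins", "CR114")),
      c(1, 3, 1, 1, 1, 1, 8)),

  rec("AI02", "nimbin", "Azadirachta indica",
      list(act("antipyretic / anti-inflammatory", "flu",
               mechanism = "suppresses inflammatory cytokines from neutrophils and macrophages",
               citations = c("CR82", "CR83", "CR84")),
           act("anti-gastric ulcer", "gastric ulcers",
               mechanism = "inhibits histamine H2 and muscarinic receptors",
               citations = "CR85"),
           act("immunomodulatory / anti-allergic", "sinusitis",
               mechanism = "inhibits macrophage migration",
               citations = "CR86")),
      "0.018 to 0.64 mg/g of oil",
      list(std("Toronto Research Chemicals", "analytical standard", 1, "mg",
               105)),
      list(met("HPLC-UV", "nimbin", "CR115")),
      c(1, 3, 1, 1, 1, 1, 8)),

  rec("AI03", "nimbolide", "Azadirachta indica",
      list(act("antibacterial", c("sore throat", "sinusitis"),
               citations = "CR87")),
      "0.9–6.7 mg/g of leaf",
      list(std("Sigma-Aldrich", ">=98%", 5, "mg", 624)),
      list(met("HPLC-UV", "nimbolide", "CR116")),
      c(1, 2, 1, 1, 1, 1, 7)),

  rec("AI04", "mahmoodin", "Azadirachta indica",
      list(act("anti-inflammatory / antibacterial", c("flu", "sore throat"),
               citations = "CR88")),
      "Not determined",
      list(), list(), c(1, 2, 1, 1, 0, 0, 5)),

  # -- Zingiber officinale ----------------------------------------------------
  rec("ZO01", "12-gingerol", "Zingiber officinale",
      list(act("antibacterial", c("sore throat", "whooping cough"),
               mechanism = "inhibits biofilm formation",
               citations = c("CR92", "CR93"))),
      "0.01–0.02 mg/g of rhizome",
      list(),
      list(met("HPLC-MS", "gingerols and related compounds", "CR119")),
      c(1, 2, 1, 1, 0, 1, 6)),

  rec("ZO02", "10-gingerol", "Zingiber officinale",
      list(act("antibacterial", c("flu", "sore throat"),
               mechanism = "inhibits biofilm formation",
               citations = c("CR92", "CR94"))),
      "0.2–0.4 mg/g of rhizome",
      list(std("Sigma-Aldrich", "analytical standard", 10, "mg", 546),
           std("Sigma-Aldrich", ">=98% (HPLC)", 5, "mg", 276),
           std("Sigma-Aldrich", "Phyproof reference substance", 10, "mg",
               472)),
      list(met("HPLC-MS", "gingerols and related compounds", "CR117")),
      c(1, 2, 1, 1, 1, 1, 7)),

  rec("ZO03", "8-gingerol", "Zingiber officinale",
      list(act("antibacterial", "sore throat",
               mechanism = "inhibits biofilm formation",
               citations = "CR92")),
      "0.4–0.5 mg/g of rhizome",
      list(std("Sigma-Aldrich/Supelco", "analytical standard", 10, "mg",
               489)),
      list(met("HPLC-MS", "gingerols and related compounds", "CR117")),
      c(1, 1, 1, 1, 1, 1, 6)),

  rec("ZO04", "6-gingerol", "Zingiber officinale",
      list(act("antioxidant / anti-inflammatory / analgesic", "fever",
               mechanism = "ROS scavenging; inhibits prostaglandin production",
               citations = c("CR89", "CR90")),
           act("anti-asthmatic / anti-allergen", "bronchial asthma",
               mechanism = "reduced Ca2+ influx; beta-2 receptor activation",
               citations = "CR91"),
           act("antibacterial", "sore throat",
               mechanism = "inhibits biofilm formation",
               citations = c("CR92", "CR93"))),
      "1.1–2.0 mg/g of rhizome",
      list(std("Sigma-Aldrich", "analytical standard", 10, "mg", 448),
           std("Sigma-Aldrich", ">=98% (HPLC)", 5, "mg", 358),
           std("Sigma-Aldrich", "Phyproof reference substance", 10, "mg",
               472)),
      list(met("HPLC-MS", "gingerols and related compounds", "CR117")),
      c(1, 3, 1, 1, 1, 1, 8)),

  rec("ZO05", "6-shogaol", "Zingiber officinale",
      list(act("antioxidant / anti-inflammatory / analgesic", "fever",
               mechanism = "ROS scavenging; inhibits prostaglandin production",
               citations = c("CR89", "CR90")),
           act("anti-asthmatic", "bronchial asthma",
               mechanism = "reduced proinflammatory cytokine production",
               citations = "CR91"),
           act("antibacterial", "flu", citations = "CR92")),
      "0.01–0.02 mg/g of rhizome",
      list(std("Sigma-Aldrich", "analytical standard", 10, "mg", 538),
           std("Sigma-Aldrich", "Phyproof reference substance", 10, "mg",
               657)),
      list(met("HPLC-MS", "gingerols and related compounds", "CR119")),
      c(1, 3, 1, 1, 1, 1, 8)),

  rec("ZO06", "zingerone", "Zingiber officinale",
      list(act("anti-inflammatory / antioxidant", "fever",
               mechanism = "reduces ROS production; metal-ion chelation",
               citations = "CR97"),
           act("antibacterial", "sore throat",
               mechanism = "dihydropterin pyrophosphokinase inhibition")),
      "ND",
      list(std("Sigma-Aldrich", "analytical standard", 50, "mg", 84.5)),
      list(), c(1, 2, 0, 0, 1, 1, 5)),

  # -- Warburgia ugandensis ---------------------------------------------------
  rec("WU01", "bemadienolide", "Warburgia ugandensis",
      list(), "ND", list(), list(), c(1, 0, 0, 0, 0, 0, 1)),

  rec("WU02", "muzigadial", "Warburgia ugandensis",
      list(act("antimycobacterial", "cough", citations = "CR99")),
      "ND", list(), list(), c(1, 1, 0, 0, 0, 0, 2)),

  rec("WU03", "polygodial", "Warburgia ugandensis",
      list(act("anti-inflammatory / anti-allergic", "rhinitis",
               mechanism = "inhibits phospholipase A2 and neuropeptide release",
               citations = "CR98"),
           act("antibacterial", "cough", citations = "CR100")),
      "ND",
      list(std("Sigma-Aldrich", ">=97% (HPLC)", 10, "mg", 216)),
      list(), c(1, 2, 0, 0, 1, 0, 3)),

  rec("WU04", "warbuganal", "Warburgia ugandensis",
      list(act("antibacterial", "cough", citations = "CR100")),
      "ND", list(), list(), c(1, 1, 0, 0, 0, 0, 2)),

  rec("WU05", "warbugadione", "Warburgia ugandensis",
      list(), "ND", list(), list(), c(1, 0, 0, 0, 0, 0, 1)),

  rec("WU06", "ugandensidial", "Warburgia ugandensis",
      list(act("antibacterial", "cough", citations = "CR100")),
      "ND", list(), list(), c(1, 1, 0, 0, 0, 0, 2)),

  rec("WU07", "ugandensolide", "Warburgia ugandensis",
      list(), "ND", list(), list(), c(1, 0, 0, 0, 0, 0, 1))
)

doc <- hm_dataset(plants = plants, compounds = compounds,
                  limits = aloin_limits)

viol <- validate_dataset(doc)
if (length(viol)) stop(paste(viol, collapse = "\n"))
stopifnot(length(doc$plants) == 7L, length(doc$compounds) == 35L)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_dataset(doc, "inst/extdata/herbmars-tables.json", "json")
write_dataset(doc, "inst/extdata/csv", "csv")
message("fixture written: inst/extdata/herbmars-tables.json + csv view")
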