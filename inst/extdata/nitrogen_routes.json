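{
  "comment": "Declarative nitrogen-assimilation routes, nitrogen-cycle modules and amino-acid biosynthesis pathways for oligotrophic surface-ocean microbial communities. Enzyme ids are gene symbols; the vocabulary maps each symbol to an optional KEGG Orthology alias (null where no single KO applies). Human-editable.",
  "vocabulary": {
    "urease": "K01428",
    "nitrilase": "K01501",
    "gdhA": "K00262",
    "amt": "K03320",
    "nrtP": "K15577",
    "NirA": "K00366",
    "nitronate_monooxygenase": "K00459",
    "cyanate_lyase": "K01725",
    "formamidase": "K01455",
    "NarB": "K00367",
    "nasA": "K00372",
    "nifH": "K02588",
    "narG": "K00370",
    "napA": "K02567",
    "nirK": "K00368",
    "nirS": "K15864",
    "norB": "K04561",
    "nosZ": "K00376",
    "amoA": "K10944",
    "hao": "K10535",
    "hzsA": "K20932",
    "hdh": "K20935",
    "metC": "K01760",
    "metH": "K00548",
    "serC": "K00831",
    "serB": "K01079",
    "ltaE": "K01620",
    "glyA": "K00600",
    "asdA": null,
    "ALT": "K00814",
    "tyrB": "K00832",
    "tyrC": null,
    "pheA2": null,
    "betT": null,
    "betS": null,
    "ala_gly_symporter": "K03310",
    "ilvD": "K01687",
    "leuB": "K00052",
    "ilvA": "K01754",
    "trpB": "K01696",
    "proC": "K00286",
    "thrC": "K01733",
    "cysK": "K01738",
    "asnB": "K01953",
    "glnA": "K01915",
    "aspC": "K00812",
    "gltB": "K00265",
    "lysA": "K01586",
    "argH": "K01755",
    "hisD": "K00013"
  },
  "routes": [
    {"route_id": "urea_hydrolysis", "steps": [["urease"]]},
    {"route_id": "nitrile_hydrolysis", "steps": [["nitrilase"]]},
    {"route_id": "glutamate_deamination", "steps": [["gdhA"]]},
    {"route_id": "ammonium_import", "steps": [["amt"]]},
    {"route_id": "nitrite_reduction", "steps": [["nrtP", "nitronate_monooxygenase"], ["NirA"]]},
    {"route_id": "cyanate_lysis", "steps": [["cyanate_lyase"]]}
  ],
  "modules": [
    {"module_id": "dissimilatory_nitrate_reduction", "markers": ["narG", "napA"]},
    {"module_id": "assimilatory_nitrate_reduction", "markers": ["NarB", "nasA", "NirA"]},
    {"module_id": "denitrification", "markers": ["nirK", "nirS", "norB", "nosZ"]},
    {"module_id": "nitrification", "markers": ["amoA", "hao"]},
    {"module_id": "nitrogen_fixation", "markers": ["nifH"]},
    {"module_id": "anammox", "markers": ["hzsA", "hdh"]}
  ],
  "aa_pathways": [
    {"amino_acid": "Ala", "routes": [[["asdA", "ALT"]]]},
    {"amino_acid": "Arg", "routes": [[["argH"]]]},
    {"amino_acid": "Asn", "routes": [[["asnB"]]]},
    {"amino_acid": "Asp", "routes": [[["aspC"]]]},
    {"amino_acid": "Cys", "routes": [[["cysK"]]]},
    {"amino_acid": "Gln", "routes": [[["glnA"]]]},
    {"amino_acid": "Glu", "routes": [[["gltB"]]]},
    {"amino_acid": "Gly", "routes": [[["serC"], ["serB"], ["glyA"]], [["ltaE"]]]},
    {"amino_acid": "His", "routes": [[["hisD"]]]},
    {"amino_acid": "Ile", "routes": [[["ilvA"]]]},
    {"amino_acid": "Leu", "routes": [[["leuB"]]]},
    {"amino_acid": "Lys", "routes": [[["lysA"]]]},
    {"amino_acid": "Met", "routes": [[["metC"], ["metH"]]]},
    {"amino_acid": "Phe", "routes": [[["pheA2"], ["tyrB"]]]},
    {"amino_acid": "Pro", "routes": [[["proC"]]]},
    {"amino_acid": "Ser", "routes": [[["serC"], ["serB"]]]},
    {"amino_acid": "Thr", "routes": [[["thrC"]]]},
    {"amino_acid": "Trp", "routes": [[["trpB"]]]},
    {"amino_acid": "Tyr", "routes": [[["tyrC"], ["tyrB"]]]},
    {"amino_acid": "Val", "routes": [[["ilvD"]]]}
  ],
  "conversions": [
    {"enzyme": "glyA", "between": ["Ser", "Gly"]},
    {"enzyme": "ltaE", "between": ["Gly", "Thr"]}
  ],
  "transporters": {
    "Gly": ["betT", "betS"],
    "Ala": ["ala_gly_symporter"]
  }
}
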