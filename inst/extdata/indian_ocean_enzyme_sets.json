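{
  "comment": "Published presence/absence patterns of nitrogen-metabolism enzymes and amino-acid biosynthesis key enzymes reported for oligotrophic Indian Ocean surface waters: the whole-community metagenome and the Prochlorococcus population extracted from it. Used as worked-example inputs for the pathway engine.",
  "prochlorococcus_metagenome": {
    "present": ["urease", "nitrilase", "gdhA", "amt", "nrtP", "NirA",
                "nitronate_monooxygenase", "cyanate_lyase"],
    "aa_enzymes_absent": ["metC", "serB", "ltaE", "asdA", "ALT", "tyrB"],
    "transporters": ["betT", "betS", "ala_gly_symporter"]
  },
  "community_metagenome": {
    "present": ["urease", "nitrilase", "gdhA", "amt", "nrtP", "NirA",
                "nitronate_monooxygenase", "cyanate_lyase", "formamidase",
                "NarB", "nasA", "narG", "nirK", "norB", "nosZ",
                "amoA", "hao"]
  }
}
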